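# Small programmatic fixtures shared across test files.

make_volume <- function(values, shape = NULL, spacing = c(1, 1, 1)) {
  if (is.null(shape)) shape <- dim(values)
  volume_grid(array(values, shape), spacing)
}

full_mask <- function(shape) roi_mask(array(TRUE, shape))

# Random ROI on a small grid: random values, random mask of given density.
random_roi <- function(seed, max_dim = 6L, density = 0.7, integer_values = TRUE) {
  set.seed(seed)
  shape <- sample(2:max_dim, 3L, replace = TRUE)
  vals <- if (integer_values) {
    array(sample(-50:80, prod(shape), replace = TRUE), shape)
  } else {
    array(rnorm(prod(shape), 0, 40), shape)
  }
  m <- array(runif(prod(shape)) < density, shape)
  if (sum(m) < 2L) m[1:2] <- TRUE
  list(volume = volume_grid(vals, c(1, 1, 1)), mask = roi_mask(m))
}

# quantized_roi built directly from a label array (NA = outside ROI)
as_quantized <- function(lab, levels) {
  structure(list(labels = lab, levels = as.integer(levels)),
            class = "quantized_roi")
}

# glcm_matrix wrapper for a hand-built probability matrix
as_glcm <- function(P, symmetrize = TRUE) {
  structure(list(P = P, levels = nrow(P), offset = c(1L, 0L, 0L),
                 symmetrize = symmetrize, n_pairs = NA_integer_),
            class = "glcm_matrix")
}

dice <- function(a, b) 2 * sum(a$mask & b$mask) / (a$size + b$size)
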