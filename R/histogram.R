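#' Intensity-histogram features of an ROI
#'
#' Computes the eight first-order density features of a region of interest:
#' mean, median, standard deviation, variance, skewness, kurtosis, entropy
#' and energy. Moments use the population convention (divide by |Omega|);
#' the median for an even count is the lower-middle order statistic. Entropy
#' (base-2 log) and energy are computed from the normalized histogram with
#' one bin per integer HU (values are rounded to integers first, matching
#' the integer-valued CT scale). For a constant ROI (sigma = 0) skewness and
#' kurtosis are reported as 0.
#'
#' @param volume a [volume_grid()].
#' @param mask a nonempty [roi_mask()] on the same grid.
#' @param kurtosis_denominator `"sigma4"` (standard non-excess kurtosis,
#'   default) or `"sigma3"` (reproduces a dimensionally inconsistent printed
#'   variant).
#' @return A named list of class `histogram_features` with the eight scalars:
#'   `Mean`, `Median`, `Stddev`, `Variance`, `Skewness`, `Kurtosis`,
#'   `Entropy`, `Energy`.
#' @examples
#' v <- volume_grid(array(c(-2, 0, 2, 0, 0, 0, 0, 0), c(2, 2, 2)))
#' m <- array(FALSE, c(2, 2, 2)); m[1:3] <- TRUE
#' histogram_features(v, roi_mask(m))$Variance  # 8/3
#' @export
histogram_features <- function(volume, mask,
                               kurtosis_denominator = c("sigma4", "sigma3")) {
  kurtosis_denominator <- match.arg(kurtosis_denominator)
  x <- roi_values(volume, mask)
  n <- length(x)
  mu <- mean(x)
  vr <- mean((x - mu)^2)
  sg <- sqrt(vr)
  if (sg > 0) {
    skw <- mean((x - mu)^3) / sg^3
    kden <- if (kurtosis_denominator == "sigma4") sg^4 else sg^3
    krt <- mean((x - mu)^4) / kden
  } else {
    skw <- 0
    krt <- 0
  }
  xs <- sort(x)
  med <- xs[(n + 1L) %/% 2L]
  p <- tabulate(round(x) - min(round(x)) + 1L)
  p <- p[p > 0] / n
  ent <- -sum(p * log2(p))
  eng <- sum(p^2)
  structure(
    list(Mean = mu, Median = med, Stddev = sg, Variance = vr,
         Skewness = skw, Kurtosis = krt, Entropy = ent, Energy = eng),
    class = "histogram_features"
  )
}

#' @export
print.histogram_features <- function(x, ...) {
  cat("<histogram_features>\n")
  for (nm in names(x)) cat(sprintf("  %-9s %g\n", nm, x[[nm]]))
  invisible(x)
}

histogram_feature_names <- c("Mean", "Median", "Stddev", "Variance",
                             "Skewness", "Kurtosis", "Entropy", "Energy")
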