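#' Canonical 3D co-occurrence offsets
#'
#' The 26-neighbourhood of a voxel contains 13 antipodal displacement pairs;
#' one representative per pair (canonical sign: first nonzero component
#' positive) gives the 13 offsets at which 3D GLCMs are computed.
#'
#' @return A 13 x 3 integer matrix of displacement vectors.
#' @examples
#' nrow(glcm_offsets())  # 13
#' @export
glcm_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  canonical <- apply(g, 1, function(d) d[which(d != 0)[1]] > 0)
  out <- g[canonical, , drop = FALSE]
  rownames(out) <- apply(out, 1, paste, collapse = ",")
  out
}

#' Quantize ROI intensities to gray levels
#'
#' Equal-width binning of the ROI's intensities over its own \[min, max\]
#' range into `levels` bins: label = floor((v - min)/w) + 1 clamped to
#' `levels`, so the maximum maps to the top level and a constant ROI maps
#' entirely to level 1.
#'
#' @param volume a [volume_grid()].
#' @param mask a nonempty [roi_mask()].
#' @param levels number of gray levels (>= 2).
#' @return An object of class `quantized_roi`: list with `labels` (integer
#'   array, `NA` outside the mask) and `levels`.
#' @export
quantize_roi <- function(volume, mask, levels) {
  check_mask_on_volume(volume, mask)
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  x <- volume$values[mask$mask]
  lo <- min(x); hi <- max(x)
  lab <- array(NA_integer_, volume$shape)
  if (hi == lo) {
    lab[mask$mask] <- 1L
  } else {
    w <- (hi - lo) / levels
    lab[mask$mask] <- pmin(as.integer(floor((x - lo) / w)) + 1L, levels)
  }
  structure(list(labels = lab, levels = levels), class = "quantized_roi")
}

#' Gray-level co-occurrence matrix for one offset
#'
#' Counts ordered voxel pairs (x, x + offset) whose both endpoints belong to
#' the ROI, optionally adds the transpose (symmetrization, the Haralick
#' convention under which the 26 neighbour directions collapse to 13), and
#' normalizes to a probability matrix.
#'
#' @param labels a `quantized_roi` from [quantize_roi()].
#' @param offset integer displacement vector of length 3.
#' @param symmetrize add the transpose before normalization (default `TRUE`).
#' @return An object of class `glcm_matrix`: list with `P` (levels x levels,
#'   sums to 1), `levels`, `offset`, `symmetrize`, `n_pairs` (ordered pairs
#'   counted before symmetrization).
#' @export
compute_glcm <- function(labels, offset, symmetrize = TRUE) {
  stopifnot(inherits(labels, "quantized_roi"))
  offset <- as.integer(offset)
  stopifnot(length(offset) == 3L)
  lab <- labels$labels
  L <- labels$levels
  dm <- dim(lab)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    d <- offset[ax]
    if (abs(d) >= dm[ax]) stop("no valid pairs: offset exceeds ROI extent")
    if (d >= 0) {
      src[[ax]] <- seq_len(dm[ax] - d)
      dst[[ax]] <- seq_len(dm[ax] - d) + d
    } else {
      src[[ax]] <- seq_len(dm[ax] + d) - d
      dst[[ax]] <- seq_len(dm[ax] + d)
    }
  }
  a <- lab[src[[1]], src[[2]], src[[3]]]
  b <- lab[dst[[1]], dst[[2]], dst[[3]]]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok))
    stop("no valid pairs: offset (", paste(offset, collapse = ","),
         ") finds no co-occurring voxel pair in the ROI")
  counts <- tabulate((a[ok] - 1L) * L + b[ok], nbins = L * L)
  P <- matrix(counts, L, L, byrow = TRUE)
  n_pairs <- sum(counts)
  if (symmetrize) P <- P + t(P)
  P <- P / sum(P)
  structure(
    list(P = P, levels = L, offset = offset, symmetrize = symmetrize,
         n_pairs = n_pairs),
    class = "glcm_matrix"
  )
}

#' @export
print.glcm_matrix <- function(x, ...) {
  cat("<glcm_matrix> ", x$levels, " levels, offset (",
      paste(x$offset, collapse = ","), "), ",
      if (x$symmetrize) "symmetrized, " else "asymmetric, ",
      x$n_pairs, " pairs\n", sep = "")
  invisible(x)
}

glcm_feature_names <- c(
  "Mean", "Variance", "Energy", "Entropy", "Contrast", "Correlation",
  "Dissimilarity", "Homogeneity", "Information correlation A",
  "Information correlation B", "Maximal correlation coefficient",
  "Diff average", "Diff variance", "Diff entropy",
  "Sum average", "Sum variance", "Sum entropy", "Angular 2nd moment"
)

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)  # 0 log 0 := 0

#' All 18 GLCM features of one co-occurrence matrix
#'
#' Evaluates the Haralick-style feature set on a normalized GLCM with 1-based
#' level indices. Entropy-family features use the natural log; 0 log 0 := 0.
#' Degenerate-distribution policies: correlation := 0 when sigma_x sigma_y
#' = 0; information correlation A := 0 when max(Hx, Hy) = 0; the maximal
#' correlation coefficient (second-largest eigenvalue of the MCC kernel
#' U = Dx^-1 P Dy^-1 P^T restricted to nonzero marginals) is 0 when fewer
#' than two levels are occupied.
#'
#' Two printed-form variants are exposed: `icb_sqrt` applies the classical
#' square root to information correlation B (default reports
#' 1 - exp(-2 (Hxy2 - Hxy)) directly), and `mcc_sqrt` reports the square root
#' of the second-largest eigenvalue rather than the eigenvalue itself.
#'
#' @param m a `glcm_matrix` from [compute_glcm()].
#' @param icb_sqrt,mcc_sqrt logical; classical square-root variants.
#' @return Named numeric vector over [glcm_feature_names].
#' @export
glcm_features <- function(m, icb_sqrt = FALSE, mcc_sqrt = FALSE) {
  stopifnot(inherits(m, "glcm_matrix"))
  P <- m$P
  L <- m$levels
  i <- seq_len(L)
  Px <- rowSums(P)
  Py <- colSums(P)
  mux <- sum(i * Px); muy <- sum(i * Py)
  vx <- sum((i - mux)^2 * Px); vy <- sum((i - muy)^2 * Py)
  sx <- sqrt(vx); sy <- sqrt(vy)

  # cross-difference P_{x-y}(k), k = 0..L-1, and cross-sum P_{x+y}(k), k = 2..2L
  dif <- abs(row(P) - col(P))
  Pxmy <- as.numeric(rowsum(as.vector(P), as.vector(dif)))
  kd <- sort(unique(as.vector(dif)))         # 0..L-1
  Pxpy <- as.numeric(rowsum(as.vector(P), as.vector(row(P) + col(P))))
  ks <- sort(unique(as.vector(row(P) + col(P))))  # 2..2L

  energy <- sum(P^2)
  Hxy <- -sum(xlogx(P))
  Hx <- -sum(xlogx(Px))
  Hy <- -sum(xlogx(Py))
  PxPy <- outer(Px, Py)
  pos <- P > 0                      # P(i,j) > 0 implies Px(i)Py(j) > 0
  Hxy1 <- -sum(P[pos] * log(PxPy[pos]))
  Hxy2 <- -sum(xlogx(PxPy))

  contrast <- sum(kd^2 * Pxmy)
  dissim <- sum(kd * Pxmy)
  homog <- sum(Pxmy / (1 + kd^2))
  corr <- if (sx * sy > 0) (sum(row(P) * col(P) * P) - mux * muy) / (sx * sy) else 0
  ica <- if (max(Hx, Hy) > 0) (Hxy - Hxy1) / max(Hx, Hy) else 0
  icb <- 1 - exp(-2 * (Hxy2 - Hxy))
  if (icb_sqrt) icb <- sqrt(max(0, icb))

  mu_d <- sum(kd * Pxmy)
  var_d <- sum((kd - mu_d)^2 * Pxmy)
  ent_d <- -sum(xlogx(Pxmy))
  mu_s <- sum(ks * Pxpy)
  var_s <- sum((ks - mu_s)^2 * Pxpy)
  ent_s <- -sum(xlogx(Pxpy))

  mcc <- glcm_mcc(P, Px, Py)
  if (mcc_sqrt) mcc <- sqrt(max(0, mcc))

  setNames(
    c(mux, vx, energy, Hxy, contrast, corr, dissim, homog, ica, icb, mcc,
      mu_d, var_d, ent_d, mu_s, var_s, ent_s, energy),
    glcm_feature_names
  )
}

## Second-largest eigenvalue of U(i,j) = sum_k P(i,k) P(j,k) / (Px(i) Py(k)),
## rows/columns with zero marginal removed first.
glcm_mcc <- function(P, Px, Py) {
  keep_i <- Px > 0
  keep_j <- Py > 0
  Q <- P[keep_i, keep_j, drop = FALSE]
  px <- Px[keep_i]; py <- Py[keep_j]
  if (nrow(Q) < 2L || ncol(Q) < 2L) return(0)
  U <- (Q / px) %*% t(Q / rep(py, each = nrow(Q)))
  ev <- eigen(U, only.values = TRUE)$values
  if (is.complex(ev)) {
    if (max(abs(Im(ev))) > 1e-8)
      warning("MCC kernel eigenvalues have non-negligible imaginary parts")
    ev <- Re(ev)
  }
  sort(ev, decreasing = TRUE)[2]
}

#' Single GLCM feature by name
#'
#' @param m a `glcm_matrix`.
#' @param feature one of [glcm_feature_names].
#' @param ... passed to [glcm_features()].
#' @return Scalar feature value.
#' @export
glcm_feature <- function(m, feature, ...) {
  if (!feature %in% glcm_feature_names)
    stop("unknown GLCM feature: '", feature, "'")
  unname(glcm_features(m, ...)[feature])
}

#' GLCM base feature names
#'
#' The 18 base co-occurrence features (energy and angular 2nd moment share
#' the formula sum P^2; both names are kept so the ranked battery has the
#' study's size).
#' @format Character vector of length 18.
#' @export
glcm_feature_names <- glcm_feature_names

#' Aggregate a feature over offsets
#'
#' Summarizes the per-offset values of one GLCM feature by their mean and
#' range (max - min). Offsets for which no valid pair existed are excluded
#' upstream; if only one offset remains the range is 0 and a warning is
#' emitted.
#'
#' @param values numeric vector, one value per included offset.
#' @return Named numeric vector `c(mean =, range =)`.
#' @export
aggregate_directions <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("all offsets excluded: nothing to aggregate")
  if (length(values) == 1L)
    warning("single offset included; range is 0 by construction")
  c(mean = mean(values), range = max(values) - min(values))
}

#' Extract the full feature battery from one ROI
#'
#' Computes the 8 histogram features plus, for each quantization level, the
#' 18 GLCM base features aggregated to mean and range over the 13 canonical
#' offsets: with levels c(25, 32) that is 8 + 2 x 36 = 80 feature values.
#' Offsets yielding no valid voxel pair are dropped from the aggregation
#' (recorded in the `excluded_offsets` attribute).
#'
#' @param volume a [volume_grid()].
#' @param mask a nonempty [roi_mask()].
#' @param levels integer vector of quantization levels (default `c(25, 32)`).
#' @param symmetrize,icb_sqrt,mcc_sqrt,kurtosis_denominator convention flags,
#'   see [compute_glcm()], [glcm_features()] and [histogram_features()].
#' @return A data.frame with columns `family`, `feature`, `value`. Families
#'   are `"Histogram"` and `"GLCM(<levels>) mean"` / `"GLCM(<levels>) range"`.
#' @export
extract_features <- function(volume, mask, levels = c(25L, 32L),
                             symmetrize = TRUE, icb_sqrt = FALSE,
                             mcc_sqrt = FALSE,
                             kurtosis_denominator = "sigma4") {
  check_mask_on_volume(volume, mask)
  hf <- histogram_features(volume, mask,
                           kurtosis_denominator = kurtosis_denominator)
  rows <- data.frame(
    family = "Histogram",
    feature = histogram_feature_names,
    value = unlist(hf[histogram_feature_names], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  offs <- glcm_offsets()
  excluded <- character()
  for (L in levels) {
    q <- quantize_roi(volume, mask, L)
    vals <- matrix(NA_real_, length(glcm_feature_names), nrow(offs),
                   dimnames = list(glcm_feature_names, rownames(offs)))
    for (k in seq_len(nrow(offs))) {
      g <- tryCatch(compute_glcm(q, offs[k, ], symmetrize = symmetrize),
                    error = function(e) NULL)
      if (is.null(g)) {
        excluded <- c(excluded, sprintf("L%d:(%s)", L,
                                        paste(offs[k, ], collapse = ",")))
        next
      }
      vals[, k] <- glcm_features(g, icb_sqrt = icb_sqrt, mcc_sqrt = mcc_sqrt)
    }
    agg <- t(apply(vals, 1, aggregate_directions))
    rows <- rbind(
      rows,
      data.frame(family = sprintf("GLCM(%d) mean", L),
                 feature = glcm_feature_names, value = agg[, "mean"],
                 stringsAsFactors = FALSE),
      data.frame(family = sprintf("GLCM(%d) range", L),
                 feature = glcm_feature_names, value = agg[, "range"],
                 stringsAsFactors = FALSE)
    )
  }
  rownames(rows) <- NULL
  attr(rows, "excluded_offsets") <- excluded
  rows
}
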