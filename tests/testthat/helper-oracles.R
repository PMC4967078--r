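# Independent reference implementations used as oracles: plain loops and
# direct transcription of the defining formulas, sharing no code with the
# package internals.

oracle_histogram <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  vr <- sum((x - mu)^2) / n
  sg <- sqrt(vr)
  skw <- if (sg > 0) sum((x - mu)^3) / n / sg^3 else 0
  krt <- if (sg > 0) sum((x - mu)^4) / n / sg^4 else 0
  xs <- sort(x)
  med <- xs[(n + 1) %/% 2]
  counts <- table(round(x))
  p <- as.numeric(counts) / n
  ent <- -sum(ifelse(p > 0, p * log2(p), 0))
  eng <- sum(p^2)
  list(Mean = mu, Median = med, Stddev = sg, Variance = vr,
       Skewness = skw, Kurtosis = krt, Entropy = ent, Energy = eng)
}

# Brute-force pair enumeration: walk every voxel, look up its displaced
# partner, count ordered label pairs.
oracle_glcm_P <- function(lab, offset, levels, symmetrize = TRUE) {
  dm <- dim(lab)
  C <- matrix(0, levels, levels)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    a <- lab[x, y, z]
    if (is.na(a)) next
    xx <- x + offset[1]; yy <- y + offset[2]; zz <- z + offset[3]
    if (xx < 1 || xx > dm[1] || yy < 1 || yy > dm[2] || zz < 1 || zz > dm[3]) next
    b <- lab[xx, yy, zz]
    if (is.na(b)) next
    C[a, b] <- C[a, b] + 1
  }
  if (sum(C) == 0) stop("oracle: no valid pairs")
  if (symmetrize) C <- C + t(C)
  C / sum(C)
}

oracle_glcm_features <- function(P) {
  L <- nrow(P)
  Px <- numeric(L); Py <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    Px[i] <- Px[i] + P[i, j]
    Py[j] <- Py[j] + P[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:L) { mux <- mux + i * Px[i]; muy <- muy + i * Py[i] }
  vx <- 0; vy <- 0
  for (i in 1:L) { vx <- vx + (i - mux)^2 * Px[i]; vy <- vy + (i - muy)^2 * Py[i] }
  sx <- sqrt(vx); sy <- sqrt(vy)

  energy <- 0; Hxy <- 0; contrast <- 0; dissim <- 0; homog <- 0; cross <- 0
  Hxy1 <- 0; Hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    energy <- energy + p^2
    if (p > 0) Hxy <- Hxy - p * log(p)
    contrast <- contrast + (i - j)^2 * p
    dissim <- dissim + abs(i - j) * p
    homog <- homog + p / (1 + (i - j)^2)
    cross <- cross + i * j * p
    q <- Px[i] * Py[j]
    if (p > 0) Hxy1 <- Hxy1 - p * log(q)
    if (q > 0) Hxy2 <- Hxy2 - q * log(q)
  }
  Hx <- -sum(ifelse(Px > 0, Px * log(Px), 0))
  Hy <- -sum(ifelse(Py > 0, Py * log(Py), 0))
  corr <- if (sx * sy > 0) (cross - mux * muy) / (sx * sy) else 0
  ica <- if (max(Hx, Hy) > 0) (Hxy - Hxy1) / max(Hx, Hy) else 0
  icb <- 1 - exp(-2 * (Hxy2 - Hxy))

  # cross-difference and cross-sum distributions
  Pd <- numeric(L)          # k = 0 .. L-1 at index k+1
  Ps <- numeric(2 * L - 1)  # k = 2 .. 2L at index k-1
  for (i in 1:L) for (j in 1:L) {
    Pd[abs(i - j) + 1] <- Pd[abs(i - j) + 1] + P[i, j]
    Ps[i + j - 1] <- Ps[i + j - 1] + P[i, j]
  }
  kd <- 0:(L - 1); ks <- 2:(2 * L)
  mu_d <- sum(kd * Pd)
  var_d <- sum((kd - mu_d)^2 * Pd)
  ent_d <- -sum(ifelse(Pd > 0, Pd * log(Pd), 0))
  mu_s <- sum(ks * Ps)
  var_s <- sum((ks - mu_s)^2 * Ps)
  ent_s <- -sum(ifelse(Ps > 0, Ps * log(Ps), 0))

  # MCC kernel on the nonzero-marginal submatrix
  keep <- which(Px > 0)
  keepj <- which(Py > 0)
  mcc <- 0
  if (length(keep) >= 2 && length(keepj) >= 2) {
    U <- matrix(0, length(keep), length(keep))
    for (a in seq_along(keep)) for (b in seq_along(keep)) {
      s <- 0
      for (kk in keepj)
        s <- s + P[keep[a], kk] * P[keep[b], kk] / (Px[keep[a]] * Py[kk])
      U[a, b] <- s
    }
    ev <- eigen(U, only.values = TRUE)$values
    ev <- Re(ev)
    mcc <- sort(ev, decreasing = TRUE)[2]
  }

  c("Mean" = mux, "Variance" = vx, "Energy" = energy, "Entropy" = Hxy,
    "Contrast" = contrast, "Correlation" = corr, "Dissimilarity" = dissim,
    "Homogeneity" = homog, "Information correlation A" = ica,
    "Information correlation B" = icb,
    "Maximal correlation coefficient" = mcc,
    "Diff average" = mu_d, "Diff variance" = var_d, "Diff entropy" = ent_d,
    "Sum average" = mu_s, "Sum variance" = var_s, "Sum entropy" = ent_s,
    "Angular 2nd moment" = energy)
}

# Exhaustive between-class-variance scan over a fixed-bin histogram, used to
# cross-check the Otsu implementation.
oracle_otsu <- function(values, bins = 256L) {
  lo <- min(values); hi <- max(values)
  w <- (hi - lo) / bins
  idx <- pmin(floor((values - lo) / w) + 1, bins)
  h <- tabulate(idx, nbins = bins)
  p <- h / sum(h)
  mids <- lo + (seq_len(bins) - 0.5) * w
  v <- rep(-Inf, bins - 1)
  for (t in 1:(bins - 1)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:t] * mids[1:t]) / w0
    m1 <- sum(p[(t + 1):bins] * mids[(t + 1):bins]) / w1
    v[t] <- w0 * w1 * (m0 - m1)^2
  }
  tol <- 1e-9 * max(1, abs(max(v)))
  ties <- which(v >= max(v) - tol)
  lo + ties[ceiling(length(ties) / 2)] * w
}
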