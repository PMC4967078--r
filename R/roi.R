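## Shift/adjacency helpers on logical 3D arrays. Voxels outside the array are
## treated as background.

shift3d <- function(a, d) {
  dm <- dim(a)
  out <- array(FALSE, dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      dst[[ax]] <- seq_len(dm[ax] - d[ax]) + d[ax]
      src[[ax]] <- seq_len(dm[ax] - d[ax])
    } else {
      dst[[ax]] <- seq_len(dm[ax] + d[ax])
      src[[ax]] <- seq_len(dm[ax] + d[ax]) - d[ax]
    }
    if (length(dst[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

offsets6 <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))

dilate6 <- function(a) {
  out <- a
  for (i in seq_len(nrow(offsets6))) out <- out | shift3d(a, offsets6[i, ])
  out
}

offsets26 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

## 26-connected component containing `seed_idx` (voxel coordinate triple)
## within logical array `bin`; frontier-based BFS on coordinates.
connected_component26 <- function(bin, seed_idx) {
  dm <- dim(bin)
  visited <- array(FALSE, dm)
  if (!bin[seed_idx[1], seed_idx[2], seed_idx[3]]) return(visited)
  visited[seed_idx[1], seed_idx[2], seed_idx[3]] <- TRUE
  frontier <- matrix(seed_idx, nrow = 1L)
  while (nrow(frontier) > 0L) {
    nb <- frontier[rep(seq_len(nrow(frontier)), each = 26L), , drop = FALSE] +
      offsets26[rep(seq_len(26L), nrow(frontier)), , drop = FALSE]
    ok <- nb[, 1] >= 1L & nb[, 1] <= dm[1] &
          nb[, 2] >= 1L & nb[, 2] <= dm[2] &
          nb[, 3] >= 1L & nb[, 3] <= dm[3]
    nb <- nb[ok, , drop = FALSE]
    if (nrow(nb) == 0L) break
    lin <- nb[, 1] + dm[1] * (nb[, 2] - 1L) + dm[1] * dm[2] * (nb[, 3] - 1L)
    keep <- bin[lin] & !visited[lin] & !duplicated(lin)
    nb <- nb[keep, , drop = FALSE]
    if (nrow(nb) == 0L) break
    lin <- lin[keep]
    visited[lin] <- TRUE
    frontier <- nb
  }
  visited
}

## Voxelized closed ball: voxel centers with physical distance <= radius.
sphere_voxels <- function(shape, spacing, center, diameter_mm) {
  r <- diameter_mm / 2
  rv <- ceiling(r / spacing)
  rng <- lapply(1:3, function(ax)
    max(1L, center[ax] - rv[ax]):min(shape[ax], center[ax] + rv[ax]))
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  d2 <- ((g[, 1] - center[1]) * spacing[1])^2 +
        ((g[, 2] - center[2]) * spacing[2])^2 +
        ((g[, 3] - center[3]) * spacing[3])^2
  g[d2 <= r^2, , drop = FALSE]
}

#' Place nonoverlapping spherical ROIs inside a region
#'
#' Places `n` pairwise voxel-disjoint spheres of a given physical diameter
#' inside an interior mask by seeded rejection sampling, emulating the manual
#' placement of sphere ROIs in a uniform phantom. Sphere centers are snapped
#' to voxel centers; a voxel belongs to a sphere when its center lies within
#' the closed ball (distance <= radius), so a 10 mm sphere on a 1 mm grid
#' contains exactly 515 voxels.
#'
#' @param volume a [volume_grid()] providing the grid and spacing.
#' @param n number of spheres.
#' @param diameter_mm physical sphere diameter in mm.
#' @param interior an [roi_mask()]; all sphere voxels must lie inside it.
#' @param seed integer seed; placement is deterministic given the seed.
#' @param max_attempts rejection-sampling bound before declaring placement
#'   infeasible.
#' @return A list of `n` [roi_mask()] objects.
#' @export
place_spherical_rois <- function(volume, n, diameter_mm, interior, seed,
                                 max_attempts = 2000L * n) {
  check_mask_on_volume(volume, interior)
  stopifnot(n >= 1L, diameter_mm > 0)
  shape <- volume$shape
  inter <- interior$mask
  candidates <- which(inter)
  if (length(candidates) == 0L) stop("interior mask is empty")
  occupied <- array(FALSE, shape)
  rois <- vector("list", n)
  placed <- 0L
  rv <- ceiling((diameter_mm / 2) / volume$spacing)
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      center <- arrayInd(sample(candidates, 1L), shape)[1, ]
      # the whole sphere must fit inside the grid, not be clipped by it
      if (any(center - rv < 1L) || any(center + rv > shape)) next
      vox <- sphere_voxels(shape, volume$spacing, center, diameter_mm)
      lin <- vox[, 1] + shape[1] * (vox[, 2] - 1L) + shape[1] * shape[2] * (vox[, 3] - 1L)
      if (!all(inter[lin]) || any(occupied[lin])) next
      m <- array(FALSE, shape)
      m[lin] <- TRUE
      occupied[lin] <- TRUE
      placed <- placed + 1L
      rois[[placed]] <- roi_mask(m)
      if (placed == n) break
    }
  })
  if (placed == n) return(rois)
  stop("placement infeasible: placed ", placed, " of ", n,
       " spheres after ", max_attempts, " attempts")
}

#' Otsu threshold of a value sample
#'
#' Computes the threshold maximizing between-class variance over a fixed-bin
#' histogram of the input (256 equal-width bins over the observed range).
#' Candidate thresholds are bin edges; ties are resolved by the middle tied
#' edge, so a perfectly bimodal sample thresholds near the midpoint of the gap.
#'
#' @param values numeric vector with at least two distinct values.
#' @param bins number of histogram bins.
#' @return Scalar threshold; values strictly above it are foreground.
#' @export
otsu_threshold <- function(values, bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least two values")
  lo <- min(values); hi <- max(values)
  if (lo == hi) stop("degenerate input: all values identical")
  w <- (hi - lo) / bins
  idx <- pmin(floor((values - lo) / w) + 1L, bins)
  h <- tabulate(idx, nbins = bins)
  p <- h / sum(h)
  mids <- lo + (seq_len(bins) - 0.5) * w
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  muT <- mu0[bins]
  # between-class variance for split after bin t (t = 1..bins-1)
  t <- seq_len(bins - 1L)
  denom <- w0[t] * (1 - w0[t])
  bcv <- ifelse(denom > 0, (muT * w0[t] - mu0[t])^2 / denom, -Inf)
  # relative plateau tolerance: perfectly bimodal inputs tie across the gap
  tol <- 1e-9 * max(1, abs(max(bcv)))
  best <- which(bcv >= max(bcv) - tol)
  tstar <- best[ceiling(length(best) / 2)]
  lo + tstar * w
}

#' Segment a nodule from a seed point
#'
#' Otsu-initialized segmentation: the threshold is computed over a local box
#' around the seed point, and the 26-connected component of supra-threshold
#' voxels containing the seed is returned. This is the programmatic analogue
#' of click-initialized semiautomatic nodule contouring (without manual
#' paint editing).
#'
#' @param volume a [volume_grid()].
#' @param seed_point integer voxel coordinate triple (1-based) inside the
#'   volume.
#' @param box_halfwidth half-width (voxels) of the local box used for the
#'   Otsu threshold.
#' @param seed unused; segmentation is deterministic. Present so stochastic
#'   re-contouring surrogates (see [perturb_mask()]) share a calling
#'   convention.
#' @return An [roi_mask()] on the volume's grid.
#' @export
segment_nodule <- function(volume, seed_point, box_halfwidth = 28L, seed = NULL) {
  stopifnot(inherits(volume, "volume_grid"))
  shape <- volume$shape
  seed_point <- as.integer(seed_point)
  if (any(seed_point < 1L) || any(seed_point > shape))
    stop("seed_point outside the volume")
  rng <- lapply(1:3, function(ax)
    max(1L, seed_point[ax] - box_halfwidth):min(shape[ax], seed_point[ax] + box_halfwidth))
  box <- volume$values[rng[[1]], rng[[2]], rng[[3]]]
  thr <- otsu_threshold(as.numeric(box))
  if (volume$values[seed_point[1], seed_point[2], seed_point[3]] <= thr)
    stop("empty segmentation: seed voxel falls below the Otsu threshold")
  bin <- array(FALSE, shape)
  bin[rng[[1]], rng[[2]], rng[[3]]] <- box > thr
  comp <- connected_component26(bin, seed_point)
  roi_mask(comp)
}

#' Stochastic repeat-contour surrogate
#'
#' Emulates re-contouring variability: each boundary voxel of the mask is
#' removed, and each background voxel 6-adjacent to the mask is added,
#' independently with probability `boundary_flip_prob`. A single-voxel mask is
#' never eroded (the lone voxel is the entire mask). The symmetric-difference
#' fraction |Phi delta Phi'| / |Phi| is attached as attribute
#' `sym_diff_frac`.
#'
#' @param mask a nonempty [roi_mask()].
#' @param boundary_flip_prob flip probability in \[0, 0.5\].
#' @param seed integer seed; deterministic given the seed.
#' @return A perturbed [roi_mask()].
#' @export
perturb_mask <- function(mask, boundary_flip_prob = 0.1, seed = 1L) {
  stopifnot(inherits(mask, "roi_mask"))
  p <- boundary_flip_prob
  if (!is.finite(p) || p < 0 || p > 0.5)
    stop("boundary_flip_prob must lie in [0, 0.5]")
  if (mask$size < 1L) stop("mask is empty")
  m <- mask$mask
  boundary <- m & dilate6(!m)
  # voxels on the array border always have an (implicit) outside neighbour
  dm <- dim(m)
  border <- array(FALSE, dm)
  border[c(1, dm[1]), , ] <- TRUE
  border[, c(1, dm[2]), ] <- TRUE
  border[, , c(1, dm[3])] <- TRUE
  boundary <- boundary | (m & border)
  adjacent <- !m & dilate6(m)
  if (mask$size == 1L) boundary[] <- FALSE
  out <- m
  bidx <- which(boundary)
  aidx <- which(adjacent)
  with_seed(seed, {
    if (length(bidx)) out[bidx[runif(length(bidx)) < p]] <- FALSE
    if (length(aidx)) out[aidx[runif(length(aidx)) < p]] <- TRUE
  })
  if (!any(out)) stop("perturbation emptied the mask")
  res <- roi_mask(out)
  attr(res, "sym_diff_frac") <- sum(xor(out, m)) / mask$size
  res
}

erode6 <- function(a) !dilate6(!a)

## Approximate signed city-block distance to the mask boundary, capped at
## K + 0.5: boundary voxels get +0.5, adjacent background -0.5, etc.
signed_distance6 <- function(m, K = 4L) {
  d <- array(0, dim(m))
  cur <- m
  for (k in seq_len(K)) {
    nxt <- erode6(cur)
    d[cur & !nxt] <- k - 0.5
    cur <- nxt
  }
  d[cur] <- K + 0.5
  cur <- m
  for (k in seq_len(K)) {
    nxt <- dilate6(cur)
    d[nxt & !cur] <- -(k - 0.5)
    cur <- nxt
  }
  d[!cur] <- -(K + 0.5)
  d
}

#' Coherent re-contouring surrogate
#'
#' Emulates the spatially smooth way human readers disagree when contouring
#' the same lesion twice: the mask's signed boundary distance d(x) (voxels,
#' positive inside) is perturbed by a smooth unit-variance random field and
#' re-thresholded, `d(x) + amplitude * g(x) > 0`, so whole boundary patches
#' move coherently in or out by roughly `amplitude` voxels rather than
#' flickering voxel by voxel (contrast [perturb_mask], which flips boundary
#' voxels independently). At `amplitude = 0` the input mask is returned
#' unchanged. The symmetric-difference fraction is attached as attribute
#' `sym_diff_frac`.
#'
#' @param mask a nonempty [roi_mask()].
#' @param amplitude SD of the boundary displacement, in voxels.
#' @param corr_length correlation length (voxels) of the perturbation field.
#' @param seed integer seed.
#' @return A perturbed [roi_mask()]; never empty (falls back to the input
#'   mask if the perturbation would erase it).
#' @export
recontour_surrogate <- function(mask, amplitude = 0.5, corr_length = 4,
                                seed = 1L) {
  stopifnot(inherits(mask, "roi_mask"), amplitude >= 0, mask$size >= 1L)
  m <- mask$mask
  d <- signed_distance6(m)
  g <- smooth_unit_field(dim(m), corr_length, seed)
  out <- (d + amplitude * g) > 0
  # keep the component containing the original mask's center of mass
  if (any(out)) {
    ctr <- round(colMeans(which(m, arr.ind = TRUE)))
    if (!out[ctr[1], ctr[2], ctr[3]]) {
      inside <- which(out & m)
      ctr <- if (length(inside)) arrayInd(inside[1], dim(m))[1, ] else NULL
    }
    if (!is.null(ctr)) out <- connected_component26(out, ctr)
  }
  if (!any(out)) {
    warning("re-contour perturbation erased the mask; returning the input")
    out <- m
  }
  res <- roi_mask(out)
  attr(res, "sym_diff_frac") <- sum(xor(out, m)) / mask$size
  res
}
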