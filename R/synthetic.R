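## Fourier transform of a normalized Gaussian kernel wrapped onto a length-L
## torus (so arbitrary smoothing scales work on small volumes).
torus_gauss_fft <- function(L, sigma) {
  if (sigma <= 0) return(rep(1 + 0i, L))
  r <- ceiling(6 * sigma)
  k <- numeric(L)
  for (o in -r:r) {
    i <- (o %% L) + 1L
    k[i] <- k[i] + dnorm(o, sd = sigma)
  }
  fft(k / sum(k))
}

## Separable 3D Gaussian transfer function on the torus.
gauss_tf3d <- function(shape, sigma) {
  fx <- torus_gauss_fft(shape[1], sigma)
  fy <- torus_gauss_fft(shape[2], sigma)
  fz <- torus_gauss_fft(shape[3], sigma)
  outer(outer(fx, fy), fz)
}

## Circular 3D convolution with a normalized Gaussian kernel via FFT.
gauss_smooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  shape <- dim(a)
  Re(fft(fft(a) * gauss_tf3d(shape, sigma), inverse = TRUE)) / prod(shape)
}

## Pure low-pass unit-variance correlated field (used for object texture and
## for the coherent re-contouring surrogate).
smooth_unit_field <- function(shape, corr_sigma, seed) {
  w <- with_seed(seed, array(rnorm(prod(shape)), shape))
  if (corr_sigma <= 0) return(w)
  tf <- gauss_tf3d(shape, corr_sigma)
  shrink <- sum(Mod(tf)^2) / prod(shape)
  sm <- Re(fft(fft(w) * tf, inverse = TRUE)) / prod(shape)
  sm / sqrt(shrink)
}

## Acquisition noise with unit marginal variance: white noise shaped by the
## FBP noise transfer surrogate, an in-plane ramp (the reconstruction
## filter's |f| weighting, which sends the noise power spectrum to zero at
## DC -- the reason ROI mean values are nearly noise-free in CT) apodized by
## the kernel's Gaussian PSF. The exact variance shrink of the transfer
## function (Parseval) restores unit marginal variance.
noise_field <- function(shape, psf_sigma, seed) {
  w <- with_seed(seed, array(rnorm(prod(shape)), shape))
  tf <- gauss_tf3d(shape, psf_sigma)
  fr <- function(L) { f <- (seq_len(L) - 1) / L; pmin(f, 1 - f) }
  rho <- sqrt(outer(fr(shape[1])^2, fr(shape[2])^2, `+`)) / 0.5
  tf <- tf * array(rep(rho, shape[3]), shape)
  shrink <- sum(Mod(tf)^2) / prod(shape)
  if (shrink <= 0) stop("degenerate noise transfer function")
  sm <- Re(fft(fft(w) * tf, inverse = TRUE)) / prod(shape)
  sm / sqrt(shrink)
}

#' Reconstruction-kernel surrogates
#'
#' Each CT reconstruction kernel is modelled by two numbers: `psf_sigma`, the
#' spatial scale (voxels) of a Gaussian smoothing surrogate shaping the noise
#' correlation, and `noise_gain`, the relative noise magnitude at fixed dose.
#' Within each family, sharper kernels (smaller `psf_sigma`) carry a larger
#' `noise_gain`; iterative-reconstruction (IR) kernels get a noise discount
#' relative to the FBP kernel of comparable sharpness, emulating the
#' noise-reducing role of IR. These are qualitative surrogates, not scanner
#' measurements; edit the data.frame to change them.
#'
#' @return data.frame with columns `name`, `family` (`"FBP"`/`"IR"`),
#'   `psf_sigma`, `noise_gain`.
#' @export
kernel_catalog <- function() {
  data.frame(
    name = c("B10f", "B30f", "B45f", "B70f",
             "I26f\\5", "I44f\\3", "I50f\\3", "I70f\\1"),
    family = rep(c("FBP", "IR"), each = 4L),
    psf_sigma = c(2.0, 1.2, 0.8, 0.3, 2.0, 1.0, 0.8, 0.3),
    noise_gain = c(0.50, 0.75, 1.00, 1.60, 0.35, 0.70, 0.75, 1.20),
    stringsAsFactors = FALSE
  )
}

get_kernel <- function(kernel) {
  if (is.character(kernel)) {
    cat_ <- kernel_catalog()
    i <- match(kernel, cat_$name)
    if (is.na(i)) stop("unknown kernel: ", kernel)
    kernel <- as.list(cat_[i, ])
  }
  stopifnot(is.list(kernel), kernel$psf_sigma >= 0, kernel$noise_gain > 0)
  kernel
}

#' CTDIvol from effective mAs by linear scaling
#'
#' Scanner dose output (CTDIvol, 32 cm phantom) scales linearly with the
#' fixed tube-current-time product; the default anchor is 225 effective mAs
#' at 17.1 mGy, so 100 mAs gives 7.6 mGy and 50 mAs gives 3.8 mGy.
#'
#' @param mas effective mAs value(s).
#' @param ref_mas,ref_ctdivol the anchor point.
#' @return CTDIvol in mGy.
#' @export
ctdivol_from_mas <- function(mas, ref_mas = 225, ref_ctdivol = 17.1) {
  stopifnot(ref_mas > 0, ref_ctdivol > 0, all(mas > 0))
  mas / ref_mas * ref_ctdivol
}

#' Study condition grids
#'
#' `phantom_conditions()` is the water-phantom grid: 3 dose levels (17.1,
#' 7.6, 3.8 mGy, i.e. fractions 1, 100/225, 50/225 of the reference output)
#' crossed with 8 kernels (B10f, B30f, B45f, B70f and the IR analogues),
#' 24 conditions, reference B45f at 17.1 mGy. `nodule_conditions()` is the
#' patient grid: 4 dose fractions (100%, 25%, 10%, 3%) crossed with 3
#' medium-sharp kernels (B45f, I44f\\3, I50f\\3), 12 conditions, reference
#' B45f at 100%.
#'
#' @return data.frame with columns `condition` (label, `<kernel>@<dose>`),
#'   `kernel`, `dose_label`, `dose_fraction`, `reference` (logical, exactly
#'   one `TRUE`).
#' @export
phantom_conditions <- function() {
  kernels <- kernel_catalog()$name
  doses <- data.frame(dose_label = c("17.1", "7.6", "3.8"),
                      dose_fraction = c(225, 100, 50) / 225)
  g <- expand.grid(kernel = kernels, dose_label = doses$dose_label,
                   stringsAsFactors = FALSE)
  g$dose_fraction <- doses$dose_fraction[match(g$dose_label, doses$dose_label)]
  g$condition <- paste0(g$kernel, "@", g$dose_label)
  g$reference <- g$kernel == "B45f" & g$dose_label == "17.1"
  g[, c("condition", "kernel", "dose_label", "dose_fraction", "reference")]
}

#' @rdname phantom_conditions
#' @export
nodule_conditions <- function() {
  kernels <- c("B45f", "I44f\\3", "I50f\\3")
  doses <- data.frame(dose_label = c("100", "25", "10", "3"),
                      dose_fraction = c(1, 0.25, 0.10, 0.03))
  g <- expand.grid(kernel = kernels, dose_label = doses$dose_label,
                   stringsAsFactors = FALSE)
  g$dose_fraction <- doses$dose_fraction[match(g$dose_label, doses$dose_label)]
  g$condition <- paste0(g$kernel, "@", g$dose_label)
  g$reference <- g$kernel == "B45f" & g$dose_label == "100"
  g[, c("condition", "kernel", "dose_label", "dose_fraction", "reference")]
}

#' Synthetic uniform water phantom
#'
#' A water cylinder (0 HU) in air (-1000 HU) with stationary correlated
#' Gaussian acquisition noise shaped by an FBP-style transfer function
#' (in-plane ramp apodized by the kernel's Gaussian PSF surrogate, so the
#' noise power spectrum vanishes at DC as in real CT) and scaled so the
#' in-water standard deviation is
#' `sigma_ref * noise_gain / sqrt(dose_fraction)` — the inverse-square-root
#' dose law of quantum noise.
#'
#' @param shape voxel grid dimensions (length 3).
#' @param spacing voxel spacing, mm.
#' @param dose_fraction dose relative to the reference output, in (0, 1].
#' @param kernel kernel name (see [kernel_catalog()]) or a list with
#'   `psf_sigma` and `noise_gain`.
#' @param sigma_ref in-water noise SD (HU) at full dose for a unit-gain
#'   kernel; the default 10 HU makes the B45f/full-dose water SD ~10 HU.
#' @param radius_frac cylinder radius as a fraction of the smaller in-plane
#'   half-extent.
#' @param seed integer seed.
#' @return A [volume_grid()]; the water-cylinder membership is attached as
#'   attribute `water_mask` (an [roi_mask()]).
#' @export
generate_water_phantom <- function(shape = c(96L, 96L, 32L),
                                   spacing = c(1, 1, 1),
                                   dose_fraction = 1, kernel = "B45f",
                                   sigma_ref = 10, seed = 1L,
                                   radius_frac = 0.9) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L)) stop("invalid geometry")
  if (dose_fraction <= 0 || dose_fraction > 1)
    stop("dose_fraction must lie in (0, 1]")
  if (sigma_ref < 0) stop("sigma_ref must be >= 0")
  k <- get_kernel(kernel)
  cx <- (shape[1] + 1) / 2; cy <- (shape[2] + 1) / 2
  R <- radius_frac * min((shape[1] - 1) / 2 * spacing[1],
                         (shape[2] - 1) / 2 * spacing[2])
  xi <- ((seq_len(shape[1]) - cx) * spacing[1])^2
  yj <- ((seq_len(shape[2]) - cy) * spacing[2])^2
  disk <- outer(xi, yj, `+`) <= R^2
  water <- array(disk, shape)
  vals <- array(-1000, shape)
  vals[water] <- 0
  if (sigma_ref > 0) {
    sigma <- sigma_ref * k$noise_gain / sqrt(dose_fraction)
    vals <- vals + sigma * noise_field(shape, k$psf_sigma, seed)
  }
  v <- volume_grid(vals, spacing)
  attr(v, "water_mask") <- roi_mask(water)
  v
}

#' Synthetic lung nodule volume
#'
#' An ellipsoidal nodule of a given mean HU with smooth correlated internal
#' texture (the intrinsic heterogeneity that masks acquisition noise in real
#' nodules), embedded in textured lung-parenchyma background, with
#' acquisition noise added as in [generate_water_phantom()]. The analytic
#' ellipsoid membership is returned as the ground-truth mask.
#'
#' @param shape,spacing grid geometry.
#' @param center ellipsoid center (voxel coordinates); default volume center.
#' @param semi_axes_mm ellipsoid semi-axes in mm.
#' @param nodule_hu nodule mean intensity (HU).
#' @param texture_sigma,texture_corr internal-texture SD (HU) and correlation
#'   length (voxels).
#' @param background_hu,background_sigma,background_corr lung background
#'   mean, texture SD and correlation length.
#' @param edge_smooth Gaussian scale (voxels) applied to the composed
#'   anatomy before noise is added: the system PSF acts on the object as
#'   well as the noise, producing partial-volume mixture voxels at the
#'   nodule rim instead of a hard step edge.
#' @param dose_fraction,kernel,sigma_ref acquisition-noise model, see
#'   [generate_water_phantom()].
#' @param seed integer seed. The anatomy (nodule + background texture) and
#'   the acquisition noise use separate sub-streams, so volumes of the same
#'   case at different conditions share their anatomy when given the same
#'   `anatomy_seed`.
#' @param anatomy_seed seed for the anatomy stream (defaults to `seed`).
#' @return A list with `volume` (a [volume_grid()]) and `mask` (ground-truth
#'   [roi_mask()]).
#' @export
generate_nodule_volume <- function(shape = c(48L, 48L, 48L),
                                   spacing = c(1, 1, 1),
                                   center = NULL,
                                   semi_axes_mm = c(9, 8, 8),
                                   nodule_hu = 40,
                                   texture_sigma = 50, texture_corr = 3,
                                   background_hu = -800,
                                   background_sigma = 40, background_corr = 1.5,
                                   edge_smooth = 2.2,
                                   dose_fraction = 1, kernel = "B45f",
                                   sigma_ref = 10, seed = 1L,
                                   anatomy_seed = seed) {
  shape <- as.integer(shape)
  if (is.null(center)) center <- (shape + 1) / 2
  if (any(center - semi_axes_mm / spacing < 1) ||
      any(center + semi_axes_mm / spacing > shape))
    stop("nodule does not fit in the volume")
  k <- get_kernel(kernel)
  xs <- ((seq_len(shape[1]) - center[1]) * spacing[1] / semi_axes_mm[1])^2
  ys <- ((seq_len(shape[2]) - center[2]) * spacing[2] / semi_axes_mm[2])^2
  zs <- ((seq_len(shape[3]) - center[3]) * spacing[3] / semi_axes_mm[3])^2
  inside <- outer(outer(xs, ys, `+`), zs, `+`) <= 1
  vals <- array(background_hu, shape)
  if (background_sigma > 0)
    vals <- vals + background_sigma *
      smooth_unit_field(shape, background_corr,
                        hash_seed(anatomy_seed, "background"))
  nod <- array(nodule_hu, shape)
  if (texture_sigma > 0)
    nod <- nod + texture_sigma *
      smooth_unit_field(shape, texture_corr,
                        hash_seed(anatomy_seed, "texture"))
  vals[inside] <- nod[inside]
  if (edge_smooth > 0) {
    vals <- gauss_smooth3d(vals, edge_smooth)
    attr(vals, "var_shrink") <- NULL
  }
  if (sigma_ref > 0) {
    if (dose_fraction <= 0 || dose_fraction > 1)
      stop("dose_fraction must lie in (0, 1]")
    sigma <- sigma_ref * k$noise_gain / sqrt(dose_fraction)
    vals <- vals + sigma * noise_field(shape, k$psf_sigma,
                                       hash_seed(seed, "acquisition"))
  }
  list(volume = volume_grid(vals, spacing), mask = roi_mask(inside))
}

#' Image-domain dose-reduction surrogate
#'
#' Simulates a lower-dose acquisition of an existing volume by adding
#' independent correlated noise with in-water SD
#' `sigma_ref * noise_gain * sqrt(1/to_fraction - 1/from_fraction)`, so the
#' total noise variance matches a direct acquisition at `to_fraction` (the
#' variances of independent Gaussian fields add). This replaces
#' sinogram-domain noise insertion, which requires scanner raw data.
#'
#' @param volume a [volume_grid()].
#' @param from_fraction,to_fraction dose fractions with
#'   `0 < to_fraction < from_fraction <= 1`.
#' @param kernel,sigma_ref noise model, see [generate_water_phantom()].
#' @param seed integer seed.
#' @return A [volume_grid()] at the reduced dose.
#' @export
simulate_dose_reduction <- function(volume, from_fraction, to_fraction,
                                    kernel = "B45f", sigma_ref = 10,
                                    seed = 1L) {
  stopifnot(inherits(volume, "volume_grid"))
  if (!(to_fraction > 0 && to_fraction < from_fraction && from_fraction <= 1))
    stop("need 0 < to_fraction < from_fraction <= 1")
  k <- get_kernel(kernel)
  sigma_add <- sigma_ref * k$noise_gain *
    sqrt(1 / to_fraction - 1 / from_fraction)
  volume_grid(
    volume$values + sigma_add * noise_field(volume$shape, k$psf_sigma, seed),
    volume$spacing
  )
}
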