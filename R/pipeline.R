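#' Study configuration
#'
#' Validates and assembles the configuration driving [generate_study()],
#' [extract_study()] and [run_pipeline()]. Defaults reproduce the study
#' design: 33 nodule cases with repeat contours on 17 of them over the
#' 12-condition nodule grid, or a water phantom with 5 spherical 10 mm ROIs
#' over the 24-condition phantom grid.
#'
#' @param mode `"nodule"` or `"phantom"`.
#' @param out_dir study directory (created if needed).
#' @param seed master seed; every volume/mask derives its own sub-seed from
#'   it, so studies are reproducible file by file.
#' @param n_cases number of nodule cases (nodule mode).
#' @param n_repeat number of cases receiving a repeat contour (nodule mode).
#' @param n_rois,roi_diameter_mm spherical ROI count and diameter (phantom
#'   mode).
#' @param levels GLCM quantization levels.
#' @param sigma_ref reference noise magnitude (HU), see
#'   [generate_water_phantom()].
#' @param recontour_amplitude,recontour_corr threshold-perturbation SD and
#'   correlation length of the repeat-contour surrogate, see
#'   [recontour_surrogate()].
#' @param sd_type,symmetrize,icb_sqrt,mcc_sqrt,kurtosis_denominator
#'   convention flags passed through to the feature and Q computations.
#' @param format `"nii.gz"`, `"nii"`, `"mha"` or `"mhd"` for on-disk volumes.
#' @param phantom_shape voxel grid of the water-phantom volumes (phantom
#'   mode).
#' @return A list of class `study_config`.
#' @export
study_config <- function(mode = c("nodule", "phantom"),
                         out_dir = tempfile("radstab_study_"),
                         seed = 1L,
                         n_cases = 33L, n_repeat = 17L,
                         n_rois = 5L, roi_diameter_mm = 10,
                         phantom_shape = c(96L, 96L, 32L),
                         levels = c(25L, 32L),
                         sigma_ref = 20,
                         recontour_amplitude = 0.35, recontour_corr = 3,
                         sd_type = "sample", symmetrize = TRUE,
                         icb_sqrt = FALSE, mcc_sqrt = FALSE,
                         kurtosis_denominator = "sigma4",
                         format = "nii.gz") {
  mode <- match.arg(mode)
  stopifnot(n_cases >= 2L, n_repeat >= 2L, n_repeat <= n_cases,
            n_rois >= 1L, roi_diameter_mm > 0, all(levels >= 2L),
            sigma_ref >= 0, recontour_amplitude >= 0, recontour_corr > 0)
  format <- match.arg(format, c("nii.gz", "nii", "mha", "mhd"))
  conds <- if (mode == "nodule") nodule_conditions() else phantom_conditions()
  if (sum(conds$reference) != 1L)
    stop("condition grid must contain exactly one reference condition")
  structure(
    list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
         n_cases = as.integer(n_cases), n_repeat = as.integer(n_repeat),
         n_rois = as.integer(n_rois), roi_diameter_mm = roi_diameter_mm,
         phantom_shape = as.integer(phantom_shape),
         levels = as.integer(levels), sigma_ref = sigma_ref,
         recontour_amplitude = recontour_amplitude,
         recontour_corr = recontour_corr,
         sd_type = sd_type, symmetrize = symmetrize,
         icb_sqrt = icb_sqrt, mcc_sqrt = mcc_sqrt,
         kurtosis_denominator = kurtosis_denominator,
         format = format, conditions = conds),
    class = "study_config"
  )
}

cond_dir <- function(label) gsub("[^A-Za-z0-9@._-]", "-", label)

vol_file <- function(dir, name, format) file.path(dir, paste0(name, ".", format))

## Case geometry/composition parameters drawn from the study's nodule-size
## distribution: longest in-plane diameter 7-46 mm, average ~18 mm.
## `noise_scale` is a per-case acquisition-noise multiplier emulating tube
## current modulation and patient habitus: the noise level reached at a given
## dose fraction differs from patient to patient.
draw_case_params <- function(config, case_id) {
  with_seed(hash_seed(config$seed, c(case_id, "params")), {
    d <- exp(rnorm(1, log(17), 0.38))
    d <- min(max(d, 7), 46)
    a <- d / 2
    b <- a * runif(1, 0.7, 1)
    c_ <- a * runif(1, 0.7, 1)
    list(
      semi_axes_mm = c(a, b, c_),
      nodule_hu = rnorm(1, 40, 15),
      texture_sigma = runif(1, 35, 65),
      texture_corr = runif(1, 2.5, 3.5),
      noise_scale = exp(rnorm(1, 0, 0.45))
    )
  })
}

#' Generate a synthetic study on disk
#'
#' Writes the full study layout for the configured mode. Nodule mode:
#' `<out>/<case>/<condition>/volume.<fmt>` for every case and condition
#' (100%-dose volumes generated directly per kernel; lower doses derived from
#' them with [simulate_dose_reduction()]), the analytic ground-truth mask
#' (`truth.<fmt>` at the case level), and — in the reference condition's
#' directory — the Otsu-initialized contour (`mask.<fmt>`) plus, for the
#' repeat subset, a perturbed repeat contour (`mask_repeat.<fmt>`).
#' Phantom mode: one volume
#' per condition plus the spherical ROI masks placed at the reference
#' condition. `manifest.json` records conditions (with the reference flag),
#' cases, seeds and generator parameters.
#'
#' @param config a [study_config()].
#' @return The study directory, invisibly.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  root <- config$out_dir
  conds <- config$conditions
  if (sum(conds$reference) != 1L)
    stop("condition grid must contain exactly one reference condition")
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  fmt <- config$format
  manifest <- list(
    mode = config$mode, seed = config$seed, format = fmt,
    sigma_ref = config$sigma_ref,
    conditions = conds, reference = conds$condition[conds$reference]
  )
  if (config$mode == "phantom") {
    case <- "phantom"
    cdirs <- file.path(root, case, cond_dir(conds$condition))
    for (d in cdirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
    ref_row <- which(conds$reference)
    vols <- vector("list", nrow(conds))
    for (i in seq_len(nrow(conds))) {
      v <- generate_water_phantom(
        shape = config$phantom_shape,
        dose_fraction = conds$dose_fraction[i], kernel = conds$kernel[i],
        sigma_ref = config$sigma_ref,
        seed = hash_seed(config$seed, c(case, conds$condition[i], "volume"))
      )
      write_volume(v, vol_file(cdirs[i], "volume", fmt))
      if (i == ref_row) {
        water <- attr(v, "water_mask")
        rois <- place_spherical_rois(
          v, config$n_rois, config$roi_diameter_mm, water,
          seed = hash_seed(config$seed, c(case, "rois"))
        )
        roidir <- file.path(root, case, "rois")
        dir.create(roidir, showWarnings = FALSE)
        for (j in seq_along(rois))
          write_volume(rois[[j]], vol_file(roidir, paste0("roi_", j), fmt))
      }
    }
    manifest$cases <- data.frame(case_id = case, stringsAsFactors = FALSE)
    manifest$n_rois <- config$n_rois
  } else {
    cases <- sprintf("case_%02d", seq_len(config$n_cases))
    repeat_cases <- with_seed(hash_seed(config$seed, "repeat-subset"),
                              sort(sample(cases, config$n_repeat)))
    ref_label <- conds$condition[conds$reference]
    for (case in cases) {
      par <- draw_case_params(config, case)
      margin <- 10
      shape <- as.integer(ceiling(2 * max(par$semi_axes_mm)) + 2 * margin)
      shape <- rep(shape, 3L)
      base <- list()
      for (kern in unique(conds$kernel)) {
        g <- generate_nodule_volume(
          shape = shape,
          semi_axes_mm = par$semi_axes_mm, nodule_hu = par$nodule_hu,
          texture_sigma = par$texture_sigma, texture_corr = par$texture_corr,
          dose_fraction = 1, kernel = kern,
          sigma_ref = config$sigma_ref * par$noise_scale,
          seed = hash_seed(config$seed, c(case, kern, "full-dose")),
          anatomy_seed = hash_seed(config$seed, c(case, "anatomy"))
        )
        base[[kern]] <- g$volume
      }
      casedir <- file.path(root, case)
      dir.create(casedir, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_len(nrow(conds))) {
        cdir <- file.path(casedir, cond_dir(conds$condition[i]))
        dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
        kern <- conds$kernel[i]
        v <- if (conds$dose_fraction[i] >= 1) base[[kern]]
             else simulate_dose_reduction(
               base[[kern]], 1, conds$dose_fraction[i], kernel = kern,
               sigma_ref = config$sigma_ref * par$noise_scale,
               seed = hash_seed(config$seed,
                                c(case, conds$condition[i], "reduce")))
        write_volume(v, vol_file(cdir, "volume", fmt))
      }
      # ground-truth mask at the case level; the working contour (drawn at
      # the reference condition and applied everywhere) and its repeat live
      # in the reference condition's directory
      gt <- generate_nodule_volume(
        shape = shape, semi_axes_mm = par$semi_axes_mm,
        nodule_hu = par$nodule_hu, texture_sigma = 0, texture_corr = 1,
        background_sigma = 0, sigma_ref = 0,
        anatomy_seed = hash_seed(config$seed, c(case, "anatomy"))
      )$mask
      write_volume(gt, vol_file(casedir, "truth", fmt))
      ref_vol <- base[[conds$kernel[conds$reference]]]
      refdir <- file.path(casedir, cond_dir(ref_label))
      seedpt <- round((shape + 1) / 2)
      contour <- tryCatch(
        segment_nodule(ref_vol, seedpt),
        error = function(e) {
          warning("segmentation failed for ", case,
                  " (", conditionMessage(e), "); using ground-truth mask")
          gt
        }
      )
      write_volume(contour, vol_file(refdir, "mask", fmt))
      if (case %in% repeat_cases) {
        rep_mask <- recontour_surrogate(
          contour, amplitude = config$recontour_amplitude,
          corr_length = config$recontour_corr,
          seed = hash_seed(config$seed, c(case, "repeat")))
        write_volume(rep_mask, vol_file(refdir, "mask_repeat", fmt))
      }
    }
    manifest$cases <- data.frame(
      case_id = cases, repeat_contour = cases %in% repeat_cases,
      stringsAsFactors = FALSE
    )
  }
  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(root)
}

read_manifest <- function(study_dir) {
  path <- file.path(study_dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", study_dir)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(m$reference) || !m$reference %in% m$conditions$condition)
    stop("manifest lacks a valid reference condition")
  m
}

#' Extract the feature battery for a whole study
#'
#' Reads the on-disk study produced by [generate_study()] and computes the
#' full feature battery for every (case, condition, contour). Nodule mode
#' applies the case's reference-condition contour to all conditions (the
#' repeat contour, where present, at the reference condition only). Phantom
#' mode treats each spherical ROI as a case. Writes `features.csv` into the
#' study directory.
#'
#' @param study_dir study directory with a `manifest.json`.
#' @param config a [study_config()] (feature-convention flags are honoured).
#' @return The long-form feature data.frame (columns `case_id`, `condition`,
#'   `contour_id`, `family`, `feature`, `value`), invisibly written to
#'   `<study_dir>/features.csv`.
#' @export
extract_study <- function(study_dir, config = study_config()) {
  m <- read_manifest(study_dir)
  conds <- m$conditions
  fmt <- m$format
  ex <- function(vol, msk, case, cond, contour) {
    ft <- extract_features(vol, msk, levels = config$levels,
                           symmetrize = config$symmetrize,
                           icb_sqrt = config$icb_sqrt,
                           mcc_sqrt = config$mcc_sqrt,
                           kurtosis_denominator = config$kurtosis_denominator)
    cbind(case_id = case, condition = cond, contour_id = contour, ft)
  }
  out <- list()
  if (m$mode == "phantom") {
    roidir <- file.path(study_dir, "phantom", "rois")
    roifiles <- sort(list.files(roidir, full.names = TRUE))
    rois <- lapply(roifiles, read_mask)
    for (i in seq_len(nrow(conds))) {
      v <- read_volume(vol_file(
        file.path(study_dir, "phantom", cond_dir(conds$condition[i])),
        "volume", fmt))
      for (j in seq_along(rois))
        out[[length(out) + 1L]] <-
          ex(v, rois[[j]], paste0("roi_", j), conds$condition[i], 1L)
    }
  } else {
    refdir_name <- cond_dir(m$reference)
    for (ci in seq_len(nrow(m$cases))) {
      case <- m$cases$case_id[ci]
      casedir <- file.path(study_dir, case)
      contour <- read_mask(vol_file(file.path(casedir, refdir_name),
                                    "mask", fmt))
      has_repeat <- isTRUE(m$cases$repeat_contour[ci])
      for (i in seq_len(nrow(conds))) {
        v <- read_volume(vol_file(
          file.path(casedir, cond_dir(conds$condition[i])), "volume", fmt))
        out[[length(out) + 1L]] <- ex(v, contour, case, conds$condition[i], 1L)
        if (has_repeat && conds$reference[i]) {
          rep_mask <- read_mask(vol_file(file.path(casedir, refdir_name),
                                         "mask_repeat", fmt))
          out[[length(out) + 1L]] <-
            ex(v, rep_mask, case, conds$condition[i], 2L)
        }
      }
    }
  }
  features <- do.call(rbind, out)
  rownames(features) <- NULL
  write.csv(features, file.path(study_dir, "features.csv"), row.names = FALSE)
  invisible(features)
}

#' Run the full simulate-extract-analyze pipeline
#'
#' Orchestrates [generate_study()], [extract_study()] and the analysis stage
#' through on-disk artifacts. Nodule mode runs the Q analysis
#' ([analyze_robustness()]) and writes `qtable.csv`, `feature_ranking.csv`,
#' `condition_ranking.csv`, `nearest_conditions.csv` and `summary.csv`;
#' phantom mode (which has no repeat contours, hence no Q denominator)
#' writes the per-condition summaries and the nearest-condition histogram.
#' Reruns with the same config and seed are bit-identical for all CSVs.
#'
#' @param config a [study_config()].
#' @return Nodule mode: a `feature_robustness` object (with the study
#'   directory in attribute `study_dir`). Phantom mode: list with `summary`
#'   and `nearest`.
#' @export
run_pipeline <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  dir_ <- generate_study(config)
  features <- extract_study(dir_, config)
  m <- read_manifest(dir_)
  summ <- condition_feature_summary(features)
  write.csv(summ, file.path(dir_, "summary.csv"), row.names = FALSE)
  near <- nearest_condition_histogram(summ, m$reference)
  write.csv(near, file.path(dir_, "nearest_conditions.csv"), row.names = FALSE)
  grDevices::png(file.path(dir_, "nearest_conditions.png"),
                 width = 900, height = 500)
  barplot(near$count, names.arg = near$condition, las = 2,
          ylab = "# features nearest to reference",
          main = paste("Nearest condition to", m$reference))
  grDevices::dev.off()
  if (config$mode == "phantom") {
    return(list(summary = summ, nearest = near, reference = m$reference,
                study_dir = dir_))
  }
  res <- analyze_robustness(features, m$reference, sd_type = config$sd_type)
  write.csv(res$qtable, file.path(dir_, "qtable.csv"), row.names = FALSE)
  write.csv(res$feature_ranking, file.path(dir_, "feature_ranking.csv"),
            row.names = FALSE)
  write.csv(res$condition_ranking, file.path(dir_, "condition_ranking.csv"),
            row.names = FALSE)
  attr(res, "study_dir") <- dir_
  res
}
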