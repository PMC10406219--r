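## The twelve numbered pre-processing pipelines and the evaluation
## battery.  Stage order within a preset: slice timing -> dummy-volume
## drop -> realignment (estimated from the magnitude, applied to both
## streams) -> one joint nuisance regression (band-stop + polynomials +
## motion + RETROICOR + tissue means, as the preset demands; a single step
## keeps residuals orthogonal to every regressor and minimizes blurring)
## -> phase regression -> smoothing.

pipeline_step_table <- function() {
  list(
    `1`  = c("realign"),
    `2`  = c("realign", "bandpass"),
    `3`  = c("realign", "bandpass", "motion_reg"),
    `4`  = c("realign", "bandpass", "motion_reg", "physio_reg"),
    `5`  = c("realign", "bandpass", "motion_reg", "physio_reg", "tissue_reg"),
    `6`  = c("realign", "bandpass", "phase"),
    `7`  = c("realign", "bandpass", "motion_reg", "phase"),
    `8`  = c("realign", "bandpass", "motion_reg", "physio_reg", "phase"),
    `9`  = c("realign", "bandpass", "motion_reg", "physio_reg", "tissue_reg",
             "phase"),
    `10` = c("realign", "bandpass", "motion_reg", "physio_reg", "phase",
             "smooth"),
    `11` = c("realign", "bandpass", "motion_reg", "tissue_reg"),
    `12` = c("realign", "bandpass", "motion_reg", "tissue_reg", "phase")
  )
}

#' Numbered pre-processing pipeline presets
#'
#' Returns the composition of one of the twelve numbered pipelines.
#' Presets 1-5 accumulate realignment, band-pass filtering, motion
#' regression, physiological (RETROICOR) regression and CSF/WM regression;
#' presets 6-9 add phase-based vein correction to presets 2-5; preset 10
#' adds smoothing to preset 8's steps plus phase correction; presets 11
#' and 12 add CSF/WM regression (and then phase correction) to preset 3.
#' All nuisance regressors of a preset are removed in a single joint
#' regression, and the phase stream receives every step the magnitude
#' receives before phase regression.
#'
#' @param id integer 1..12.
#' @return An object of class `pipeline_spec`: `id`, `steps`,
#'   `requires_phase`, `requires_physio`.
#' @export
preset <- function(id) {
  tab <- pipeline_step_table()
  key <- as.character(as.integer(id))
  if (!key %in% names(tab)) stop_lp("preset id must be an integer in 1..12")
  steps <- tab[[key]]
  structure(list(id = as.integer(id), steps = steps,
                 requires_phase = "phase" %in% steps,
                 requires_physio = "physio_reg" %in% steps),
            class = "pipeline_spec")
}

#' @export
print.pipeline_spec <- function(x, ...) {
  cat(sprintf("<pipeline_spec #%d> %s\n", x$id,
              paste(x$steps, collapse = " + ")))
  invisible(x)
}

## ---- shared pipeline front-end ------------------------------------------

## slice timing + dummy drop + realignment, common to every preset
pipeline_prefix <- function(mag, phase = NULL, physio = NULL,
                            slice_times_s = NULL, ref_time_s = 0,
                            n_dummy = 4L, motion = NULL) {
  if (!is.null(slice_times_s)) {
    mag <- slice_timing_correct(mag, slice_times_s, ref_time_s)
    if (!is.null(phase)) {
      phase <- slice_timing_correct(phase, slice_times_s, ref_time_s)
    }
  }
  if (n_dummy > 0) {
    mag <- drop_initial_volumes(mag, n_dummy)
    if (!is.null(phase)) phase <- drop_initial_volumes(phase, n_dummy)
    if (!is.null(physio)) physio <- shift_physio(physio, n_dummy, mag$tr_s)
  }
  if (is.null(motion)) motion <- estimate_motion(mag)
  mag <- apply_rigid(mag, motion)
  if (!is.null(phase)) phase <- apply_rigid(phase, motion)
  list(mag = mag, phase = phase, physio = physio, motion = motion)
}

## the preset-specific part, applied after the shared front-end
pipeline_tail <- function(pre, spec, tissue = NULL,
                          band_hz = c(0.005, 0.12), poly_degree = 5L,
                          retroicor_order = 5L, fwhm_mm = 1.0,
                          mask_threshold = 0.99) {
  mag <- pre$mag; phase <- pre$phase
  steps <- spec$steps
  nt <- n_volumes(mag)
  t_vol <- (seq_len(nt) - 1) * mag$tr_s
  reg_parts <- list()
  if ("bandpass" %in% steps) {
    reg_parts$bandstop <- build_bandstop_regressors(nt, mag$tr_s, band_hz,
                                                    poly_degree)
  }
  if ("motion_reg" %in% steps) {
    mp <- pre$motion$params
    keep <- apply(mp, 2, function(col) stats::sd(col) > 0)
    if (any(keep)) {
      reg_parts$motion <- regressor_matrix(mp[, keep, drop = FALSE],
                                           colnames(mp)[keep],
                                           rep("motion", sum(keep)))
    }
  }
  if ("physio_reg" %in% steps) {
    assert_that(!is.null(pre$physio),
                sprintf("preset %d requires a physiological recording",
                        spec$id))
    reg_parts$physio <- build_retroicor_regressors(pre$physio, t_vol,
                                                   retroicor_order)
  }
  if ("tissue_reg" %in% steps) {
    assert_that(!is.null(tissue),
                sprintf("preset %d requires tissue fraction maps", spec$id))
    masks <- make_tissue_masks(tissue, mask_threshold)
    csf_tc <- mean_timecourse(mag, masks$csf)
    wm_tc <- mean_timecourse(mag, masks$wm)
    reg_parts$tissue <- regressor_matrix(cbind(csf_tc, wm_tc),
                                         c("mean_csf", "mean_wm"),
                                         c("tissue", "tissue"))
  }
  fit <- NULL
  if (length(reg_parts) > 0) {
    regressors <- do.call(bind_regressors, unname(reg_parts))
    mag <- regress_nuisance(mag, regressors)$series
    if (!is.null(phase) && "phase" %in% steps) {
      phase <- regress_nuisance(phase, regressors)$series
    }
  }
  if ("phase" %in% steps) {
    assert_that(!is.null(phase),
                sprintf("preset %d requires a phase series", spec$id))
    pr <- phase_regress(mag, phase)
    mag <- pr$series
    fit <- pr$fit
  }
  if ("smooth" %in% steps) {
    mag <- smooth_gaussian(mag, fwhm_mm)
  }
  list(series = mag, fit = fit, motion = pre$motion)
}

#' Run one pre-processing pipeline over a scan bundle
#'
#' @param bundle list with `mag` (a [bold_series()]) and, as the preset
#'   requires, `phase` ([phase_series()]), `physio`
#'   ([physio_recording()]) and `tissue` ([tissue_maps()]).
#' @param spec a [preset()] (or an integer preset id).
#' @param slice_times_s optional per-slice acquisition offsets; when
#'   supplied, slice-timing correction runs first.
#' @param ref_time_s slice-timing reference offset.
#' @param n_dummy leading volumes to discard (default 4).
#' @param motion optional precomputed [motion_trace()] for the *retained*
#'   volumes (e.g. ground truth for a simulated scan); estimated from the
#'   magnitude when `NULL`.
#' @param band_hz,poly_degree band-pass projection parameters.
#' @param retroicor_order RETROICOR Fourier order.
#' @param fwhm_mm smoothing kernel width.
#' @param mask_threshold tissue mask threshold.
#' @return List: `series` (processed magnitude), `fit` (de-veining fit or
#'   NULL), `motion` (the trace used), `spec`.
#' @export
run_pipeline <- function(bundle, spec, slice_times_s = NULL, ref_time_s = 0,
                         n_dummy = 4L, motion = NULL,
                         band_hz = c(0.005, 0.12), poly_degree = 5L,
                         retroicor_order = 5L, fwhm_mm = 1.0,
                         mask_threshold = 0.99) {
  if (is.numeric(spec)) spec <- preset(spec)
  assert_that(!is.null(bundle$mag), "bundle must contain a magnitude series")
  if (spec$requires_phase && is.null(bundle$phase)) {
    stop_lp(sprintf("preset %d requires the phase stream", spec$id))
  }
  if (spec$requires_physio && is.null(bundle$physio)) {
    stop_lp(sprintf("preset %d requires the physio stream", spec$id))
  }
  pre <- pipeline_prefix(bundle$mag, bundle$phase, bundle$physio,
                         slice_times_s, ref_time_s, n_dummy, motion)
  out <- pipeline_tail(pre, spec, tissue = bundle$tissue, band_hz = band_hz,
                       poly_degree = poly_degree,
                       retroicor_order = retroicor_order, fwhm_mm = fwhm_mm,
                       mask_threshold = mask_threshold)
  out$spec <- spec
  out
}

#' Evaluate a set of pipelines over one scan
#'
#' Runs each requested preset (sharing the slice-timing / dummy-drop /
#' realignment front-end) and computes the evaluation battery: GM fAvLFF,
#' GM/CSF fAvLFF ratio, AvLFF GM/CSF ratio, mean cross-cortex homogeneity,
#' mean correlation with noise, and -- when a task design is supplied --
#' the GM/CSF beta ratio and the depth of the most superficial
#' activation-profile peak.  Pairwise paired t-tests across presets are
#' computed on the per-line homogeneity values.
#'
#' @param bundle scan bundle as in [run_pipeline()]; `tissue` is required
#'   for the tissue-specific metrics.
#' @param lines list of [cross_cortex_line()].
#' @param preset_ids integer vector of presets to evaluate (may be empty).
#' @param task optional [task_design()] for evoked metrics.
#' @param mask_threshold tissue mask threshold for the metric masks.
#' @param ... passed through to the pipeline stages (see
#'   [run_pipeline()]).
#' @return List of class `pipeline_report`: `table` (one row per preset),
#'   `homogeneity_by_line` (lines x presets), `pairwise` (paired-test
#'   matrices), `series` (named list of processed series).
#' @export
evaluate_all <- function(bundle, lines, preset_ids, task = NULL,
                         mask_threshold = 0.99, slice_times_s = NULL,
                         ref_time_s = 0, n_dummy = 4L, motion = NULL, ...) {
  if (length(preset_ids) == 0L) {
    return(structure(list(table = data.frame(), homogeneity_by_line = NULL,
                          pairwise = NULL, series = list()),
                     class = "pipeline_report"))
  }
  pre <- pipeline_prefix(bundle$mag, bundle$phase, bundle$physio,
                         slice_times_s, ref_time_s, n_dummy, motion)
  masks <- make_tissue_masks(bundle$tissue, mask_threshold)
  rois <- if (!is.null(task)) define_task_rois(bundle$tissue) else NULL
  nt <- n_volumes(pre$mag)
  t_vol <- (seq_len(nt) - 1) * pre$mag$tr_s
  noise_parts <- NULL
  if (!is.null(pre$physio)) {
    al <- alias_physio(pre$physio, t_vol)
    noise_parts <- list(aliased = cbind(al$cardiac, al$respiratory),
                        retroicor = build_retroicor_regressors(pre$physio,
                                                               t_vol))
  }
  rows <- list(); hom_by_line <- list(); series_out <- list()
  for (id in preset_ids) {
    spec <- preset(id)
    run <- pipeline_tail(pre, spec, tissue = bundle$tissue,
                         mask_threshold = mask_threshold, ...)
    s <- run$series
    gm_tc <- mean_timecourse(s, masks$gm)
    csf_tc <- mean_timecourse(s, masks$csf)
    gm_fav <- favlff(power_spectrum(gm_tc, s$tr_s, "none"))
    csf_fav <- favlff(power_spectrum(csf_tc, s$tr_s, "none"))
    bpr <- band_power_ratio(s, masks$gm, masks$csf)
    hom <- vapply(lines, function(ln) {
      homogeneity(line_courses(s, ln), s$tr_s)$mean
    }, numeric(1))
    mnc <- NA_real_
    if (!is.null(noise_parts)) {
      wm_tc <- mean_timecourse(s, masks$wm)
      mag_courses <- line_courses(s, lines[[1]])
      phase_courses <- if (!is.null(pre$phase)) {
        line_courses(pre$phase, lines[[1]])
      } else mag_courses   # phase stream absent: stack degenerates
      stack <- noise_correlation_stack(pre$motion, noise_parts$aliased,
                                       noise_parts$retroicor,
                                       cbind(csf_tc, gm_tc, wm_tc),
                                       mag_courses, phase_courses)
      mnc <- stack$mean_noise_correlation
    }
    row <- data.frame(preset = id, gm_favlff = gm_fav,
                      favlff_ratio = if (csf_fav > 0) gm_fav / csf_fav else NA,
                      avlff_ratio = bpr$avlff_ratio,
                      mean_homogeneity = mean(hom),
                      mean_noise_correlation = mnc)
    if (!is.null(task)) {
      des <- build_design(task)
      amap <- fit_glm(s, des)
      ratio <- gm_csf_beta_ratio(amap, rois$gm, rois$csf)
      prof <- line_profile(amap, lines)
      row$beta_ratio <- ratio$ratio
      row$beta_ratio_defined <- ratio$defined
      row$peak_depth <- profile_peak_depth(prof$profile, prof$depth)
    }
    rows[[as.character(id)]] <- row
    hom_by_line[[sprintf("preset_%d", id)]] <- hom
    series_out[[sprintf("preset_%d", id)]] <- s
  }
  hom_mat <- do.call(cbind, hom_by_line)
  pairwise <- if (length(lines) >= 3 && length(preset_ids) >= 2) {
    paired_test_matrix(hom_mat)
  } else NULL
  structure(list(table = do.call(rbind, rows),
                 homogeneity_by_line = hom_mat, pairwise = pairwise,
                 series = series_out),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (nrow(x$table)) print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
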