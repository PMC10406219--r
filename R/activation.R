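## Task analysis: design construction, voxel-wise GLM, thresholding,
## GM/CSF activation ratio and cortical-depth activation profiles.

#' Block task design
#'
#' @param onsets_s strictly increasing, non-negative block onsets (s),
#'   relative to the first retained volume.
#' @param durations_s positive block durations (s), same length.
#' @param n_volumes number of retained volumes.
#' @param tr_s repetition time (s).
#' @return An object of class `task_design`.
#' @export
task_design <- function(onsets_s, durations_s, n_volumes, tr_s) {
  assert_that(length(onsets_s) >= 1L, "onsets must be non-empty")
  assert_that(length(onsets_s) == length(durations_s),
              "onsets and durations must have equal length")
  assert_that(all(onsets_s >= 0) && all(diff(onsets_s) > 0),
              "onsets must be non-negative and strictly increasing")
  assert_that(all(durations_s > 0), "durations must be positive")
  scan_end <- n_volumes * tr_s
  assert_that(all(onsets_s + durations_s <= scan_end),
              "blocks must end before the end of the scan")
  structure(list(onsets_s = onsets_s, durations_s = durations_s,
                 n_volumes = as.integer(n_volumes), tr_s = tr_s),
            class = "task_design")
}

#' Read a BIDS-style events TSV into a task design
#'
#' @param path TSV with columns `onset` and `duration` (seconds).
#' @param n_volumes,tr_s series timing.
#' @return A [task_design()].
#' @export
read_events <- function(path, n_volumes, tr_s) {
  ev <- utils::read.delim(path, sep = "\t", header = TRUE)
  assert_that(all(c("onset", "duration") %in% names(ev)),
              "events file needs `onset` and `duration` columns")
  task_design(ev$onset, ev$duration, n_volumes, tr_s)
}

#' Build the GLM task regressor
#'
#' Boxcar at volume resolution (a volume is "on" when its acquisition time
#' falls inside a block) convolved with the shared double-gamma HRF
#' ([hrf_double_gamma()]), trimmed to the scan length and scaled to unit
#' peak; plus an intercept column.
#'
#' @param task a [task_design()].
#' @return A [regressor_matrix()] with columns `task` (kind `task`) and
#'   `intercept` (kind `poly`).
#' @export
build_design <- function(task) {
  nt <- task$n_volumes
  t_vol <- (seq_len(nt) - 1) * task$tr_s
  box <- rep(0, nt)
  for (i in seq_along(task$onsets_s)) {
    box[t_vol >= task$onsets_s[i] &
          t_vol < task$onsets_s[i] + task$durations_s[i]] <- 1
  }
  hrf_t <- seq(0, 32, by = task$tr_s)
  h <- hrf_double_gamma(hrf_t)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_len(nt)]
  peak <- max(abs(conv))
  assert_that(peak > 0, "task regressor is identically zero")
  regressor_matrix(cbind(task = conv / peak, intercept = rep(1, nt)),
                   c("task", "intercept"), c("task", "poly"))
}

#' Voxel-wise GLM activation maps
#'
#' Ordinary least squares per voxel on `[task | nuisance | intercept]`.
#' `beta` is the task coefficient, `t = beta / SE(beta)` with
#' `dof = t_volumes - rank(design)`, and `p` is the two-sided Student-t
#' tail probability.  No prewhitening is applied.
#'
#' @param series a processed `bold_series`.
#' @param design a [regressor_matrix()] containing a `task` column (e.g.
#'   from [build_design()]).
#' @param nuisance optional extra [regressor_matrix()] (already-removed
#'   nuisance does not need repeating).
#' @return An object of class `activation_map`: 3D arrays `beta`,
#'   `t_stat`, `p`, plus scalar `dof`.
#' @export
fit_glm <- function(series, design, nuisance = NULL) {
  d <- dim(series$data)
  X <- design$values
  if (!is.null(nuisance)) X <- cbind(X, nuisance$values)
  assert_that(nrow(X) == d[4], "design rows must match volumes")
  task_col <- which(design$kind == "task")[1]
  assert_that(!is.na(task_col), "design has no task column")
  dup <- duplicated(t(X))
  X <- X[, !dup, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop_lp("rank-deficient GLM design")
  dof <- d[4] - qrX$rank
  assert_that(dof > 0, "no residual degrees of freedom")
  Y <- t(matrix(series$data, nrow = prod(d[1:3]), ncol = d[4]))
  coefs <- qr.coef(qrX, Y)
  resid <- qr.resid(qrX, Y)
  sigma2 <- colSums(resid^2) / dof
  XtX_inv <- chol2inv(qr.R(qrX)[seq_len(qrX$rank), seq_len(qrX$rank)])
  ## map the task column through the pivot
  pos <- which(qrX$pivot == task_col)
  se <- sqrt(sigma2 * XtX_inv[pos, pos])
  beta <- coefs[task_col, ]
  t_stat <- ifelse(se > 0, beta / se, 0)
  p <- 2 * stats::pt(abs(t_stat), df = dof, lower.tail = FALSE)
  structure(list(beta = array(beta, dim = d[1:3]),
                 t_stat = array(t_stat, dim = d[1:3]),
                 p = array(p, dim = d[1:3]), dof = dof),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  thr <- stats::qt(1 - 0.001 / 2, df = x$dof)
  cat(sprintf("<activation_map> dof %d; |t| range [%.2f, %.2f]; two-sided t threshold at p=0.001: %.2f\n",
              x$dof, min(x$t_stat), max(x$t_stat), thr))
  invisible(x)
}

#' Threshold an activation map
#'
#' Keeps voxels with `p < p_threshold` (strict); no cluster-extent or
#' multiplicity correction is applied.  The implied two-sided t threshold
#' is attached as an attribute.
#'
#' @param map an `activation_map`.
#' @param p_threshold two-sided p-value cut (default 0.001).
#' @return Logical 3D array; `attr(, "t_threshold")` gives the equivalent
#'   t cut at the map's degrees of freedom.
#' @export
threshold_activation <- function(map, p_threshold = 0.001) {
  assert_that(is_scalar_num(p_threshold) && p_threshold > 0 &&
                p_threshold < 1, "p_threshold must lie in (0, 1)")
  mask <- map$p < p_threshold
  attr(mask, "t_threshold") <- stats::qt(1 - p_threshold / 2, df = map$dof)
  mask
}

#' GM/CSF activation ratio
#'
#' Mean beta over surviving (thresholded) voxels in the GM ROI divided by
#' the same in the CSF ROI.  If either ROI has no surviving voxel the
#' ratio is returned as `NA` with `defined = FALSE` (flagged, not an
#' error).
#'
#' @param map an `activation_map`.
#' @param gm_roi,csf_roi logical 3D ROI masks (non-empty).
#' @param p_threshold threshold passed to [threshold_activation()].
#' @return List: `ratio`, `defined`, `gm_mean`, `csf_mean`,
#'   `n_gm`, `n_csf` (surviving voxel counts).
#' @export
gm_csf_beta_ratio <- function(map, gm_roi, csf_roi, p_threshold = 0.001) {
  assert_that(any(gm_roi) && any(csf_roi), "both ROIs must be non-empty")
  surv <- threshold_activation(map, p_threshold)
  g <- gm_roi & surv
  c_ <- csf_roi & surv
  n_gm <- sum(g); n_csf <- sum(c_)
  if (n_gm == 0 || n_csf == 0) {
    return(list(ratio = NA_real_, defined = FALSE,
                gm_mean = if (n_gm) mean(map$beta[g]) else NA_real_,
                csf_mean = if (n_csf) mean(map$beta[c_]) else NA_real_,
                n_gm = n_gm, n_csf = n_csf))
  }
  gm_mean <- mean(map$beta[g]); csf_mean <- mean(map$beta[c_])
  list(ratio = gm_mean / csf_mean, defined = TRUE, gm_mean = gm_mean,
       csf_mean = csf_mean, n_gm = n_gm, n_csf = n_csf)
}

#' Define slab GM / adjacent-CSF ROIs from tissue fractions
#'
#' GM ROI: voxels with GM fraction >= 0.5.  CSF ROI: voxels with CSF
#' fraction >= 0.5 that touch (6-neighbourhood) a voxel with GM fraction
#' >= 0.25 -- the CSF layer adjacent to the cortical surface, where pial
#' veins run.
#'
#' @param tissue a [tissue_maps()].
#' @return List of logical 3D masks `gm` and `csf`.
#' @export
define_task_rois <- function(tissue) {
  gm_roi <- tissue$gm >= 0.5
  near_gm <- tissue$gm >= 0.25
  d <- dim(near_gm)
  touch <- array(FALSE, dim = d)
  shift_or <- function(acc, arr, ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    src <- rep(list(quote(expr = )), 3)
    n <- d[ax]
    if (by == 1) { idx[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
    else { idx[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
    acc[idx[[1]], idx[[2]], idx[[3]]] <- acc[idx[[1]], idx[[2]], idx[[3]]] |
      arr[src[[1]], src[[2]], src[[3]]]
    acc
  }
  for (ax in 1:3) for (by in c(1, -1)) {
    if (d[ax] > 1) touch <- shift_or(touch, near_gm, ax, by)
  }
  list(gm = gm_roi, csf = tissue$csf >= 0.5 & touch)
}

#' Cortical-depth profile of a statistic map along cross-cortex lines
#'
#' Each line's polyline through its voxel centres is resampled at
#' `n_points` equidistant arc positions by trilinear interpolation of the
#' map, and the profiles are averaged across lines.  Depth 0 is the CSF
#' end.
#'
#' @param volume 3D statistic map (e.g. `beta`), or an `activation_map`
#'   (its `beta` is used).
#' @param lines list of [cross_cortex_line()] within the volume bounds.
#' @param n_points number of sampling points per line (default 30).
#' @return List: `depth` (length `n_points`, 0 to 1), `profile` (mean
#'   across lines), `per_line` (matrix n_points x n_lines).
#' @export
line_profile <- function(volume, lines, n_points = 30L) {
  if (inherits(volume, "activation_map")) volume <- volume$beta
  d <- dim(volume)
  assert_that(length(d) == 3L, "`volume` must be a 3D array")
  assert_that(length(lines) >= 1L, "need at least one line")
  per_line <- vapply(seq_along(lines), function(i) {
    v <- lines[[i]]$voxels
    if (any(v < 1L) || any(v[, 1] > d[1]) || any(v[, 2] > d[2]) ||
        any(v[, 3] > d[3])) {
      stop_lp(sprintf("line %d extends outside the volume", i))
    }
    ## arc-length parameterization through voxel centres
    seg <- sqrt(rowSums(diff(v)^2))
    s <- c(0, cumsum(seg))
    s_out <- seq(0, s[length(s)], length.out = n_points)
    pts <- vapply(1:3, function(ax) {
      stats::approx(s, v[, ax], xout = s_out)$y
    }, numeric(n_points))
    trilinear_interp(volume, pts)
  }, numeric(n_points))
  list(depth = seq(0, 1, length.out = n_points),
       profile = rowMeans(per_line), per_line = per_line)
}

#' Depth of the most superficial salient profile peak
#'
#' Finds the most superficial (closest to the CSF end) interior local
#' maximum whose height reaches `min_height_frac` of the profile maximum;
#' used to quantify the de-veining shift of the superficial activation
#' peak toward deeper cortex.  The prominence requirement keeps noise
#' ripples in the flat CSF segment from registering as peaks.  Falls back
#' to the global maximum when no interior peak qualifies.
#'
#' @param profile numeric vector (a `line_profile()$profile`).
#' @param depth matching depth axis (default linear 0..1).
#' @param min_height_frac salience threshold as a fraction of the profile
#'   maximum (default 0.2).
#' @return The depth of the peak.
#' @export
profile_peak_depth <- function(profile, depth = seq(0, 1,
                                                    length.out = length(profile)),
                               min_height_frac = 0.2) {
  n <- length(profile)
  m <- max(profile)
  cand <- which(vapply(2:(n - 1), function(i) {
    profile[i] > profile[i - 1] && profile[i] >= profile[i + 1] &&
      profile[i] >= min_height_frac * m
  }, logical(1))) + 1L
  if (length(cand) == 0L) return(depth[which.max(profile)])
  depth[cand[1]]
}
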