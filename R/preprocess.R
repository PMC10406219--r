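## Pre-processing stage vocabulary: slice timing, realignment, tissue
## masks, band-pass-as-projection regressors, RETROICOR regressors,
## nuisance regression in a single step, Gaussian smoothing.

#' Slice-timing correction
#'
#' Resamples each slice's time courses onto a common reference time within
#' the TR.  Interior samples are shifted by sinc interpolation over the full
#' series; samples whose shifted position falls within one sample of the
#' series ends use linear interpolation (with edge hold) instead.
#'
#' @param series a `bold_series` or `phase_series`.
#' @param slice_times_s per-slice acquisition offsets in `[0, TR)`, one per
#'   z slice.
#' @param ref_time_s reference offset the slices are aligned to (default 0).
#' @return The corrected series.
#' @export
slice_timing_correct <- function(series, slice_times_s, ref_time_s = 0) {
  d <- dim(series$data)
  assert_that(length(slice_times_s) == d[3],
              "need one slice time per z slice")
  assert_that(all(slice_times_s >= 0 & slice_times_s < series$tr_s),
              "slice times must lie in [0, TR)")
  nt <- d[4]
  for (z in seq_len(d[3])) {
    delta <- (ref_time_s - slice_times_s[z]) / series$tr_s  # in samples
    if (abs(delta) < 1e-12) next
    S <- shift_matrix(nt, delta)
    sl <- matrix(series$data[, , z, ], nrow = d[1] * d[2], ncol = nt)
    series$data[, , z, ] <- array(sl %*% t(S), dim = c(d[1], d[2], nt))
  }
  add_step(series, sprintf("slice_timing_correct(ref=%g)", ref_time_s))
}

## nt x nt operator mapping a sampled course to the course shifted by
## `delta` samples.  The course is mirror-padded before the sinc sum (the
## value discontinuity at the series ends otherwise rings well into the
## interior); rows are renormalized so constants pass exactly, and samples
## whose shifted position leaves the original support fall back to linear
## interpolation with edge hold.
shift_matrix <- function(nt, delta, pad = 32L) {
  pad <- min(pad, nt - 1L)
  idx <- c((pad + 1):2, seq_len(nt), (nt - 1):(nt - pad))   # mirror indices
  np <- nt + 2L * pad
  pos <- seq_len(nt) + pad + delta            # output positions, padded frame
  Sp <- sinc(outer(pos, seq_len(np), `-`))
  Sp <- Sp / rowSums(Sp)
  ## collapse padded columns onto original sample indices
  S <- matrix(0, nt, nt)
  for (j in seq_len(np)) S[, idx[j]] <- S[, idx[j]] + Sp[, j]
  edge <- pos - pad < 1 | pos - pad > nt
  if (any(edge)) {
    for (i in which(edge)) {
      p <- min(max(pos[i] - pad, 1), nt)
      lo <- floor(p); hi <- min(lo + 1, nt)
      w <- p - lo
      row <- rep(0, nt)
      row[lo] <- 1 - w
      row[hi] <- row[hi] + w
      S[i, ] <- row
    }
  }
  S
}

sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))

#' Estimate rigid-body motion parameters
#'
#' Registers every volume to the reference volume by minimizing the mean
#' squared intensity difference over six rigid parameters (three rotations
#' in degrees, three translations in mm), using Nelder-Mead search with
#' trilinear resampling inside the cost.  Each volume's search starts from
#' the previous volume's estimate.
#'
#' Volumes whose optimization reports non-convergence are returned in the
#' `flagged` attribute of the trace rather than raising an error.
#'
#' Both images are pre-smoothed (Gaussian, `smooth_vox` voxels sd) before
#' entering the cost: voxel-scale texture otherwise biases the estimate,
#' because the moving volume is interpolated while the reference is not.
#'
#' @param series a `bold_series` with at least 2 volumes.
#' @param reference_index volume used as registration target (default 1).
#' @param smooth_vox sd (voxels) of the cost pre-smoothing kernel.
#' @return A [motion_trace()]; `attr(, "flagged")` lists non-converged
#'   volume indices (possibly empty).
#' @export
estimate_motion <- function(series, reference_index = 1L, smooth_vox = 1) {
  d <- dim(series$data)
  nt <- d[4]
  assert_that(nt >= 2L, "need at least 2 volumes to estimate motion")
  smooth3 <- function(vol) {
    if (smooth_vox <= 0) return(vol)
    for (ax in 1:3) {
      M <- gaussian_conv_matrix(d[ax], smooth_vox)
      perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 1, 2))
      iperm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(2, 3, 1))
      vol <- aperm(array(M %*% matrix(aperm(vol, perm), d[ax]),
                         dim = d[perm]), iperm)
    }
    vol
  }
  ref <- smooth3(series$data[, , , reference_index])
  vox <- series$voxel_size_mm
  ## margin excluded from the cost: boundary extension contaminates both
  ## the smoothing (radius 3*sigma) and the moving volume's edges
  mrg <- ceiling(3 * max(smooth_vox, 0)) + 3L
  lo <- pmin(1L + mrg, floor((d[1:3] + 1) / 2))
  hi <- pmax(d[1:3] - mrg, lo)
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  interior <- g$x >= lo[1] & g$x <= hi[1] & g$y >= lo[2] & g$y <= hi[2] &
    g$z >= lo[3] & g$z <= hi[3]
  params <- matrix(0, nt, 6)
  flagged <- integer()
  prev <- rep(0, 6)
  for (v in seq_len(nt)) {
    if (v == reference_index) { prev <- rep(0, 6); next }
    vol <- smooth3(series$data[, , , v])
    ## symmetric half-transform cost: both volumes are resampled by half
    ## the candidate motion, so interpolation blur affects both arms
    ## equally and does not bias the minimum.  The target grid is shifted
    ## by a sub-voxel offset (no candidate may sample exactly on nodes,
    ## which would be spuriously blur-free) and the cost is averaged over
    ## complementary offsets, cancelling the odd part of the residual
    ## interpolation bias.  It lives on the interior box and excludes
    ## out-of-volume samples (edge voxels carry boundary-extension
    ## artefacts).
    offsets <- list(c(0.35, 0.27, 0.41), c(0.65, 0.73, 0.59))
    cost_one <- function(theta, off) {
      p1 <- rigid_sample_points(d[1:3], theta / 2, vox, inverse = TRUE,
                                grid_offset_vox = off)
      p2 <- rigid_sample_points(d[1:3], theta / 2, vox, inverse = FALSE,
                                grid_offset_vox = off)
      inb <- function(p) {
        p[, 1] >= lo[1] & p[, 1] <= hi[1] & p[, 2] >= lo[2] &
          p[, 2] <= hi[2] & p[, 3] >= lo[3] & p[, 3] <= hi[3]
      }
      valid <- interior & inb(p1) & inb(p2)
      if (sum(valid) < 50) {
        ## vanishing overlap: finite, growing penalty keeps line searches
        ## well-defined instead of returning NaN
        return(1e12 * (1 + sum(theta^2)))
      }
      mean((trilinear_interp(vol, p1[valid, , drop = FALSE]) -
              trilinear_interp(ref, p2[valid, , drop = FALSE]))^2)
    }
    cost <- function(theta) {
      (cost_one(theta, offsets[[1]]) + cost_one(theta, offsets[[2]])) / 2
    }
    ## cheap exit when the volume already matches the reference
    if (cost(prev) <= .Machine$double.eps * mean(ref^2)) {
      params[v, ] <- prev
      next
    }
    ## gradient descent first (the cost is smooth), then Nelder-Mead with
    ## parameter scaling -- a degree of rotation displaces content far
    ## less than a millimetre of translation -- and a restart, since NM
    ## contracts prematurely in 6 dimensions
    scl <- c(1, 1, 1, 0.2, 0.2, 0.2)
    fit <- stats::optim(prev, cost, method = "BFGS",
                        control = list(maxit = 100, reltol = 1e-10))
    fit <- stats::optim(fit$par, cost, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000,
                                       parscale = scl))
    fit <- stats::optim(fit$par, cost, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000,
                                       parscale = scl))
    params[v, ] <- fit$par
    prev <- fit$par
    if (fit$convergence != 0) flagged <- c(flagged, v)
  }
  params[reference_index, ] <- 0
  if (reference_index != 1L) {
    params <- sweep(params, 2, params[1, ])  # re-reference to volume 1
  }
  out <- motion_trace(params)
  attr(out, "flagged") <- flagged
  out
}

#' Apply (undo) rigid motion to a series
#'
#' Each volume is resampled by the inverse of its motion parameters, i.e.
#' the estimated displacement is undone.  Phase volumes are resampled on
#' the unit circle (cos/sin interpolated, recombined via the angle) to
#' avoid wrap artefacts.  Volumes with all-zero parameters are passed
#' through untouched.
#'
#' @param series a `bold_series` or `phase_series`.
#' @param motion a [motion_trace()] with one row per volume.
#' @param method interpolation kernel: `"linear"` (fast default) or
#'   `"lanczos"` (windowed sinc; sharper, for band-limited data).
#' @return The realigned series.
#' @export
apply_rigid <- function(series, motion, method = c("linear", "lanczos")) {
  method <- match.arg(method)
  d <- dim(series$data)
  assert_that(nrow(motion$params) == d[4],
              "motion trace rows must match the number of volumes")
  vox <- series$voxel_size_mm
  is_phase <- inherits(series, "phase_series")
  for (v in seq_len(d[4])) {
    p <- motion$params[v, ]
    if (all(p == 0)) next
    series$data[, , , v] <- if (is_phase) {
      rigid_resample_phase(series$data[, , , v], p, vox, inverse = TRUE,
                           method = method)
    } else {
      rigid_resample(series$data[, , , v], p, vox, inverse = TRUE,
                     method = method)
    }
  }
  add_step(series, "apply_rigid")
}

#' Binarize tissue fraction maps
#'
#' A voxel enters a tissue mask when its fraction of that tissue strictly
#' exceeds the threshold (default 0.99, i.e. "above 99%").
#'
#' @param tissue a [tissue_maps()].
#' @param threshold strict lower bound in (0, 1).
#' @return List of logical 3D arrays `csf`, `gm`, `wm` (disjoint by
#'   construction of the fractions).
#' @export
make_tissue_masks <- function(tissue, threshold = 0.99) {
  assert_that(is_scalar_num(threshold) && threshold > 0 && threshold < 1,
              "threshold must lie in (0, 1)")
  list(csf = tissue$csf > threshold,
       gm = tissue$gm > threshold,
       wm = tissue$wm > threshold)
}

## Legendre polynomials P_0..P_k evaluated over the scan mapped to [-1, 1]
legendre_basis <- function(nt, degree) {
  x <- seq(-1, 1, length.out = nt)
  P <- matrix(0, nt, degree + 1)
  P[, 1] <- 1
  if (degree >= 1) P[, 2] <- x
  if (degree >= 2) {
    for (k in 2:degree) {
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
    }
  }
  P
}

#' Band-pass filtering as stop-band regressors
#'
#' Builds the projection version of a band-pass filter: sine/cosine pairs
#' at every Fourier grid frequency `k/(n_t * tr_s)` *outside* the closed
#' pass band (cosine only at Nyquist for even `n_t`), plus Legendre
#' polynomials of degree 0..`poly_degree` over the scan.  Regressing these
#' out zeroes the stop-band exactly while leaving pass-band grid
#' frequencies untouched up to polynomial overlap.
#'
#' @param n_t number of volumes (>= 8).
#' @param tr_s repetition time (s).
#' @param band_hz pass band (default `c(0.005, 0.12)` Hz).
#' @param poly_degree maximum Legendre degree (default 5).
#' @return A [regressor_matrix()] with kinds `bandstop` and `poly`.
#' @export
build_bandstop_regressors <- function(n_t, tr_s, band_hz = c(0.005, 0.12),
                                      poly_degree = 5L) {
  assert_that(n_t >= 8L, "need at least 8 volumes")
  nyquist <- 1 / (2 * tr_s)
  assert_that(band_hz[1] > 0 && band_hz[1] < band_hz[2] &&
                band_hz[2] <= nyquist,
              "band must satisfy 0 < lo < hi <= Nyquist")
  kmax <- floor(n_t / 2)
  f <- seq_len(kmax) / (n_t * tr_s)
  stop_k <- which(f < band_hz[1] | f > band_hz[2])
  t_idx <- seq_len(n_t) - 1
  cols <- list(); labels <- character(); kind <- character()
  for (k in stop_k) {
    w <- 2 * pi * k * t_idx / n_t
    cols[[length(cols) + 1]] <- cos(w)
    labels <- c(labels, sprintf("bs_cos_%d", k))
    kind <- c(kind, "bandstop")
    if (!(n_t %% 2 == 0 && k == kmax)) {  # sine vanishes at Nyquist
      cols[[length(cols) + 1]] <- sin(w)
      labels <- c(labels, sprintf("bs_sin_%d", k))
      kind <- c(kind, "bandstop")
    }
  }
  P <- legendre_basis(n_t, poly_degree)
  for (j in seq_len(ncol(P))) {
    cols[[length(cols) + 1]] <- P[, j]
    labels <- c(labels, sprintf("poly_%d", j - 1))
    kind <- c(kind, "poly")
  }
  regressor_matrix(do.call(cbind, cols), labels, kind)
}

## cardiac cycle phase at arbitrary times: linear 0 -> 2*pi between
## successive detected peaks, extrapolated at the ends
cardiac_phase <- function(trace, fs_hz, t0_s, times_s,
                          min_sep_s = 0.25, quantile_thr = 0.6) {
  pk <- detect_peaks(trace, fs_hz, min_sep_s, quantile_thr)
  if (length(pk) < 3L) {
    stop_lp("fewer than 3 peaks detected in the cardiac trace")
  }
  pk_t <- t0_s + (pk - 1) / fs_hz
  ## phase = 2*pi * (cycle index interpolated at t); linear extrapolation
  ## beyond the first/last peak reuses the neighbouring interval
  cyc <- stats::approx(pk_t, seq_along(pk_t) - 1, xout = times_s,
                       rule = 2)$y
  lo <- times_s < pk_t[1]
  hi <- times_s > pk_t[length(pk_t)]
  if (any(lo)) {
    slope <- 1 / diff(pk_t[1:2])
    cyc[lo] <- (times_s[lo] - pk_t[1]) * slope
  }
  if (any(hi)) {
    np <- length(pk_t)
    slope <- 1 / diff(pk_t[(np - 1):np])
    cyc[hi] <- (np - 1) + (times_s[hi] - pk_t[np]) * slope
  }
  2 * pi * (cyc %% 1)
}

detect_peaks <- function(trace, fs_hz, min_sep_s, quantile_thr) {
  n <- length(trace)
  thr <- stats::quantile(trace, quantile_thr)
  is_pk <- c(FALSE, trace[2:(n - 1)] > trace[1:(n - 2)] &
               trace[2:(n - 1)] >= trace[3:n], FALSE) & trace > thr
  pk <- which(is_pk)
  if (length(pk) == 0) return(integer())
  min_sep <- round(min_sep_s * fs_hz)
  keep <- pk[1]
  for (p in pk[-1]) {
    if (p - keep[length(keep)] >= min_sep) keep <- c(keep, p)
  }
  keep
}

## respiratory phase via amplitude histogram equalization with
## inspiration/expiration sign (Glover-style RETROICOR)
respiratory_phase <- function(trace, fs_hz, t0_s, times_s) {
  n <- length(trace)
  win <- max(3L, round(fs_hz))  # ~1 s smoothing for the derivative sign
  sm <- as.numeric(stats::filter(trace, rep(1 / win, win), sides = 2))
  sm[is.na(sm)] <- trace[is.na(sm)]
  dr <- c(diff(sm), 0)
  cdf <- stats::ecdf(sm)(sm)
  ph <- pi * cdf * sign(ifelse(dr == 0, 1, dr))
  ## evaluate at requested times through the unit circle (phase jumps at
  ## inflection points must not be averaged across)
  tt <- t0_s + (seq_len(n) - 1) / fs_hz
  ci <- stats::approx(tt, cos(ph), xout = times_s, rule = 2)$y
  si <- stats::approx(tt, sin(ph), xout = times_s, rule = 2)$y
  atan2(si, ci)
}

#' RETROICOR physiological regressors
#'
#' Detects cardiac and respiratory cycles in the recorded traces, computes
#' the cycle phase at every volume time, and expands each phase in a
#' sine/cosine Fourier series up to `order`, plus a multiplicative
#' cardiac-x-respiratory block with harmonics `m, n in {1, 2}` (16 terms).
#' At the default order 5 this yields `2*2*5 + 16 = 36` regressors.
#'
#' @param physio a [physio_recording()] covering all volume times.
#' @param volume_times_s acquisition time of each retained volume (s),
#'   relative to the same origin as `physio$t0_s`.
#' @param order Fourier expansion order (default 5).
#' @param include_multiplicative include the 16 interaction terms
#'   (default TRUE).
#' @return A [regressor_matrix()] with kind `physio`.
#' @export
build_retroicor_regressors <- function(physio, volume_times_s, order = 5L,
                                       include_multiplicative = TRUE) {
  check_physio_coverage(physio, volume_times_s)
  ph_c <- cardiac_phase(physio$cardiac, physio$fs_hz, physio$t0_s,
                        volume_times_s)
  resp_peaks <- detect_peaks(physio$respiratory, physio$fs_hz, 1.0, 0.6)
  if (length(resp_peaks) < 3L) {
    stop_lp("fewer than 3 peaks detected in the respiratory trace")
  }
  ph_r <- respiratory_phase(physio$respiratory, physio$fs_hz, physio$t0_s,
                            volume_times_s)
  cols <- list(); labels <- character()
  for (m in seq_len(order)) {
    cols[[length(cols) + 1]] <- sin(m * ph_c); labels <- c(labels, sprintf("card_sin_%d", m))
    cols[[length(cols) + 1]] <- cos(m * ph_c); labels <- c(labels, sprintf("card_cos_%d", m))
  }
  for (m in seq_len(order)) {
    cols[[length(cols) + 1]] <- sin(m * ph_r); labels <- c(labels, sprintf("resp_sin_%d", m))
    cols[[length(cols) + 1]] <- cos(m * ph_r); labels <- c(labels, sprintf("resp_cos_%d", m))
  }
  if (include_multiplicative) {
    fns <- list(sin = sin, cos = cos)
    for (m in 1:2) for (fc in names(fns)) for (n in 1:2) for (fr in names(fns)) {
      cols[[length(cols) + 1]] <- fns[[fc]](m * ph_c) * fns[[fr]](n * ph_r)
      labels <- c(labels, sprintf("mult_%s%d_%s%d", fc, m, fr, n))
    }
  }
  regressor_matrix(do.call(cbind, cols), labels, rep("physio", length(cols)))
}

check_physio_coverage <- function(physio, times_s) {
  tc <- physio_times(physio, "cardiac")
  tr <- physio_times(physio, "respiratory")
  lo <- max(tc[1], tr[1]); hi <- min(tc[length(tc)], tr[length(tr)])
  if (min(times_s) < lo || max(times_s) > hi) {
    stop_lp(sprintf("physio recording covers [%.2f, %.2f] s but volumes span [%.2f, %.2f] s",
                    lo, hi, min(times_s), max(times_s)))
  }
  invisible(TRUE)
}

#' Mean time course over a mask
#'
#' @param series a series object.
#' @param mask logical or 0/1 3D array; must select at least one voxel.
#' @return Numeric vector, one value per volume.
#' @export
mean_timecourse <- function(series, mask) {
  d <- dim(series$data)
  flat <- which(as.logical(mask))
  assert_that(length(flat) > 0, "mask is empty")
  m <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
  colMeans(m[flat, , drop = FALSE])
}

#' Down-sample (alias) physiological traces to volume times
#'
#' Linear interpolation of each trace at the volume acquisition times; this
#' is the aliased version of the physiological signal as seen by the scan.
#'
#' @param physio a [physio_recording()].
#' @param volume_times_s volume acquisition times (s).
#' @return List with numeric vectors `cardiac` and `respiratory`.
#' @export
alias_physio <- function(physio, volume_times_s) {
  check_physio_coverage(physio, volume_times_s)
  list(cardiac = stats::approx(physio_times(physio, "cardiac"),
                               physio$cardiac, xout = volume_times_s)$y,
       respiratory = stats::approx(physio_times(physio, "respiratory"),
                                   physio$respiratory,
                                   xout = volume_times_s)$y)
}

#' Single-step nuisance regression
#'
#' Voxel-wise ordinary least squares of all supplied regressor columns
#' simultaneously (duplicated columns are dropped first); the residuals
#' replace the data.  Performing all regressions in one step keeps the
#' residuals exactly orthogonal to every column, which sequential
#' regression of non-orthogonal blocks does not.
#'
#' Include an intercept (or polynomial) block unless the data are already
#' demeaned: projecting a large baseline onto non-constant regressors
#' inflates the residual variance.
#'
#' @param series a series object.
#' @param regressors a [regressor_matrix()] with `t` rows.
#' @return List with `series` (residuals, meta updated) and `beta`, a 4D
#'   array (x, y, z, p) of per-column coefficients (dimnames on the 4th
#'   margin).
#' @export
regress_nuisance <- function(series, regressors) {
  d <- dim(series$data)
  X <- regressors$values
  assert_that(nrow(X) == d[4],
              "regressor rows must match the number of volumes")
  dup <- duplicated(t(X))
  if (any(dup)) {
    X <- X[, !dup, drop = FALSE]
  }
  labels <- colnames(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- labels[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_lp("rank-deficient design; collinear columns: ",
            paste(bad, collapse = ", "))
  }
  Y <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
  ## project through the orthonormal Q factor: numerically safe for
  ## harmonically related (ill-conditioned) designs, and cheaper than
  ## Householder updates on the (voxels x time) matrix
  p <- ncol(X)
  Q <- qr.Q(qrX)[, seq_len(p), drop = FALSE]
  Rm <- qr.R(qrX)[seq_len(p), seq_len(p), drop = FALSE]
  piv <- qrX$pivot[seq_len(p)]
  B0 <- Y %*% Q                       # nvox x p, coordinates in Q basis
  resid <- Y - tcrossprod(B0, Q)
  beta <- matrix(0, nrow(Y), p)
  beta[, piv] <- t(backsolve(Rm, t(B0)))
  series$data <- array(resid, dim = d)
  series <- add_step(series, sprintf("regress_nuisance(p=%d)", ncol(X)))
  beta_arr <- array(beta, dim = c(d[1:3], ncol(X)),
                    dimnames = list(NULL, NULL, NULL, labels))
  list(series = series, beta = beta_arr)
}

#' Spatial Gaussian smoothing
#'
#' Per-volume separable 3D Gaussian blur specified by its full width at
#' half maximum in mm.  The truncated kernel is renormalized at the volume
#' edges, so the spatial mean of each volume is preserved.
#'
#' @param series a series object.
#' @param fwhm_mm full width at half maximum (mm); 0 is the identity.
#' @return The smoothed series.
#' @export
smooth_gaussian <- function(series, fwhm_mm = 1.0) {
  assert_that(is_scalar_num(fwhm_mm) && fwhm_mm >= 0, "fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(add_step(series, "smooth_gaussian(fwhm=0)"))
  d <- dim(series$data)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / series$voxel_size_mm
  ops <- lapply(1:3, function(ax) gaussian_conv_matrix(d[ax], sigma_vox[ax]))
  dat <- series$data
  ## axis 1
  dat <- array(ops[[1]] %*% matrix(dat, d[1], prod(d[2:4])), dim = d)
  ## axis 2
  dat <- aperm(array(ops[[2]] %*% matrix(aperm(dat, c(2, 1, 3, 4)), d[2],
                                         prod(d[c(1, 3, 4)])),
                     dim = d[c(2, 1, 3, 4)]), c(2, 1, 3, 4))
  ## axis 3
  dat <- aperm(array(ops[[3]] %*% matrix(aperm(dat, c(3, 1, 2, 4)), d[3],
                                         prod(d[c(1, 2, 4)])),
                     dim = d[c(3, 1, 2, 4)]), c(2, 3, 1, 4))
  series$data <- dat
  add_step(series, sprintf("smooth_gaussian(fwhm=%g)", fwhm_mm))
}

## n x n convolution operator with a truncated Gaussian whose columns are
## renormalized to sum to one: each source voxel's mass is conserved, so
## the spatial mean of a volume is preserved exactly, including at edges
gaussian_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma_vox))
  offsets <- -r:r
  w <- exp(-offsets^2 / (2 * sigma_vox^2))
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offsets
    ok <- j >= 1 & j <= n
    M[i, j[ok]] <- w[ok]
  }
  sweep(M, 2, colSums(M), `/`)
}
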