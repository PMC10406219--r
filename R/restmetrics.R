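## Resting-state evaluation: power spectra, fractional amplitude of
## very-low-frequency fluctuations (fAvLFF), cross-cortex homogeneity
## (temporal correlation + spectral coherence), noise correlation matrices
## and paired tests across pipelines.

#' One-sided power spectrum of a time course
#'
#' Squared-magnitude periodogram of the demeaned course on the Fourier
#' grid `k/(t * tr_s)`, `k = 1..floor(t/2)`, scaled so that the total
#' power equals `t * var(x)` (Parseval).  With `normalization = "max1"`
#' every value is divided by the spectrum maximum.
#'
#' @param tc numeric time course with at least 8 samples.
#' @param tr_s sampling interval (s).
#' @param normalization `"max1"` (default) or `"none"`.
#' @return An object of class `spectrum_profile`: `freqs_hz`, `power`,
#'   `normalization`.
#' @export
power_spectrum <- function(tc, tr_s, normalization = c("max1", "none")) {
  normalization <- match.arg(normalization)
  nt <- length(tc)
  assert_that(nt >= 8L, "need at least 8 samples")
  x <- tc - mean(tc)
  X <- stats::fft(x)
  kmax <- floor(nt / 2)
  k <- seq_len(kmax)
  w <- rep(2, kmax)
  if (nt %% 2 == 0) w[kmax] <- 1   # Nyquist bin is its own conjugate
  power <- w * Mod(X[k + 1])^2 / nt
  if (normalization == "max1") {
    mx <- max(power)
    if (mx == 0) stop_lp("cannot max-normalize the spectrum of a constant course")
    power <- power / mx
  }
  structure(list(freqs_hz = k / (nt * tr_s), power = power,
                 normalization = normalization),
            class = "spectrum_profile")
}

#' @export
print.spectrum_profile <- function(x, ...) {
  cat(sprintf("<spectrum_profile> %d bins, %.4g-%.4g Hz, normalization: %s\n",
              length(x$power), min(x$freqs_hz), max(x$freqs_hz),
              x$normalization))
  invisible(x)
}

#' Fractional amplitude of very-low-frequency fluctuations
#'
#' Power summed over the closed band divided by power summed over the full
#' spectrum; the relative weight of the 0.015-0.04 Hz range typical of
#' resting neuronal fluctuations.
#'
#' @param spectrum a [power_spectrum()] result.
#' @param band_hz closed frequency band (default `c(0.015, 0.04)`).
#' @return Fraction in `[0, 1]`.
#' @export
favlff <- function(spectrum, band_hz = c(0.015, 0.04)) {
  in_band <- spectrum$freqs_hz >= band_hz[1] & spectrum$freqs_hz <= band_hz[2]
  assert_that(any(in_band), "no spectrum bins inside the band")
  total <- sum(spectrum$power)
  if (total == 0) return(0)
  sum(spectrum$power[in_band]) / total
}

## per-voxel in-band absolute power and fAvLFF for the voxels of a mask
voxel_band_power <- function(series, mask, band_hz) {
  d <- dim(series$data)
  flat <- which(as.logical(mask))
  assert_that(length(flat) > 0, "mask is empty")
  Y <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])[flat, ,
                                                             drop = FALSE]
  Y <- Y - rowMeans(Y)
  X <- stats::mvfft(t(Y))
  nt <- d[4]
  kmax <- floor(nt / 2)
  w <- rep(2, kmax); if (nt %% 2 == 0) w[kmax] <- 1
  pw <- (Mod(X[seq_len(kmax) + 1, , drop = FALSE])^2) * w / nt
  f <- seq_len(kmax) / (nt * series$tr_s)
  in_band <- f >= band_hz[1] & f <= band_hz[2]
  assert_that(any(in_band), "no spectrum bins inside the band")
  band_power <- colSums(pw[in_band, , drop = FALSE])
  total <- colSums(pw)
  list(band = band_power,
       fraction = ifelse(total > 0, band_power / total, 0))
}

#' In-band power ratio between two compartments
#'
#' Mean in-band (absolute) spectral power across the voxels of `mask_a`
#' divided by the same for `mask_b` -- the AvLFF ratio, an indicator of
#' signal localization when `a` is GM and `b` is CSF.  The fAvLFF-ratio
#' variant (ratio of mean fractional power) is returned alongside.
#'
#' @param series a processed series.
#' @param mask_a,mask_b non-empty logical 3D masks.
#' @param band_hz closed band (default `c(0.015, 0.04)`).
#' @return List: `avlff_ratio`, `favlff_ratio`, `defined`.
#' @export
band_power_ratio <- function(series, mask_a, mask_b,
                             band_hz = c(0.015, 0.04)) {
  a <- voxel_band_power(series, mask_a, band_hz)
  b <- voxel_band_power(series, mask_b, band_hz)
  den <- mean(b$band)
  if (den == 0) {
    return(list(avlff_ratio = NA_real_, favlff_ratio = NA_real_,
                defined = FALSE))
  }
  fden <- mean(b$fraction)
  list(avlff_ratio = mean(a$band) / den,
       favlff_ratio = if (fden > 0) mean(a$fraction) / fden else NA_real_,
       defined = TRUE)
}

## Welch cross-spectral matrix: returns per-frequency-bin segment-averaged
## cross-spectra for all course pairs.  Hann window, 50% overlap.
welch_segments <- function(X, seg_len) {
  nt <- nrow(X)
  step <- max(1L, floor(seg_len / 2))
  starts <- seq(1L, nt - seg_len + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / seg_len))
  lapply(starts, function(s) {
    seg <- X[s:(s + seg_len - 1L), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    stats::mvfft(seg * w)
  })
}

#' Magnitude-squared coherence, Welch estimate
#'
#' Averaged over segments of length `min(64, floor(t/2))` with 50% overlap
#' and a Hann window, then averaged across the frequency bins inside
#' `band_hz`.
#'
#' @param x,y numeric courses of equal length.
#' @param tr_s sampling interval (s).
#' @param band_hz band over which coherence is averaged.
#' @return Band-mean magnitude-squared coherence in `[0, 1]`.
#' @export
band_coherence <- function(x, y, tr_s, band_hz = c(0.01, 0.1)) {
  co <- coherence_matrix(cbind(x, y), tr_s, band_hz)
  co[1, 2]
}

## band-mean magnitude-squared coherence between all columns of `courses`
coherence_matrix <- function(courses, tr_s, band_hz) {
  nt <- nrow(courses)
  n <- ncol(courses)
  seg_len <- min(64L, floor(nt / 2))
  segs <- welch_segments(courses, seg_len)
  f <- (seq_len(seg_len) - 1) / (seg_len * tr_s)
  bins <- which(f >= band_hz[1] & f <= band_hz[2] & seq_along(f) - 1 >= 1 &
                  seq_along(f) - 1 <= seg_len / 2)
  assert_that(length(bins) >= 1L, "no Welch frequency bins inside the band")
  nb <- length(bins)
  Sxy <- array(0 + 0i, dim = c(nb, n, n))
  for (Fm in segs) {
    Fb <- Fm[bins, , drop = FALSE]
    for (j in seq_len(n)) {
      Sxy[, , j] <- Sxy[, , j] + Fb * Conj(Fb[, rep(j, n), drop = FALSE])
    }
  }
  out <- matrix(1, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      msc <- Mod(Sxy[, i, j])^2 / (Re(Sxy[, i, i]) * Re(Sxy[, j, j]))
      out[i, j] <- out[j, i] <- mean(msc)
    }
  }
  out
}

#' Cross-voxel homogeneity of a set of time courses
#'
#' For every pair of courses, homogeneity is the average of the temporal
#' Pearson correlation (signed) and the band-mean magnitude-squared
#' coherence ([band_coherence()]).  The mean scalar averages the strictly
#' off-diagonal entries.  Lower homogeneity indicates better signal
#' separation (more independence) across the cortical depth.
#'
#' @param courses numeric matrix, `t x n` (`n >= 2`, `t >= 32`), e.g. the
#'   ten voxels of a cross-cortex line.
#' @param tr_s sampling interval (s).
#' @param band_hz coherence band (default `c(0.01, 0.1)` Hz).
#' @return An object of class `homogeneity_matrix`: `values` (n x n,
#'   symmetric, unit diagonal) and `mean` (scalar).
#' @export
homogeneity <- function(courses, tr_s, band_hz = c(0.01, 0.1)) {
  courses <- as.matrix(courses)
  nt <- nrow(courses); n <- ncol(courses)
  assert_that(n >= 2L, "need at least 2 courses")
  assert_that(nt >= 32L, "need at least 32 time points")
  sds <- apply(courses, 2, stats::sd)
  if (any(sds == 0)) {
    stop_lp("zero-variance course at index ",
            paste(which(sds == 0), collapse = ", "))
  }
  r <- stats::cor(courses)
  coh <- coherence_matrix(courses, tr_s, band_hz)
  h <- (r + coh) / 2
  diag(h) <- 1
  dimnames(h) <- NULL
  structure(list(values = h, mean = mean(h[lower.tri(h)])),
            class = "homogeneity_matrix")
}

#' @export
print.homogeneity_matrix <- function(x, ...) {
  cat(sprintf("<homogeneity_matrix> %d x %d, mean off-diagonal %.3f\n",
              nrow(x$values), ncol(x$values), x$mean))
  invisible(x)
}

#' Correlation matrix of nuisance components and data voxels
#'
#' Stacks, in order: six motion parameters (3 rotations, 3 translations),
#' the aliased cardiac and respiratory traces, the 36 RETROICOR
#' regressors, the mean CSF/GM/WM courses, the magnitude courses of the
#' cross-cortex line voxels (CSF to WM) and their phase courses, and
#' returns the labelled Pearson correlation matrix plus the mean absolute
#' correlation of each data voxel with the noise components (motion,
#' aliased, RETROICOR, tissue means).
#'
#' @param motion a [motion_trace()] or `t x 6` matrix.
#' @param aliased `t x 2` matrix (cardiac, respiratory) from
#'   [alias_physio()].
#' @param retroicor a [regressor_matrix()] of RETROICOR columns.
#' @param tissue_means `t x 3` matrix (CSF, GM, WM mean courses).
#' @param mag_courses,phase_courses `t x k` matrices of line-voxel courses
#'   (CSF to WM order).
#' @return List: `correlation` (labelled symmetric matrix),
#'   `mean_noise_correlation` (scalar; mean |r| between magnitude voxels
#'   and noise components, NA-safe for zero-variance components),
#'   `labels`.
#' @export
noise_correlation_stack <- function(motion, aliased, retroicor, tissue_means,
                                    mag_courses, phase_courses) {
  if (inherits(motion, "motion_trace")) motion <- motion$params
  if (inherits(retroicor, "regressor_matrix")) retroicor <- retroicor$values
  aliased <- as.matrix(aliased); tissue_means <- as.matrix(tissue_means)
  mag_courses <- as.matrix(mag_courses)
  phase_courses <- as.matrix(phase_courses)
  parts <- list(motion = motion, aliased = aliased, retroicor = retroicor,
                tissue = tissue_means, mag = mag_courses,
                phase = phase_courses)
  nt <- vapply(parts, nrow, integer(1))
  if (length(unique(nt)) != 1L) {
    bad <- names(nt)[nt != nt[1]]
    stop_lp("component length mismatch: ", paste(bad, collapse = ", "))
  }
  labels <- c(colnames(motion_trace(matrix(0, 2, 6))$params),
              c("aliased_cardiac", "aliased_resp"),
              colnames(retroicor) %||% paste0("retroicor_", seq_len(ncol(retroicor))),
              c("mean_csf", "mean_gm", "mean_wm"),
              paste0("mag_vox_", seq_len(ncol(mag_courses))),
              paste0("phase_vox_", seq_len(ncol(phase_courses))))
  stack <- do.call(cbind, parts)
  colnames(stack) <- labels
  keep_var <- apply(stack, 2, stats::sd) > 0
  cm <- suppressWarnings(stats::cor(stack))
  n_noise <- ncol(motion) + 2 + ncol(retroicor) + 3
  mag_idx <- n_noise + seq_len(ncol(mag_courses))
  noise_idx <- which(keep_var[seq_len(n_noise)])
  mnc <- mean(abs(cm[noise_idx, mag_idx]), na.rm = TRUE)
  list(correlation = cm, mean_noise_correlation = mnc, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paired t-test between pipelines
#'
#' Classical two-sided paired t-test on per-unit (e.g. per-line)
#' measurements under two pipelines.  Zero-variance differences are
#' flagged (`defined = FALSE`, p undefined) rather than raising an error.
#'
#' @param a,b equal-length numeric vectors of paired measurements
#'   (`n >= 3`).
#' @return List: `t`, `p`, `significant` (at 0.05), `defined`, `n`.
#' @export
paired_pipeline_test <- function(a, b) {
  assert_that(length(a) == length(b), "paired samples must have equal length")
  n <- length(a)
  assert_that(n >= 3L, "need at least 3 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, p = NA_real_, significant = FALSE,
                defined = FALSE, n = n))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < 0.05, defined = TRUE, n = n)
}

#' Pairwise paired-test matrix across pipelines
#'
#' @param values numeric matrix, units x pipelines (columns named by
#'   pipeline).
#' @return List of matrices `p` and `significant` (pipelines x pipelines).
#' @export
paired_test_matrix <- function(values) {
  values <- as.matrix(values)
  k <- ncol(values)
  p <- matrix(NA_real_, k, k, dimnames = list(colnames(values),
                                              colnames(values)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      res <- paired_pipeline_test(values[, i], values[, j])
      p[i, j] <- p[j, i] <- res$p
    }
  }
  list(p = p, significant = !is.na(p) & p < 0.05)
}
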