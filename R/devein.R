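## Phase-based macrovascular correction ("de-veining").
##
## Field inhomogeneities around large veins modulate the MR phase; the
## microvasculature in the parenchyma, being small and randomly oriented,
## does not.  Fitting each voxel's magnitude time course against its phase
## time course and subtracting the fitted part therefore removes the
## macrovascular contribution while leaving microvascular (neural) signal
## largely untouched.

#' Count temporal phase wraps
#'
#' Advisory diagnostic: counts, per voxel, successive-volume phase jumps
#' exceeding pi in absolute value.  A well-behaved reconstructed phase
#' series has essentially none, in which case no unwrapping is needed.
#'
#' @param phase a `phase_series` with at least 2 volumes.
#' @return List with `count_map` (integer 3D array of wrap counts) and
#'   `wrap_fraction` (fraction of voxels with at least one wrap).
#' @export
check_phase_wraps <- function(phase) {
  d <- dim(phase$data)
  assert_that(d[4] >= 2L, "need at least 2 volumes")
  m <- matrix(phase$data, nrow = prod(d[1:3]), ncol = d[4])
  jumps <- abs(m[, -1, drop = FALSE] - m[, -d[4], drop = FALSE]) > pi
  counts <- rowSums(jumps)
  list(count_map = array(as.integer(counts), dim = d[1:3]),
       wrap_fraction = mean(counts >= 1))
}

#' Temporal phase unwrapping
#'
#' Per-voxel 1D unwrapping along time: multiples of 2*pi are added so that
#' no successive jump exceeds pi.  Idempotent, and the identity on
#' wrap-free input.
#'
#' @param phase a `phase_series`.
#' @return The unwrapped series (values may leave `[-pi, pi)`).
#' @export
unwrap_temporal <- function(phase) {
  d <- dim(phase$data)
  assert_that(d[4] >= 2L, "need at least 2 volumes")
  m <- matrix(phase$data, nrow = prod(d[1:3]), ncol = d[4])
  dm <- m[, -1, drop = FALSE] - m[, -d[4], drop = FALSE]
  corr <- -2 * pi * round(dm / (2 * pi))
  adj <- t(apply(cbind(0, corr), 1, cumsum))
  phase$data <- array(m + adj, dim = d)
  add_step(phase, "unwrap_temporal")
}

#' Phase regression (de-veining)
#'
#' Per voxel, fits `M(t) = a * phi(t) + b + r(t)` by ordinary least squares
#' and returns `r(t) + mean(M)` as the corrected magnitude: the part of the
#' magnitude explainable by the phase -- the putative macrovascular
#' component -- is subtracted, and the temporal mean is restored so that
#' downstream GLMs and spectra keep their baseline.  Voxels with zero phase
#' variance pass through unchanged with slope 0.
#'
#' The phase series must have received exactly the same pre-processing as
#' the magnitude (identical `meta` step lists); this is enforced.
#'
#' @param mag a `bold_series`.
#' @param phase the paired `phase_series`.
#' @return List with `series` (corrected magnitude) and `fit` (class
#'   `devein_fit`: 3D maps `slope` (magnitude units per radian),
#'   `intercept`, and `variance_explained` in `[0, 1]`).
#' @export
phase_regress <- function(mag, phase) {
  check_pair(mag, phase, check_meta = TRUE)
  d <- dim(mag$data)
  nv <- prod(d[1:3]); nt <- d[4]
  M <- matrix(mag$data, nrow = nv, ncol = nt)
  P <- matrix(phase$data, nrow = nv, ncol = nt)
  mM <- rowMeans(M)
  mP <- rowMeans(P)
  Mc <- M - mM
  Pc <- P - mP
  varP <- rowSums(Pc^2)
  varM <- rowSums(Mc^2)
  covMP <- rowSums(Mc * Pc)
  slope <- ifelse(varP > 0, covMP / varP, 0)
  intercept <- mM - slope * mP
  corrected <- Mc - slope * Pc + mM       # residuals + temporal mean restored
  ve <- ifelse(varP > 0 & varM > 0, slope^2 * varP / varM, 0)
  ve <- pmin(pmax(ve, 0), 1)
  out <- mag
  out$data <- array(corrected, dim = d)
  out <- add_step(out, "phase_regress")
  fit <- structure(list(slope = array(slope, dim = d[1:3]),
                        intercept = array(intercept, dim = d[1:3]),
                        variance_explained = array(ve, dim = d[1:3])),
                   class = "devein_fit")
  list(series = out, fit = fit)
}

#' @export
print.devein_fit <- function(x, ...) {
  cat(sprintf("<devein_fit> mean variance explained by phase: %.3f (max %.3f)\n",
              mean(x$variance_explained), max(x$variance_explained)))
  invisible(x)
}

#' Write de-veining fit maps as NIfTI
#'
#' @param fit a `devein_fit`.
#' @param prefix output path prefix; writes `<prefix>_slope.nii.gz`,
#'   `<prefix>_intercept.nii.gz`, `<prefix>_varexp.nii.gz`.
#' @param voxel_size_mm voxel size recorded in the headers.
#' @return The three paths, invisibly.
#' @export
write_devein_fit <- function(fit, prefix, voxel_size_mm = c(0.63, 0.63, 0.63)) {
  paths <- c(paste0(prefix, "_slope.nii.gz"),
             paste0(prefix, "_intercept.nii.gz"),
             paste0(prefix, "_varexp.nii.gz"))
  write_volume(fit$slope, paths[1], voxel_size_mm)
  write_volume(fit$intercept, paths[2], voxel_size_mm)
  write_volume(fit$variance_explained, paths[3], voxel_size_mm)
  invisible(paths)
}
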