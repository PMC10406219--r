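#' @keywords internal
"_PACKAGE"

## ---- internal assertion helpers ----------------------------------------

stop_lp <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_lp(msg)
  invisible(TRUE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## ---- bold_series / phase_series ----------------------------------------

#' 4D magnitude or phase fMRI series
#'
#' `bold_series()` wraps a real-valued 4D array (x, y, z, t) of magnitude
#' data together with its voxel geometry, repetition time, voxel-to-world
#' affine and a provenance record listing every processing step applied so
#' far.  `phase_series()` is the companion container for the paired phase
#' image; phase values are stored in radians and must lie in `[-pi, pi)` at
#' load time (after processing, e.g. nuisance regression, they are
#' unconstrained reals and are used as-is).
#'
#' Arrays are indexed `(x, y, z, t)`; world coordinates are obtained through
#' the affine only.
#'
#' @param data numeric 4D array `(x, y, z, t)`.
#' @param voxel_size_mm positive length-3 numeric, voxel edge lengths in mm.
#' @param tr_s positive scalar, repetition time in seconds.
#' @param affine 4x4 voxel-to-world transform; defaults to a scaled identity
#'   built from `voxel_size_mm`.
#' @param meta character vector of applied processing steps, in order.
#' @return An object of class `bold_series` (resp. `phase_series`).
#' @export
bold_series <- function(data, voxel_size_mm = c(0.63, 0.63, 0.63),
                        tr_s = 3.5, affine = NULL, meta = character()) {
  new_series(data, voxel_size_mm, tr_s, affine, meta, "bold_series")
}

#' @rdname bold_series
#' @export
phase_series <- function(data, voxel_size_mm = c(0.63, 0.63, 0.63),
                         tr_s = 3.5, affine = NULL, meta = character()) {
  s <- new_series(data, voxel_size_mm, tr_s, affine, meta, "phase_series")
  if (length(meta) == 0L) {
    rng <- range(s$data)
    assert_that(rng[1] >= -pi && rng[2] < pi,
                "phase values must lie in [-pi, pi) radians on load")
  }
  s
}

new_series <- function(data, voxel_size_mm, tr_s, affine, meta, class) {
  assert_that(is.numeric(data) && length(dim(data)) == 4L,
              sprintf("%s data must be a numeric 4D (x, y, z, t) array", class))
  assert_that(all(dim(data) >= 1L), "all spatial dimensions must be >= 1")
  assert_that(is.numeric(voxel_size_mm) && length(voxel_size_mm) == 3L &&
                all(voxel_size_mm > 0),
              "voxel_size_mm must be 3 positive numbers")
  assert_that(is_scalar_num(tr_s) && tr_s > 0, "tr_s must be a positive scalar")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  assert_that(is.matrix(affine) && all(dim(affine) == c(4L, 4L)),
              "affine must be a 4x4 matrix")
  assert_that(is.character(meta), "meta must be a character vector of steps")
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 tr_s = as.numeric(tr_s), affine = affine, meta = meta),
            class = c(class, "lp_series"))
}

#' @export
print.lp_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, %d volumes\n",
              class(x)[1], d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size: %s mm, TR: %g s\n",
              paste(format(x$voxel_size_mm), collapse = " x "), x$tr_s))
  if (length(x$meta)) {
    cat("  steps applied:\n")
    for (m in x$meta) cat("    - ", m, "\n", sep = "")
  } else {
    cat("  steps applied: (none)\n")
  }
  invisible(x)
}

#' Number of volumes in a series
#'
#' @param series a `bold_series` or `phase_series`.
#' @return Integer count of time points.
#' @export
n_volumes <- function(series) dim(series$data)[4]

#' Record a processing step in a series' provenance
#'
#' @param series a `bold_series` or `phase_series`.
#' @param step single string describing the operation and its parameters.
#' @return The series with `meta` extended by one entry.
#' @keywords internal
add_step <- function(series, step) {
  series$meta <- c(series$meta, step)
  series
}

#' Check that a magnitude/phase pair is consistent
#'
#' Enforces identical array shape and repetition time (difference
#' > 1e-6 s is an error, not a warning) between a magnitude series and its
#' paired phase series.
#'
#' @param mag a `bold_series`.
#' @param phase a `phase_series`.
#' @param check_meta if `TRUE`, additionally require identical step lists
#'   (used by [phase_regress()], which presumes matched pre-processing).
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_pair <- function(mag, phase, check_meta = FALSE) {
  assert_that(inherits(mag, "bold_series"), "`mag` must be a bold_series")
  assert_that(inherits(phase, "phase_series"), "`phase` must be a phase_series")
  assert_that(identical(dim(mag$data), dim(phase$data)),
              "magnitude and phase series must have identical shape")
  assert_that(abs(mag$tr_s - phase$tr_s) <= 1e-6,
              "magnitude and phase TR differ by more than 1e-6 s")
  if (check_meta) {
    assert_that(identical(mag$meta, phase$meta),
                "phase not preprocessed identically to magnitude (meta step lists differ)")
  }
  invisible(TRUE)
}

## ---- physio_recording ---------------------------------------------------

#' Physiological recording (pulse oximeter + respiratory belt)
#'
#' Cardiac and respiratory traces sampled at a common native rate, with the
#' offset of the first sample relative to the first retained fMRI volume.
#'
#' @param cardiac,respiratory numeric vectors of equal meaning (arbitrary
#'   units); lengths may differ.
#' @param fs_hz positive sampling rate in Hz.
#' @param t0_s time (s) of the first sample relative to the first retained
#'   fMRI volume; negative means the recording started before the scan.
#' @return An object of class `physio_recording`.
#' @export
physio_recording <- function(cardiac, respiratory, fs_hz, t0_s = 0) {
  assert_that(is.numeric(cardiac) && is.numeric(respiratory),
              "cardiac and respiratory traces must be numeric vectors")
  assert_that(!anyNA(cardiac) && !anyNA(respiratory),
              "physiological traces must not contain NA")
  assert_that(is_scalar_num(fs_hz) && fs_hz > 0, "fs_hz must be positive")
  assert_that(is_scalar_num(t0_s), "t0_s must be a finite scalar")
  structure(list(cardiac = as.numeric(cardiac),
                 respiratory = as.numeric(respiratory),
                 fs_hz = as.numeric(fs_hz), t0_s = as.numeric(t0_s)),
            class = "physio_recording")
}

#' @export
print.physio_recording <- function(x, ...) {
  cat(sprintf("<physio_recording> %d cardiac / %d respiratory samples @ %g Hz, t0 = %g s\n",
              length(x$cardiac), length(x$respiratory), x$fs_hz, x$t0_s))
  invisible(x)
}

## sample times (s, relative to first retained volume) of a trace
physio_times <- function(physio, which = c("cardiac", "respiratory")) {
  which <- match.arg(which)
  n <- length(physio[[which]])
  physio$t0_s + (seq_len(n) - 1) / physio$fs_hz
}

## ---- tissue_maps --------------------------------------------------------

#' Per-voxel tissue fraction maps
#'
#' CSF, grey-matter and white-matter fraction volumes on the functional
#' grid.  Fractions must lie in `[0, 1]` and sum to at most 1 per voxel.
#'
#' @param csf,gm,wm numeric 3D arrays of identical shape.
#' @return An object of class `tissue_maps`.
#' @export
tissue_maps <- function(csf, gm, wm) {
  for (m in list(csf, gm, wm)) {
    assert_that(is.numeric(m) && length(dim(m)) == 3L,
                "tissue fraction maps must be numeric 3D arrays")
  }
  assert_that(identical(dim(csf), dim(gm)) && identical(dim(gm), dim(wm)),
              "tissue maps must share one shape")
  assert_that(min(csf, gm, wm) >= 0 && max(csf, gm, wm) <= 1 + 1e-6,
              "tissue fractions must lie in [0, 1]")
  assert_that(max(csf + gm + wm) <= 1 + 1e-6,
              "tissue fractions must sum to <= 1 per voxel")
  structure(list(csf = csf, gm = gm, wm = wm), class = "tissue_maps")
}

## ---- cross_cortex_line --------------------------------------------------

#' Ordered voxel path from CSF across GM into WM
#'
#' A cross-cortex line samples the cortical ribbon perpendicular to its
#' surface: the first voxel lies in CSF, the last in WM, and the path has at
#' most ten voxels.  `depth_index` runs linearly from 0 (CSF end) to 1 (WM
#' end).
#'
#' @param voxels integer matrix (n x 3) of 1-based array indices, ordered
#'   CSF to WM.
#' @param depth_index optional numeric vector in `[0, 1]`; defaults to a
#'   linear ramp.
#' @return An object of class `cross_cortex_line`.
#' @export
cross_cortex_line <- function(voxels, depth_index = NULL) {
  voxels <- as.matrix(voxels)
  storage.mode(voxels) <- "integer"
  n <- nrow(voxels)
  assert_that(ncol(voxels) == 3L, "voxels must be an n x 3 index matrix")
  assert_that(n >= 2L && n <= 10L,
              "a cross-cortex line must have between 2 and 10 voxels")
  assert_that(!anyDuplicated(voxels), "line voxels must be unique")
  steps <- abs(diff(voxels))
  assert_that(all(steps <= 1L) && all(rowSums(steps) >= 1L),
              "consecutive line voxels must be (face/edge/corner) neighbours")
  if (is.null(depth_index)) depth_index <- seq(0, 1, length.out = n)
  assert_that(length(depth_index) == n && min(depth_index) >= 0 &&
                max(depth_index) <= 1,
              "depth_index must be one value in [0, 1] per voxel")
  structure(list(voxels = voxels, depth_index = as.numeric(depth_index)),
            class = "cross_cortex_line")
}

## linear indices of a line's voxels in a 3D volume of dim `d`
line_flat_index <- function(line, d) {
  v <- line$voxels
  v[, 1] + (v[, 2] - 1L) * d[1] + (v[, 3] - 1L) * d[1] * d[2]
}

#' Extract the time courses of a cross-cortex line's voxels
#'
#' @param series a `bold_series` or `phase_series`.
#' @param line a [cross_cortex_line()].
#' @return Numeric matrix, `t x n` (one column per line voxel, CSF end
#'   first) -- the input [homogeneity()] expects.
#' @export
line_courses <- function(series, line) {
  d <- dim(series$data)
  flat <- line_flat_index(line, d[1:3])
  nt <- d[4]
  m <- matrix(series$data, nrow = prod(d[1:3]), ncol = nt)
  t(m[flat, , drop = FALSE])
}

## ---- regressor_matrix ---------------------------------------------------

#' Labelled nuisance / design regressor matrix
#'
#' A `t x p` numeric matrix with unique column labels and a per-column kind
#' tag (`motion`, `physio`, `tissue`, `bandstop`, `poly` or `task`).
#' All-zero columns are rejected.
#'
#' @param values numeric matrix, one row per volume.
#' @param labels character vector of unique column names.
#' @param kind character vector of per-column kind tags.
#' @return An object of class `regressor_matrix`.
#' @export
regressor_matrix <- function(values, labels, kind) {
  values <- as.matrix(values)
  assert_that(is.numeric(values), "regressor values must be numeric")
  p <- ncol(values)
  assert_that(length(labels) == p && !anyDuplicated(labels),
              "labels must be unique, one per column")
  allowed <- c("motion", "physio", "tissue", "bandstop", "poly", "task")
  assert_that(length(kind) == p && all(kind %in% allowed),
              sprintf("kind tags must be one of: %s", paste(allowed, collapse = ", ")))
  zero <- apply(values, 2, function(col) all(col == 0))
  if (any(zero)) {
    stop_lp("all-zero regressor column(s): ", paste(labels[zero], collapse = ", "))
  }
  colnames(values) <- labels
  structure(list(values = values, labels = as.character(labels),
                 kind = as.character(kind)),
            class = "regressor_matrix")
}

#' @export
print.regressor_matrix <- function(x, ...) {
  cat(sprintf("<regressor_matrix> %d volumes x %d regressors (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$kind)), table(x$kind)),
                    collapse = ", ")))
  invisible(x)
}

#' Concatenate regressor matrices column-wise
#'
#' @param ... `regressor_matrix` objects with matching row counts.
#' @return A single `regressor_matrix`.
#' @export
bind_regressors <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  assert_that(length(parts) >= 1L, "nothing to bind")
  nr <- vapply(parts, function(p) nrow(p$values), integer(1))
  assert_that(length(unique(nr)) == 1L,
              "regressor matrices must have the same number of rows")
  regressor_matrix(do.call(cbind, lapply(parts, `[[`, "values")),
                   unlist(lapply(parts, `[[`, "labels")),
                   unlist(lapply(parts, `[[`, "kind")))
}

## ---- motion_trace -------------------------------------------------------

#' Rigid-body motion parameters per volume
#'
#' Six parameters per volume: three rotations (degrees, about the volume
#' centre, applied in z-y-x order) and three translations (mm), referenced
#' to volume 0, whose row is all zeros.
#'
#' @param params numeric matrix (t x 6), columns
#'   `rot_x, rot_y, rot_z, trans_x, trans_y, trans_z`.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  assert_that(is.numeric(params) && ncol(params) == 6L,
              "motion parameters must be a t x 6 numeric matrix")
  assert_that(all(params[1, ] == 0), "reference volume (row 1) must be all zeros")
  colnames(params) <- c("rot_x", "rot_y", "rot_z",
                        "trans_x", "trans_y", "trans_z")
  structure(list(params = params), class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  mx <- apply(abs(x$params), 2, max)
  cat(sprintf("<motion_trace> %d volumes; max |rot| %.3g deg, max |trans| %.3g mm\n",
              nrow(x$params), max(mx[1:3]), max(mx[4:6])))
  invisible(x)
}
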