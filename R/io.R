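## NIfTI and TSV input/output.
##
## All volumes travel as NIfTI-1 via RNifti; phase is never auto-detected
## from value ranges -- the caller states which stream a file holds.

#' Read a 4D NIfTI series
#'
#' Reads a NIfTI-1/2 file into a [bold_series()] or [phase_series()].  The
#' affine, voxel sizes and TR are taken from the header.  Whether the file
#' holds magnitude or phase data is stated by the caller through `type`; no
#' value-range heuristic is attempted.  Phase stored as scaled integers
#' (e.g. `[-4096, 4096]`) is converted to radians through an explicit
#' `phase_scale` factor, never guessed.
#'
#' @param path path to a 4D NIfTI file.
#' @param type `"magnitude"` or `"phase"`.
#' @param tr_s optional TR override (s); required when the header stores a
#'   missing/zero TR.
#' @param phase_scale multiplicative factor applied to phase data so the
#'   result is radians (default 1, i.e. the file already stores radians).
#' @return A `bold_series` or `phase_series`.  A provenance sidecar written
#'   by [write_series()] (same path + `.steps.txt`) is restored into `meta`
#'   when present.
#' @export
read_series <- function(path, type = c("magnitude", "phase"), tr_s = NULL,
                        phase_scale = 1) {
  type <- match.arg(type)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) {
    stop_lp(sprintf("expected a 4D series, got %d dimension(s): %s",
                    length(d), path))
  }
  hdr <- RNifti::niftiHeader(img)
  vox <- abs(hdr$pixdim[2:4])
  file_tr <- hdr$pixdim[5]
  if (is.null(tr_s)) {
    if (!is.finite(file_tr) || file_tr <= 0) {
      stop_lp("header TR is missing or zero; pass an explicit `tr_s` override")
    }
    tr_s <- file_tr
  }
  affine <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  affine <- matrix(as.numeric(affine), 4, 4)
  data <- array(as.numeric(img), dim = d)
  meta <- character()
  sidecar <- paste0(path, ".steps.txt")
  if (file.exists(sidecar)) meta <- readLines(sidecar)
  if (type == "magnitude") {
    bold_series(data, vox, tr_s, affine, meta)
  } else {
    phase_series(data * phase_scale, vox, tr_s, affine, meta)
  }
}

#' Write a series to NIfTI
#'
#' Stores the data as float64 (lossless for double payloads), the affine as
#' the sform, and the TR in `pixdim[5]`.  The provenance step list is
#' serialized to a plain-text sidecar (`<path>.steps.txt`) when non-empty.
#'
#' @param series a `bold_series` or `phase_series`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  assert_that(inherits(series, "lp_series"), "`series` must be a series object")
  img <- RNifti::asNifti(series$data,
                         reference = list(pixdim = c(-1, series$voxel_size_mm,
                                                     series$tr_s, 0, 0, 0),
                                          pixunits = c("mm", "s")),
                         datatype = "double")
  img <- RNifti::`sform<-`(img, structure(series$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  if (length(series$meta)) {
    writeLines(series$meta, paste0(path, ".steps.txt"))
  }
  invisible(path)
}

#' Read / write a 3D volume (masks, maps)
#'
#' Thin helpers for tissue-fraction maps, label maps and statistic maps.
#'
#' @param path NIfTI path.
#' @param volume numeric or integer 3D array.
#' @param voxel_size_mm voxel size used when writing.
#' @return `read_volume`: a 3D array. `write_volume`: `path`, invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop_lp("expected a 3D volume: ", path)
  array(as.numeric(img), dim = d)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path, voxel_size_mm = c(0.63, 0.63, 0.63)) {
  assert_that(length(dim(volume)) == 3L, "`volume` must be a 3D array")
  img <- RNifti::asNifti(volume,
                         reference = list(pixdim = c(-1, voxel_size_mm, 0, 0, 0, 0),
                                          pixunits = c("mm", "s")),
                         datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a physiological trace file
#'
#' Expects a two-column (cardiac, respiratory) tab-separated file with a
#' header row, as written by [write_physio()].
#'
#' @param path TSV path.
#' @param fs_hz sampling rate of the recording (Hz); stated by the caller,
#'   not inferred.
#' @param t0_s offset of the first sample relative to the first retained
#'   fMRI volume (s).
#' @return A [physio_recording()].
#' @export
read_physio <- function(path, fs_hz, t0_s = 0) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE)
  if (ncol(tab) != 2L) {
    stop_lp(sprintf("physio file must have exactly 2 columns (cardiac, respiratory); got %d",
                    ncol(tab)))
  }
  if (anyNA(tab)) stop_lp("physio trace contains NA rows")
  physio_recording(tab[[1]], tab[[2]], fs_hz, t0_s)
}

#' @rdname read_physio
#' @param physio a `physio_recording` (cardiac and respiratory must have
#'   equal length to be written as columns).
#' @export
write_physio <- function(physio, path) {
  assert_that(length(physio$cardiac) == length(physio$respiratory),
              "cannot write traces of different lengths as two columns")
  utils::write.table(data.frame(cardiac = physio$cardiac,
                                respiratory = physio$respiratory),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a motion trace or regressor matrix as labelled TSV
#'
#' @param x a `motion_trace` or `regressor_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(x, path) {
  m <- if (inherits(x, "motion_trace")) x$params else x$values
  utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Remove initial (dummy) volumes
#'
#' Scanner signal needs a few TRs to reach a steady state; the first
#' acquisition volumes are therefore discarded before analysis (default 4).
#' The paired physiological recording's `t0_s` must be shifted by
#' `-n * tr_s` by the caller (or use [shift_physio()]).
#'
#' @param series a `bold_series` or `phase_series`.
#' @param n number of leading volumes to drop (default 4).
#' @return The series with `n` fewer volumes and an updated step list.
#' @export
drop_initial_volumes <- function(series, n = 4L) {
  assert_that(inherits(series, "lp_series"), "`series` must be a series object")
  n <- as.integer(n)
  assert_that(n >= 0L, "n must be >= 0")
  nt <- n_volumes(series)
  if (n >= nt) stop_lp(sprintf("cannot drop %d of %d volumes", n, nt))
  if (n == 0L) return(series)
  series$data <- series$data[, , , (n + 1L):nt, drop = FALSE]
  add_step(series, sprintf("drop_initial_volumes(n=%d)", n))
}

#' @rdname drop_initial_volumes
#' @param physio a `physio_recording`.
#' @param tr_s repetition time of the series whose volumes were dropped.
#' @export
shift_physio <- function(physio, n, tr_s) {
  physio$t0_s <- physio$t0_s - n * tr_s
  physio
}
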