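# Shared phantom configurations for tests.  Sizes are kept small where the
# property under test does not depend on the full study geometry.

# small, fast resting phantom
tiny_rest_config <- function(...) {
  args <- utils::modifyList(list(grid = c(16L, 16L, 12L), n_volumes = 60L,
                                 n_lines = 2L), list(...))
  do.call(phantom_config, args)
}

# contaminant-free static phantom (baseline + texture only)
static_config <- function(...) {
  phantom_config(grid = c(16L, 16L, 12L), n_volumes = 8L, neural_amp = 0,
                 vein_gain = 0,
                 physio_gain_cardiac = c(csf = 0, gm = 0, wm = 0),
                 physio_gain_resp = c(csf = 0, gm = 0, wm = 0),
                 drift_amp = 0, thermal_sd = 0, phase_noise_sd = 0,
                 n_lines = 2L, ...)
}

# clean-phase phantom for de-veining recovery: vein and coupling present,
# phase noise at the identifiability floor
devein_config <- function(...) {
  phantom_config(grid = c(20L, 20L, 12L), n_volumes = 174L,
                 phase_noise_sd = 0.01, motion_amp_deg = 0,
                 motion_amp_mm = 0, n_lines = 2L, ...)
}

expect_series_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$data, b$data, tolerance = tol)
  expect_equal(a$tr_s, b$tr_s)
  expect_equal(a$voxel_size_mm, b$voxel_size_mm)
}
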