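test_that("task designs validate their timing", {
  expect_error(task_design(numeric(0), numeric(0), 100, 3.5), "non-empty")
  expect_error(task_design(c(0, 42), c(21, 0), 100, 3.5), "positive")
  expect_error(task_design(c(42, 0), c(21, 21), 100, 3.5), "increasing")
  expect_error(task_design(0, 1000, 100, 3.5), "end")
  td <- task_design(seq(0, 462, 42), rep(21, 12), 144, 3.5)
  expect_s3_class(td, "task_design")
})

test_that("the task regressor is a unit-peak convolved boxcar", {
  td <- task_design(seq(0, 462, 42), rep(21, 12), 144, 3.5)
  des <- build_design(td)
  expect_equal(colnames(des$values), c("task", "intercept"))
  expect_equal(max(des$values[, "task"]), 1)
  expect_equal(des$kind, c("task", "poly"))
  # events TSV round trip
  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(onset = seq(0, 462, 42), duration = 21),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  td2 <- read_events(path, 144, 3.5)
  expect_equal(build_design(td2)$values, des$values)
  unlink(path)
})

test_that("a noise-free phantom response is recovered exactly", {
  cfg <- phantom_config(mode = "task", grid = c(12L, 12L, 12L),
                        depth_profile = "flat", response_amp = 1,
                        vein_gain = 0,
                        physio_gain_cardiac = c(csf = 0, gm = 0, wm = 0),
                        physio_gain_resp = c(csf = 0, gm = 0, wm = 0),
                        drift_amp = 0, thermal_sd = 0, phase_noise_sd = 0,
                        n_lines = 2L, seed = 31)
  ph <- make_phantom(cfg)
  mag <- drop_initial_volumes(ph$mag, 4)
  des <- build_design(task_design(cfg$task_onsets_s, cfg$task_durations_s,
                                  n_volumes(mag), cfg$tr_s))
  amap <- fit_glm(mag, des)
  # pure-GM voxel away from the taper: beta equals the injected amplitude
  z_gm <- ph$truth$gm_layers[3]
  expect_equal(amap$beta[6, 6, z_gm], 1, tolerance = 1e-6)
  expect_equal(amap$dof, n_volumes(mag) - 2)
})

test_that("GLM type-I error matches the nominal p threshold", {
  set.seed(41)
  nt <- 144
  n_null <- 10000
  dat <- array(rnorm(n_null * nt), dim = c(100, 100, 1, nt))
  s <- bold_series(dat, tr_s = 3.5)
  des <- build_design(task_design(seq(0, 462, 42), rep(21, 12), nt, 3.5))
  amap <- fit_glm(s, des)
  surv <- threshold_activation(amap, 0.001)
  ci <- qbinom(c(0.025, 0.975), n_null, 0.001)
  expect_gte(sum(surv), ci[1])
  expect_lte(sum(surv), ci[2])
  # the implied t threshold is reported and near 3.4 at these dof
  expect_equal(attr(surv, "t_threshold"),
               qt(1 - 0.001 / 2, df = amap$dof))
})

test_that("beta estimates fall inside their analytic confidence intervals", {
  set.seed(42)
  nt <- 144; n_rep <- 100; amp <- 2
  des <- build_design(task_design(seq(0, 462, 42), rep(21, 12), nt, 3.5))
  x <- des$values[, "task"]
  dat <- array(rnorm(n_rep * nt), dim = c(n_rep, 1, 1, nt))
  for (i in seq_len(n_rep)) dat[i, 1, 1, ] <- dat[i, 1, 1, ] + amp * x
  amap <- fit_glm(bold_series(dat, tr_s = 3.5), des)
  # coverage of the analytic 95% CI: beta +/- t_crit * SE
  se_hat <- amap$beta / amap$t_stat
  t_crit <- qt(0.975, amap$dof)
  covered <- abs(amap$beta - amp) <= t_crit * se_hat
  expect_gte(sum(covered), 93)
})

test_that("thresholding is strict and ratio arithmetic is exact", {
  beta <- array(c(2, 2, 1, 1), dim = c(4, 1, 1))
  p <- array(c(1e-5, 1e-5, 1e-5, 0.001), dim = c(4, 1, 1))
  amap <- structure(list(beta = beta,
                         t_stat = array(5, dim = c(4, 1, 1)), p = p,
                         dof = 100), class = "activation_map")
  mask <- threshold_activation(amap, 0.001)
  expect_equal(sum(mask), 3)                 # p == threshold excluded
  expect_error(threshold_activation(amap, 1.5), "0, 1")
  gm <- array(c(TRUE, TRUE, FALSE, FALSE), dim = c(4, 1, 1))
  csf <- array(c(FALSE, FALSE, TRUE, TRUE), dim = c(4, 1, 1))
  r <- gm_csf_beta_ratio(amap, gm, csf)
  expect_equal(r$ratio, 2)                   # 2.0 GM over 1.0 CSF
  expect_equal(r$n_gm, 2); expect_equal(r$n_csf, 1)
  # identical distributions give ratio 1
  csf2 <- gm
  expect_equal(gm_csf_beta_ratio(amap, gm, csf2)$ratio, 1)
  # no survivors in an ROI: flagged, not an error
  amap$p[] <- 1
  r2 <- gm_csf_beta_ratio(amap, gm, csf)
  expect_false(r2$defined)
  expect_true(is.na(r2$ratio))
})

test_that("line profiles are linear samplers with a flat-field identity", {
  ph <- make_phantom(tiny_rest_config(seed = 33))
  lines <- ph$truth$lines
  cmap <- array(7, dim = dim(ph$mag$data)[1:3])
  prof <- line_profile(cmap, lines)
  expect_length(prof$profile, 30)            # default sampling points
  expect_equal(prof$profile, rep(7, 30), tolerance = 1e-12)
  # linearity: profile(aX + bY) == a profile(X) + b profile(Y)
  set.seed(3)
  X <- array(rnorm(prod(dim(cmap))), dim = dim(cmap))
  Y <- array(rnorm(prod(dim(cmap))), dim = dim(cmap))
  pX <- line_profile(X, lines)$profile
  pY <- line_profile(Y, lines)$profile
  pXY <- line_profile(2 * X + 3 * Y, lines)$profile
  expect_equal(pXY, 2 * pX + 3 * pY, tolerance = 1e-10)
  # out-of-bounds line errors with its id
  bad <- cross_cortex_line(cbind(1, 1, 1:10))
  small <- array(0, dim = c(2, 2, 2))
  expect_error(line_profile(small, list(bad)), "line 1")
})

test_that("the superficial-peak locator ignores noise ripples", {
  depth <- seq(0, 1, length.out = 30)
  # salient superficial peak at depth ~0.2 plus a deep peak
  prof <- 0.6 * exp(-((depth - 0.2) / 0.08)^2) + exp(-((depth - 0.7) / 0.1)^2)
  expect_equal(profile_peak_depth(prof, depth), depth[which.max(
    prof * (depth < 0.4))])
  # tiny ripple near the CSF end must not register
  prof2 <- prof + c(0.02, rep(0, 29))
  expect_equal(profile_peak_depth(prof2, depth),
               profile_peak_depth(prof, depth))
  # unimodal profile: returns its maximum
  uni <- exp(-((depth - 0.6) / 0.15)^2)
  expect_equal(profile_peak_depth(uni, depth), depth[which.max(uni)])
})

test_that("slab task ROIs cover GM and the adjacent pial CSF layer", {
  ph <- make_phantom(tiny_rest_config(seed = 34))
  rois <- define_task_rois(ph$truth$tissue)
  expect_gt(sum(rois$gm), 0)
  expect_gt(sum(rois$csf), 0)
  expect_equal(sum(rois$gm & rois$csf), 0)
  # the pial layer (CSF adjacent to GM) is inside the CSF ROI
  pial_z <- ph$truth$pial_z
  expect_true(rois$csf[8, 8, pial_z])
  # distant CSF (top cap) is not
  nz <- dim(ph$truth$tissue$csf)[3]
  expect_false(rois$csf[8, 8, nz])
})
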