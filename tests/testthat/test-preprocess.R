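test_that("slice timing: identities and a shifted-sinusoid oracle", {
  nt <- 120; tr <- 3.5
  t_vol <- (seq_len(nt) - 1) * tr
  f <- 0.02
  make_series <- function(course_by_slice) {
    dat <- array(0, dim = c(2, 2, 3, nt))
    for (z in 1:3) dat[, , z, ] <- rep(course_by_slice[[z]], each = 4)
    bold_series(dat, tr_s = tr)
  }
  # constant course is unchanged by any offset
  s <- make_series(list(rep(2, nt), rep(2, nt), rep(2, nt)))
  out <- slice_timing_correct(s, c(0, 1.2, 2.4))
  expect_equal(out$data, s$data, tolerance = 1e-10)
  # slice acquired at the reference time is untouched
  s2 <- make_series(list(sin(2 * pi * f * t_vol), sin(2 * pi * f * t_vol),
                         sin(2 * pi * f * t_vol)))
  out2 <- slice_timing_correct(s2, c(1.75, 0, 1.75), ref_time_s = 1.75)
  expect_equal(out2$data[1, 1, 1, ], s2$data[1, 1, 1, ], tolerance = 1e-10)
  # sinusoid sampled at t + offset, corrected to ref 0, must match the
  # analytic sinusoid at the volume times (away from the ends)
  off <- 1.75
  observed <- sin(2 * pi * f * (t_vol + off))
  s3 <- make_series(list(observed, observed, observed))
  out3 <- slice_timing_correct(s3, c(off, off, off), ref_time_s = 0)
  mid <- 10:(nt - 10)
  expect_lt(max(abs(out3$data[1, 1, 1, mid] - sin(2 * pi * f * t_vol)[mid])),
            0.01)
  # offsets outside [0, TR) are rejected
  expect_error(slice_timing_correct(s, c(0, 1, 3.6)), "\\[0, TR\\)")
})

test_that("motion estimation recovers injected displacements", {
  cfg <- phantom_config(grid = c(28L, 28L, 16L), n_volumes = 8L,
                        neural_amp = 0, vein_gain = 0,
                        physio_gain_cardiac = c(csf = 0, gm = 0, wm = 0),
                        physio_gain_resp = c(csf = 0, gm = 0, wm = 0),
                        drift_amp = 0, thermal_sd = 0, phase_noise_sd = 0,
                        seed = 3)
  ph <- make_phantom(cfg)
  vol0 <- ph$mag$data[, , , 1]
  d <- dim(vol0); vox <- cfg$voxel_size_mm
  two_vol <- function(theta) {
    moved <- laminaprep:::rigid_resample(vol0, theta, vox, inverse = FALSE,
                                         method = "lanczos")
    bold_series(array(c(vol0, moved), dim = c(d, 2)), vox, cfg$tr_s)
  }
  # motion-free: parameters are essentially zero
  m0 <- estimate_motion(bold_series(array(rep(vol0, 2), dim = c(d, 2)),
                                    vox, cfg$tr_s))
  expect_lt(max(abs(m0$params)), 0.02)
  # pure one-voxel translation recovered within 0.1 voxel
  mt <- estimate_motion(two_vol(c(0, 0, 0, 0.63, 0, 0)))
  expect_lt(max(abs(mt$params[2, 4:6] - c(0.63, 0, 0))), 0.06)
  expect_lt(max(abs(mt$params[2, 1:3])), 0.1)
  # 1 degree rotation about z recovered within 0.1 degree
  mr <- estimate_motion(two_vol(c(0, 0, 1, 0, 0, 0)))
  expect_lt(max(abs(mr$params[2, 1:3] - c(0, 0, 1))), 0.1)
})

test_that("realignment restores a moved phantom", {
  cfg <- phantom_config(grid = c(28L, 28L, 16L), n_volumes = 8L,
                        neural_amp = 0, vein_gain = 0,
                        physio_gain_cardiac = c(csf = 0, gm = 0, wm = 0),
                        physio_gain_resp = c(csf = 0, gm = 0, wm = 0),
                        drift_amp = 0, thermal_sd = 0, phase_noise_sd = 0,
                        motion_amp_deg = 1, motion_amp_mm = 0.63, seed = 13)
  ph <- make_phantom(cfg)
  m <- estimate_motion(ph$mag)
  realigned <- apply_rigid(ph$mag, m, method = "lanczos")
  ref <- ph$mag$data[, , , 1]
  box <- list(6:23, 6:23, 5:12)
  for (v in 2:8) {
    vol <- realigned$data[box[[1]], box[[2]], box[[3]], v]
    expect_gt(cor(as.vector(vol),
                  as.vector(ref[box[[1]], box[[2]], box[[3]]])), 0.999)
  }
  # zero motion is the identity
  zero <- motion_trace(matrix(0, 8, 6))
  expect_identical(apply_rigid(ph$mag, zero)$data, ph$mag$data)
  # a constant phase field is invariant under any rigid transform
  pconst <- phase_series(array(0.7, dim = c(dim(ph$mag$data)[1:3], 2)),
                         tr_s = cfg$tr_s)
  mt <- motion_trace(rbind(rep(0, 6), c(0.5, -0.3, 0.8, 0.2, -0.4, 0.15)))
  moved_const <- apply_rigid(pconst, mt)
  expect_equal(moved_const$data[5:12, 5:12, 4:9, 2],
               pconst$data[5:12, 5:12, 4:9, 2], tolerance = 1e-10)
})

test_that("tissue masks use a strict 99% threshold", {
  f <- array(0, dim = c(2, 2, 2))
  f[1, 1, 1] <- 0.99        # exactly at threshold: excluded
  f[2, 1, 1] <- 0.995
  masks <- make_tissue_masks(tissue_maps(f, f * 0, f * 0))
  expect_false(masks$csf[1, 1, 1])
  expect_true(masks$csf[2, 1, 1])
  expect_error(make_tissue_masks(tissue_maps(f, f * 0, f * 0), 1.2), "0, 1")
  # on the phantom, masks are disjoint and GM mask voxels are pure GM
  ph <- make_phantom(tiny_rest_config(seed = 14))
  mk <- make_tissue_masks(ph$truth$tissue)
  expect_equal(sum(mk$csf & mk$gm) + sum(mk$gm & mk$wm), 0)
  expect_true(all(ph$truth$tissue$gm[mk$gm] > 0.99))
})

test_that("band-stop regressor construction matches enumeration", {
  n_t <- 170; tr <- 3.5
  rm_ <- build_bandstop_regressors(n_t, tr)     # defaults 0.005-0.12, poly 5
  # independent enumeration of the expected column count
  f <- seq_len(n_t / 2) / (n_t * tr)
  stop_k <- which(f < 0.005 | f > 0.12)
  expected <- 2 * sum(stop_k < n_t / 2) + sum(stop_k == n_t / 2) + 6
  expect_equal(ncol(rm_$values), expected)
  expect_setequal(unique(rm_$kind), c("bandstop", "poly"))
  # a pass band covering every grid frequency leaves only the polynomials
  all_pass <- build_bandstop_regressors(n_t, tr,
                                        band_hz = c(1 / (n_t * tr) / 2,
                                                    1 / (2 * tr)))
  expect_equal(ncol(all_pass$values), 6)
  expect_error(build_bandstop_regressors(n_t, tr, band_hz = c(0.2, 0.3)),
               "Nyquist")
})

test_that("band-pass projection zeroes the stop band exactly", {
  n_t <- 170; tr <- 3.5
  # unit sinusoids at every grid frequency plus a drift, so each bin has
  # substantial amplitude and relative changes are meaningful
  f_all <- seq_len(n_t / 2) / (n_t * tr)
  t_vol <- (seq_len(n_t) - 1) * tr
  y <- rowSums(sapply(f_all, function(f) sin(2 * pi * f * t_vol + f * 10))) +
    10 * seq(0, 1, length.out = n_t)
  s <- bold_series(array(y, dim = c(1, 1, 1, n_t)), tr_s = tr)
  rm_ <- build_bandstop_regressors(n_t, tr)
  out <- regress_nuisance(s, rm_)
  before <- Mod(fft(y - mean(y)))^2
  after <- Mod(fft(out$series$data[1, 1, 1, ]))^2
  f <- seq_len(n_t / 2) / (n_t * tr)
  stop_k <- which(f < 0.005 | f > 0.12)
  pass_k <- setdiff(which(f >= 0.005 & f <= 0.12), 1:2)
  expect_lt(max(after[stop_k + 1] / pmax(before[stop_k + 1], 1e-12)), 1e-8)
  # pass-band grid frequencies change only through polynomial overlap:
  # without the polynomial block they are untouched to round-off ...
  bs_only_cols <- rm_$kind == "bandstop"
  bs_only <- regressor_matrix(rm_$values[, bs_only_cols, drop = FALSE],
                              rm_$labels[bs_only_cols],
                              rm_$kind[bs_only_cols])
  out_bs <- regress_nuisance(s, bs_only)
  after_bs <- Mod(fft(out_bs$series$data[1, 1, 1, ]))^2
  expect_equal(sqrt(after_bs[pass_k + 1]), sqrt(before[pass_k + 1]),
               tolerance = 1e-8)
  # ... and the polynomial overlap itself decays with frequency (the
  # Legendre basis is non-periodic, so low pass-band bins are affected;
  # the overlap falls below 1% only well above the band edge)
  overlap <- vapply(c(4, 10, 40, 60), function(k) {
    yk <- sin(2 * pi * k * (seq_len(n_t) - 1) / n_t)
    sk <- bold_series(array(yk, dim = c(1, 1, 1, n_t)), tr_s = tr)
    ok <- regress_nuisance(sk, rm_)$series$data[1, 1, 1, ]
    abs(Mod(fft(ok))[k + 1] - Mod(fft(yk))[k + 1]) / Mod(fft(yk))[k + 1]
  }, numeric(1))
  expect_true(all(diff(overlap) < 0))
  expect_lt(overlap[4], 0.01)
})

test_that("RETROICOR regressors have the printed counts and phases", {
  cfg <- tiny_rest_config(seed = 15)
  ph <- make_phantom(cfg)
  t_vol <- (seq_len(cfg$n_volumes) - 1) * cfg$tr_s
  rr <- build_retroicor_regressors(ph$physio, t_vol, order = 5)
  expect_equal(ncol(rr$values), 36)
  rr1 <- build_retroicor_regressors(ph$physio, t_vol, order = 1,
                                    include_multiplicative = FALSE)
  expect_equal(ncol(rr1$values), 4)
  # perfectly periodic cardiac trace: recovered phase matches 2*pi*frac(f*t)
  fs <- 100; f0 <- 1.1; dur <- 300
  tt <- seq(0, dur, by = 1 / fs)
  periodic <- physio_recording(cos(2 * pi * f0 * tt), cos(2 * pi * 0.3 * tt),
                               fs_hz = fs)
  times <- seq(5, 250, by = 3.5)
  ph_c <- laminaprep:::cardiac_phase(periodic$cardiac, fs, 0, times)
  expected <- 2 * pi * ((f0 * times) %% 1)
  dphi <- (ph_c - expected + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dphi)), 0.05)
  # too few peaks is an error naming the trace
  flat <- physio_recording(rep(0, 1000) + 1e-6 * sin(1:1000 / 500),
                           cos(2 * pi * 0.3 * (1:1000) / fs), fs_hz = fs)
  expect_error(build_retroicor_regressors(flat, c(1, 2, 3)), "cardiac")
})

test_that("mean time course and aliasing behave as closed forms", {
  dat <- array(0, dim = c(2, 1, 1, 5))
  dat[1, 1, 1, ] <- 1:5
  dat[2, 1, 1, ] <- -(1:5)
  s <- bold_series(dat, tr_s = 1)
  m1 <- array(c(TRUE, FALSE), dim = c(2, 1, 1))
  expect_equal(mean_timecourse(s, m1), 1:5)
  expect_equal(mean_timecourse(s, array(TRUE, dim = c(2, 1, 1))), rep(0, 5))
  expect_error(mean_timecourse(s, array(FALSE, dim = c(2, 1, 1))), "empty")

  fs <- 100; dur <- 700; tt <- seq(0, dur, by = 1 / fs)
  phr <- physio_recording(cos(2 * pi * 1.1 * tt), rep(1, length(tt)),
                          fs_hz = fs)
  t_vol <- seq(0, 595, by = 3.5)
  al <- alias_physio(phr, t_vol)
  expect_equal(al$respiratory, rep(1, length(t_vol)))
  # 1.1 Hz sampled at TR 3.5 equals the closed-form aliased sinusoid
  f_alias <- abs(1.1 - round(1.1 * 3.5) / 3.5)
  expect_equal(al$cardiac, cos(2 * pi * f_alias * t_vol), tolerance = 1e-9)
  expect_error(alias_physio(phr, c(-10, 0)), "covers")
})

test_that("nuisance regression is exact joint OLS", {
  ph <- make_phantom(tiny_rest_config(seed = 16))
  cfg <- ph$config
  nt <- cfg$n_volumes
  # residuals orthogonal to every column
  rm_ <- build_bandstop_regressors(nt, cfg$tr_s, poly_degree = 3)
  out <- regress_nuisance(ph$mag, rm_)
  set.seed(1)
  vox <- sample(prod(dim(ph$mag$data)[1:3]), 100)
  Y <- matrix(out$series$data, ncol = nt)[vox, ]
  X <- rm_$values
  cosines <- abs(Y %*% X) /
    outer(sqrt(rowSums(Y^2)), sqrt(colSums(X^2)))
  expect_lt(max(cosines), 1e-8)
  # intercept-only regression demeans
  int_only <- regressor_matrix(matrix(1, nt, 1), "intercept", "poly")
  dm <- regress_nuisance(ph$mag, int_only)$series
  expect_equal(dm$data[4, 4, 4, ],
               ph$mag$data[4, 4, 4, ] - mean(ph$mag$data[4, 4, 4, ]),
               tolerance = 1e-10)
  # duplicated columns are dropped, collinear ones are an error
  dup <- regressor_matrix(cbind(a = 1:nt, b = 1:nt), c("a", "b"),
                          c("poly", "poly"))
  expect_silent(regress_nuisance(ph$mag, dup))
  colin <- regressor_matrix(cbind(a = 1:nt, b = 2 * (1:nt)), c("a", "b"),
                            c("poly", "poly"))
  expect_error(regress_nuisance(ph$mag, colin), "collinear")
})

test_that("regressing the generating columns leaves the thermal floor", {
  cfg <- phantom_config(grid = c(12L, 12L, 12L), n_volumes = 174L, seed = 17)
  ph <- make_phantom(cfg)
  nt <- cfg$n_volumes
  # exact generating courses for one pure-GM layer
  z <- ph$truth$gm_layers[3]
  neural_course <- ph$truth$neural[6, 6, z, ] /
    max(abs(ph$truth$neural[6, 6, z, ]))
  drift_course <- ph$truth$drift[6, 6, z, ]
  X <- regressor_matrix(cbind(neural_course, ph$truth$cardiac_alias,
                              ph$truth$respiratory_alias, drift_course,
                              rep(1, nt)),
                        c("neural", "card", "resp", "drift", "intercept"),
                        c("task", "physio", "physio", "poly", "poly"))
  layer <- bold_series(ph$mag$data[, , z, , drop = FALSE] , tr_s = cfg$tr_s)
  out <- regress_nuisance(layer, X)
  expect_lt(abs(sd(out$series$data) / cfg$thermal_sd - 1), 0.02)
})

test_that("joint regression differs from sequential and stays orthogonal", {
  set.seed(7)
  nt <- 80
  a <- rnorm(nt)
  b <- 0.7 * a + 0.3 * rnorm(nt)     # deliberately correlated blocks
  y <- 2 * a - b + rnorm(nt)
  s <- bold_series(array(y, dim = c(1, 1, 1, nt)), tr_s = 1)
  A <- regressor_matrix(cbind(a), "a", "motion")
  B <- regressor_matrix(cbind(b), "b", "tissue")
  joint <- regress_nuisance(s, bind_regressors(A, B))$series$data[1, 1, 1, ]
  seq_res <- regress_nuisance(regress_nuisance(s, A)$series,
                              B)$series$data[1, 1, 1, ]
  expect_false(isTRUE(all.equal(joint, seq_res)))
  expect_lt(abs(sum(joint * a)) / sqrt(sum(joint^2) * sum(a^2)), 1e-8)
  expect_lt(abs(sum(joint * b)) / sqrt(sum(joint^2) * sum(b^2)), 1e-8)
  # sequential residuals are no longer orthogonal to the first block
  expect_gt(abs(sum(seq_res * a)) / sqrt(sum(seq_res^2) * sum(a^2)), 1e-3)
})

test_that("RETROICOR regression removes most CSF physiological variance", {
  cfg <- tiny_rest_config(seed = 18, n_volumes = 120L)
  ph <- make_phantom(cfg)
  masks <- make_tissue_masks(ph$truth$tissue)
  csf_before <- mean_timecourse(ph$mag, masks$csf)
  t_vol <- (seq_len(cfg$n_volumes) - 1) * cfg$tr_s
  rr <- build_retroicor_regressors(ph$physio, t_vol)
  intercept <- regressor_matrix(matrix(1, cfg$n_volumes, 1), "intercept",
                                "poly")
  out <- regress_nuisance(ph$mag, bind_regressors(rr, intercept))
  csf_after <- mean_timecourse(out$series, masks$csf)
  expect_lt(var(csf_after) / var(csf_before), 0.5)
})

test_that("Gaussian smoothing preserves volume means and has identities", {
  ph <- make_phantom(tiny_rest_config(seed = 19, n_volumes = 10L))
  sm <- smooth_gaussian(ph$mag)            # default 1 mm FWHM
  for (v in c(1, 5, 10)) {
    expect_equal(mean(sm$data[, , , v]), mean(ph$mag$data[, , , v]),
                 tolerance = 1e-10)
  }
  expect_identical(smooth_gaussian(ph$mag, 0)$data, ph$mag$data)
  # smoothing reduces voxel-scale variance
  expect_lt(var(as.vector(sm$data[, , , 1])),
            var(as.vector(ph$mag$data[, , , 1])))
})
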