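test_that("power spectra follow DFT closed forms", {
  nt <- 170; tr <- 3.5
  t_idx <- (seq_len(nt) - 1)
  # sinusoid at an exact grid frequency occupies a single bin
  k <- 12
  x <- sin(2 * pi * k * t_idx / nt)
  sp <- power_spectrum(x, tr, "none")
  expect_equal(which.max(sp$power), k)
  expect_lt(max(sp$power[-k]) / sp$power[k], 1e-10)
  # max-1 normalization
  spn <- power_spectrum(x, tr)
  expect_equal(max(spn$power), 1)
  expect_error(power_spectrum(rep(3, nt), tr), "constant")
  # Parseval: total power equals variance * t for white noise
  set.seed(51)
  w <- rnorm(nt)
  spw <- power_spectrum(w, tr, "none")
  expect_equal(sum(spw$power), nt * mean((w - mean(w))^2),
               tolerance = 1e-8)
})

test_that("fAvLFF has its closed forms and flat-spectrum expectation", {
  nt <- 170; tr <- 3.5
  f_grid <- seq_len(nt / 2) / (nt * tr)
  k_in <- which(f_grid >= 0.015 & f_grid <= 0.04)[3]
  x <- sin(2 * pi * k_in * (seq_len(nt) - 1) / nt)
  sp <- power_spectrum(x, tr, "none")
  expect_equal(favlff(sp), 1.0, tolerance = 1e-10)
  expect_error(favlff(sp, band_hz = c(0.1415, 0.1418)), "bins")
  # white noise: expected fraction equals the share of in-band bins
  bin_share <- mean(f_grid >= 0.015 & f_grid <= 0.04)
  set.seed(52)
  vals <- replicate(500, favlff(power_spectrum(rnorm(nt), tr, "none")))
  expect_lt(abs(mean(vals) / bin_share - 1), 0.02)
})

test_that("band power ratio localizes GM signal against CSF", {
  ph <- make_phantom(tiny_rest_config(
    seed = 53, n_volumes = 174L,
    physio_gain_cardiac = c(csf = 0, gm = 0, wm = 0),
    physio_gain_resp = c(csf = 0, gm = 0, wm = 0), vein_gain = 0,
    drift_amp = 0))
  masks <- make_tissue_masks(ph$truth$tissue)
  same <- band_power_ratio(ph$mag, masks$gm, masks$gm)
  expect_equal(same$avlff_ratio, 1.0)
  expect_equal(same$favlff_ratio, 1.0)
  # neural signal lives in GM; CSF is white thermal noise only
  r <- band_power_ratio(ph$mag, masks$gm, masks$csf)
  expect_gt(r$avlff_ratio, 1)
})

test_that("RETROICOR regression raises the GM/CSF localization ratio", {
  # strong CSF physiological contamination whose TR-aliases land inside
  # the 0.015-0.04 Hz band (cardiac 1.17 Hz -> 0.027 Hz, resp 0.31 Hz ->
  # 0.024 Hz at TR 3.5 s)
  n_rep <- 20
  better <- logical(n_rep)
  before_ratios <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    cfg <- tiny_rest_config(seed = 530 + i, n_volumes = 120L,
                            cardiac_hz = 1.17, resp_hz = 0.31,
                            physio_gain_cardiac = c(csf = 30, gm = 5, wm = 3),
                            physio_gain_resp = c(csf = 20, gm = 4, wm = 2))
    ph <- make_phantom(cfg)
    masks <- make_tissue_masks(ph$truth$tissue)
    before <- band_power_ratio(ph$mag, masks$gm, masks$csf)
    t_vol <- (seq_len(cfg$n_volumes) - 1) * cfg$tr_s
    design <- bind_regressors(
      build_retroicor_regressors(ph$physio, t_vol),
      regressor_matrix(matrix(1, cfg$n_volumes, 1), "intercept", "poly"))
    cleaned <- regress_nuisance(ph$mag, design)$series
    after <- band_power_ratio(cleaned, masks$gm, masks$csf)
    better[i] <- after$avlff_ratio > before$avlff_ratio
    before_ratios[i] <- before$avlff_ratio
  }
  expect_lt(mean(before_ratios), 1)   # CSF dominates the band going in
  expect_gte(mean(better), 0.9)
})

test_that("homogeneity reproduces its closed forms", {
  nt <- 170
  set.seed(54)
  x <- rnorm(nt)
  # identical courses: every entry 1
  h1 <- homogeneity(cbind(x, x, x), tr_s = 3.5)
  expect_equal(h1$values, matrix(1, 3, 3), tolerance = 1e-10)
  expect_equal(h1$mean, 1.0, tolerance = 1e-10)
  # sign-flipped pair: r = -1, coherence = 1, homogeneity 0
  h2 <- homogeneity(cbind(x, -x), tr_s = 3.5)
  expect_equal(h2$mean, 0.0, tolerance = 1e-10)
  # zero-variance course names the offender
  expect_error(homogeneity(cbind(x, rep(1, nt)), tr_s = 3.5), "index 2")
})

test_that("independent noise courses have low mean homogeneity", {
  set.seed(55)
  means <- replicate(100, {
    homogeneity(matrix(rnorm(256 * 10), 256, 10), tr_s = 3.5)$mean
  })
  expect_lt(mean(means), 0.3)
})

test_that("coherence detects delayed copies that correlation misses", {
  nt <- 256; tr <- 3.5
  set.seed(56)
  # band-limited course and a 3-volume (10.5 s) delayed copy
  x <- as.numeric(stats::filter(rnorm(nt + 3), rep(1 / 8, 8), sides = 1))
  x[is.na(x)] <- 0
  a <- x[4:(nt + 3)]
  b <- x[1:nt]
  coh <- band_coherence(a, b, tr, band_hz = c(0.01, 0.1))
  expect_gt(coh, 0.95)
  expect_lt(abs(cor(a, b)), 0.9)
})

test_that("the noise correlation stack enumerates 67 labelled components", {
  cfg <- tiny_rest_config(seed = 57, motion_amp_deg = 0.2,
                          motion_amp_mm = 0.1)
  ph <- make_phantom(cfg)
  nt <- cfg$n_volumes
  t_vol <- (seq_len(nt) - 1) * cfg$tr_s
  al <- alias_physio(ph$physio, t_vol)
  rr <- build_retroicor_regressors(ph$physio, t_vol)
  masks <- make_tissue_masks(ph$truth$tissue)
  tiss <- cbind(mean_timecourse(ph$mag, masks$csf),
                mean_timecourse(ph$mag, masks$gm),
                mean_timecourse(ph$mag, masks$wm))
  line <- ph$truth$lines[[1]]
  magc <- laminaprep:::line_courses(ph$mag, line)
  phc <- laminaprep:::line_courses(ph$phase, line)
  stack <- noise_correlation_stack(ph$truth$motion,
                                   cbind(al$cardiac, al$respiratory), rr,
                                   tiss, magc, phc)
  expect_equal(ncol(stack$correlation), 6 + 2 + 36 + 3 + 10 + 10)
  expect_equal(stack$correlation, t(stack$correlation))
  expect_equal(unname(diag(stack$correlation)), rep(1, 67))
  expect_true(stack$mean_noise_correlation >= 0 &&
                stack$mean_noise_correlation <= 1)
  # a magnitude course that copies the aliased cardiac trace correlates 1
  magc2 <- magc
  magc2[, 1] <- al$cardiac
  stack2 <- noise_correlation_stack(ph$truth$motion,
                                    cbind(al$cardiac, al$respiratory), rr,
                                    tiss, magc2, phc)
  expect_equal(abs(stack2$correlation["aliased_cardiac", "mag_vox_1"]), 1,
               tolerance = 1e-12)
  # mismatched lengths are an error naming the component
  expect_error(noise_correlation_stack(ph$truth$motion,
                                       cbind(al$cardiac, al$respiratory)[1:10, ],
                                       rr, tiss, magc, phc), "aliased")
})

test_that("paired pipeline tests behave classically", {
  set.seed(58)
  a <- rnorm(50)
  # identical measurements: zero-variance flag
  r0 <- paired_pipeline_test(a, a)
  expect_false(r0$defined)
  # constant shift with tiny noise: overwhelming evidence
  r1 <- paired_pipeline_test(a, a + 1 + rnorm(50, sd = 1e-3))
  expect_lt(r1$p, 1e-6)
  expect_true(r1$significant)
  expect_error(paired_pipeline_test(a[1:2], a[1:2] + 1), "3 pairs")
  # matrix form over pipelines
  vals <- cbind(p1 = a, p2 = a + 1 + rnorm(50, sd = 1e-3),
                p3 = a + rnorm(50, sd = 1))
  pm <- paired_test_matrix(vals)
  expect_true(pm$significant["p1", "p2"])
  expect_equal(pm$p, t(pm$p))
})

test_that("paired t-test type-I error sits at the nominal level", {
  set.seed(59)
  n_rep <- 400
  rej <- replicate(n_rep, {
    a <- rnorm(280); b <- rnorm(280)
    paired_pipeline_test(a, b)$p < 0.05
  })
  ci <- qbinom(c(0.025, 0.975), n_rep, 0.05) / n_rep
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})
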