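## Synthetic magnitude+phase phantom.
##
## A flat cortical slab (WM base, GM ribbon, CSF cap along z) carrying the
## signal structure the evaluation battery assumes: depth-dependent
## band-limited "neural" fluctuations (rest) or a block response (task), a
## pooled and delayed vein component with a proportional phase counterpart
## that decays with cortical depth, quasi-periodic cardiac/respiratory
## signals recorded at high rate and aliased into the volumes, slow Legendre
## drift, optional rigid head motion, and white thermal noise.  Every
## component is returned voxel-wise as ground truth.

#' Phantom configuration
#'
#' Collects every tunable of [make_phantom()] with defaults matching a
#' sub-millimetre 7T acquisition: 0.63 mm isotropic voxels, TR 3.5 s, a
#' ~10 min resting run of 174 volumes (4 dummies + 170) or, in task mode, a
#' (21 s on / 21 s off) x 12 block paradigm.  The vein component decays over
#' 20% of the cortical thickness, the approximate point-spread of the
#' macrovascular BOLD contribution along depth.
#'
#' @param grid integer 3-vector of voxel counts (x, y, z).
#' @param voxel_size_mm voxel edge lengths (mm).
#' @param tr_s repetition time (s).
#' @param n_volumes total volumes including dummies; defaults to 174 (rest)
#'   or 148 (task, i.e. 4 dummies + 144 = 12 blocks of 42 s).
#' @param gm_thickness_vox GM ribbon thickness in voxels (>= 2).
#' @param csf_thickness_vox CSF cap thickness in voxels.
#' @param mode `"rest"` or `"task"`.
#' @param task_onsets_s,task_durations_s block timing in seconds, relative
#'   to the first *retained* volume (the generator shifts by the dummy
#'   duration internally).
#' @param neural_band_hz frequency band of the resting neural process.
#' @param depth_profile `"M"` (deep-layer peak), `"M+T"` (mid-layer peak),
#'   `"flat"`, or a function of depth in `[0, 1]`.
#' @param neural_amp resting neural fluctuation amplitude (scanner units;
#'   ~1% of the GM baseline).
#' @param depth_corr correlation of the neural signal between depths
#'   (shared-component mixing weight).
#' @param response_amp task-response amplitude (scanner units; ~4% of the
#'   GM baseline, a strong motor response).
#' @param vein_gain vein amplitude at the cortical surface, as a
#'   dimensionless multiple of the pooled GM neural signal it drains.
#' @param vein_delay_s delay of the pooled vein signal relative to the GM
#'   neural signal (s).
#' @param vein_depth_decay_frac e-folding depth of the vein amplitude, as a
#'   fraction of cortical thickness.
#' @param phase_vein_coupling phase change per unit vein signal (rad);
#'   applied in vein-carrying voxels only (pial layer and GM shallower than
#'   `vein_depth_decay_frac`) -- parenchymal microvasculature couples to the
#'   magnitude, not the phase.
#' @param phase_noise_sd non-vein phase fluctuation (rad), lumping thermal
#'   phase noise with unmodelled physiological field modulation; sets how
#'   completely the phase fit can remove the vein component.
#' @param cardiac_hz,resp_hz centre frequencies of the cardiac and
#'   respiratory oscillators.
#' @param freq_jitter relative slow jitter of the physiological frequencies.
#' @param physio_gain_cardiac,physio_gain_resp named numeric
#'   `c(csf=, gm=, wm=)` voxel amplitudes of the aliased physiological
#'   signals (CSF largest).
#' @param drift_order,drift_amp Legendre drift: maximum degree and overall
#'   amplitude (sd of the drift course, scanner units).
#' @param motion_amp_deg,motion_amp_mm peak rotation/translation of the
#'   smooth motion trajectory (0 disables motion).
#' @param motion_phase_coupling global phase offset per mm of framewise
#'   displacement (rad/mm).
#' @param thermal_sd standard deviation of i.i.d. Gaussian thermal noise.
#' @param baseline named numeric `c(csf=, gm=, wm=)` tissue baselines.
#' @param baseline_texture_sd sd of a static, spatially smoothed texture
#'   added to the baseline (anatomical contrast; required for rigid
#'   registration to be identifiable in-plane).
#' @param physio_fs_hz sampling rate of the physiological recording (Hz).
#' @param n_lines number of cross-cortex lines generated with the phantom.
#' @param seed integer RNG seed; the same seed yields a bit-identical
#'   phantom.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(40L, 40L, 12L),
                           voxel_size_mm = c(0.63, 0.63, 0.63),
                           tr_s = 3.5,
                           n_volumes = NULL,
                           gm_thickness_vox = 5L,
                           csf_thickness_vox = 3L,
                           mode = c("rest", "task"),
                           task_onsets_s = seq(0, by = 42, length.out = 12),
                           task_durations_s = rep(21, 12),
                           neural_band_hz = c(0.015, 0.04),
                           depth_profile = "M",
                           neural_amp = 10,
                           depth_corr = 0.6,
                           response_amp = 40,
                           vein_gain = 2.5,
                           vein_delay_s = 2,
                           vein_depth_decay_frac = 0.2,
                           phase_vein_coupling = 0.003,
                           phase_noise_sd = 0.08,
                           cardiac_hz = 1.1,
                           resp_hz = 0.3,
                           freq_jitter = 0.03,
                           physio_gain_cardiac = c(csf = 15, gm = 5, wm = 3),
                           physio_gain_resp = c(csf = 10, gm = 4, wm = 2),
                           drift_order = 3L,
                           drift_amp = 5,
                           motion_amp_deg = 0,
                           motion_amp_mm = 0,
                           motion_phase_coupling = 0,
                           thermal_sd = 30,
                           baseline = c(csf = 900, gm = 1000, wm = 700),
                           baseline_texture_sd = 100,
                           physio_fs_hz = 100,
                           n_lines = 8L,
                           seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(n_volumes)) n_volumes <- if (mode == "task") 148L else 174L
  cfg <- list(grid = as.integer(grid), voxel_size_mm = voxel_size_mm,
              tr_s = tr_s, n_volumes = as.integer(n_volumes),
              gm_thickness_vox = as.integer(gm_thickness_vox),
              csf_thickness_vox = as.integer(csf_thickness_vox),
              mode = mode, task_onsets_s = task_onsets_s,
              task_durations_s = task_durations_s,
              neural_band_hz = neural_band_hz,
              depth_profile = depth_profile, neural_amp = neural_amp,
              depth_corr = depth_corr, response_amp = response_amp,
              vein_gain = vein_gain, vein_delay_s = vein_delay_s,
              vein_depth_decay_frac = vein_depth_decay_frac,
              phase_vein_coupling = phase_vein_coupling,
              phase_noise_sd = phase_noise_sd,
              cardiac_hz = cardiac_hz, resp_hz = resp_hz,
              freq_jitter = freq_jitter,
              physio_gain_cardiac = physio_gain_cardiac,
              physio_gain_resp = physio_gain_resp,
              drift_order = as.integer(drift_order), drift_amp = drift_amp,
              motion_amp_deg = motion_amp_deg, motion_amp_mm = motion_amp_mm,
              motion_phase_coupling = motion_phase_coupling,
              thermal_sd = thermal_sd, baseline = baseline,
              baseline_texture_sd = baseline_texture_sd,
              physio_fs_hz = physio_fs_hz, n_lines = as.integer(n_lines),
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  assert_that(length(cfg$grid) == 3L && all(cfg$grid >= 1L),
              "grid must be 3 positive integers")
  assert_that(cfg$gm_thickness_vox >= 2L, "gm_thickness_vox must be >= 2")
  assert_that(cfg$csf_thickness_vox >= 1L, "csf_thickness_vox must be >= 1")
  assert_that(cfg$grid[3] > cfg$gm_thickness_vox + cfg$csf_thickness_vox,
              "grid z extent must exceed GM + CSF thickness (need a WM base)")
  gains <- c(cfg$neural_amp, cfg$response_amp, cfg$vein_gain,
             cfg$phase_noise_sd, cfg$drift_amp, cfg$thermal_sd,
             cfg$motion_amp_deg, cfg$motion_amp_mm, cfg$baseline_texture_sd,
             cfg$physio_gain_cardiac, cfg$physio_gain_resp)
  assert_that(all(gains >= 0), "all gains and noise sds must be >= 0")
  assert_that(cfg$depth_corr >= 0 && cfg$depth_corr <= 1,
              "depth_corr must lie in [0, 1]")
  assert_that(cfg$n_volumes >= 8L, "n_volumes must be >= 8")
  assert_that(cfg$physio_fs_hz > 2 * cfg$cardiac_hz * (1 + cfg$freq_jitter),
              "physio_fs_hz must exceed twice the highest cardiac frequency")
  assert_that(cfg$neural_band_hz[1] > 0 &&
                cfg$neural_band_hz[2] > cfg$neural_band_hz[1],
              "neural_band_hz must be an increasing positive pair")
  invisible(TRUE)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("<phantom_config> %s mode, %dx%dx%d grid, %d volumes, TR %g s, seed %d\n",
              x$mode, x$grid[1], x$grid[2], x$grid[3], x$n_volumes, x$tr_s,
              x$seed))
  invisible(x)
}

## per-depth neural amplitude presets; depth d in [0,1], 0 = pial surface
depth_profile_fun <- function(profile) {
  if (is.function(profile)) return(profile)
  switch(profile,
         "flat"  = function(d) rep(1, length(d)),
         "M"     = function(d) 0.6 + 0.8 * exp(-((d - 0.75) / 0.18)^2),
         "M+T"   = function(d) 0.6 + 0.8 * exp(-((d - 0.5) / 0.18)^2),
         stop_lp("unknown depth profile: ", profile))
}

## slab layout: per-z tissue label, smoothed one voxel at the interfaces.
## z runs from the WM base (z = 1) to the CSF cap (z = nz).
slab_fractions <- function(nz, gm, csf) {
  wm_top <- nz - gm - csf
  lab <- c(rep("wm", wm_top), rep("gm", gm), rep("csf", csf))
  smooth1 <- function(ind) {
    out <- ind
    n <- length(ind)
    out[2:(n - 1)] <- 0.25 * ind[1:(n - 2)] + 0.5 * ind[2:(n - 1)] +
      0.25 * ind[3:n]
    out[1] <- 0.75 * ind[1] + 0.25 * ind[2]
    out[n] <- 0.75 * ind[n] + 0.25 * ind[n - 1]
    out
  }
  list(csf = smooth1(as.numeric(lab == "csf")),
       gm = smooth1(as.numeric(lab == "gm")),
       wm = smooth1(as.numeric(lab == "wm")),
       gm_layers = which(lab == "gm"),   # ordered deep -> superficial
       pial_z = nz - csf + 1L,           # CSF layer adjacent to GM
       wm_top = wm_top)
}

## band-limited unit-sd Gaussian processes, one per column
band_limited_noise <- function(nt, tr_s, band_hz, n) {
  f <- (seq_len(nt) - 1) / (nt * tr_s)
  k <- which(f >= band_hz[1] & f <= band_hz[2] & seq_len(nt) - 1 <= nt / 2 &
               seq_len(nt) - 1 >= 1)
  assert_that(length(k) >= 1L, "no Fourier grid frequencies inside the band")
  out <- matrix(0, nt, n)
  for (j in seq_len(n)) {
    spec <- complex(real = rep(0, nt), imaginary = rep(0, nt))
    z <- complex(real = stats::rnorm(length(k)),
                 imaginary = stats::rnorm(length(k)))
    spec[k] <- z
    spec[nt - (k - 1) + 1] <- Conj(z)
    x <- Re(stats::fft(spec, inverse = TRUE)) / nt
    out[, j] <- x / stats::sd(x)
  }
  out
}

## quasi-periodic oscillator with slow frequency jitter
quasi_periodic <- function(n_samp, fs_hz, f0_hz, jitter, harmonic = 0) {
  z <- as.numeric(stats::filter(stats::rnorm(n_samp), 0.995,
                                method = "recursive"))
  if (stats::sd(z) > 0) z <- z / stats::sd(z)
  f_inst <- f0_hz * (1 + jitter * z)
  ph <- 2 * pi * cumsum(f_inst) / fs_hz
  cos(ph) + harmonic * cos(2 * ph)
}

## apply a course to a 3D gain map -> 4D component
outer_component <- function(gain_map, course) {
  array(outer(as.vector(gain_map), course), dim = c(dim(gain_map),
                                                    length(course)))
}

## delayed copy of a volume-sampled course (linear interpolation, edge hold)
delay_course <- function(x, delay_s, tr_s) {
  t_v <- (seq_along(x) - 1) * tr_s
  stats::approx(t_v, x, xout = t_v - delay_s, rule = 2)$y
}

#' Generate a paired magnitude/phase phantom with ground truth
#'
#' See [phantom_config()] for the model.  Determinism: the same
#' configuration (including `seed`) produces bit-identical output.
#'
#' @param config a [phantom_config()].
#' @return A list of class `lp_phantom` with elements `mag`
#'   ([bold_series()]), `phase` ([phase_series()]), `physio`
#'   ([physio_recording()]), `truth` (class `synthetic_truth`: per-voxel
#'   `baseline`, `neural`, `vein`, `phase_vein`, `physio_card`,
#'   `physio_resp`, `drift` components, the applied `motion` trace, the
#'   `tissue` fraction maps, the cross-cortex `lines`, and layout helpers)
#'   and `config`.
#' @export
make_phantom <- function(config = phantom_config()) {
  cfg <- config
  validate_phantom_config(cfg)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(cfg$seed)

  d <- cfg$grid
  nt <- cfg$n_volumes
  nz <- d[3]
  gm <- cfg$gm_thickness_vox
  slab <- slab_fractions(nz, gm, cfg$csf_thickness_vox)
  ## in-plane air margin: tissue tapers to zero over 2 voxels at the x/y
  ## borders, so head motion moves tissue within the FOV instead of
  ## replicating edge content
  taper <- function(n) pmin(1, (seq_len(n) - 1) / 2, (n - seq_len(n)) / 2)
  apod <- array(outer(taper(d[1]), taper(d[2])), dim = d)  # recycled over z
  per_z <- function(v) array(rep(v, each = d[1] * d[2]), dim = d) * apod
  tissue <- tissue_maps(per_z(slab$csf), per_z(slab$gm), per_z(slab$wm))

  ## ---- neural component -------------------------------------------------
  t_vol <- (seq_len(nt) - 1) * cfg$tr_s
  gm_layers <- slab$gm_layers                       # deep -> superficial z
  depth_of_layer <- rev(seq_len(gm)) / gm - 0.5 / gm # d: superficial ~0, deep ~1
  prof <- depth_profile_fun(cfg$depth_profile)(depth_of_layer)
  if (cfg$mode == "rest") {
    shared <- band_limited_noise(nt, cfg$tr_s, cfg$neural_band_hz, 1)[, 1]
    own <- band_limited_noise(nt, cfg$tr_s, cfg$neural_band_hz, gm)
    rho <- cfg$depth_corr
    layer_courses <- sqrt(rho) * matrix(shared, nt, gm) + sqrt(1 - rho) * own
    layer_courses <- sweep(layer_courses, 2, cfg$neural_amp * prof, `*`)
  } else {
    des <- build_design(task_design(
      onsets_s = cfg$task_onsets_s + 4 * cfg$tr_s,  # place after the dummies
      durations_s = cfg$task_durations_s,
      n_volumes = nt, tr_s = cfg$tr_s))
    resp <- des$values[, "task"]
    layer_courses <- outer(resp, cfg$response_amp * prof)
  }
  ## per-z course: GM layers take their own course; the mixed interface
  ## layers inherit the adjacent GM course (partial-volume leakage)
  z_course <- matrix(0, nt, nz)
  z_course[, gm_layers] <- layer_courses
  z_course[, min(gm_layers) - 1L] <- layer_courses[, 1]        # GM/WM boundary
  z_course[, max(gm_layers) + 1L] <- layer_courses[, gm]       # GM/CSF boundary
  gm_frac_z <- slab$gm
  neural <- array(0, dim = c(d, nt))
  for (z in which(gm_frac_z > 0)) {
    neural[, , z, ] <- outer(as.vector(apod[, , z]) * gm_frac_z[z],
                             z_course[, z])
  }

  ## ---- vein component ---------------------------------------------------
  gm_mean_neural <- rowMeans(layer_courses)
  vein_course <- delay_course(gm_mean_neural, cfg$vein_delay_s, cfg$tr_s)
  vein_amp_z <- rep(0, nz)
  vein_amp_z[gm_layers] <- cfg$vein_gain *
    exp(-depth_of_layer / cfg$vein_depth_decay_frac) * gm_frac_z[gm_layers]
  vein_amp_z[slab$pial_z] <- cfg$vein_gain        # pial vein, full amplitude
  vein <- array(0, dim = c(d, nt))
  for (z in which(vein_amp_z > 0)) {
    vein[, , z, ] <- outer(as.vector(apod[, , z]) * vein_amp_z[z],
                           vein_course)
  }
  ## phase counterpart only where the vein dominates (pial + superficial GM)
  vein_mask_z <- rep(FALSE, nz)
  vein_mask_z[slab$pial_z] <- TRUE
  vein_mask_z[gm_layers[depth_of_layer <= cfg$vein_depth_decay_frac]] <- TRUE
  phase_vein <- array(0, dim = c(d, nt))
  for (z in which(vein_mask_z & vein_amp_z > 0)) {
    phase_vein[, , z, ] <- cfg$phase_vein_coupling * vein[, , z, ]
  }

  ## ---- physiological components -----------------------------------------
  n_samp <- ceiling((nt * cfg$tr_s + 2) * cfg$physio_fs_hz)
  cardiac_trace <- quasi_periodic(n_samp, cfg$physio_fs_hz, cfg$cardiac_hz,
                                  cfg$freq_jitter, harmonic = 0.3)
  resp_trace <- quasi_periodic(n_samp, cfg$physio_fs_hz, cfg$resp_hz,
                               cfg$freq_jitter)
  physio <- physio_recording(cardiac_trace, resp_trace, cfg$physio_fs_hz,
                             t0_s = 0)
  card_alias <- alias_physio(physio, t_vol)$cardiac
  resp_alias <- alias_physio(physio, t_vol)$respiratory
  gain3 <- function(g) per_z(slab$csf * g["csf"] + slab$gm * g["gm"] +
                               slab$wm * g["wm"])
  physio_card <- outer_component(gain3(cfg$physio_gain_cardiac), card_alias)
  physio_resp <- outer_component(gain3(cfg$physio_gain_resp), resp_alias)

  ## ---- drift -------------------------------------------------------------
  if (cfg$drift_order >= 1L && cfg$drift_amp > 0) {
    L <- legendre_basis(nt, cfg$drift_order)[, -1, drop = FALSE]  # degrees 1..k
    coef <- stats::rnorm(ncol(L))
    course <- as.numeric(L %*% coef)
    course <- course / stats::sd(course) * cfg$drift_amp
    drift_gain <- array(1 + stats::runif(prod(d), -0.25, 0.25), dim = d) *
      apod
    drift <- outer_component(drift_gain, course)
  } else {
    drift <- array(0, dim = c(d, nt))
  }

  ## ---- assemble, motion, noise -------------------------------------------
  baseline3 <- per_z(slab$csf * cfg$baseline["csf"] +
                       slab$gm * cfg$baseline["gm"] +
                       slab$wm * cfg$baseline["wm"])
  if (cfg$baseline_texture_sd > 0) {
    tex <- array(stats::rnorm(prod(d)), dim = d)
    for (rep_sm in 1:2) {
      tex <- array(gaussian_conv_matrix(d[1], 1) %*%
                     matrix(tex, d[1], d[2] * d[3]), dim = d)
      tex <- aperm(array(gaussian_conv_matrix(d[2], 1) %*%
                           matrix(aperm(tex, c(2, 1, 3)), d[2], d[1] * d[3]),
                         dim = d[c(2, 1, 3)]), c(2, 1, 3))
      tex <- aperm(array(gaussian_conv_matrix(d[3], 1) %*%
                           matrix(aperm(tex, c(3, 1, 2)), d[3], d[1] * d[2]),
                         dim = d[c(3, 1, 2)]), c(2, 3, 1))
    }
    baseline3 <- baseline3 + tex / stats::sd(tex) * cfg$baseline_texture_sd *
      apod
  }
  mag_clean <- array(rep(baseline3, nt), dim = c(d, nt)) + neural + vein +
    physio_card + physio_resp + drift
  phase_clean <- phase_vein

  motion <- make_motion_trajectory(nt, cfg$motion_amp_deg, cfg$motion_amp_mm)
  if (any(motion$params != 0)) {
    fd <- c(0, rowSums(abs(diff(motion$params[, 4:6, drop = FALSE]))))
    for (v in seq_len(nt)) {
      p <- motion$params[v, ]
      if (any(p != 0)) {
        ## windowed-sinc resampling: the phantom's content is band-limited,
        ## so the moved volume is a near-exact rigid copy rather than a
        ## trilinearly blurred one
        mag_clean[, , , v] <- rigid_resample(mag_clean[, , , v], p,
                                             cfg$voxel_size_mm,
                                             inverse = FALSE,
                                             method = "lanczos")
        phase_clean[, , , v] <- rigid_resample_phase(phase_clean[, , , v], p,
                                                     cfg$voxel_size_mm,
                                                     inverse = FALSE,
                                                     method = "lanczos")
      }
      phase_clean[, , , v] <- phase_clean[, , , v] +
        cfg$motion_phase_coupling * fd[v]
    }
  }
  mag_data <- mag_clean + array(stats::rnorm(prod(d) * nt, 0, cfg$thermal_sd),
                                dim = c(d, nt))
  phase_data <- phase_clean +
    array(stats::rnorm(prod(d) * nt, 0, cfg$phase_noise_sd), dim = c(d, nt))

  mag <- bold_series(mag_data, cfg$voxel_size_mm, cfg$tr_s)
  phase <- phase_series(phase_data, cfg$voxel_size_mm, cfg$tr_s)

  truth <- structure(list(baseline = baseline3, neural = neural, vein = vein,
                          phase_vein = phase_vein, physio_card = physio_card,
                          physio_resp = physio_resp, drift = drift,
                          motion = motion, tissue = tissue,
                          cardiac_alias = card_alias,
                          respiratory_alias = resp_alias,
                          vein_course = vein_course,
                          gm_layers = gm_layers, pial_z = slab$pial_z,
                          depth_of_layer = depth_of_layer,
                          vein_mask_z = vein_mask_z, grid = d,
                          lines = NULL),
                     class = "synthetic_truth")
  truth$lines <- make_lines(truth, cfg$n_lines)
  structure(list(mag = mag, phase = phase, physio = physio, truth = truth,
                 config = cfg),
            class = "lp_phantom")
}

#' @export
print.lp_phantom <- function(x, ...) {
  print(x$config)
  print(x$mag)
  invisible(x)
}

## smooth 6-parameter trajectory with given peak amplitudes; row 1 zero
make_motion_trajectory <- function(nt, amp_deg, amp_mm) {
  params <- matrix(0, nt, 6)
  if (amp_deg > 0 || amp_mm > 0) {
    for (j in 1:6) {
      amp <- if (j <= 3) amp_deg else amp_mm
      if (amp == 0) next
      w <- cumsum(stats::rnorm(nt))
      win <- min(15L, max(1L, nt - 1L))
      w <- as.numeric(stats::filter(w, rep(1 / win, win), sides = 2))
      w[is.na(w)] <- 0
      w <- w - w[1]
      m <- max(abs(w))
      if (m > 0) params[, j] <- w / m * amp
    }
    params[1, ] <- 0
  }
  motion_trace(params)
}

#' Generate straight cross-cortex lines through the phantom slab
#'
#' Lines are full 10-voxel columns along z starting in the CSF cap,
#' crossing the GM ribbon and ending in WM, at deterministic, evenly spread
#' (x, y) positions away from the volume edges.  `depth_index` is assigned
#' linearly from 0 (CSF end) to 1 (WM end).
#'
#' @param truth a `synthetic_truth` (for the slab layout), or an
#'   `lp_phantom`.
#' @param n_lines number of lines (0 gives an empty list).
#' @return List of [cross_cortex_line()] objects.
#' @export
make_lines <- function(truth, n_lines = 8L) {
  if (inherits(truth, "lp_phantom")) truth <- truth$truth
  n_lines <- as.integer(n_lines)
  if (n_lines == 0L) return(list())
  d <- truth$grid
  nz <- d[3]
  if (nz < 10L) stop_lp("slab too thin for 10-voxel cross-cortex lines")
  zs <- seq(nz, nz - 9L)
  ## must start in CSF and end in WM
  wm_top <- min(truth$gm_layers) - 1L
  assert_that(min(zs) <= wm_top && max(zs) > max(truth$gm_layers),
              "slab layout does not admit CSF->GM->WM 10-voxel columns")
  margin <- 3L
  lo <- margin + 1L
  hix <- d[1] - margin
  hiy <- d[2] - margin
  assert_that(hix >= lo && hiy >= lo, "grid too small for line placement")
  k <- ceiling(sqrt(n_lines))
  xs <- round(seq(lo, hix, length.out = k))
  ys <- round(seq(lo, hiy, length.out = ceiling(n_lines / k)))
  pos <- expand.grid(x = xs, y = ys)[seq_len(n_lines), , drop = FALSE]
  lapply(seq_len(n_lines), function(i) {
    cross_cortex_line(cbind(pos$x[i], pos$y[i], zs))
  })
}

#' Rasterize cross-cortex lines into an integer label volume
#'
#' Each line's voxels receive the line's 1-based id; all other voxels are 0.
#' Overlapping lines are an error.  [parse_line_labelmap()] inverts the
#' operation (voxels of each id are ordered from the CSF end downwards,
#' i.e. by decreasing z).
#'
#' @param lines list of [cross_cortex_line()].
#' @param grid integer 3-vector, volume dimensions.
#' @return Integer 3D array of line labels.
#' @export
make_line_labelmap <- function(lines, grid) {
  vol <- array(0L, dim = grid)
  for (i in seq_along(lines)) {
    v <- lines[[i]]$voxels
    flat <- v[, 1] + (v[, 2] - 1L) * grid[1] + (v[, 3] - 1L) * grid[1] * grid[2]
    if (any(vol[flat] != 0L)) {
      stop_lp(sprintf("line %d overlaps line %d in the label map", i,
                      vol[flat][vol[flat] != 0L][1]))
    }
    vol[flat] <- i
  }
  vol
}

#' @rdname make_line_labelmap
#' @param labelmap integer 3D array as produced by [make_line_labelmap()].
#' @export
parse_line_labelmap <- function(labelmap) {
  ids <- sort(unique(labelmap[labelmap > 0]))
  lapply(ids, function(id) {
    idx <- which(labelmap == id, arr.ind = TRUE)
    idx <- idx[order(-idx[, 3], idx[, 1], idx[, 2]), , drop = FALSE]
    dimnames(idx) <- NULL
    cross_cortex_line(idx)
  })
}

#' Write a complete phantom fixture set to a directory
#'
#' Emits `magnitude.nii.gz`, `phase.nii.gz`, tissue fraction maps, the line
#' label map, the physiological traces as TSV, each ground-truth component
#' as NIfTI and the configuration as YAML.
#'
#' @param phantom an `lp_phantom`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_dir <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vx <- phantom$config$voxel_size_mm
  write_series(phantom$mag, file.path(dir, "magnitude.nii.gz"))
  write_series(phantom$phase, file.path(dir, "phase.nii.gz"))
  tt <- phantom$truth$tissue
  write_volume(tt$csf, file.path(dir, "tissue_csf.nii.gz"), vx)
  write_volume(tt$gm, file.path(dir, "tissue_gm.nii.gz"), vx)
  write_volume(tt$wm, file.path(dir, "tissue_wm.nii.gz"), vx)
  write_volume(make_line_labelmap(phantom$truth$lines, phantom$config$grid),
               file.path(dir, "lines.nii.gz"), vx)
  write_physio(phantom$physio, file.path(dir, "physio.tsv"))
  for (comp in c("neural", "vein", "phase_vein", "physio_card",
                 "physio_resp", "drift")) {
    write_series(bold_series(phantom$truth[[comp]], vx, phantom$config$tr_s),
                 file.path(dir, sprintf("truth_%s.nii.gz", comp)))
  }
  cfg <- phantom$config
  class(cfg) <- NULL
  cfg$depth_profile <- if (is.function(cfg$depth_profile)) "custom"
  else cfg$depth_profile
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
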