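# Seeded generators for every input the pipeline consumes: pH decay,
# smooth four-phase parameter trajectories, stage-2 forward-modelled SANS
# series (GdL) and stage-1 series (methanol), logistic ThT traces,
# emission spectra with 485 nm ThT and 450 nm turbidity channels, two-band
# amide-I FTIR series, and an explicit 3-component bilinear joint dataset
# for factorisation tests. All generators are pure functions of
# (config, seed).

with_seed <- function(seed, expr) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  expr
}

#' Default phase script for a GdL-triggered gelation run
#'
#' Encodes the four gelation regimes as per-parameter anchor values
#' (the plateau level of each structural parameter within Initiation,
#' Pre-assembly, Network Assembly and Maturation), phase boundaries at
#' 35, 180 and 300 min, logistic transition widths, and per-phase
#' "wobble" amplitudes for the structurally plastic parameters — the
#' Pre-assembly regime fluctuates strongly around n ~ 4, m ~ 2.7 while
#' the flanking regimes are comparatively quiet. The power-law amplitude
#' is parameterised through `i_ref`, the power-law intensity at
#' `q_ref = 0.002` A^-1, so that low-q intensities stay at realistic
#' absolute levels while `n` varies (`a = i_ref * q_ref^n`).
#'
#' @param boundaries phase-transition times, min.
#' @param widths logistic transition width per boundary, min.
#' @param noise relative intensity noise fraction (0-0.2).
#' @param seed generator seed.
#' @return object of class `phase_script` (a list of anchor tables).
#' @export
default_phase_script <- function(boundaries = c(35, 180, 300),
                                 widths = c(3, 4, 4),
                                 noise = 0.01, seed = 101,
                                 wobble_scale = 1) {
  stopifnot(is.unsorted(boundaries) == FALSE, length(widths) == length(boundaries),
            noise >= 0, noise <= 0.2)
  anchors <- list(
    i_ref  = c(30, 20, 60, 80),          # power-law intensity at q_ref, cm^-1
    n      = c(2.8, 4.0, 3.0, 2.5),
    c      = c(1.5, 0.35, 1.2, 0.8),
    eta    = c(100, 50, 70, 62),          # Angstrom
    m      = c(2.2, 2.7, 2.6, 2.5),
    d      = c(0.05, 0.35, 0.15, 0.08),
    d_star = c(365, 380, 295, 235),       # Angstrom; q0 = 2*pi/d_star
    sigma  = c(0.003, 0.0035, 0.0025, 0.0028),
    b      = c(0.03, 0.03, 0.03, 0.03)
  )
  wobble <- list(                          # sinusoidal amplitude per phase
    i_ref  = c(0.6, 0.5, 1.0, 0.8),
    n      = c(0.06, 0.55, 0.05, 0.03),
    c      = c(0.12, 0.03, 0.04, 0.03),
    eta    = c(1.5, 8, 2.0, 1),
    m      = c(0.02, 0.15, 0.02, 0.015),
    d      = c(0.003, 0.08, 0.006, 0.003),
    d_star = c(3, 10, 4, 2),
    sigma  = c(2e-5, 1.2e-4, 4e-5, 2e-5),
    b      = c(0, 0, 0, 0)
  )
  for (p in names(wobble)) wobble[[p]] <- wobble[[p]] * wobble_scale
  phi1 <- c(i_ref = 0.0, n = 2.4, c = 4.0, eta = 1.0, m = 5.2, d = 2.094,
            d_star = 3.5, sigma = 0.7, b = 0)
  phi2 <- c(i_ref = 1.1, n = 3.3, c = 0.4, eta = 2.2, m = 1.8, d = 4.291,
            d_star = 5.0, sigma = 2.9, b = 0)
  structure(list(boundaries = boundaries, widths = widths,
                 anchors = anchors, wobble = wobble,
                 wobble_periods = c(60, 97), wobble_phase1 = phi1,
                 wobble_phase2 = phi2, noise = noise, seed = seed,
                 q_ref = 0.002),
            class = "phase_script")
}

# smooth blend of per-phase levels: sum of logistic steps
blend_phases <- function(t, levels, boundaries, widths) {
  v <- rep(levels[1], length(t))
  for (i in seq_along(boundaries))
    v <- v + (levels[i + 1] - levels[i]) * stats::plogis((t - boundaries[i]) / widths[i])
  v
}

#' Simulate an off-line pH trace
#'
#' Phenomenological GdL acidification: exponential decay
#' `pH(t) = 3.6 + (7.5 - 3.6) * exp(-k t)` from the initial pH 7.5 toward
#' the ~3.6 asymptote, with rate `k` proportional to the GdL
#' concentration (calibrated so 1% w/v GdL reaches pH 4.5 at 35 min);
#' doubling the GdL concentration halves the time to any given pH level.
#' Small seeded measurement noise is added.
#'
#' @param gdl_percent GdL concentration, % w/v.
#' @param t_grid times, min.
#' @param noise_sd measurement noise sd, pH units.
#' @param seed RNG seed.
#' @param ph0,ph_inf initial and asymptotic pH.
#' @return a [kinetic_trace()] of kind `"ph"`.
#' @export
simulate_ph <- function(gdl_percent = 1, t_grid = seq(5, 400, by = 5),
                        noise_sd = 0.01, seed = 1,
                        ph0 = 7.5, ph_inf = 3.6) {
  k <- gdl_percent * log((4.5 - ph_inf) / (ph0 - ph_inf)) / -35
  v <- ph_inf + (ph0 - ph_inf) * exp(-k * t_grid)
  if (noise_sd > 0)
    v <- v + with_seed(seed, stats::rnorm(length(t_grid), 0, noise_sd))
  kinetic_trace(t_grid, v, kind = "ph")
}

#' Simulate the true parameter trajectory of a phase script
#'
#' Each parameter follows a sum of logistic steps between its phase
#' anchors plus a smooth sinusoidal wobble whose amplitude is itself
#' phase-blended (seeded phases per parameter), so the trajectory is
#' smooth, deterministic given the seed, and has unambiguous per-frame
#' truth values for recovery tests.
#'
#' @param script a [default_phase_script()].
#' @param t_grid frame times, min.
#' @return data.frame with columns `time_min, a, n, c, eta, m, d, q0,
#'   sigma, b, d_star` (the generative truth per frame).
#' @export
simulate_param_trajectory <- function(script = default_phase_script(),
                                      t_grid = seq(5, 400, by = 5)) {
  an <- script$anchors; wo <- script$wobble
  pp <- script$wobble_periods
  traj <- lapply(names(an), function(p) {
    base <- blend_phases(t_grid, an[[p]], script$boundaries, script$widths)
    amp <- blend_phases(t_grid, wo[[p]], script$boundaries, script$widths)
    base + amp * (0.7 * sin(2 * pi * t_grid / pp[1] + script$wobble_phase1[[p]]) +
                    0.3 * sin(2 * pi * t_grid / pp[2] + script$wobble_phase2[[p]]))
  })
  names(traj) <- names(an)
  q0 <- 2 * pi / traj$d_star
  a <- traj$i_ref * script$q_ref^traj$n
  out <- data.frame(time_min = t_grid, a = a, n = traj$n, c = traj$c,
                    eta = traj$eta, m = traj$m, d = traj$d, q0 = q0,
                    sigma = traj$sigma, b = traj$b, d_star = traj$d_star)
  out
}

#' Default instrument q grid
#' @param n number of points.
#' @param qmin,qmax range, A^-1.
#' @return log-spaced q grid.
#' @export
default_q_grid <- function(n = 120, qmin = 0.002, qmax = 0.5) {
  exp(seq(log(qmin), log(qmax), length.out = n))
}

#' Forward-model a SANS series from a truth trajectory
#'
#' Each frame is the stage-2 model evaluated at the frame's truth
#' parameters, degraded with seeded multiplicative Gaussian noise of
#' relative sd `noise` plus an additive floor of sd `background / 50`
#' (reduced SANS data carry roughly relative errors at mid-q and a flat
#' floor at high q). The `dI` column carries the noise-model sd.
#'
#' @param truth trajectory data.frame from [simulate_param_trajectory()].
#' @param q_grid scattering-vector grid, A^-1.
#' @param noise relative noise fraction.
#' @param seed RNG seed.
#' @param sample_label,trigger_percent,rsf_mg_ml series metadata.
#' @return a [curve_series()] with trigger `"gdl"`.
#' @export
simulate_sans_series <- function(truth, q_grid = default_q_grid(),
                                 noise = 0.02, seed = 1,
                                 sample_label = "synthetic-gdl",
                                 trigger_percent = 1, rsf_mg_ml = 10) {
  frames <- with_seed(seed, lapply(seq_len(nrow(truth)), function(i) {
    p <- as.list(truth[i, ])
    I0 <- eval_peak_model(p, q_grid)
    floor_sd <- if (noise > 0) p$b / 50 else 0
    dI <- sqrt((noise * I0)^2 + floor_sd^2)
    I <- I0 * (1 + stats::rnorm(length(q_grid), 0, noise)) +
      stats::rnorm(length(q_grid), 0, floor_sd)
    scattering_curve(q_grid, I, dI, time_min = truth$time_min[i])
  }))
  curve_series(frames, sample_label = sample_label, trigger = "gdl",
               trigger_percent = trigger_percent, rsf_mg_ml = rsf_mg_ml)
}

#' Simulate a methanol-triggered series (no correlation peak)
#'
#' Methanol-induced aggregation shows a rapid, continuous intensity rise
#' with no mid-q correlation peak: the stage-1 model with monotonically
#' growing power-law and Lorentzian amplitudes, no Gaussian term.
#'
#' @param q_grid scattering-vector grid, A^-1.
#' @param t_grid frame times, min.
#' @param noise relative noise fraction.
#' @param seed RNG seed.
#' @return list `series` (a [curve_series()], trigger `"methanol"`) and
#'   `truth` (per-frame stage-1 parameter data.frame).
#' @export
simulate_methanol_series <- function(q_grid = default_q_grid(),
                                     t_grid = seq(5, 200, by = 5),
                                     noise = 0.02, seed = 1) {
  g <- 1 - exp(-t_grid / 60)               # saturating growth
  truth <- data.frame(
    time_min = t_grid,
    a = 2e-5 * (1 + 4 * g), n = 2.5,
    c = 0.4 * (1 + 5 * g), eta = 40, m = 2.0, b = 0.03)
  frames <- with_seed(seed, lapply(seq_len(nrow(truth)), function(i) {
    p <- as.list(truth[i, ])
    I0 <- eval_gel_model(p, q_grid)
    floor_sd <- if (noise > 0) p$b / 50 else 0
    I <- I0 * (1 + stats::rnorm(length(q_grid), 0, noise)) +
      stats::rnorm(length(q_grid), 0, floor_sd)
    scattering_curve(q_grid, I, sqrt((noise * I0)^2 + floor_sd^2),
                     time_min = t_grid[i])
  }))
  list(series = curve_series(frames, sample_label = "synthetic-methanol",
                             trigger = "methanol", trigger_percent = 15,
                             rsf_mg_ml = 10),
       truth = truth)
}

#' Simulate a ThT kinetic trace
#'
#' Logistic `baseline + A / (1 + exp(-(t - t_m)/tau))` plus seeded
#' Gaussian noise. Defaults reproduce the reference run's landmarks:
#' midpoint 128 min, characteristic time 20.5 min, hence onset
#' `t_m - 2 tau = 87` min.
#'
#' @param t_grid times, min.
#' @param A,t_m,tau,baseline logistic parameters.
#' @param noise relative noise (fraction of A).
#' @param seed RNG seed.
#' @return a [kinetic_trace()] of kind `"tht"`.
#' @export
simulate_tht <- function(t_grid = seq(1, 400, by = 1), A = 1, t_m = 128,
                         tau = 20.5, baseline = 0.05, noise = 0,
                         seed = 1) {
  v <- baseline + A / (1 + exp(-(t_grid - t_m) / tau))
  if (noise > 0)
    v <- v + with_seed(seed, stats::rnorm(length(t_grid), 0, noise * A))
  kinetic_trace(t_grid, v, kind = "tht")
}

#' Simulate a turbidity waveform
#'
#' Steady logistic rise through Pre-assembly surging in Network Assembly.
#'
#' @inheritParams simulate_tht
#' @return a [kinetic_trace()] of kind `"turbidity"`.
#' @export
simulate_turbidity <- function(t_grid = seq(1, 400, by = 1), A = 1,
                               t_m = 190, tau = 45, baseline = 0.1,
                               noise = 0, seed = 2) {
  v <- baseline + A / (1 + exp(-(t_grid - t_m) / tau))
  if (noise > 0)
    v <- v + with_seed(seed, stats::rnorm(length(t_grid), 0, noise * A))
  kinetic_trace(t_grid, v, kind = "turbidity")
}

#' Simulate a fluorescence emission spectral series
#'
#' Wavelength axis 400-600 nm. A Gaussian ThT emission band centred at
#' 485 nm (sd 12 nm) whose amplitude follows the ThT logistic, plus a
#' narrow 450 nm excitation-scatter channel (sd 3 nm) whose amplitude
#' follows the turbidity waveform, over a small flat offset, with seeded
#' noise. [tht_trace()] and [turbidity_trace()] applied to the output
#' recover the two waveforms within noise.
#'
#' @param t_grid spectrum timestamps, min.
#' @param tht_pars list of logistic parameters for the ThT waveform
#'   (`A, t_m, tau, baseline`).
#' @param turb_pars list for the turbidity waveform.
#' @param axis wavelength grid, nm.
#' @param noise additive noise sd (intensity units).
#' @param seed RNG seed.
#' @return a [spectrum_series()] of kind `"fluorescence_emission"`.
#' @export
simulate_emission_series <- function(t_grid = seq(5, 400, by = 5),
                                     tht_pars = list(A = 1, t_m = 128,
                                                     tau = 20.5, baseline = 0.05),
                                     turb_pars = list(A = 0.8, t_m = 190,
                                                      tau = 45, baseline = 0.1),
                                     axis = seq(400, 600, by = 1),
                                     noise = 0.005, seed = 3) {
  wave <- function(p, t) p$baseline + p$A / (1 + exp(-(t - p$t_m) / p$tau))
  tht_amp <- wave(tht_pars, t_grid)
  turb_amp <- wave(turb_pars, t_grid)
  band485 <- exp(-(axis - 485)^2 / (2 * 12^2))
  band450 <- exp(-(axis - 450)^2 / (2 * 3^2))
  M <- outer(band485, tht_amp) + outer(band450, turb_amp) + 0.01
  if (noise > 0)
    M <- M + with_seed(seed, matrix(stats::rnorm(length(M), 0, noise),
                                    nrow(M), ncol(M)))
  spectrum_series(axis, M, t_grid, kind = "fluorescence_emission")
}

#' Simulate a time-resolved amide-I FTIR series
#'
#' Two Gaussian bands — 1620 cm^-1 (crystalline beta-sheet, sd 12) whose
#' amplitude follows a lagged sigmoid, and 1695 cm^-1 (antiparallel beta
#' contacts, sd 8) following fast saturation `1 - exp(-t/tau)` — over a
#' broad random-coil band at 1650 cm^-1 that declines as order grows,
#' plus a buffer contribution, a linear drift baseline and seeded noise.
#' The 1695 half-rise precedes the 1620 half-rise by construction.
#'
#' @param t_grid spectrum timestamps, min.
#' @param axis wavenumber grid, cm^-1.
#' @param k1620 list `t_m, tau` of the 1620 sigmoid.
#' @param tau1695 saturation time constant of the 1695 band, min.
#' @param drift linear baseline slope per cm^-1 (absorbance units).
#' @param noise additive noise sd.
#' @param seed RNG seed.
#' @return list `series` (a [spectrum_series()] of kind `"ftir"`),
#'   `buffer` (buffer spectrum on the same axis), `truth_1620`,
#'   `truth_1695` (the injected waveforms as [kinetic_trace()]s,
#'   min-max normalised).
#' @export
simulate_ftir_series <- function(t_grid = seq(4, 400, by = 4),
                                 axis = seq(1500, 1800, by = 2),
                                 k1620 = list(t_m = 150, tau = 25),
                                 tau1695 = 40,
                                 drift = 2e-4, noise = 0.002, seed = 4) {
  amp1620 <- 1 / (1 + exp(-(t_grid - k1620$t_m) / k1620$tau))
  amp1695 <- 1 - exp(-t_grid / tau1695)
  # the amide backbone is conserved: the random-coil band shrinks by the
  # integrated area the two beta bands gain, keeping total area constant
  ampcoil <- 1 - (12 * amp1620 + 0.45 * 8 * amp1695) / (2 * 12)
  band <- function(c0, s) exp(-(axis - c0)^2 / (2 * s^2))
  buffer <- 0.3 * band(1645, 60) + 0.05
  M <- outer(band(1620, 12), amp1620) +
    0.45 * outer(band(1695, 8), amp1695) +
    2 * outer(band(1650, 12), ampcoil) +
    drift * outer(axis - min(axis), rep(1, length(t_grid))) +
    matrix(buffer, length(axis), length(t_grid))
  if (noise > 0)
    M <- M + with_seed(seed, matrix(stats::rnorm(length(M), 0, noise),
                                    nrow(M), ncol(M)))
  mm <- function(v) (v - min(v)) / (max(v) - min(v))
  list(series = spectrum_series(axis, M, t_grid, kind = "ftir"),
       buffer = buffer,
       truth_1620 = kinetic_trace(t_grid, mm(amp1620), kind = "ftir_band"),
       truth_1695 = kinetic_trace(t_grid, mm(amp1695), kind = "ftir_band"))
}

#' Simulate an explicit 3-component bilinear joint dataset
#'
#' Builds the factorisation ground truth directly: three non-negative
#' concentration waveforms (an initial species declining, a transient
#' pre-assembly species rising and falling, a final network species
#' accumulating), three SANS signatures (stage-2 model curves for three
#' structural states) and three emission signatures (C3 carries the
#' 485 nm ThT band, the turbidity channel rises with C3), multiplied out
#' to `D = C S^T` with seeded relative noise. Used to test and measure
#' MCR-ALS recovery against known truth.
#'
#' @param t_grid frame times, min.
#' @param q_grid SANS q grid (coarser than the instrument default keeps
#'   the matrix compact).
#' @param axis emission wavelength grid, nm.
#' @param noise relative noise fraction.
#' @param seed RNG seed.
#' @return list `jm` (a `joint_matrix`), `C_truth` (times x 3),
#'   `S_truth`, `noise`.
#' @export
simulate_mcr_dataset <- function(t_grid = seq(5, 400, by = 5),
                                 q_grid = default_q_grid(60),
                                 axis = seq(420, 560, by = 2),
                                 noise = 0.01, seed = 5) {
  C <- cbind(
    c1 = 1 - stats::plogis((t_grid - 40) / 12),
    c2 = stats::plogis((t_grid - 45) / 15) * (1 - stats::plogis((t_grid - 200) / 25)),
    c3 = stats::plogis((t_grid - 220) / 30))
  s_sol <- eval_gel_model(c(a = 1e-4 * 0.002^0, n = 2.2, c = 1.2, eta = 90,
                            m = 2.2, b = 0.03), q_grid)
  s_pre <- eval_peak_model(c(a = 20 * 0.002^4, n = 4, c = 0.4, eta = 50,
                             m = 2.7, d = 0.5, q0 = 0.0165, sigma = 0.0035,
                             b = 0.02), q_grid)
  s_net <- eval_gel_model(c(a = 80 * 0.002^2.5, n = 2.5, c = 3, eta = 65,
                            m = 2.5, b = 0.04), q_grid)
  em <- function(c0, s, amp) amp * exp(-(axis - c0)^2 / (2 * s^2))
  e_sol <- em(450, 3, 0.05) + 0.01
  e_pre <- em(450, 3, 0.3) + 0.01
  e_net <- em(485, 12, 1.0) + em(450, 3, 0.8) + 0.01
  S <- rbind(cbind(s_sol, s_pre, s_net), cbind(e_sol, e_pre, e_net))
  colnames(S) <- NULL
  D <- C %*% t(S)
  D <- D * (1 + with_seed(seed, matrix(stats::rnorm(length(D), 0, noise),
                                       nrow(D), ncol(D))))
  D[D < 0] <- 0
  # same block conditioning as build_joint_matrix: per-block max 1, then
  # equal summed variance; column scaling preserves the bilinear truth
  blk <- rep(c("sans", "fluor"), c(length(q_grid), length(axis)))
  w_s <- 1 / max(D[, blk == "sans"]); w_f <- 1 / max(D[, blk == "fluor"])
  D[, blk == "sans"] <- D[, blk == "sans"] * w_s
  D[, blk == "fluor"] <- D[, blk == "fluor"] * w_f
  vs <- sum(apply(D[, blk == "sans"], 2, stats::var))
  vf <- sum(apply(D[, blk == "fluor"], 2, stats::var))
  adj <- sqrt(vs / vf)
  D[, blk == "fluor"] <- D[, blk == "fluor"] * adj
  w_f <- w_f * adj
  jm <- structure(list(
    D = D, time_min = t_grid,
    block = factor(blk, levels = c("sans", "fluor")),
    col_axis = c(q_grid, axis),
    block_weights = c(sans = w_s, fluor = w_f)),
    class = "joint_matrix")
  list(jm = jm, C_truth = C, S_truth = S, noise = noise)
}

#' Simulate a complete multimodal sample
#'
#' One call producing every input of the reference study conditions:
#' the GdL SANS series with its truth trajectory, pH, ThT, emission
#' spectra and FTIR series — all deterministic given `seed`. Optionally
#' writes a sample directory (per-frame CSVs + manifest + trace CSVs)
#' readable back with [read_series()] and friends.
#'
#' @param seed master seed; per-stream seeds are derived from it.
#' @param t_grid SANS frame times, min.
#' @param q_grid instrument q grid.
#' @param noise relative SANS noise.
#' @param script phase script; default [default_phase_script()] with the
#'   given noise and a seed derived from `seed`.
#' @param dir optional output directory; created if given.
#' @return list `sans, truth, ph, tht, emission, ftir, script`.
#' @export
simulate_sample <- function(seed = 1, t_grid = seq(5, 400, by = 5),
                            q_grid = default_q_grid(), noise = 0.01,
                            script = NULL, dir = NULL) {
  if (is.null(script))
    script <- default_phase_script(noise = noise, seed = seed + 1000L)
  truth <- simulate_param_trajectory(script, t_grid)
  sans <- simulate_sans_series(truth, q_grid, noise = script$noise,
                               seed = seed)
  ph <- simulate_ph(1, seq(1, max(t_grid), by = 1), seed = seed + 1L)
  tht <- simulate_tht(seq(1, max(t_grid), by = 1), noise = 0.01,
                      seed = seed + 2L)
  emission <- simulate_emission_series(t_grid, seed = seed + 3L)
  ftir <- simulate_ftir_series(seed = seed + 4L)
  out <- list(sans = sans, truth = truth, ph = ph, tht = tht,
              emission = emission, ftir = ftir, script = script)
  if (!is.null(dir)) write_sample(out, dir)
  out
}

#' Write a simulated sample as a CSV + manifest directory
#' @param sample output of [simulate_sample()].
#' @param dir target directory (created).
#' @return `dir`, invisibly.
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames <- lapply(sample$sans$frames, function(f) {
    fn <- sprintf("frame_%04d.csv", round(f$time_min))
    write_curve(f, file.path(dir, fn))
    list(path = fn, time_min = f$time_min)
  })
  manifest <- list(sample_label = sample$sans$sample_label,
                   trigger = sample$sans$trigger,
                   trigger_percent = sample$sans$trigger_percent,
                   rsf_mg_ml = sample$sans$rsf_mg_ml,
                   frames = frames)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  write_trace(sample$ph, file.path(dir, "ph.csv"))
  write_trace(sample$tht, file.path(dir, "tht.csv"))
  write_spectra(sample$emission, file.path(dir, "emission.csv"))
  write_spectra(sample$ftir$series, file.path(dir, "ftir.csv"))
  utils::write.csv(sample$truth, file.path(dir, "truth_trajectory.csv"),
                   row.names = FALSE)
  invisible(dir)
}
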