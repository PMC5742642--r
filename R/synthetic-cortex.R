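#' Physiology program for a cardiac-arrest / resuscitation experiment
#'
#' Piecewise definition of the experiment's phases (baseline, asphyxial
#' ischemia, CPR, hyperemic reperfusion, oxygen-extraction recovery) as
#' per-quantity percent-change targets approached exponentially. The default
#' amplitudes are the cohort-mean landmark differences of the in-vivo study
#' this pipeline is designed for: ischemic drops of -19.4% ctHbO2 / +66.9%
#' ctHb (StO2 minimum reached 0.46 min after asphyxia onset), reperfusion
#' swings of +32.0 / -94.0, post-peak oxygen-extraction drifts of -9.9 /
#' +31.0, and biphasic scattering with trough-to-peak excursions of 9.7% over
#' 1.1 min during ischemia and 21.2% over 2.1 min during reperfusion.
#' Baseline bulk values: ctHbO2 85 uM, ctHb 40 uM, musp(655 nm) 0.87 mm^-1.
#'
#' Two timelines are provided: `"paper"` replicates the in-vivo session
#' structure (5 min baseline washout, 5 min asphyxia, 45 s CPR, ~24 min
#' total), while `"compressed"` keeps every amplitude and the short timing
#' constants (0.46 min to ischemic minimum, 1.1 / 2.1 min scattering
#' trough-to-peak) but shortens the long inter-landmark plateaus to fit a
#' < 6-simulated-minute run for desk-scale end-to-end work.
#'
#' @param timeline `"paper"` or `"compressed"`.
#' @param baseline Named list of baseline bulk values: `ct_hbo2` (uM),
#'   `ct_hb` (uM), `musp` (mm^-1 at 655 nm).
#' @param amplitude_scale Multiplies every percent-change target (0 gives a
#'   null program with constant series).
#' @param hr_baseline_bpm,hr_post_rosc_bpm Heart-rate plateau values.
#' @return Object of class `physiology_program`: per-quantity segment tables,
#'   [event_annotations()], heart-rate and pulse-amplitude knots, duration.
#' @export
physiology_program <- function(timeline = c("paper", "compressed"),
                               baseline = list(ct_hbo2 = 85, ct_hb = 40,
                                               musp = 0.87),
                               amplitude_scale = 1,
                               hr_baseline_bpm = 360,
                               hr_post_rosc_bpm = 390) {
  timeline <- match.arg(timeline)
  stopifnot(amplitude_scale >= 0, baseline$ct_hbo2 > 0, baseline$ct_hb > 0,
            baseline$musp > 0)
  if (timeline == "paper") {
    ev <- c(asphyxia_onset = 300, cpr_start = 600, rosc = 645,
            first_burst = 1419.6)
    dur <- 1440
    seg <- list(
      ct_hbo2 = segs(c(300, 0, 5), c(327.6, -19.4, 5.52), c(600, -18.4, 60),
                     c(645, -18.4, 60), c(951.6, 12.6, 60), c(1419.6, 2.7, 140),
                     c(1440, 2.7, 60)),
      ct_hb = segs(c(300, 0, 5), c(327.6, 66.9, 5.52), c(600, 64.9, 60),
                   c(645, 64.9, 60), c(951.6, -27.1, 60), c(1419.6, 3.9, 140),
                   c(1440, 3.9, 60)),
      musp = segs(c(300, 0, 5), c(318, -5, 6), c(384, 4.7, 16.5),
                  c(600, 4.0, 90), c(645, 4.0, 60), c(675, -16.7, 7.5),
                  c(801, 4.5, 31.5), c(1419.6, 3.5, 250), c(1440, 3.5, 60))
    )
  } else {
    ev <- c(asphyxia_onset = 60, cpr_start = 150, rosc = 165,
            first_burst = 330)
    dur <- 345
    seg <- list(
      ct_hbo2 = segs(c(60, 0, 5), c(87.6, -19.4, 5.52), c(150, -18.4, 30),
                     c(165, -18.4, 30), c(240, 12.6, 18), c(330, 2.7, 30),
                     c(345, 2.7, 30)),
      ct_hb = segs(c(60, 0, 5), c(87.6, 66.9, 5.52), c(150, 64.9, 30),
                   c(165, 64.9, 30), c(240, -27.1, 18), c(330, 3.9, 40),
                   c(345, 3.9, 30)),
      musp = segs(c(60, 0, 5), c(78, -5, 6), c(144, 4.7, 16.5),
                  c(150, 4.5, 30), c(165, 4.5, 30), c(195, -16.7, 7.5),
                  c(321, 4.5, 31.5), c(330, 4.3, 30), c(345, 4.3, 30))
    )
  }
  seg <- lapply(seg, function(s) {
    s$target_pct <- s$target_pct * amplitude_scale
    s
  })
  t_on <- ev[["asphyxia_onset"]]; t_rosc <- ev[["rosc"]]
  hr_knots <- tibble::tibble(
    time_s = c(0, t_on, t_on + 15, t_rosc, t_rosc + 20, dur),
    hr_bpm = c(hr_baseline_bpm, hr_baseline_bpm, 0, 0, hr_post_rosc_bpm,
               hr_baseline_bpm)
  )
  pulse_knots <- tibble::tibble(
    time_s = c(0, t_on, t_on + 15, t_rosc, t_rosc + 10, dur),
    pulse_amp = c(1, 1, 0, 0, 1, 1)
  )
  structure(list(baseline = baseline, segments = seg,
                 events = event_annotations(ev, span_s = c(0, dur)),
                 duration_s = dur, hr_knots = hr_knots,
                 pulse_knots = pulse_knots, timeline = timeline),
            class = "physiology_program")
}

# build a segment table from c(t_end, target_pct, tau) triples
segs <- function(...) {
  m <- do.call(rbind, list(...))
  tbl <- tibble::tibble(t_end_s = m[, 1], target_pct = m[, 2], tau_s = m[, 3])
  if (is.unsorted(tbl$t_end_s, strictly = TRUE)) {
    stop("segment ends must be strictly increasing", call. = FALSE)
  }
  tbl
}

# Piecewise exponential approach toward per-segment targets; continuous,
# starts at 0% at t = 0.
eval_segments <- function(seg, times) {
  out <- numeric(length(times))
  v0 <- 0
  t0 <- 0
  for (i in seq_len(nrow(seg))) {
    idx <- times > t0 & times <= seg$t_end_s[i]
    if (any(idx)) {
      out[idx] <- seg$target_pct[i] +
        (v0 - seg$target_pct[i]) * exp(-(times[idx] - t0) / seg$tau_s[i])
    }
    v0 <- seg$target_pct[i] +
      (v0 - seg$target_pct[i]) * exp(-(seg$t_end_s[i] - t0) / seg$tau_s[i])
    t0 <- seg$t_end_s[i]
  }
  out[times > t0] <- v0
  out[times <= 0] <- 0
  out
}

#' Simulate bulk physiology time courses
#'
#' Evaluates a [physiology_program()] on a regular time grid: percent-change
#' and absolute trajectories of ctHbO2, ctHb and musp(655), the derived StO2
#' (computed from the concentrations, so the design is internally consistent
#' by construction), the programmed heart rate, and the pulse-amplitude gate
#' (0 during circulatory arrest).
#'
#' @param program A [physiology_program()].
#' @param dt_s Time step, s. Must be <= 1/14 s so the reconstruction rate of
#'   the imaging system is exercised.
#' @return Tibble: `time_s`, `ct_hbo2`, `ct_hb`, `musp`, `sto2`, the percent
#'   columns `pct_*`, `hr_bpm`, `pulse_amp`.
#' @export
simulate_physiology <- function(program, dt_s = 1 / 14) {
  stopifnot(inherits(program, "physiology_program"), dt_s > 0,
            dt_s <= 1 / 14 + 1e-12)
  times <- seq(0, program$duration_s, by = dt_s)
  pct <- lapply(program$segments, eval_segments, times = times)
  ct_hbo2 <- program$baseline$ct_hbo2 * (1 + pct$ct_hbo2 / 100)
  ct_hb <- program$baseline$ct_hb * (1 + pct$ct_hb / 100)
  if (any(ct_hbo2 <= 0) || any(ct_hb <= 0)) {
    stop("program drives concentrations non-positive", call. = FALSE)
  }
  tibble::tibble(
    time_s = times,
    ct_hbo2 = ct_hbo2, ct_hb = ct_hb,
    musp = program$baseline$musp * (1 + pct$musp / 100),
    sto2 = ct_hbo2 / (ct_hbo2 + ct_hb),
    pct_ct_hbo2 = pct$ct_hbo2, pct_ct_hb = pct$ct_hb, pct_musp = pct$musp,
    hr_bpm = approx(program$hr_knots$time_s, program$hr_knots$hr_bpm, times,
                    rule = 2)$y,
    pulse_amp = approx(program$pulse_knots$time_s, program$pulse_knots$pulse_amp,
                       times, rule = 2)$y
  )
}

#' Add cardiac pulsatility to simulated time courses
#'
#' Multiplicative sinusoidal modulation of ctHbO2 (and hence of the absorption
#' it generates) at the instantaneous programmed heart rate, gated by the
#' pulse-amplitude column (no pulsation during arrest). The oscillator phase
#' is the cumulative integral of the instantaneous rate, so rate ramps chirp
#' smoothly.
#'
#' @param courses Output of [simulate_physiology()].
#' @param fractional_amplitude Peak fractional modulation (default 1%).
#' @return `courses` with `ct_hbo2` modulated (and `sto2` recomputed) plus a
#'   `pulse_phase` column.
#' @export
add_pulsatility <- function(courses, fractional_amplitude = 0.01) {
  stopifnot(fractional_amplitude >= 0)
  dt <- diff(courses$time_s[1:2])
  phase <- 2 * pi * cumsum(courses$hr_bpm / 60) * dt
  mod <- 1 + fractional_amplitude * courses$pulse_amp * sin(phase)
  out <- courses
  out$ct_hbo2 <- courses$ct_hbo2 * mod
  out$sto2 <- out$ct_hbo2 / (out$ct_hbo2 + out$ct_hb)
  out$pulse_phase <- phase
  out
}

# Smooth Gaussian random field via circular FFT convolution, normalized to
# zero mean / unit sd.
gaussian_field <- function(nr, nc, sigma_px) {
  noise <- matrix(rnorm(nr * nc), nr, nc)
  gr <- dnorm(pmin(0:(nr - 1), nr - (0:(nr - 1))), sd = sigma_px)
  gc <- dnorm(pmin(0:(nc - 1), nc - (0:(nc - 1))), sd = sigma_px)
  kern <- outer(gr, gc)
  kern <- kern / sum(kern)
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
    (nr * nc)
  (sm - mean(sm)) / sd(sm)
}

# A few sinuous vessel curves of the given half-width, drawn column-wise.
draw_vessels <- function(nr, nc, n_vessels = 2L, half_width = 1L) {
  mask <- matrix(FALSE, nr, nc)
  for (v in seq_len(n_vessels)) {
    c0 <- runif(1, 0.2, 0.8) * nc
    amp <- runif(1, 0.05, 0.15) * nc
    k <- sample(1:2, 1)
    ph <- runif(1, 0, 2 * pi)
    for (r in seq_len(nr)) {
      cc <- round(c0 + amp * sin(2 * pi * k * r / nr + ph))
      lo <- max(1L, cc - half_width); hi <- min(nc, cc + half_width)
      if (lo <= hi) mask[r, lo:hi] <- TRUE
    }
  }
  mask
}

#' Ground-truthed synthetic cortex scene
#'
#' Builds the spatial side of a synthetic experiment: smooth +/-5% textured
#' base maps of ctHbO2, ctHb and musp around the program's bulk baselines, a
#' drawn vessel mask (vessels carry elevated deoxyhemoglobin), a column-wise
#' linear stagger of the scattering dynamics' onset across the field (the
#' spatial-propagation emulation; exposed as a free parameter since no
#' propagation speed is asserted), and the bulk physiology time courses with
#' pulsatility. Scattering at the other wavelengths follows a power-law
#' spectrum `musp(lambda) = musp(655) * (lambda/655)^(-b)`.
#'
#' @param program A [physiology_program()].
#' @param shape Field of view, `c(rows, cols)` pixels.
#' @param pixel_pitch_mm mm/pixel.
#' @param texture_sd Fractional sd of the spatial texture.
#' @param texture_sigma_px Correlation length of the texture, px.
#' @param vessel_ct_hb_boost Fractional ctHb elevation in vessel pixels.
#' @param stagger_s Scattering-onset stagger across the field (s; 0 disables).
#' @param scattering_power Exponent b of the musp wavelength power law.
#' @param wavelengths_nm Simulated wavelengths.
#' @param pulse_amplitude Fractional cardiac modulation of ctHbO2.
#' @param dt_s Time step of the underlying physiology grid (defaults to one
#'   camera frame at 167 Hz so per-frame timestamps resolve the pulsation).
#' @param seed Integer seed; the full scene is reproducible given it.
#' @return Object of class `scene_truth`.
#' @export
scene_truth <- function(program = physiology_program(), shape = c(64, 64),
                        pixel_pitch_mm = 0.1, texture_sd = 0.05,
                        texture_sigma_px = 4, vessel_ct_hb_boost = 0.5,
                        stagger_s = 10, scattering_power = 1.2,
                        wavelengths_nm = c(655, 730, 850),
                        pulse_amplitude = 0.01, dt_s = 1 / 167, seed = 1L) {
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  courses <- add_pulsatility(simulate_physiology(program, dt_s),
                             pulse_amplitude)
  vessel_mask <- draw_vessels(nr, nc)
  ct_hbo2_map <- program$baseline$ct_hbo2 *
    (1 + texture_sd * gaussian_field(nr, nc, texture_sigma_px))
  ct_hb_map <- program$baseline$ct_hb *
    (1 + texture_sd * gaussian_field(nr, nc, texture_sigma_px))
  ct_hb_map[vessel_mask] <- ct_hb_map[vessel_mask] * (1 + vessel_ct_hb_boost)
  musp_map <- program$baseline$musp *
    (1 + texture_sd * gaussian_field(nr, nc, texture_sigma_px))
  if (any(ct_hbo2_map <= 0) || any(ct_hb_map <= 0) || any(musp_map <= 0)) {
    stop("spatial texture drove a base map non-positive", call. = FALSE)
  }
  offset_map <- matrix(rep((seq_len(nc) - 1) / max(nc - 1, 1) * stagger_s,
                           each = nr), nr, nc)
  structure(list(
    program = program, courses = courses, shape = c(nr, nc),
    pixel_pitch_mm = pixel_pitch_mm,
    ct_hbo2_map = ct_hbo2_map, ct_hb_map = ct_hb_map, musp_map = musp_map,
    vessel_mask = vessel_mask, offset_map = offset_map,
    scattering_power = scattering_power,
    wavelengths_nm = as.numeric(wavelengths_nm),
    pulse_amplitude = pulse_amplitude, seed = as.integer(seed)
  ), class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf(
    "<scene_truth> %dx%d px, %.0f s '%s' timeline, %d wavelengths, seed %d\n",
    x$shape[1], x$shape[2], x$program$duration_s, x$program$timeline,
    length(x$wavelengths_nm), x$seed))
  invisible(x)
}

# temporal interpolators over the fine physiology grid
scene_interp <- function(scene) {
  cc <- scene$courses
  list(
    hbo2 = stats::approxfun(cc$time_s, cc$ct_hbo2 / scene$program$baseline$ct_hbo2,
                            rule = 2),
    hb = stats::approxfun(cc$time_s, cc$ct_hb / scene$program$baseline$ct_hb,
                          rule = 2),
    musp_pct = stats::approxfun(cc$time_s, cc$pct_musp, rule = 2)
  )
}

# per-pixel musp factor at time t, honoring the onset stagger: post-onset the
# pixel's trajectory is delayed by its offset, never rewound before the onset
scene_musp_factor <- function(scene, interp, t) {
  t_on <- event_time(scene$program$events, "asphyxia_onset")
  t_eff <- if (t <= t_on) matrix(t, scene$shape[1], scene$shape[2])
  else pmax(t_on, t - scene$offset_map)
  1 + matrix(interp$musp_pct(t_eff), scene$shape[1], scene$shape[2]) / 100
}

scene_musp_scale <- function(scene, wavelength_nm) {
  (wavelength_nm / 655)^(-scene$scattering_power)
}

# per-pixel optical properties of the scene at one wavelength and time
scene_props_at <- function(scene, interp, eps_row, wavelength_nm, t) {
  mua <- EXTINCTION_TO_MUA_MM_PER_UM *
    (eps_row$eps_hbo2 * scene$ct_hbo2_map * interp$hbo2(t) +
       eps_row$eps_hb * scene$ct_hb_map * interp$hb(t))
  musp <- scene$musp_map * scene_musp_scale(scene, wavelength_nm) *
    scene_musp_factor(scene, interp, t)
  list(mua = mua, musp = musp, n = 1.4)
}

# Precompute the per-frame rendering plan for one cycle: wavelength,
# extinction row, pattern spec. Avoids rebuilding tag tables in the hot loop.
cycle_plan <- function(config, eps) {
  seq_tbl <- build_sequence(config)
  lapply(seq_len(nrow(seq_tbl)), function(k) {
    wl <- seq_tbl$wavelength_nm[k]
    i <- which(eps$wavelength_nm == wl)
    list(
      wavelength_nm = wl,
      eps_row = list(eps_hbo2 = eps$eps_hbo2[i], eps_hb = eps$eps_hb[i]),
      spec = if (seq_tbl$waveform[k] == "dc") pattern_spec(0, 360, "dc")
      else pattern_spec(seq_tbl$fx[k], seq_tbl$phase_deg[k], "square")
    )
  })
}

render_cycle_frames <- function(scene, config, interp, plan, t0, source_power,
                                noise, prop_bounds, quantize = TRUE) {
  fpc <- length(plan)
  frames <- array(0, dim = c(fpc, scene$shape[1], scene$shape[2]))
  for (k in seq_len(fpc)) {
    t_frame <- t0 + (k - 1) / config$camera_rate_hz
    pk <- plan[[k]]
    props <- scene_props_at(scene, interp, pk$eps_row, pk$wavelength_nm, t_frame)
    if (!is.null(prop_bounds)) {
      if (min(props$mua) < prop_bounds$mua[1] || max(props$mua) > prop_bounds$mua[2] ||
          min(props$musp) < prop_bounds$musp[1] || max(props$musp) > prop_bounds$musp[2]) {
        stop(sprintf("optical properties outside inversion bounds at t = %.3f s",
                     t_frame), call. = FALSE)
      }
    }
    img <- render_tissue_image(props, pk$spec, source_power,
                               config$pixel_pitch_mm, noise = noise)
    frames[k, , ] <- if (quantize) quantize_counts(img) else pmax(img, 0)
  }
  frames
}

#' Render a phantom calibration stack
#'
#' Homogeneous tissue-simulating phantom of known optical properties, imaged
#' with the identical acquisition sequence; several cycles so the reference
#' can be mean-combined.
#'
#' @param config An [acq_config()].
#' @param props_per_wl Named list (by `wl<nm>`) of [optical_props()]; a single
#'   `optical_props` is recycled across wavelengths.
#' @param n_cycles Cycles to record.
#' @param source_power,noise,seed Rendering controls (match the tissue run).
#' @return A [frame_stack()].
#' @export
render_phantom_stack <- function(config, props_per_wl = optical_props(0.01, 1.0),
                                 n_cycles = 8, source_power = 1e5,
                                 noise = noise_model(), seed = 2L) {
  if (inherits(props_per_wl, "optical_props")) {
    props_per_wl <- setNames(
      rep(list(props_per_wl), length(config$wavelengths_nm)),
      paste0("wl", config$wavelengths_nm))
  }
  set.seed(seed)
  fpc <- frames_per_cycle(config)
  seq_tbl <- build_sequence(config)
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  frames <- array(0, dim = c(n_cycles * fpc, nr, nc))
  for (cyc in seq_len(n_cycles)) {
    for (k in seq_len(fpc)) {
      pr <- props_per_wl[[paste0("wl", seq_tbl$wavelength_nm[k])]]
      maps <- list(mua = matrix(pr$mua, nr, nc),
                   musp = matrix(pr$musp, nr, nc), n = pr$n)
      spec <- if (seq_tbl$waveform[k] == "dc") pattern_spec(0, 360, "dc")
      else pattern_spec(seq_tbl$fx[k], seq_tbl$phase_deg[k], "square")
      frames[(cyc - 1) * fpc + k, , ] <- quantize_counts(
        render_tissue_image(maps, spec, source_power, config$pixel_pitch_mm,
                            noise = noise))
    }
  }
  st <- frame_stack(frames, config)
  attr(st, "props_per_wl") <- props_per_wl
  st
}

#' Render a full synthetic experiment to a raw frame stack
#'
#' Embodies the acquisition model in reverse: for every reconstruction cycle
#' and wavelength, the per-pixel absorption map is composed from the scene's
#' chromophore maps via Beer-Lambert, and the four frames (planar + three
#' phases) are rendered at their true per-frame timestamps (frames within a
#' cycle advance by one camera period, so fast pulsatile signals see the
#' intra-cycle time skew of the real instrument). Also returns the phantom
#' reference stack and the arterial-pressure validation trace.
#'
#' @param scene A [scene_truth()].
#' @param config An [acq_config()] (wavelengths must match the scene).
#' @param n_cycles Number of cycles to render (default: the whole program).
#' @param t_start_s Start time of the first cycle.
#' @param source_power Incident power scale, counts.
#' @param noise A [noise_model()] or `NULL`.
#' @param seed Integer seed for noise and the arterial trace.
#' @param table Extinction table used for the Beer-Lambert composition.
#' @param phantom_props [optical_props()] of the phantom.
#' @param prop_bounds Optional list `mua = c(lo, hi), musp = c(lo, hi)`;
#'   rendering errors (naming the timestamp) if the scene leaves it.
#' @return List: `stack` (tissue [frame_stack()]), `phantom` (stack with known
#'   properties attached), `arterial` (pressure trace tibble), `scene`.
#' @export
render_experiment <- function(scene, config, n_cycles = NULL, t_start_s = 0,
                              source_power = 1e5, noise = noise_model(),
                              seed = 3L, table = extinction_table(),
                              phantom_props = optical_props(0.01, 1.0),
                              prop_bounds = NULL) {
  stopifnot(inherits(scene, "scene_truth"), inherits(config, "acq_config"),
            isTRUE(all.equal(sort(scene$wavelengths_nm),
                             sort(config$wavelengths_nm))))
  fpc <- frames_per_cycle(config)
  cycle_period <- fpc / config$camera_rate_hz
  if (is.null(n_cycles)) {
    n_cycles <- floor((scene$program$duration_s - t_start_s) / cycle_period)
  }
  eps <- extinction_at(table, config$wavelengths_nm)
  plan <- cycle_plan(config, eps)
  interp <- scene_interp(scene)
  set.seed(seed)
  frames <- array(0, dim = c(n_cycles * fpc, scene$shape[1], scene$shape[2]))
  for (cyc in seq_len(n_cycles)) {
    t0 <- t_start_s + (cyc - 1) * cycle_period
    frames[((cyc - 1) * fpc + 1):(cyc * fpc), , ] <-
      render_cycle_frames(scene, config, interp, plan, t0, source_power, noise,
                          prop_bounds)
  }
  stack <- frame_stack(frames, config, t0_s = t_start_s)
  phantom <- render_phantom_stack(config, phantom_props,
                                  source_power = source_power, noise = noise,
                                  seed = seed + 1L)
  arterial <- arterial_trace(scene, seed = seed + 2L)
  list(stack = stack, phantom = phantom, arterial = arterial, scene = scene)
}

#' Synthetic arterial-pressure trace
#'
#' Asymmetric pulse waveform (fast systolic rise, exponential decay with a
#' dicrotic bump) at the programmed instantaneous heart rate, gated to zero
#' pulse pressure during arrest, with additive measurement noise. Serves as
#' the invasive validation reference for optical heart-rate extraction.
#'
#' @param scene A [scene_truth()] (or anything with `$courses`).
#' @param fs_hz Sampling rate of the pressure channel.
#' @param mean_mmhg,pulse_mmhg Mean and pulse pressure scales.
#' @param noise_mmhg Additive Gaussian noise sd.
#' @param seed Integer seed.
#' @return Tibble `time_s`, `pressure_mmhg`, `hr_true_bpm`.
#' @export
arterial_trace <- function(scene, fs_hz = 100, mean_mmhg = 80, pulse_mmhg = 40,
                           noise_mmhg = 0.5, seed = 4L) {
  set.seed(seed)
  cc <- scene$courses
  times <- seq(0, max(cc$time_s), by = 1 / fs_hz)
  hr <- approx(cc$time_s, cc$hr_bpm, times, rule = 2)$y
  gate <- approx(cc$time_s, cc$pulse_amp, times, rule = 2)$y
  phase <- (cumsum(hr / 60) / fs_hz) %% 1
  shape <- exp(-((phase - 0.15) / 0.06)^2) + 0.35 * exp(-((phase - 0.45) / 0.1)^2)
  tibble::tibble(
    time_s = times,
    pressure_mmhg = mean_mmhg + pulse_mmhg * gate * shape +
      rnorm(length(times), sd = noise_mmhg),
    hr_true_bpm = hr
  )
}

#' Reference heart rate from an arterial-pressure trace
#'
#' Systolic peak detection (local maxima above a pulse-pressure threshold,
#' with a refractory interval so the dicrotic bump is not double-counted)
#' followed by inter-beat-interval conversion; windows with too few beats
#' return `NA`. Kept deliberately simple: it is only the validation reference.
#'
#' @param arterial Tibble from [arterial_trace()].
#' @param window_s Averaging window for reported rates.
#' @param min_ibi_s Refractory interval: peaks closer than this to the
#'   previous accepted beat are discarded (default 0.1 s, i.e. 600 bpm).
#' @return Tibble `t_center_s`, `hr_bpm`.
#' @export
reference_hr <- function(arterial, window_s = 10, min_ibi_s = 0.1) {
  p <- arterial$pressure_mmhg
  t <- arterial$time_s
  thr <- median(p) + 0.5 * (max(p) - median(p))
  is_peak <- c(FALSE, diff(sign(diff(p))) == -2, FALSE) & p > thr
  tp <- t[is_peak]
  if (length(tp) > 1) {
    kept <- tp[1]
    for (tk in tp[-1]) {
      if (tk - kept[length(kept)] >= min_ibi_s) kept <- c(kept, tk)
    }
    tp <- kept
  }
  centers <- seq(window_s / 2, max(t) - window_s / 2, by = window_s / 2)
  purrr::map_dfr(centers, function(tc) {
    beats <- tp[tp >= tc - window_s / 2 & tp <= tc + window_s / 2]
    hr <- if (length(beats) >= 4) 60 / mean(diff(beats)) else NA_real_
    tibble::tibble(t_center_s = tc, hr_bpm = hr)
  })
}

#' Truth-side ROI series of a scene
#'
#' ROI-mean ground-truth trajectories on the reconstruction time grid, the
#' oracle that pipeline-recovered ROI series are compared against.
#'
#' @param scene A [scene_truth()].
#' @param roi Logical ROI matrix.
#' @param times_s Reconstruction timestamps.
#' @return Long tibble `time_s`, `quantity` (ct_hbo2, ct_hb, sto2, musp),
#'   `mean`.
#' @export
truth_roi_series <- function(scene, roi, times_s) {
  interp <- scene_interp(scene)
  px <- which(roi)
  baseO <- scene$ct_hbo2_map[px]; baseH <- scene$ct_hb_map[px]
  baseS <- scene$musp_map[px]
  off <- scene$offset_map[px]
  t_on <- event_time(scene$program$events, "asphyxia_onset")
  purrr::map_dfr(times_s, function(t) {
    cO <- baseO * interp$hbo2(t)
    cH <- baseH * interp$hb(t)
    t_eff <- if (t <= t_on) rep(t, length(px)) else pmax(t_on, t - off)
    ms <- baseS * (1 + interp$musp_pct(t_eff) / 100)
    tibble::tibble(
      time_s = t,
      quantity = c("ct_hbo2", "ct_hb", "sto2", "musp"),
      mean = c(mean(cO), mean(cH), mean(cO / (cO + cH)), mean(ms))
    )
  })
}
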