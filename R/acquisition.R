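#' Projection pattern specification
#'
#' Describes one structured-illumination pattern: its spatial frequency,
#' spatial phase and waveform. The rapid acquisition scheme interleaves one
#' unmodulated ("dc") frame with three binary square-wave frames whose phases
#' step by 120 degrees; a sinusoid waveform is provided for comparison studies.
#'
#' @param spatial_frequency Spatial frequency fx in cycles/mm (>= 0; must be 0
#'   for `waveform = "dc"`).
#' @param phase_deg Spatial phase in degrees, in (0, 360]. 360 is equivalent to
#'   0 modulo a full turn and is the convention used for the third phase frame.
#' @param waveform One of `"square"`, `"sinusoid"`, `"dc"`.
#' @param orientation Axis along which the pattern varies: `"x"` (varies along
#'   image columns, the default stripe geometry) or `"y"`.
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(spatial_frequency, phase_deg = 360,
                         waveform = c("square", "sinusoid", "dc"),
                         orientation = c("x", "y")) {
  waveform <- match.arg(waveform)
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(spatial_frequency), length(spatial_frequency) == 1L)
  if (spatial_frequency < 0) {
    stop("spatial_frequency must be >= 0", call. = FALSE)
  }
  if (waveform == "dc" && spatial_frequency != 0) {
    stop("dc waveform requires spatial_frequency = 0", call. = FALSE)
  }
  if (waveform != "dc" && spatial_frequency == 0) {
    stop("square/sinusoid waveforms require spatial_frequency > 0", call. = FALSE)
  }
  if (!(phase_deg > 0 && phase_deg <= 360)) {
    stop("phase_deg must lie in (0, 360]", call. = FALSE)
  }
  structure(
    list(spatial_frequency = spatial_frequency, phase_deg = phase_deg,
         waveform = waveform, orientation = orientation),
    class = "pattern_spec"
  )
}

#' Acquisition configuration
#'
#' Defines the projection/acquisition sequence of the rapid SFDI system: per
#' wavelength, one planar (fx = 0) frame followed by three phase-stepped
#' square-wave frames at the AC spatial frequency. With the defaults
#' (3 wavelengths, 3 phases) a full cycle is (1 + 3) x 3 = 12 camera frames, so
#' a 167 Hz camera reconstructs optical-property maps at 167/12 ~ 14 Hz.
#'
#' @param wavelengths_nm LED wavelengths in nm.
#' @param fx_ac AC spatial frequency in cycles/mm.
#' @param phases_deg Spatial phases in degrees (120-degree steps by default).
#' @param camera_rate_hz Overall camera frame rate in frames/s.
#' @param pixel_pitch_mm Object-plane pixel size, mm/pixel.
#' @param image_shape Image dimensions, `c(rows, cols)`.
#' @return An object of class `acq_config`.
#' @examples
#' cfg <- acq_config()
#' effective_rates(cfg)
#' @export
acq_config <- function(wavelengths_nm = c(655, 730, 850), fx_ac = 0.3,
                       phases_deg = c(120, 240, 360), camera_rate_hz = 167,
                       pixel_pitch_mm = 0.05, image_shape = c(128L, 128L)) {
  if (length(wavelengths_nm) == 0L) stop("at least one wavelength required", call. = FALSE)
  if (length(phases_deg) == 0L) stop("at least one phase required", call. = FALSE)
  stopifnot(fx_ac > 0, camera_rate_hz > 0, pixel_pitch_mm > 0,
            length(image_shape) == 2L, all(image_shape >= 1))
  structure(
    list(wavelengths_nm = as.numeric(wavelengths_nm), fx_ac = fx_ac,
         phases_deg = as.numeric(phases_deg), camera_rate_hz = camera_rate_hz,
         pixel_pitch_mm = pixel_pitch_mm, image_shape = as.integer(image_shape)),
    class = "acq_config"
  )
}

frames_per_cycle <- function(config) {
  (1L + length(config$phases_deg)) * length(config$wavelengths_nm)
}

#' Ordered projection/acquisition sequence
#'
#' Expands an [acq_config()] into the deterministic frame ordering used by the
#' instrument: for each wavelength in listed order, the planar DC frame and
#' then the three phase frames in listed phase order.
#'
#' @param config An [acq_config()].
#' @return A tibble with one row per frame in a cycle: `frame` (0-based index
#'   within the cycle), `wavelength_nm`, `waveform`, `fx`, `phase_deg`.
#' @export
build_sequence <- function(config) {
  stopifnot(inherits(config, "acq_config"))
  per_wl <- tibble::tibble(
    waveform = c("dc", rep("square", length(config$phases_deg))),
    fx = c(0, rep(config$fx_ac, length(config$phases_deg))),
    phase_deg = c(NA_real_, config$phases_deg)
  )
  seq_tbl <- purrr::map_dfr(config$wavelengths_nm, function(wl) {
    dplyr::mutate(per_wl, wavelength_nm = wl, .before = 1L)
  })
  dplyr::mutate(seq_tbl, frame = dplyr::row_number() - 1L, .before = 1L)
}

#' Acquisition timing arithmetic
#'
#' @param config An [acq_config()].
#' @return A one-row tibble: `frames_per_cycle`, `reconstruction_rate_hz`
#'   (camera rate divided by frames per cycle) and `nyquist_hr_bpm`, the
#'   heart-rate ceiling `(reconstruction_rate / 2) * 60` above which optically
#'   sampled pulsation aliases.
#' @examples
#' effective_rates(acq_config())           # ~13.9 Hz, ~417 bpm
#' effective_rates(acq_config(camera_rate_hz = 168))  # exactly 14 Hz, 420 bpm
#' @export
effective_rates <- function(config) {
  stopifnot(inherits(config, "acq_config"), config$camera_rate_hz > 0)
  fpc <- frames_per_cycle(config)
  rate <- config$camera_rate_hz / fpc
  tibble::tibble(
    frames_per_cycle = fpc,
    reconstruction_rate_hz = rate,
    nyquist_hr_bpm = rate / 2 * 60
  )
}

#' Generate an illumination pattern image
#'
#' Renders the projected pattern on the camera grid, normalized to [0, 1].
#' Square patterns are binary: 1 where `sin(2*pi*fx*x + phi) >= 0`, with
#' `x = pixel_index * pixel_pitch` along the pattern axis; sinusoids are
#' `0.5 + 0.5 * sin(...)`; the dc pattern is uniform 0.5 so that all waveforms
#' carry the same mean power.
#'
#' @param spec A [pattern_spec()].
#' @param shape Image dimensions `c(rows, cols)`.
#' @param pixel_pitch_mm mm per pixel.
#' @return A `rows x cols` numeric matrix in [0, 1].
#' @export
generate_pattern <- function(spec, shape, pixel_pitch_mm) {
  stopifnot(inherits(spec, "pattern_spec"), length(shape) == 2L,
            pixel_pitch_mm > 0)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (spec$waveform == "dc") {
    return(matrix(0.5, nr, nc))
  }
  period_px <- 1 / (spec$spatial_frequency * pixel_pitch_mm)
  if (period_px < 2) {
    stop(sprintf("pattern period (%.2f px) is below 2 pixels: aliasing", period_px),
         call. = FALSE)
  }
  n_axis <- if (spec$orientation == "x") nc else nr
  x_mm <- (seq_len(n_axis) - 1L) * pixel_pitch_mm
  carrier <- sin(2 * pi * spec$spatial_frequency * x_mm + spec$phase_deg * pi / 180)
  profile <- if (spec$waveform == "square") as.numeric(carrier >= 0) else 0.5 + 0.5 * carrier
  if (spec$orientation == "x") {
    matrix(profile, nr, nc, byrow = TRUE)
  } else {
    matrix(profile, nr, nc)
  }
}

#' Raw frame stack
#'
#' Time-ordered raw camera frames with per-frame tags. The tag table repeats
#' the acquisition sequence of `config` cyclically; frames advance by
#' `1 / camera_rate` seconds.
#'
#' @param pixels 3-D array `(frame, row, col)` of nonnegative intensities
#'   (camera counts).
#' @param config The [acq_config()] that produced the stack.
#' @param t0_s Timestamp of the first frame, seconds.
#' @return An object of class `frame_stack` with elements `pixels`, `tags`
#'   (tibble with frame-level wavelength/pattern/timestamp), `config`.
#' @export
frame_stack <- function(pixels, config, t0_s = 0) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L,
            inherits(config, "acq_config"))
  if (any(pixels < 0)) stop("frame intensities must be nonnegative", call. = FALSE)
  fpc <- frames_per_cycle(config)
  n_frames <- dim(pixels)[1]
  if (n_frames %% fpc != 0L) {
    stop(sprintf("number of frames (%d) is not a multiple of frames_per_cycle (%d)",
                 n_frames, fpc), call. = FALSE)
  }
  base <- build_sequence(config)
  n_cycles <- n_frames %/% fpc
  tags <- dplyr::bind_rows(rep(list(base), n_cycles))
  tags$frame <- seq_len(n_frames) - 1L
  tags$cycle <- rep(seq_len(n_cycles) - 1L, each = fpc)
  tags$timestamp_s <- t0_s + tags$frame / config$camera_rate_hz
  structure(list(pixels = pixels, tags = tags, config = config),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<frame_stack> %d frames of %dx%d px (%d cycles of %d), %.3g mm/px\n",
              d[1], d[2], d[3], d[1] / frames_per_cycle(x$config),
              frames_per_cycle(x$config), x$config$pixel_pitch_mm))
  invisible(x)
}
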