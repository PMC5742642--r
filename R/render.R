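#' Detector noise model
#'
#' Signal-dependent Gaussian noise with variance `read_noise^2 +
#' intensity / gain` (shot-noise approximation for an sCMOS detector).
#'
#' @param read_noise Read noise, counts RMS.
#' @param gain Conversion gain, counts per electron.
#' @return An object of class `noise_model`; `NULL` disables noise.
#' @export
noise_model <- function(read_noise = 2, gain = 0.5) {
  stopifnot(read_noise >= 0, gain > 0)
  structure(list(read_noise = read_noise, gain = gain), class = "noise_model")
}

apply_noise <- function(img, noise) {
  if (is.null(noise)) return(img)
  sdv <- sqrt(noise$read_noise^2 + pmax(img, 0) / noise$gain)
  img + matrix(rnorm(length(img), sd = sdv), nrow(img), ncol(img))
}

# Fourier decomposition of a pattern_spec into mean term + harmonics.
# Square wave taking values {0,1} where sin(theta+phi) >= 0:
#   1/2 + sum_{n odd} (2 / (n*pi)) * sin(n*(theta + phi))
# Sinusoid 0.5 + 0.5 sin(theta+phi); dc: mean 1/2 only.
# Harmonics are truncated at the pixel grid's Nyquist (period >= 2 px).
pattern_harmonics <- function(spec, pixel_pitch_mm) {
  if (spec$waveform == "dc") {
    return(list(a0 = 0.5, n = integer(0)))
  }
  n_max <- floor(1 / (2 * spec$spatial_frequency * pixel_pitch_mm))
  if (spec$waveform == "sinusoid") {
    return(list(a0 = 0.5, n = 1L, amp = 0.5))
  }
  n <- seq(1L, max(n_max, 1L), by = 2L)
  list(a0 = 0.5, n = n, amp = 2 / (n * pi))
}

#' Render a camera frame from per-pixel optical properties
#'
#' Forward-renders the diffuse image a camera would record when the pattern
#' `spec` is projected onto tissue whose per-pixel properties are given. The
#' illumination is decomposed into its Fourier harmonics; each harmonic's
#' amplitude is attenuated by the medium's spatial-frequency response
#' `Rd(n * fx)` evaluated from the local pixel properties (turbid media act as
#' spatial low-pass filters, which is why binary square-wave projection with
#' three-phase demodulation recovers the same base-frequency information as
#' sinusoidal projection); the harmonics are then resummed per pixel and
#' detector noise applied. Harmonics are truncated at the pixel grid's
#' Nyquist; the residual Gibbs ripple of the truncated series is part of the
#' rendered signal, not windowed away.
#'
#' Lateral photon crosstalk between pixels of different properties is ignored
#' (the local-MTF approximation): exact for homogeneous regions, a documented
#' simulator limitation near sharp property boundaries.
#'
#' @param prop_maps List with matrices `mua`, `musp` (mm^-1) and scalar `n`.
#' @param spec A [pattern_spec()].
#' @param source_power Incident power scale, counts.
#' @param pixel_pitch_mm mm/pixel.
#' @param noise A [noise_model()] or `NULL` for noiseless rendering.
#' @param seed Optional integer seed (set before drawing noise).
#' @param rd_fun Optional test hook: a function `fx -> Rd` (scalar or matrix
#'   matching the map shape) replacing the diffusion forward model.
#' @return Numeric matrix of rendered intensities.
#' @export
render_tissue_image <- function(prop_maps, spec, source_power = 5000,
                                pixel_pitch_mm, noise = NULL, seed = NULL,
                                rd_fun = NULL) {
  stopifnot(is.matrix(prop_maps$mua), is.matrix(prop_maps$musp),
            all(dim(prop_maps$mua) == dim(prop_maps$musp)),
            all(is.finite(prop_maps$mua)), all(is.finite(prop_maps$musp)),
            inherits(spec, "pattern_spec"))
  if (!is.null(seed)) set.seed(seed)
  nr <- nrow(prop_maps$mua); nc <- ncol(prop_maps$mua)
  harm <- pattern_harmonics(spec, pixel_pitch_mm)
  transposed <- spec$orientation == "y"
  mua <- prop_maps$mua; musp <- prop_maps$musp
  if (transposed) { mua <- t(mua); musp <- t(musp); tmp <- nr; nr <- nc; nc <- tmp }

  if (length(harm$n) > 0) {
    x_mm <- (seq_len(nc) - 1L) * pixel_pitch_mm
    theta <- 2 * pi * spec$spatial_frequency * x_mm + spec$phase_deg * pi / 180
    carriers <- t(vapply(harm$n, function(k) sin(k * theta), numeric(nc)))
    fx_h <- harm$n * spec$spatial_frequency
  } else {
    carriers <- matrix(0, 0, nc)
    fx_h <- numeric(0)
  }

  if (is.null(rd_fun)) {
    A <- internal_reflection_A(prop_maps$n %||% 1.4)
    img <- render_harmonics_cpp(as.numeric(mua), as.numeric(musp), nr, nc, A,
                                source_power, harm$a0, fx_h,
                                if (length(fx_h)) harm$amp else numeric(0),
                                carriers)
  } else {
    rd_eval <- function(f) {
      v <- rd_fun(f)
      if (length(v) == 1L) matrix(v, nr, nc) else v
    }
    img <- harm$a0 * rd_eval(0)
    for (h in seq_along(fx_h)) {
      img <- img + harm$amp[h] * rd_eval(fx_h[h]) *
        matrix(carriers[h, ], nr, nc, byrow = TRUE)
    }
    img <- source_power * img
  }
  if (transposed) img <- t(img)
  apply_noise(img, noise)
}

#' Quantize rendered intensities to camera counts
#'
#' Rounds to integers and clips to the 16-bit range of an sCMOS readout.
#'
#' @param img Numeric matrix or array.
#' @return Same shape, integer-valued doubles in [0, 65535].
#' @export
quantize_counts <- function(img) {
  pmin(pmax(round(img), 0), 65535)
}
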