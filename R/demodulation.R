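#' Three-phase amplitude demodulation
#'
#' Recovers the per-pixel AC modulation amplitude from three images of the
#' same pattern at spatial phases 120 degrees apart:
#' \deqn{M_{AC} = \frac{\sqrt{2}}{3}\sqrt{(I_1-I_2)^2 + (I_2-I_3)^2 + (I_3-I_1)^2}.}
#' For `I_k = A + B sin(theta(x) + phi_k)` with 120-degree phase steps the
#' output equals `|B|` exactly, independent of the planar offset A and of the
#' local carrier phase theta. Harmonics whose order is a multiple of 3 acquire
#' phase steps of full turns and cancel exactly — the property that lets
#' binary square-wave projection stand in for sinusoids.
#'
#' @param i1,i2,i3 2-D images of identical shape (phases in acquisition order).
#' @return Per-pixel nonnegative amplitude matrix.
#' @export
demodulate_three_phase <- function(i1, i2, i3) {
  if (!all(dim(i1) == dim(i2)) || !all(dim(i1) == dim(i3))) {
    stop("phase frames must share the same shape", call. = FALSE)
  }
  sqrt(2) / 3 * sqrt((i1 - i2)^2 + (i2 - i3)^2 + (i3 - i1)^2)
}

#' Extract the DC (planar) amplitude map
#'
#' The unmodulated frame is itself the planar measurement; this is an identity
#' pass-through with a nonnegativity contract.
#'
#' @param dc_frame 2-D image acquired with the planar (fx = 0) pattern.
#' @return The same matrix.
#' @export
extract_dc <- function(dc_frame) {
  if (any(dc_frame < 0)) stop("negative intensities in DC frame", call. = FALSE)
  dc_frame
}

#' Modulation amplitude maps for one wavelength
#'
#' @param m_dc Planar amplitude map (from [extract_dc()]).
#' @param m_ac AC modulation amplitude map (from [demodulate_three_phase()]).
#' @param wavelength_nm Wavelength, nm.
#' @param fx AC spatial frequency, cycles/mm.
#' @return An object of class `modulation_maps`.
#' @export
modulation_maps <- function(m_dc, m_ac, wavelength_nm, fx) {
  stopifnot(all(dim(m_dc) == dim(m_ac)), all(m_dc >= 0), all(m_ac >= 0))
  structure(list(m_dc = m_dc, m_ac = m_ac, wavelength_nm = wavelength_nm,
                 fx = fx), class = "modulation_maps")
}

#' Demodulate one acquisition cycle of a frame stack
#'
#' Splits a cycle into per-wavelength (DC frame, three phase frames) groups
#' and produces [modulation_maps()] for each wavelength. Multi-cycle stacks
#' are mean-combined per (wavelength, pattern) before demodulation, the
#' averaging used for phantom reference stacks.
#'
#' @param stack A [frame_stack()].
#' @param cycle Which cycle (0-based) to demodulate, or `"mean"` to average
#'   all cycles frame-position-wise first.
#' @return Named list of `modulation_maps`, one per wavelength.
#' @export
demodulate_stack <- function(stack, cycle = 0L) {
  stopifnot(inherits(stack, "frame_stack"))
  cfg <- stack$config
  fpc <- frames_per_cycle(cfg)
  n_cycles <- dim(stack$pixels)[1] %/% fpc
  frame_at <- function(pos) {  # pos: 0-based position within the cycle
    if (identical(cycle, "mean")) {
      idx <- pos + 1L + fpc * (seq_len(n_cycles) - 1L)
      m <- stack$pixels[idx[1], , , drop = TRUE]
      if (length(idx) > 1L) {
        for (i in idx[-1]) m <- m + stack$pixels[i, , , drop = TRUE]
        m <- m / length(idx)
      }
      m
    } else {
      stack$pixels[cycle * fpc + pos + 1L, , , drop = TRUE]
    }
  }
  n_ph <- length(cfg$phases_deg)
  out <- lapply(seq_along(cfg$wavelengths_nm), function(iw) {
    base <- (iw - 1L) * (1L + n_ph)
    dc <- extract_dc(frame_at(base))
    ph <- lapply(seq_len(n_ph), function(k) frame_at(base + k))
    ac <- demodulate_three_phase(ph[[1]], ph[[2]], ph[[3]])
    modulation_maps(dc, ac, cfg$wavelengths_nm[iw], cfg$fx_ac)
  })
  names(out) <- paste0("wl", cfg$wavelengths_nm)
  out
}

#' Calibrate modulation maps against a phantom reference
#'
#' Converts instrument-scale modulation amplitudes into absolute diffuse
#' reflectance by ratioing against a tissue-simulating phantom of known
#' optical properties measured with the identical sequence:
#' `rd_ac = (tissue_ac / phantom_ac) * Rd_model(phantom_props, fx)` and
#' analogously at fx = 0. The per-pixel ratio cancels source nonuniformity,
#' vignetting and detector gain. Pixels where the phantom amplitude falls
#' below `floor_frac` of its median are flagged invalid (NaN) rather than
#' divided through.
#'
#' @param tissue,phantom [modulation_maps()] at matching wavelength and fx.
#' @param phantom_props [optical_props()] of the phantom at this wavelength.
#' @param floor_frac Validity floor as a fraction of the phantom's median
#'   amplitude.
#' @return An object of class `reflectance_maps`: `rd_dc`, `rd_ac`, `valid`
#'   (logical matrix), `wavelength_nm`, `fx`.
#' @export
calibrate <- function(tissue, phantom, phantom_props, floor_frac = 0.01) {
  stopifnot(inherits(tissue, "modulation_maps"),
            inherits(phantom, "modulation_maps"))
  if (!isTRUE(all.equal(tissue$wavelength_nm, phantom$wavelength_nm)) ||
      !isTRUE(all.equal(tissue$fx, phantom$fx))) {
    stop("tissue/phantom wavelength or spatial-frequency mismatch", call. = FALSE)
  }
  ref_dc <- rd_diffusion(phantom_props, 0)
  ref_ac <- rd_diffusion(phantom_props, tissue$fx)
  med_dc <- median(phantom$m_dc)
  med_ac <- median(phantom$m_ac)
  if (med_dc <= 0 || med_ac <= 0) {
    stop("phantom amplitude below validity floor everywhere: calibration failure",
         call. = FALSE)
  }
  floor_dc <- floor_frac * med_dc
  floor_ac <- floor_frac * med_ac
  valid <- phantom$m_dc >= floor_dc & phantom$m_ac >= floor_ac
  rd_dc <- tissue$m_dc / phantom$m_dc * ref_dc
  rd_ac <- tissue$m_ac / phantom$m_ac * ref_ac
  rd_dc[!valid] <- NaN
  rd_ac[!valid] <- NaN
  structure(list(rd_dc = rd_dc, rd_ac = rd_ac, valid = valid,
                 wavelength_nm = tissue$wavelength_nm, fx = tissue$fx),
            class = "reflectance_maps")
}

#' @export
print.reflectance_maps <- function(x, ...) {
  cat(sprintf("<reflectance_maps> %g nm, fx = %g /mm, %dx%d px, %.1f%% valid\n",
              x$wavelength_nm, x$fx, nrow(x$rd_dc), ncol(x$rd_dc),
              100 * mean(x$valid)))
  invisible(x)
}

#' @rdname tidy.rapidsfdi
#' @method tidy reflectance_maps
#' @export
tidy.reflectance_maps <- function(x, ...) {
  tibble::tibble(
    row = as.integer(row(x$rd_dc)), col = as.integer(col(x$rd_dc)),
    rd_dc = as.numeric(x$rd_dc), rd_ac = as.numeric(x$rd_ac),
    valid = as.logical(x$valid),
    wavelength_nm = x$wavelength_nm, fx = x$fx
  )
}
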