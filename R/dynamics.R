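#' Event annotations for a recording
#'
#' Named experiment landmarks (seconds from recording start) consumed by the
#' phase-metric analytics: asphyxia onset, CPR start, return of spontaneous
#' circulation (ROSC), first ECoG burst, and any additional named events.
#'
#' @param ... Named scalar times in seconds, e.g. `asphyxia_onset = 300`.
#' @param span_s Optional recording span `c(t0, t1)`; events outside it error.
#' @return A tibble with columns `event`, `time_s`, class `event_annotations`.
#' @export
event_annotations <- function(..., span_s = NULL) {
  ev <- c(...)
  if (is.null(names(ev)) || any(names(ev) == "")) {
    stop("all events must be named", call. = FALSE)
  }
  if (!is.null(span_s) && (any(ev < span_s[1]) || any(ev > span_s[2]))) {
    stop("event times outside the recording span", call. = FALSE)
  }
  out <- tibble::tibble(event = names(ev), time_s = as.numeric(ev))
  class(out) <- c("event_annotations", class(out))
  out
}

event_time <- function(events, name) {
  t <- events$time_s[events$event == name]
  if (length(t) != 1L) stop(sprintf("event '%s' missing", name), call. = FALSE)
  t
}

#' ROI statistics over a sequence of maps
#'
#' Reduces per-pixel map sequences to mean and standard deviation over a
#' region of interest (the standard deviation over ROI pixels is what the
#' error bars in the downstream analytics represent).
#'
#' @param maps List of matrices (one per time point), or a 3-D array
#'   `(time, row, col)`.
#' @param time_s Time stamps, seconds (strictly increasing).
#' @param roi Logical matrix selecting ROI pixels.
#' @param quantity Label for the measured quantity.
#' @param roi_id ROI label.
#' @return Tibble `time_s`, `quantity`, `roi_id`, `mean`, `sd`, `n_valid`.
#' @export
roi_series <- function(maps, time_s, roi, quantity = "value", roi_id = "roi1") {
  if (is.array(maps) && length(dim(maps)) == 3L) {
    maps <- lapply(seq_len(dim(maps)[1]), function(i) maps[i, , , drop = TRUE])
  }
  stopifnot(length(maps) == length(time_s), is.logical(roi),
            !is.unsorted(time_s, strictly = TRUE))
  px <- which(roi)
  stats <- vapply(maps, function(m) {
    v <- m[px]
    v <- v[is.finite(v)]
    c(mean(v), sd(v), length(v))
  }, numeric(3))
  tibble::tibble(time_s = as.numeric(time_s), quantity = quantity,
                 roi_id = roi_id, mean = stats[1, ], sd = stats[2, ],
                 n_valid = as.integer(stats[3, ]))
}

#' Baseline-referenced percent change
#'
#' `100 * (x(t) - mean(x over baseline window)) / mean(x over baseline window)`.
#' The baseline is the mean over `(t0, t1]`-style closed window
#' `[baseline_window[1], baseline_window[2]]` and must precede the analyzed
#' samples; a non-positive baseline mean for these positive-definite
#' quantities is an error.
#'
#' For data frames (ROI series), the percent change of the `mean` column is
#' added as `pct`, computed per `(quantity, roi_id)` group, and the `sd`
#' column is rescaled by the same baseline.
#'
#' @param x A numeric vector (with `time_s`) or a tibble from [roi_series()].
#' @param baseline_window `c(t0, t1)`, seconds.
#' @param time_s Sample times for the vector method.
#' @param ... Passed between methods.
#' @return Same shape as the input: a vector of percent changes, or the input
#'   tibble with `pct` (and `pct_sd`) columns.
#' @export
percent_change <- function(x, baseline_window, ...) UseMethod("percent_change")

#' @rdname percent_change
#' @export
percent_change.numeric <- function(x, baseline_window, time_s, ...) {
  stopifnot(length(x) == length(time_s), length(baseline_window) == 2L,
            baseline_window[1] < baseline_window[2])
  in_win <- time_s >= baseline_window[1] & time_s <= baseline_window[2]
  if (!any(in_win)) stop("baseline window contains no samples", call. = FALSE)
  b <- mean(x[in_win])
  if (!is.finite(b) || b <= 0) {
    stop("baseline mean is not positive", call. = FALSE)
  }
  100 * (x - b) / b
}

#' @rdname percent_change
#' @export
percent_change.data.frame <- function(x, baseline_window, ...) {
  stopifnot(all(c("time_s", "mean") %in% names(x)))
  grp <- intersect(c("quantity", "roi_id"), names(x))
  x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(d, key) {
      in_win <- d$time_s >= baseline_window[1] & d$time_s <= baseline_window[2]
      if (!any(in_win)) stop("baseline window contains no samples", call. = FALSE)
      b <- mean(d$mean[in_win])
      if (!is.finite(b) || b <= 0) stop("baseline mean is not positive", call. = FALSE)
      d$pct <- 100 * (d$mean - b) / b
      if ("sd" %in% names(d)) d$pct_sd <- 100 * d$sd / b
      d
    }) |>
    dplyr::ungroup()
}

#' Mask unphysical scattering changes atop vessels
#'
#' Large apparent increases in the reduced scattering coefficient over major
#' blood vessels are artifacts of the strong vessel absorption; pixels where
#' the vessel mask is set and the percent change in musp exceeds the
#' threshold (default 10%) are marked invalid. By default the rule is
#' vessel-conditioned; `everywhere = TRUE` applies the threshold to all
#' pixels.
#'
#' @param pct_musp_map Percent-change map of musp.
#' @param vessel_mask Logical matrix of major-vessel pixels.
#' @param threshold Percent-change threshold.
#' @param everywhere Apply the rule to every pixel, not only vessels.
#' @return Logical validity matrix (`TRUE` = keep).
#' @export
mask_unphysical <- function(pct_musp_map, vessel_mask, threshold = 10,
                            everywhere = FALSE) {
  stopifnot(all(dim(pct_musp_map) == dim(vessel_mask)))
  bad <- pct_musp_map > threshold
  if (!everywhere) bad <- bad & vessel_mask
  bad[is.na(bad)] <- FALSE
  !bad
}

first_extreme <- function(values, times, window, what = c("min", "max"),
                          window_name = "window") {
  what <- match.arg(what)
  sel <- times >= window[1] & times <= window[2] & is.finite(values)
  if (!any(sel)) {
    stop(sprintf("empty search window '%s' [%g, %g] s", window_name,
                 window[1], window[2]), call. = FALSE)
  }
  v <- values[sel]; t <- times[sel]
  i <- if (what == "min") which(v == min(v))[1] else which(v == max(v))[1]
  list(value = v[i], time_s = t[i])
}

#' Phase-landmark metrics from percent-change series
#'
#' Locates the experiment's hemodynamic landmarks on the ROI percent-change
#' series and reports differences in percent change between landmark pairs,
#' with the elapsed time in minutes:
#' * ischemic minimum: earliest global StO2 minimum between `asphyxia_onset`
#'   and `cpr_start`;
#' * reperfusion peak: earliest StO2 maximum between `rosc` and `first_burst`;
#' * scattering trough/peak: earliest musp minimum in each of the two windows,
#'   and the subsequent maximum between the trough and the window end.
#'
#' Landmark search runs on the unsmoothed series with an earliest-extremum
#' tie-break. Quantities evaluated at the landmark times: `ct_hbo2`, `ct_hb`,
#' `sto2` across the three ranges (baseline to ischemic minimum, ischemic
#' minimum to reperfusion peak, reperfusion peak to first burst), and `musp`
#' trough-to-peak within the ischemia and reperfusion windows.
#'
#' @param series Tibble with columns `time_s`, `quantity`, `pct` (from
#'   [percent_change()]), containing quantities `sto2`, `ct_hbo2`, `ct_hb`,
#'   `musp`.
#' @param events An [event_annotations()] with `asphyxia_onset`, `cpr_start`,
#'   `rosc`, `first_burst`.
#' @return Tibble `period`, `quantity`, `delta_pct`, `dt_min`, `t_start_s`,
#'   `t_end_s`.
#' @export
phase_metrics <- function(series, events) {
  stopifnot(all(c("time_s", "quantity", "pct") %in% names(series)))
  t_on <- event_time(events, "asphyxia_onset")
  t_cpr <- event_time(events, "cpr_start")
  t_rosc <- event_time(events, "rosc")
  t_burst <- event_time(events, "first_burst")
  if (is.unsorted(c(t_on, t_cpr, t_rosc, t_burst))) {
    stop("events must be ordered: asphyxia_onset <= cpr_start <= rosc <= first_burst",
         call. = FALSE)
  }
  q <- function(name) {
    d <- series[series$quantity == name, ]
    if (nrow(d) == 0L) stop(sprintf("series for '%s' missing", name), call. = FALSE)
    d[order(d$time_s), ]
  }
  sto2 <- q("sto2")
  isch_min <- first_extreme(sto2$pct, sto2$time_s, c(t_on, t_cpr), "min",
                            "asphyxia_onset..cpr_start")
  rep_peak <- first_extreme(sto2$pct, sto2$time_s, c(t_rosc, t_burst), "max",
                            "rosc..first_burst")
  at_time <- function(d, t) d$pct[which.min(abs(d$time_s - t))]

  hemo <- purrr::map_dfr(c("ct_hbo2", "ct_hb", "sto2"), function(name) {
    d <- q(name)
    tibble::tibble(
      period = c("baseline_to_ischemic_min", "ischemic_min_to_reperfusion_peak",
                 "reperfusion_peak_to_first_burst"),
      quantity = name,
      delta_pct = c(at_time(d, isch_min$time_s),
                    at_time(d, rep_peak$time_s) - at_time(d, isch_min$time_s),
                    at_time(d, t_burst) - at_time(d, rep_peak$time_s)),
      dt_min = c(isch_min$time_s - t_on, rep_peak$time_s - isch_min$time_s,
                 t_burst - rep_peak$time_s) / 60,
      t_start_s = c(t_on, isch_min$time_s, rep_peak$time_s),
      t_end_s = c(isch_min$time_s, rep_peak$time_s, t_burst)
    )
  })

  musp <- q("musp")
  scatter <- purrr::map_dfr(
    list(list(name = "ischemia_trough_to_peak", win = c(t_on, t_cpr),
              label = "asphyxia_onset..cpr_start"),
         list(name = "reperfusion_trough_to_peak", win = c(t_rosc, t_burst),
              label = "rosc..first_burst")),
    function(p) {
      trough <- first_extreme(musp$pct, musp$time_s, p$win, "min", p$label)
      peak <- first_extreme(musp$pct, musp$time_s, c(trough$time_s, p$win[2]),
                            "max", paste0(p$label, " (post-trough)"))
      tibble::tibble(period = p$name, quantity = "musp",
                     delta_pct = peak$value - trough$value,
                     dt_min = (peak$time_s - trough$time_s) / 60,
                     t_start_s = trough$time_s, t_end_s = peak$time_s)
    })
  dplyr::bind_rows(hemo, scatter)
}

#' Heart rate from pulsatile intensity by windowed FFT
#'
#' Slides a Hann-tapered window along the detrended planar-intensity series,
#' takes the amplitude spectrum, and reports the peak frequency within the
#' physiologic band as beats per minute. Windows whose band peak lies within
#' the guard fraction of the Nyquist heart-rate ceiling `(fs/2)*60` bpm are
#' flagged unreliable: a true rate above the ceiling aliases into the band
#' and is indistinguishable from a genuine near-ceiling rate without an
#' external reference, so near-ceiling peaks are treated as suspect.
#'
#' @param intensity Planar (fx = 0) intensity samples at one wavelength.
#' @param fs_hz Sampling (reconstruction) rate, Hz.
#' @param window_s Sliding-window length, seconds.
#' @param overlap Fractional overlap between consecutive windows.
#' @param band_bpm Search band `c(lo, hi)` in bpm.
#' @param detrend_span_s Span of the moving mean subtracted before analysis.
#' @param alias_guard Fraction of the Nyquist ceiling above which peaks are
#'   flagged unreliable.
#' @return Tibble `t_center_s`, `hr_bpm`, `amplitude`, `reliable`, plus
#'   attributes `nyquist_bpm` and `bin_bpm`.
#' @export
heart_rate_fft <- function(intensity, fs_hz, window_s = 10, overlap = 0.5,
                           band_bpm = c(120, 420), detrend_span_s = 2,
                           alias_guard = 0.9) {
  stopifnot(fs_hz > 0, window_s > 0, overlap >= 0, overlap < 1)
  nyq_hz <- fs_hz / 2
  band_hz <- band_bpm / 60
  if (band_hz[1] >= nyq_hz) {
    stop("search band lies entirely above the Nyquist frequency", call. = FALSE)
  }
  if (window_s < 4 / band_hz[1]) {
    stop("window must span at least 4 periods of the band's low edge", call. = FALSE)
  }
  nw <- round(window_s * fs_hz)
  if (length(intensity) < nw) stop("series shorter than one window", call. = FALSE)
  span <- max(1L, round(detrend_span_s * fs_hz))
  trend <- stats::filter(intensity, rep(1 / span, span), sides = 2)
  trend[is.na(trend)] <- mean(intensity)
  x <- intensity - as.numeric(trend)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  freqs <- (seq_len(nw) - 1L) * fs_hz / nw
  in_band <- freqs >= band_hz[1] & freqs <= min(band_hz[2], nyq_hz)
  nyquist_bpm <- nyq_hz * 60
  out <- purrr::map_dfr(starts, function(s) {
    seg <- x[s:(s + nw - 1L)]
    amp <- Mod(fft((seg - mean(seg)) * hann))
    k <- which(in_band)[which.max(amp[in_band])]
    peak_bpm <- freqs[k] * 60
    edge <- k == max(which(in_band))  # band-edge peak
    tibble::tibble(
      t_center_s = (s - 1L + nw / 2) / fs_hz,
      hr_bpm = peak_bpm,
      amplitude = amp[k],
      reliable = !(edge || peak_bpm >= alias_guard * nyquist_bpm)
    )
  })
  attr(out, "nyquist_bpm") <- nyquist_bpm
  attr(out, "bin_bpm") <- fs_hz / nw * 60
  out
}

#' Agreement of optical heart rate with an arterial reference
#'
#' Coefficient of determination against the identity line:
#' `R^2 = 1 - sum((y - x)^2) / sum((y - mean(y))^2)` for time-aligned pairs
#' (x = reference, y = optical) whose reference rate is below the aliasing
#' cutoff.
#'
#' @param optical_hr,reference_hr Paired heart-rate series, bpm.
#' @param cutoff_bpm Pairs with reference at or above this are excluded
#'   (default: the 14 Hz system's 420 bpm Nyquist ceiling).
#' @return One-row tibble `r_squared`, `n_pairs`, `cutoff_bpm`.
#' @export
hr_agreement <- function(optical_hr, reference_hr, cutoff_bpm = 420) {
  stopifnot(length(optical_hr) == length(reference_hr))
  keep <- is.finite(optical_hr) & is.finite(reference_hr) &
    reference_hr < cutoff_bpm
  y <- optical_hr[keep]; x <- reference_hr[keep]
  if (length(y) < 3L) stop("fewer than 3 usable pairs", call. = FALSE)
  ss_y <- sum((y - mean(y))^2)
  if (ss_y <= 0 || sd(x) == 0) {
    stop("zero variance: agreement to y = x is undefined", call. = FALSE)
  }
  tibble::tibble(r_squared = 1 - sum((y - x)^2) / ss_y,
                 n_pairs = length(y), cutoff_bpm = cutoff_bpm)
}
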