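test_that("percent change is exact, baseline-anchored and scale-invariant", {
  t <- seq(0, 100, by = 1)
  x <- rep(5, length(t))
  expect_equal(percent_change(x, c(0, 10), time_s = t), rep(0, length(t)))
  # baseline 0.87 rising to 0.957 is +10%
  x2 <- c(rep(0.87, 50), rep(0.957, 51))
  pc <- percent_change(x2, c(0, 49), time_s = t)
  expect_equal(pc[101], 10, tolerance = 1e-12)
  # invariant to multiplying the series by any positive constant
  expect_equal(percent_change(3.7 * x2, c(0, 49), time_s = t), pc)
  expect_error(percent_change(x2, c(200, 210), time_s = t), "no samples")
  expect_error(percent_change(x2 - 1, c(0, 49), time_s = t), "positive")
})

test_that("percent change on ROI tables works per quantity and rescales the spread", {
  tbl <- tibble::tibble(
    time_s = rep(0:9, 2),
    quantity = rep(c("a", "b"), each = 10),
    roi_id = "roi1",
    mean = c(rep(2, 10), c(rep(4, 5), rep(5, 5))),
    sd = 0.2
  )
  out <- percent_change(tbl, c(0, 4))
  expect_equal(out$pct[out$quantity == "a"], rep(0, 10))
  expect_equal(out$pct[out$quantity == "b"], c(rep(0, 5), rep(25, 5)))
  expect_equal(out$pct_sd[out$quantity == "b"], rep(100 * 0.2 / 4, 10))
})

test_that("the unphysical-scattering rule masks vessel pixels above threshold only", {
  pct <- matrix(c(12, 8, 50, 12), 2, 2)
  vessels <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  keep <- mask_unphysical(pct, vessels)
  expect_false(keep[1, 1])   # vessel at +12% -> invalid
  expect_true(keep[2, 1])    # vessel at +8% -> valid
  expect_true(keep[1, 2])    # +50% off-vessel -> valid under the vessel rule
  expect_true(keep[2, 2])
  # the everywhere variant extends the threshold to all pixels
  keep_all <- mask_unphysical(pct, vessels, everywhere = TRUE)
  expect_false(keep_all[1, 2])
  expect_equal(sum(keep_all), 1)
})

make_landmark_series <- function() {
  # piecewise series with known landmarks:
  # onset 60 s, StO2 minimum at 87.6 s (-24%), CPR 150 s, ROSC 165 s,
  # reperfusion peak at 240 s (+12%), first burst 330 s (-5% at burst)
  t <- seq(0, 340, by = 1 / 14)
  seg <- approx(c(0, 60, 87.6, 150, 165, 240, 330, 340),
                c(0, 0, -24, -23, -23, 12, -5, -5), t)$y
  musp <- approx(c(0, 60, 78, 144, 165, 195, 321, 340),
                 c(0, 0, -5, 4.7, 4.5, -16.7, 4.5, 4.4), t)$y
  dplyr::bind_rows(
    tibble::tibble(time_s = t, quantity = "sto2", pct = seg),
    tibble::tibble(time_s = t, quantity = "ct_hbo2", pct = 0.8 * seg),
    tibble::tibble(time_s = t, quantity = "ct_hb", pct = -2 * seg),
    tibble::tibble(time_s = t, quantity = "musp", pct = musp)
  )
}

test_that("phase metrics locate programmed landmarks to within one sample", {
  series <- make_landmark_series()
  ev <- event_annotations(asphyxia_onset = 60, cpr_start = 150, rosc = 165,
                          first_burst = 330)
  pm <- phase_metrics(series, ev)
  get <- function(p, q) pm[pm$period == p & pm$quantity == q, ]
  m <- get("baseline_to_ischemic_min", "sto2")
  expect_equal(m$delta_pct, -24, tolerance = 0.15)
  expect_equal(m$dt_min, 27.6 / 60, tolerance = (1 / 14) / 60 * 1.5)
  m2 <- get("ischemic_min_to_reperfusion_peak", "sto2")
  expect_equal(m2$delta_pct, 36, tolerance = 0.2)
  expect_equal(m2$dt_min, (240 - 87.6) / 60, tolerance = (1 / 14) / 60 * 1.5)
  m3 <- get("reperfusion_peak_to_first_burst", "sto2")
  expect_equal(m3$delta_pct, -17, tolerance = 0.2)
  # scattering trough-to-peak in both windows
  s1 <- get("ischemia_trough_to_peak", "musp")
  expect_equal(s1$delta_pct, 9.7, tolerance = 0.2)
  expect_equal(s1$dt_min, 1.1, tolerance = 0.02)
  s2 <- get("reperfusion_trough_to_peak", "musp")
  expect_equal(s2$delta_pct, 21.2, tolerance = 0.3)
  expect_equal(s2$dt_min, 2.1, tolerance = 0.02)
  # derived quantities scale with the driving series
  expect_equal(get("baseline_to_ischemic_min", "ct_hb")$delta_pct, 48,
               tolerance = 0.3)
})

test_that("phase metrics tie-breaks, monotone windows and empty windows behave", {
  t <- seq(0, 340, by = 0.5)
  mono <- function(q, v) tibble::tibble(time_s = t, quantity = q, pct = v)
  # monotone decreasing StO2: trough at window end; monotone musp likewise
  series <- dplyr::bind_rows(
    mono("sto2", -t / 10), mono("ct_hbo2", -t / 10), mono("ct_hb", t / 10),
    mono("musp", t / 100))
  ev <- event_annotations(asphyxia_onset = 60, cpr_start = 150, rosc = 165,
                          first_burst = 330)
  pm <- phase_metrics(series, ev)
  expect_equal(pm$t_end_s[pm$period == "baseline_to_ischemic_min" &
                            pm$quantity == "sto2"], 150)
  # musp monotone increasing: trough at window start, peak at window end
  s1 <- pm[pm$period == "ischemia_trough_to_peak", ]
  expect_equal(s1$t_start_s, 60)
  expect_equal(s1$t_end_s, 150)
  # two identical minima -> earliest reported
  twin <- series
  twin$pct[twin$quantity == "sto2"] <- 0
  twin$pct[twin$quantity == "sto2"][c(150, 250)] <- -5  # t = 74.5 and 124.5
  pm2 <- phase_metrics(twin, ev)
  expect_equal(pm2$t_end_s[pm2$period == "baseline_to_ischemic_min" &
                             pm2$quantity == "sto2"], 74.5)
  # a window with no samples errors, naming the window
  short <- dplyr::filter(series, time_s < 160)
  expect_error(phase_metrics(short, ev), "rosc..first_burst", fixed = TRUE)
})

test_that("FFT heart-rate extraction hits the programmed rate within one bin", {
  fs <- 14
  t <- seq(0, 60, by = 1 / fs)
  set.seed(3)
  x <- 1000 + 10 * sin(2 * pi * 6 * t) + rnorm(length(t), sd = 2)
  hr <- heart_rate_fft(x, fs)
  expect_lt(abs(median(hr$hr_bpm) - 360), attr(hr, "bin_bpm") + 1e-9)
  expect_true(all(hr$reliable))
  expect_equal(attr(hr, "nyquist_bpm"), 420)
  # 20 seeded realizations across the physiologic band
  for (s in 1:20) {
    set.seed(s)
    true_bpm <- runif(1, 205, 415)
    x <- 1000 + 10 * sin(2 * pi * true_bpm / 60 * t) + rnorm(length(t), sd = 3)
    hr <- heart_rate_fft(x, fs)
    expect_lt(abs(median(hr$hr_bpm) - true_bpm), attr(hr, "bin_bpm") + 1e-9)
  }
})

test_that("rates beyond the Nyquist ceiling alias predictably and get flagged", {
  fs <- 14
  t <- seq(0, 60, by = 1 / fs)
  set.seed(1)
  x <- 1000 + 10 * sin(2 * pi * 7.5 * t) + rnorm(length(t), sd = 2)
  hr <- heart_rate_fft(x, fs)
  # |450 - 840| = 390 bpm alias
  expect_lt(abs(median(hr$hr_bpm) - 390), attr(hr, "bin_bpm") + 1e-9)
  expect_false(any(hr$reliable))
  expect_error(heart_rate_fft(x, fs, band_bpm = c(500, 800)), "Nyquist")
  expect_error(heart_rate_fft(x, fs, window_s = 1), "4 periods")
})

test_that("heart-rate agreement to the identity line behaves like R^2", {
  ref <- seq(300, 410, by = 10)
  expect_equal(hr_agreement(ref, ref)$r_squared, 1)
  set.seed(11)
  noisy <- ref + rnorm(length(ref), sd = 5)
  r2 <- hr_agreement(noisy, ref)
  expect_gt(r2$r_squared, 0.9)
  expect_equal(r2$n_pairs, length(ref))
  # pairs at or above the cutoff are excluded
  r2b <- hr_agreement(c(noisy, 500), c(ref, 430))
  expect_equal(r2b$n_pairs, length(ref))
  expect_error(hr_agreement(c(1, 2), c(1, 2)), "pairs")
  expect_error(hr_agreement(rep(350, 10), rep(350, 10)), "variance")
})
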