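test_that("a null program yields constant series; defaults hit the programmed minimum", {
  null_prog <- physiology_program("compressed", amplitude_scale = 0)
  phys0 <- simulate_physiology(null_prog, 1 / 14)
  expect_equal(diff(range(phys0$ct_hbo2)), 0)
  expect_equal(diff(range(phys0$musp)), 0)
  expect_equal(phys0$ct_hbo2[1], 85)
  expect_equal(phys0$ct_hb[1], 40)
  expect_equal(phys0$musp[1], 0.87)

  prog <- physiology_program("compressed")
  phys <- simulate_physiology(prog, 1 / 14)
  # StO2 minimum 0.46 min after asphyxia onset
  t_on <- prog$events$time_s[prog$events$event == "asphyxia_onset"]
  t_cpr <- prog$events$time_s[prog$events$event == "cpr_start"]
  win <- phys$time_s >= t_on & phys$time_s <= t_cpr
  t_min <- phys$time_s[win][which.min(phys$sto2[win])]
  expect_equal((t_min - t_on) / 60, 0.46, tolerance = 1.5 * (1 / 14) / 60)
  # internal consistency: StO2 equals the concentration ratio by construction
  expect_equal(phys$sto2, phys$ct_hbo2 / (phys$ct_hbo2 + phys$ct_hb))
  # the paper-structured timeline carries the same defaults at full length
  prog_full <- physiology_program("paper")
  expect_equal(prog_full$duration_s, 1440)
  expect_error(
    simulate_physiology(physiology_program(amplitude_scale = 40), 1 / 14),
    "non-positive")
  expect_error(simulate_physiology(physiology_program(), dt_s = 0.5), "dt_s")
})

test_that("pulsatility modulates ctHbO2 multiplicatively at the programmed rate", {
  prog <- physiology_program("compressed")
  phys <- simulate_physiology(prog, 1 / 167)
  same <- add_pulsatility(phys, 0)
  expect_equal(same$ct_hbo2, phys$ct_hbo2)
  mod <- add_pulsatility(phys, 0.01)
  base_win <- phys$time_s < 50
  rel <- mod$ct_hbo2[base_win] / phys$ct_hbo2[base_win]
  expect_lt(max(abs(rel - 1)), 0.0101)
  # spectral peak at the programmed 360 bpm during baseline
  fs <- 167
  seg <- rel - mean(rel)
  amp <- Mod(fft(seg * (0.5 - 0.5 * cos(2 * pi * seq_along(seg) / length(seg)))))
  freqs <- (seq_along(seg) - 1) * fs / length(seg)
  pk <- freqs[which.max(amp[freqs > 0.5 & freqs < 20])]
  expect_equal(pk * 60, 360, tolerance = fs / length(seg) * 60)
  # no pulsation while the circulation is arrested
  arrest <- phys$time_s > 80 & phys$time_s < 160
  expect_equal(mod$ct_hbo2[arrest], phys$ct_hbo2[arrest])
})

test_that("scenes are bit-reproducible for a fixed seed", {
  prog <- physiology_program("compressed")
  a <- scene_truth(prog, shape = c(16, 16), seed = 4)
  b <- scene_truth(prog, shape = c(16, 16), seed = 4)
  expect_identical(a$ct_hbo2_map, b$ct_hbo2_map)
  expect_identical(a$vessel_mask, b$vessel_mask)
  expect_identical(a$courses, b$courses)
  c2 <- scene_truth(prog, shape = c(16, 16), seed = 5)
  expect_false(identical(a$ct_hbo2_map, c2$ct_hbo2_map))

  cfg <- acq_config(wavelengths_nm = c(655, 730, 850), image_shape = c(16, 16),
                    pixel_pitch_mm = 0.1)
  r1 <- render_experiment(a, cfg, n_cycles = 2, seed = 8)
  r2 <- render_experiment(b, cfg, n_cycles = 2, seed = 8)
  expect_identical(r1$stack$pixels, r2$stack$pixels)
  expect_identical(r1$arterial$pressure_mmhg, r2$arterial$pressure_mmhg)
})

test_that("rendered experiments have the 12-frame cycle structure and sane counts", {
  prog <- physiology_program("compressed")
  scene <- scene_truth(prog, shape = c(16, 16), seed = 4)
  cfg <- acq_config(image_shape = c(16, 16), pixel_pitch_mm = 0.1)
  out <- render_experiment(scene, cfg, n_cycles = 1, seed = 8)
  expect_equal(dim(out$stack$pixels)[1], 12L)
  expect_true(all(out$stack$pixels == round(out$stack$pixels)))
  expect_true(all(out$stack$pixels >= 0 & out$stack$pixels <= 65535))
  # 60 s at an exactly 14 Hz reconstruction rate is 840 cycles = 10,080 frames
  rate14 <- effective_rates(acq_config(camera_rate_hz = 168))
  expect_equal(60 * rate14$reconstruction_rate_hz, 840)
  expect_equal(60 * rate14$reconstruction_rate_hz * rate14$frames_per_cycle, 10080)
})

test_that("the scattering-onset stagger shifts trough timing between distant ROIs", {
  prog <- physiology_program("compressed")
  scene <- scene_truth(prog, shape = c(8, 48), stagger_s = 10, seed = 4)
  times <- seq(0, prog$duration_s, by = 1 / 14)
  roi_left <- matrix(FALSE, 8, 48); roi_left[, 1:4] <- TRUE
  roi_right <- matrix(FALSE, 8, 48); roi_right[, 45:48] <- TRUE
  tr_l <- truth_roi_series(scene, roi_left, times)
  tr_r <- truth_roi_series(scene, roi_right, times)
  trough_time <- function(tr) {
    d <- tr[tr$quantity == "musp" & tr$time_s > 60 & tr$time_s < 150, ]
    d$time_s[which.min(d$mean)]
  }
  stagger_measured <- trough_time(tr_r) - trough_time(tr_l)
  offsets <- range(scene$offset_map[, c(1:4, 45:48)])
  expect_equal(stagger_measured, diff(offsets), tolerance = 3 / 14)
})

test_that("the arterial reference reproduces the programmed heart rate", {
  prog <- physiology_program("compressed")
  scene <- scene_truth(prog, shape = c(8, 8), seed = 4)
  art <- arterial_trace(scene, seed = 6)
  ref <- reference_hr(art)
  base <- ref[ref$t_center_s < 50, ]
  expect_lt(max(abs(base$hr_bpm - 360), na.rm = TRUE), 15)
  # no beats during arrest
  arrest <- ref[ref$t_center_s > 90 & ref$t_center_s < 150, ]
  expect_true(all(is.na(arrest$hr_bpm)))
})
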