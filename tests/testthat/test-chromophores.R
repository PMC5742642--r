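eps3 <- extinction_at(extinction_table(), c(655, 730, 850))

test_that("the shipped extinction table is valid and covers the device wavelengths", {
  tbl <- extinction_table()
  expect_true(all(tbl$eps_hbo2 > 0) && all(tbl$eps_hb > 0))
  expect_true(!is.unsorted(tbl$wavelength_nm, strictly = TRUE))
  expect_equal(attr(tbl, "source_id"), "prahl-omlc-hemoglobin (transcribed subset)")
  # 655 nm falls between the tabulated 650/660 rows and is flagged as
  # interpolated; 730 and 850 are exact rows
  expect_equal(eps3$interpolated, c(TRUE, FALSE, FALSE))
  expect_equal(eps3$eps_hbo2[1], (368.0 + 319.6) / 2)
  expect_error(extinction_at(tbl, 500), "span")
})

test_that("noiseless unmixing recovers the programmed concentrations exactly", {
  mua <- mua_from_chromophores(85, 40, eps3)
  maps <- lapply(mua, function(m) matrix(m, 4, 4))
  ch <- unmix(maps, c(655, 730, 850))
  expect_equal(unname(ch$ct_hbo2[1, 1]), 85, tolerance = 1e-9)
  expect_equal(unname(ch$ct_hb[1, 1]), 40, tolerance = 1e-9)
  expect_equal(unname(ch$sto2[1, 1]), 85 / 125, tolerance = 1e-12)
  expect_lt(max(ch$residual), 1e-12)
  expect_true(all(ch$valid))
  # a pure-HbO2 spectrum returns (c, 0)
  mua0 <- mua_from_chromophores(60, 0, eps3)
  ch0 <- unmix(lapply(mua0, function(m) matrix(m, 2, 2)), c(655, 730, 850))
  expect_equal(unname(ch0$ct_hbo2[1, 1]), 60, tolerance = 1e-9)
  expect_equal(unname(ch0$ct_hb[1, 1]), 0, tolerance = 1e-9)
})

test_that("unmixing reprojects exactly with two wavelengths and is scale-equivariant", {
  eps2 <- extinction_at(extinction_table(), c(655, 850))
  mua <- mua_from_chromophores(70, 30, eps2)
  maps <- lapply(mua, function(m) matrix(m, 3, 3))
  ch <- unmix(maps, c(655, 850))
  expect_lt(max(ch$residual), 1e-14)  # 2x2 system: exact reprojection
  # scaling all mua by k scales concentrations by k, StO2 unchanged
  k <- 2.5
  chk <- unmix(lapply(maps, function(m) k * m), c(655, 850))
  expect_equal(chk$ct_hbo2, k * ch$ct_hbo2)
  expect_equal(chk$ct_hb, k * ch$ct_hb)
  expect_equal(chk$sto2, ch$sto2)
})

test_that("noisy unmixing matches the closed-form error propagation", {
  set.seed(7)
  n_px <- 1e4
  mua_true <- vapply(mua_from_chromophores(85, 40, eps3), identity, numeric(1))
  Y <- sapply(mua_true, function(m) m * (1 + rnorm(n_px, sd = 0.02)))
  maps <- lapply(seq_len(3), function(i) matrix(Y[, i], 100, 100))
  ch <- unmix(maps, c(655, 730, 850))
  expect_lt(abs(mean(ch$ct_hbo2) / 85 - 1), 0.01)
  expect_lt(abs(mean(ch$ct_hb) / 40 - 1), 0.01)
  # predicted concentration sd from the pseudoinverse rows
  E <- log(10) * 1e-7 * cbind(eps3$eps_hbo2, eps3$eps_hb)
  pinv <- solve(crossprod(E), t(E))
  pred_sd <- sqrt((pinv^2) %*% (0.02 * mua_true)^2)
  expect_rel_equal(sd(ch$ct_hbo2), pred_sd[1], 0.1)
  expect_rel_equal(sd(ch$ct_hb), pred_sd[2], 0.1)
})

test_that("negative solutions are flagged unclipped unless a constrained solve is requested", {
  # a spectrum steeper than deoxyhemoglobin alone forces a negative HbO2 part
  mua <- mua_from_chromophores(-5, 45, eps3)
  maps <- lapply(mua, function(m) matrix(m, 2, 2))
  ch <- unmix(maps, c(655, 730, 850))
  expect_lt(ch$ct_hbo2[1, 1], 0)
  expect_false(any(ch$valid))
  chn <- unmix(maps, c(655, 730, 850), nonneg = TRUE)
  expect_gte(min(chn$ct_hbo2), 0)
  expect_gte(min(chn$ct_hb), 0)
  expect_true(all(chn$valid))
})

test_that("oxygen saturation handles its degenerate cases", {
  expect_equal(oxygen_saturation(85, 40), 0.68)
  expect_equal(oxygen_saturation(0, 30), 0)
  expect_equal(oxygen_saturation(30, 0), 1)
  expect_true(is.nan(oxygen_saturation(0, 0)))
  m <- oxygen_saturation(matrix(c(85, 0), 1, 2), matrix(c(40, 0), 1, 2))
  expect_equal(m[1, 1], 0.68)
  expect_true(is.nan(m[1, 2]))
})

test_that("a rank-deficient extinction system is rejected", {
  tbl <- extinction_table()
  expect_error(unmix(list(matrix(0.01, 2, 2)), 655, tbl), "2")
  # duplicated wavelength -> collinear columns are fine (rows differ), but a
  # single-row system is rank deficient for two chromophores
  expect_error(unmix(list(matrix(0.01, 2, 2), matrix(0.01, 2, 2)), c(655, 655),
                     tbl), "rank deficient")
})
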