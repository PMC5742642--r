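test_that("three-phase demodulation recovers the exact amplitude of any sinusoid triplet", {
  # across offsets, amplitudes and global phase offsets, |B| comes back at
  # machine precision, independent of A and theta
  for (theta0 in c(0, 0.7, 2.9)) {
    for (amp in c(1, 20)) {
      tri <- sinusoid_triplet(offset = 37.5, amp = amp, theta0 = theta0)
      out <- demodulate_three_phase(tri[[1]], tri[[2]], tri[[3]])
      expect_equal(max(abs(out - amp)), 0, tolerance = 1e-10)
    }
  }
  # flat frames: zero
  f <- matrix(100, 8, 8)
  expect_equal(demodulate_three_phase(f, f, f), matrix(0, 8, 8))
  # invariance to adding a constant to all three frames
  tri <- sinusoid_triplet()
  base <- demodulate_three_phase(tri[[1]], tri[[2]], tri[[3]])
  shifted <- demodulate_three_phase(tri[[1]] + 13, tri[[2]] + 13, tri[[3]] + 13)
  expect_equal(base, shifted)
  expect_error(demodulate_three_phase(matrix(0, 2, 2), matrix(0, 2, 3),
                                      matrix(0, 2, 2)), "shape")
})

test_that("DC extraction is an identity with a nonnegativity contract", {
  m <- matrix(80, 4, 4)
  expect_identical(extract_dc(m), m)
  m2 <- matrix(runif(16, 0, 100), 4, 4)
  expect_identical(extract_dc(m2), m2)
  m2[2, 2] <- -1
  expect_error(extract_dc(m2), "negative")
})

test_that("phantom calibration recovers absolute reflectance and cancels gain", {
  php <- optical_props(0.01, 1.0)
  phm <- render_homogeneous_mod(php, "square")
  # self-calibration: tissue == phantom returns the model value everywhere
  rm <- calibrate(phm, phm, php)
  expect_equal(unname(rm$rd_ac[rm$valid]),
               rep(rd_diffusion(php, 0.3), sum(rm$valid)))
  expect_equal(unname(rm$rd_dc[rm$valid]),
               rep(rd_diffusion(php, 0), sum(rm$valid)))
  # a gain applied to the tissue only scales the result; applied to both it cancels
  g <- 1.7
  tis_g <- modulation_maps(phm$m_dc * g, phm$m_ac * g, 655, 0.3)
  phm_g <- modulation_maps(phm$m_dc * g, phm$m_ac * g, 655, 0.3)
  expect_equal(calibrate(tis_g, phm, php)$rd_ac,
               g * calibrate(phm, phm, php)$rd_ac)
  expect_equal(calibrate(tis_g, phm_g, php)$rd_ac, calibrate(phm, phm, php)$rd_ac)
})

test_that("calibration cancels smooth source nonuniformity exactly", {
  php <- optical_props(0.01, 1.0)
  pp <- optical_props(0.02, 0.87)
  tis <- render_homogeneous_mod(pp, "square")
  phm <- render_homogeneous_mod(php, "square")
  vign <- outer(seq(0.7, 1, length.out = 32), seq(0.8, 1, length.out = 32))
  tis_v <- modulation_maps(tis$m_dc * vign, tis$m_ac * vign, 655, 0.3)
  phm_v <- modulation_maps(phm$m_dc * vign, phm$m_ac * vign, 655, 0.3)
  expect_equal(calibrate(tis_v, phm_v, php)$rd_ac,
               calibrate(tis, phm, php)$rd_ac, tolerance = 1e-12)
})

test_that("end-to-end calibration against the forward model is accurate to 3%", {
  php <- optical_props(0.01, 1.0)
  pp <- optical_props(0.02, 1.0)
  rm <- calibrate(render_homogeneous_mod(pp, "square"),
                  render_homogeneous_mod(php, "square"), php)
  expect_rel_equal(mean(rm$rd_ac), rd_diffusion(pp, 0.3), 0.03)
  expect_rel_equal(mean(rm$rd_dc), rd_diffusion(pp, 0), 0.03)
})

test_that("square-wave and sinusoidal projections give the same calibrated reflectance", {
  php <- optical_props(0.01, 1.0)
  pp <- optical_props(0.02, 0.87)
  # the paper-level equivalence claim, quantitative: both media satisfy
  # Rd(5 fx)/Rd(fx) < 0.25
  expect_lt(rd_diffusion(pp, 1.5) / rd_diffusion(pp, 0.3), 0.25)
  expect_lt(rd_diffusion(php, 1.5) / rd_diffusion(php, 0.3), 0.25)
  rd <- sapply(c("square", "sinusoid"), function(w) {
    rm <- calibrate(render_homogeneous_mod(pp, w),
                    render_homogeneous_mod(php, w), php)
    mean(rm$rd_ac)
  })
  expect_lt(abs(rd[["square"]] - rd[["sinusoid"]]) / rd[["sinusoid"]], 0.03)
})

test_that("calibration flags weak-phantom pixels and rejects mismatched pairs", {
  php <- optical_props(0.01, 1.0)
  phm <- render_homogeneous_mod(php, "square")
  weak <- phm
  weak$m_ac[1, 1] <- 1e-6 * median(phm$m_ac)
  rm <- calibrate(phm, weak, php)
  expect_false(rm$valid[1, 1])
  expect_true(is.nan(rm$rd_ac[1, 1]))
  expect_true(all(rm$valid[-1, ]))

  other <- modulation_maps(phm$m_dc, phm$m_ac, 730, 0.3)
  expect_error(calibrate(phm, other, php), "mismatch")
  dead <- modulation_maps(phm$m_dc * 0, phm$m_ac * 0, 655, 0.3)
  expect_error(calibrate(phm, dead, php), "calibration failure")
})
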