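test_that("lookup tables tabulate the forward model and pass build-time checks", {
  lut <- shared_lut()
  # a node is just a function evaluation
  i <- 10; j <- 20
  pr <- optical_props(lut$mua_grid[i], lut$musp_grid[j])
  expect_equal(lut$rd_dc[i, j], rd_diffusion(pr, 0))
  expect_equal(lut$rd_ac[i, j], rd_diffusion(pr, lut$fx_ac))
  # default grid over mua [0.001, 0.5] x musp [0.3, 3] builds with the
  # channel-separability invariants holding
  expect_true(all(apply(lut$rd_dc, 2, diff) < 0))
  expect_true(all(apply(lut$rd_ac, 1, diff) > 0))
  expect_error(build_lut(mua_range = c(0.5, 0.001)))
})

test_that("Monte Carlo lookup tables are reproducible for a fixed seed", {
  args <- list(fx_ac = 0.3, mua_range = c(0.005, 0.1), musp_range = c(0.6, 1.6),
               grid_sizes = c(32, 6), method = "monte_carlo",
               n_photons = 2e4, seed = 5L)
  a <- do.call(build_lut, args)
  b <- do.call(build_lut, args)
  expect_identical(a$rd_dc, b$rd_dc)
  expect_identical(a$rd_ac, b$rd_ac)
  expect_equal(a$method, "monte_carlo")
})

test_that("pixel inversion is exact at nodes and sub-0.5% on random draws", {
  lut <- shared_lut()
  # exact LUT node comes back exactly
  pr <- optical_props(lut$mua_grid[30], lut$musp_grid[40])
  s <- invert_pixel(rd_diffusion(pr, 0), rd_diffusion(pr, 0.3), lut)
  expect_equal(s$mua, pr$mua, tolerance = 1e-8)
  expect_equal(s$musp, pr$musp, tolerance = 1e-8)
  # noiseless round trip, 100 random interior draws
  set.seed(42)
  mua <- exp(runif(100, log(0.003), log(0.3)))
  musp <- runif(100, 0.4, 2.5)
  pl <- list(mua = mua, musp = musp, n = 1.4)
  sol <- rapidsfdi:::invert_rd_vec(rd_diffusion(pl, 0), rd_diffusion(pl, 0.3),
                                   lut)
  expect_true(all(is.finite(sol$mua)))
  expect_lt(max(abs(sol$mua / mua - 1)), 0.005)
  expect_lt(max(abs(sol$musp / musp - 1)), 0.005)
})

test_that("reflectance outside the table is flagged invalid, not clamped", {
  lut <- shared_lut()
  # rd_dc brighter than the lowest-absorption limit of the table
  rd_hi <- rd_diffusion(optical_props(1e-5, 1.0), 0)
  expect_gt(rd_hi, max(lut$rd_dc))
  s <- invert_pixel(rd_hi, rd_diffusion(optical_props(1e-5, 1.0), 0.3), lut)
  expect_true(is.na(s$mua) && is.na(s$musp))
  # nonsense input likewise
  expect_true(is.na(invert_pixel(0.999, 0.999, lut)$mua))
})

test_that("map inversion equals the scalar operation and propagates validity", {
  lut <- shared_lut()
  pr <- optical_props(0.02, 0.87)
  rd0 <- rd_diffusion(pr, 0); rdac <- rd_diffusion(pr, 0.3)
  rm <- structure(list(rd_dc = matrix(rd0, 8, 8), rd_ac = matrix(rdac, 8, 8),
                       valid = matrix(TRUE, 8, 8), wavelength_nm = 655,
                       fx = 0.3), class = "reflectance_maps")
  rm$valid[3, 3] <- FALSE
  rm$rd_dc[3, 3] <- NaN
  opm <- invert_maps(rm, lut)
  scalar <- invert_pixel(rd0, rdac, lut)
  expect_equal(unname(opm$mua[1, 1]), scalar$mua)
  expect_equal(unname(opm$musp[8, 8]), scalar$musp)
  expect_false(opm$valid[3, 3])
  expect_true(is.na(opm$mua[3, 3]))
  expect_equal(mean(opm$valid), 63 / 64)
  # fx mismatch is a pairing error
  rm2 <- rm; rm2$fx <- 0.2
  expect_error(invert_maps(rm2, lut), "spatial frequency")
})

test_that("noisy homogeneous inversions stay within bias 2% and spread 5%", {
  lut <- shared_lut()
  pp <- optical_props(0.02, 0.87)
  php <- optical_props(0.01, 1.0)
  tis <- render_homogeneous_mod(pp, "square", noise = noise_model(), seed = 1)
  phm <- render_homogeneous_mod(php, "square")
  opm <- invert_maps(calibrate(tis, phm, php), lut)
  expect_gt(mean(opm$valid), 0.99)
  expect_lt(abs(mean(opm$mua, na.rm = TRUE) / pp$mua - 1), 0.02)
  expect_lt(abs(mean(opm$musp, na.rm = TRUE) / pp$musp - 1), 0.02)
  expect_lt(sd(opm$mua, na.rm = TRUE) / pp$mua, 0.05)
  expect_lt(sd(opm$musp, na.rm = TRUE) / pp$musp, 0.05)
})

test_that("a two-region phantom inverts with accurate region means and a sharp edge", {
  lut <- shared_lut()
  nr <- 24; nc <- 24
  mua <- cbind(matrix(0.01, nr, nc / 2), matrix(0.03, nr, nc / 2))
  musp <- cbind(matrix(0.8, nr, nc / 2), matrix(1.2, nr, nc / 2))
  # noiseless per-pixel forward evaluation (local-MTF regime: exact per pixel)
  rd0 <- matrix(rd_diffusion(list(mua = c(mua), musp = c(musp), n = 1.4), 0),
                nr, nc)
  rdac <- matrix(rd_diffusion(list(mua = c(mua), musp = c(musp), n = 1.4), 0.3),
                 nr, nc)
  rm <- structure(list(rd_dc = rd0, rd_ac = rdac, valid = matrix(TRUE, nr, nc),
                       wavelength_nm = 655, fx = 0.3),
                  class = "reflectance_maps")
  opm <- invert_maps(rm, lut)
  expect_rel_equal(mean(opm$mua[, 1:(nc / 2)]), 0.01, 0.02)
  expect_rel_equal(mean(opm$mua[, (nc / 2 + 1):nc]), 0.03, 0.02)
  expect_rel_equal(mean(opm$musp[, 1:(nc / 2)]), 0.8, 0.02)
  # the boundary stays a boundary: transition within 2 px
  edge_profile <- opm$musp[12, ]
  expect_lt(max(abs(edge_profile[1:(nc / 2 - 1)] - 0.8)), 0.02)
  expect_lt(max(abs(edge_profile[(nc / 2 + 2):nc] - 1.2)), 0.02)
})

test_that("inverting Monte Carlo reflectance with a diffusion table gives a bounded model-mismatch error", {
  lut <- shared_lut()
  pr <- optical_props(0.02, 0.87)
  mc <- rd_monte_carlo(pr, c(0, 0.3), n_photons = 1e5, seed = 3)
  s <- invert_pixel(mc$rd[1], mc$rd[2], lut)
  expect_lt(abs(s$mua / pr$mua - 1), 0.15)
  expect_lt(abs(s$musp / pr$musp - 1), 0.15)
})

test_that("lookup tables round-trip through their JSON persistence", {
  lut <- build_lut(grid_sizes = c(8, 8))
  path <- withr::local_tempfile(fileext = ".json")
  write_lut(lut, path)
  lut2 <- read_lut(path)
  expect_equal(lut2$rd_dc, lut$rd_dc)
  expect_equal(lut2$rd_ac, lut$rd_ac)
  expect_equal(lut2$mua_grid, lut$mua_grid)
  expect_equal(lut2$fx_ac, lut$fx_ac)
  expect_equal(lut2$method, lut$method)
})
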