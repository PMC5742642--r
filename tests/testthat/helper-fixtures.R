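# Shared fixtures: everything is generated in code at test time.

fixture_pitch <- 0.1    # mm/px -> fx = 0.3 gives a 33.3 px stripe period
fixture_power <- 1e5    # counts

# Render the four-frame (dc + three phases) modulation maps of a homogeneous
# medium, optionally noisy.
render_homogeneous_mod <- function(props, waveform = "square", nr = 32,
                                   nc = 32, noise = NULL, seed = NULL,
                                   pitch = fixture_pitch,
                                   power = fixture_power) {
  maps <- list(mua = matrix(props$mua, nr, nc),
               musp = matrix(props$musp, nr, nc), n = props$n)
  if (!is.null(seed)) set.seed(seed)
  ph <- lapply(c(120, 240, 360), function(p)
    render_tissue_image(maps, pattern_spec(0.3, p, waveform), power, pitch,
                        noise = noise))
  dc <- render_tissue_image(maps, pattern_spec(0, 360, "dc"), power, pitch,
                            noise = noise)
  modulation_maps(pmax(dc, 0), demodulate_three_phase(ph[[1]], ph[[2]], ph[[3]]),
                  655, 0.3)
}

# Three-phase sinusoid triplet i_k = offset + amp * sin(theta(x) + phi_k),
# evaluated on an nr x nc pixel grid with carrier frequency fx (cycles/mm).
sinusoid_triplet <- function(offset = 50, amp = 20, fx = 0.3, nr = 16,
                             nc = 128, pitch = fixture_pitch, theta0 = 0,
                             harmonic = 1) {
  x <- (seq_len(nc) - 1) * pitch
  lapply(c(120, 240, 360), function(phi) {
    profile <- offset + amp * sin(harmonic * (2 * pi * fx * x + phi * pi / 180) +
                                    theta0)
    matrix(profile, nr, nc, byrow = TRUE)
  })
}

# Small shared LUT (64x64 default grid), built once per test run.
shared_lut <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) lut <<- build_lut()
    lut
  }
})

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
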