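#' Optical properties of a turbid medium
#'
#' @param mua Absorption coefficient, mm^-1 (> 0).
#' @param musp Reduced scattering coefficient, mm^-1 (> 0).
#' @param n Refractive index of the medium (tissue default 1.4).
#' @return An object of class `optical_props`.
#' @export
optical_props <- function(mua, musp, n = 1.4) {
  stopifnot(is.numeric(mua), is.numeric(musp), mua > 0, musp > 0, n >= 1)
  structure(list(mua = mua, musp = musp, n = n), class = "optical_props")
}

#' Internal-reflection parameter A from refractive index
#'
#' The boundary condition of the diffusion solution enters through a single
#' parameter A = (1 - Reff) / (2 * (1 + Reff)), where Reff is the effective
#' internal reflection coefficient of the tissue-air interface. Reff is
#' computed from the refractive index by the standard cubic-in-1/n polynomial
#' fit (Reff = 0.0636 n + 0.668 + 0.710/n - 1.440/n^2). This is the one frozen
#' definition used everywhere in the package.
#'
#' @param n Refractive index (>= 1). For n = 1 (matched boundary) Reff = 0 is
#'   used exactly.
#' @return Scalar A (dimensionless).
#' @export
internal_reflection_A <- function(n = 1.4) {
  stopifnot(n >= 1)
  r_eff <- if (n == 1) 0 else 0.0636 * n + 0.668 + 0.710 / n - 1.440 / n^2
  r_eff <- min(max(r_eff, 0), 1 - 1e-9)
  (1 - r_eff) / (2 * (1 + r_eff))
}

#' Diffusion-approximation diffuse reflectance in the spatial frequency domain
#'
#' Closed-form diffuse reflectance of a semi-infinite homogeneous medium under
#' spatially modulated illumination:
#' \deqn{R_d(f_x) = \frac{3 A a'}{(\mu_{eff}'/\mu_{tr} + 1)(\mu_{eff}'/\mu_{tr} + 3A)}}
#' with \eqn{\mu_{tr} = \mu_a + \mu_s'}, \eqn{a' = \mu_s'/\mu_{tr}} and
#' \eqn{\mu_{eff}' = \sqrt{3\mu_a\mu_{tr} + (2\pi f_x)^2}}. This is the fast
#' forward model used for rendering, calibration and lookup-table inversion;
#' [rd_monte_carlo()] provides the independent transport-level cross-check.
#'
#' Arguments are recycled to a common length, so per-pixel property vectors can
#' be evaluated in one call.
#'
#' @param props An [optical_props()], or a list with numeric vectors `mua`,
#'   `musp` and scalar `n`.
#' @param fx Spatial frequency (cycles/mm), scalar or vector, >= 0.
#' @return Reflectance values in (0, 1), strictly decreasing in both `fx` and
#'   `mua`.
#' @examples
#' rd_diffusion(optical_props(0.02, 0.87), fx = c(0, 0.3))
#' @export
rd_diffusion <- function(props, fx) {
  stopifnot(all(fx >= 0), all(props$mua > 0), all(props$musp > 0))
  A <- internal_reflection_A(props$n %||% 1.4)
  rd_diffusion_cpp(as.numeric(props$mua), as.numeric(props$musp),
                   as.numeric(fx), A)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' White Monte Carlo diffuse reflectance curve
#'
#' Simulates photon transport in a semi-infinite homogeneous medium:
#' Henyey-Greenstein scattering with anisotropy `g` at rate
#' `mus = musp / (1 - g)` in the near-surface zone where the reflectance is
#' sensitive to the phase function, switching to isotropic steps at the
#' transport rate `musp` below a few transport lengths (the diffusive zone,
#' where the walk is phase-function independent — similarity holds there but
#' demonstrably not near the surface at high spatial frequency). The boundary
#' is refractive-index mismatched with unpolarized Fresnel reflection; no
#' absorption occurs during transport. Each escaping photon records its exit
#' radius rho and total pathlength L; absorption is applied afterwards by
#' reweighting with `exp(-mua * L)` (the "white" Monte Carlo device, so one
#' transport run serves any `mua`). The
#' spatial-frequency response is the zeroth-order Hankel transform of the
#' radially resolved reflectance, evaluated as the per-photon sum
#' \deqn{R_d(f_x) = \frac{1}{N}\sum_i w_i J_0(2\pi f_x \rho_i),}
#' the continuum limit of \eqn{2\pi\int R(\rho)J_0(2\pi f_x\rho)\rho\,d\rho}.
#'
#' Reproducible for a fixed seed (uses R's RNG stream).
#'
#' @param props An [optical_props()].
#' @param fx_grid Spatial frequencies (cycles/mm) at which to evaluate.
#' @param n_photons Number of photons (>= 1e5 recommended for percent-level
#'   tolerances).
#' @param seed Integer seed.
#' @param g Scattering anisotropy of the near-surface transport (tissue
#'   default 0.9); `g = 0` gives a pure isotropic-equivalent walk.
#' @param z_deep_transport_lengths Depth of the fine-transport zone in units
#'   of the transport mean free path `1/musp`.
#' @param max_path_mm Pathlength cap; photons exceeding it are dropped. The
#'   induced bias is `O(exp(-mua * max_path))`, negligible for
#'   `mua >= 0.005 mm^-1` at the default.
#' @return An object of class `mtf_curve`: list with `fx_grid`, `rd`, `props`,
#'   `method = "monte_carlo"`, `n_photons`, `seed`, and the per-photon `rho`,
#'   `weight` used for the transform.
#' @export
rd_monte_carlo <- function(props, fx_grid = c(0, 0.3), n_photons = 1e5,
                           seed = 1L, g = 0.9, z_deep_transport_lengths = 4,
                           max_path_mm = 2000) {
  stopifnot(inherits(props, "optical_props") || is.list(props),
            n_photons >= 1, all(fx_grid >= 0), g >= 0, g < 1)
  set.seed(seed)
  sim <- white_mc_cpp(props$musp, g, props$n %||% 1.4, as.integer(n_photons),
                      max_path_mm, z_deep_transport_lengths / props$musp)
  w <- exp(-props$mua * sim$path)
  rd <- vapply(fx_grid, function(f) {
    v <- sum(w * besselJ(2 * pi * f * sim$rho, 0)) / sim$n_photons
    if (!is.finite(v)) stop("non-finite Hankel transform: rho grid truncated",
                            call. = FALSE)
    v
  }, numeric(1))
  structure(
    list(fx_grid = as.numeric(fx_grid), rd = rd, props = props,
         method = "monte_carlo", n_photons = as.integer(n_photons),
         seed = as.integer(seed), rho = sim$rho, weight = w,
         n_killed = sim$n_killed),
    class = "mtf_curve"
  )
}

#' MTF curve from the diffusion forward model
#'
#' @param props An [optical_props()].
#' @param fx_grid Spatial frequencies (cycles/mm).
#' @return An `mtf_curve` with `method = "diffusion"`.
#' @export
mtf_diffusion <- function(props, fx_grid = seq(0, 0.5, by = 0.02)) {
  structure(
    list(fx_grid = as.numeric(fx_grid),
         rd = rd_diffusion(props, fx_grid), props = props,
         method = "diffusion"),
    class = "mtf_curve"
  )
}

#' @export
print.mtf_curve <- function(x, ...) {
  cat(sprintf("<mtf_curve> %s, %d frequencies in [%g, %g] /mm, Rd(0) = %.4f\n",
              x$method, length(x$fx_grid), min(x$fx_grid), max(x$fx_grid),
              x$rd[which.min(x$fx_grid)]))
  invisible(x)
}

#' @rdname tidy.rapidsfdi
#' @method tidy mtf_curve
#' @export
tidy.mtf_curve <- function(x, ...) {
  tibble::tibble(fx = x$fx_grid, rd = x$rd, method = x$method,
                 mua = x$props$mua, musp = x$props$musp)
}
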