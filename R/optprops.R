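#' Build a two-frequency lookup table from the forward model
#'
#' Tabulates the forward model's diffuse reflectance at fx = 0 and at the AC
#' spatial frequency over a (mua, musp) grid. mua nodes are log-spaced (the
#' reflectance is most sensitive to absorption at low values), musp nodes
#' linear. Well-posedness of the two-frequency inversion is verified at build
#' time: the DC table must be strictly decreasing in mua along every musp row
#' (absorption sensitivity lives in the DC channel) and the AC table strictly
#' increasing in musp along every mua row (scattering sensitivity lives in the
#' AC channel). A violation signals a model or grid misconfiguration and is an
#' error, not a warning. The AC table is deliberately not required to be
#' monotone in mua: at fx well above the transport coefficient the
#' high-frequency reflectance is nearly absorption-blind, and for low musp the
#' closed form is non-monotone there — the separability of the two channels,
#' not AC-vs-mua monotonicity, is what makes the inversion well posed.
#'
#' @param fx_ac AC spatial frequency, cycles/mm (> 0).
#' @param mua_range,musp_range Grid bounds, mm^-1.
#' @param grid_sizes `c(n_mua, n_musp)`.
#' @param method `"diffusion"` (closed form) or `"monte_carlo"` (white Monte
#'   Carlo per musp node, reweighted across the mua nodes).
#' @param n Refractive index.
#' @param n_photons,seed Monte Carlo controls (ignored for diffusion).
#' @return An object of class `sfdi_lut` with `mua_grid`, `musp_grid`,
#'   `rd_dc`, `rd_ac` (matrices indexed `[mua, musp]`), `fx_ac`, `method`, `n`.
#' @examples
#' lut <- build_lut(grid_sizes = c(16, 16))
#' @export
build_lut <- function(fx_ac = 0.3, mua_range = c(0.001, 0.5),
                      musp_range = c(0.3, 3.0), grid_sizes = c(64, 64),
                      method = c("diffusion", "monte_carlo"), n = 1.4,
                      n_photons = 1e5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(fx_ac > 0, all(mua_range > 0), all(musp_range > 0),
            mua_range[2] > mua_range[1], musp_range[2] > musp_range[1],
            all(grid_sizes >= 2))
  mua_grid <- exp(seq(log(mua_range[1]), log(mua_range[2]),
                      length.out = grid_sizes[1]))
  musp_grid <- seq(musp_range[1], musp_range[2], length.out = grid_sizes[2])
  rd_dc <- matrix(NA_real_, grid_sizes[1], grid_sizes[2])
  rd_ac <- matrix(NA_real_, grid_sizes[1], grid_sizes[2])
  if (method == "diffusion") {
    for (j in seq_along(musp_grid)) {
      pr <- list(mua = mua_grid, musp = musp_grid[j], n = n)
      rd_dc[, j] <- rd_diffusion(pr, 0)
      rd_ac[, j] <- rd_diffusion(pr, fx_ac)
    }
  } else {
    set.seed(seed)
    for (j in seq_along(musp_grid)) {
      sim <- white_mc_cpp(musp_grid[j], 0.9, n, as.integer(n_photons), 2000,
                          4 / musp_grid[j])
      j0_dc <- rep(1, length(sim$rho))
      j0_ac <- besselJ(2 * pi * fx_ac * sim$rho, 0)
      for (i in seq_along(mua_grid)) {
        w <- exp(-mua_grid[i] * sim$path)
        rd_dc[i, j] <- sum(w * j0_dc) / sim$n_photons
        rd_ac[i, j] <- sum(w * j0_ac) / sim$n_photons
      }
    }
  }
  if (any(apply(rd_dc, 2, diff) >= 0)) {
    stop("DC lookup table is not strictly decreasing in mua: build error",
         call. = FALSE)
  }
  if (any(apply(rd_ac, 1, diff) <= 0)) {
    stop("AC lookup table is not strictly increasing in musp: build error",
         call. = FALSE)
  }
  structure(list(mua_grid = mua_grid, musp_grid = musp_grid, rd_dc = rd_dc,
                 rd_ac = rd_ac, fx_ac = fx_ac, method = method, n = n,
                 n_photons = if (method == "monte_carlo") as.integer(n_photons),
                 seed = if (method == "monte_carlo") as.integer(seed),
                 version = 1L),
            class = "sfdi_lut")
}

#' @export
print.sfdi_lut <- function(x, ...) {
  cat(sprintf(
    "<sfdi_lut> %s, fx_ac = %g /mm, mua [%g, %g] x musp [%g, %g] mm^-1 (%dx%d)\n",
    x$method, x$fx_ac, min(x$mua_grid), max(x$mua_grid), min(x$musp_grid),
    max(x$musp_grid), length(x$mua_grid), length(x$musp_grid)))
  invisible(x)
}

#' @rdname tidy.rapidsfdi
#' @method tidy sfdi_lut
#' @export
tidy.sfdi_lut <- function(x, ...) {
  tidyr::crossing(musp = x$musp_grid, mua = x$mua_grid) |>
    dplyr::arrange(.data$musp, .data$mua) |>
    dplyr::mutate(rd_dc = as.numeric(x$rd_dc), rd_ac = as.numeric(x$rd_ac),
                  fx_ac = x$fx_ac, method = x$method)
}

# Coarse nearest-node search on the LUT (squared relative error objective).
lut_nearest <- function(rd_dc, rd_ac, lut, stride = 4L) {
  ii <- unique(c(seq(1L, length(lut$mua_grid), by = stride), length(lut$mua_grid)))
  jj <- unique(c(seq(1L, length(lut$musp_grid), by = stride), length(lut$musp_grid)))
  tdc <- as.numeric(lut$rd_dc[ii, jj])
  tac <- as.numeric(lut$rd_ac[ii, jj])
  node_mua <- rep(lut$mua_grid[ii], times = length(jj))
  node_musp <- rep(lut$musp_grid[jj], each = length(ii))
  lut_nearest_cpp(rd_dc, rd_ac, tdc, tac, node_mua, node_musp)
}

# Bilinear interpolation of a LUT table at arbitrary (mua, musp); log-mua axis.
lut_interp <- function(lut, table, mua, musp) {
  lx <- log(lut$mua_grid)
  ix <- findInterval(log(mua), lx, all.inside = TRUE)
  iy <- findInterval(musp, lut$musp_grid, all.inside = TRUE)
  tx <- (log(mua) - lx[ix]) / (lx[ix + 1L] - lx[ix])
  ty <- (musp - lut$musp_grid[iy]) / (lut$musp_grid[iy + 1L] - lut$musp_grid[iy])
  nm <- length(lut$mua_grid)
  v00 <- table[ix + nm * (iy - 1L)]
  v10 <- table[ix + 1L + nm * (iy - 1L)]
  v01 <- table[ix + nm * iy]
  v11 <- table[ix + 1L + nm * iy]
  (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
}

invert_rd_vec <- function(rd_dc, rd_ac, lut, tol = 1e-10) {
  n <- length(rd_dc)
  mua <- rep(NA_real_, n); musp <- rep(NA_real_, n)
  usable <- is.finite(rd_dc) & is.finite(rd_ac) & rd_dc > 0 & rd_dc < 1 &
    rd_ac > 0 & rd_ac < 1
  if (any(usable)) {
    init <- lut_nearest(rd_dc[usable], rd_ac[usable], lut)
    if (lut$method == "diffusion") {
      A <- internal_reflection_A(lut$n)
      sol <- invert_rd_cpp(rd_dc[usable], rd_ac[usable], lut$fx_ac, A,
                           init$mua, init$musp, 60L, tol)
      mua[usable] <- sol$mua
      musp[usable] <- sol$musp
    } else {
      # continuous minimization on the bilinearly interpolated table
      idx <- which(usable)
      for (k in seq_along(idx)) {
        tdc <- rd_dc[idx[k]]; tac <- rd_ac[idx[k]]
        obj <- function(p) {
          m <- exp(p[1]); s <- p[2]
          ((lut_interp(lut, lut$rd_dc, m, s) - tdc) / tdc)^2 +
            ((lut_interp(lut, lut$rd_ac, m, s) - tac) / tac)^2
        }
        fit <- stats::optim(c(log(init$mua[k]), init$musp[k]), obj,
                            method = "L-BFGS-B",
                            lower = c(log(min(lut$mua_grid)), min(lut$musp_grid)),
                            upper = c(log(max(lut$mua_grid)), max(lut$musp_grid)))
        if (fit$value < 1e-4) {  # poor fit => ambiguous/out-of-model, flag
          mua[idx[k]] <- exp(fit$par[1])
          musp[idx[k]] <- fit$par[2]
        }
      }
    }
  }
  # out-of-table results are flagged invalid, not clamped
  eps <- 1e-9
  oob <- !is.na(mua) &
    (mua < min(lut$mua_grid) * (1 - eps) | mua > max(lut$mua_grid) * (1 + eps) |
       musp < min(lut$musp_grid) * (1 - eps) | musp > max(lut$musp_grid) * (1 + eps))
  mua[oob] <- NA_real_
  musp[oob] <- NA_real_
  list(mua = mua, musp = musp)
}

#' Invert one reflectance pair to optical properties
#'
#' Finds the (mua, musp) whose forward reflectances at fx = 0 and the LUT's AC
#' frequency match the measurement: a coarse lookup-table search provides the
#' starting point, followed (for the diffusion method) by damped Newton
#' refinement on the continuous closed form, or (for the Monte Carlo method)
#' by continuous minimization on the bilinearly interpolated table. Targets
#' outside the table range or without a trustworthy minimum return `NA`
#' (flagged invalid), never a silently clamped value.
#'
#' @param rd_dc,rd_ac Measured diffuse reflectances in (0, 1).
#' @param lut An [build_lut()] table.
#' @return Named list `mua`, `musp` (mm^-1; `NA` if invalid).
#' @export
invert_pixel <- function(rd_dc, rd_ac, lut) {
  stopifnot(inherits(lut, "sfdi_lut"), length(rd_dc) == 1L, length(rd_ac) == 1L)
  sol <- invert_rd_vec(rd_dc, rd_ac, lut)
  list(mua = sol$mua, musp = sol$musp)
}

#' Invert reflectance maps to per-pixel optical property maps
#'
#' Vectorized application of [invert_pixel()]: identical numerics, with
#' validity propagation from the input maps.
#'
#' @param rmaps A `reflectance_maps` object (see [calibrate()]).
#' @param lut An [build_lut()] table (must share `fx_ac` with `rmaps`).
#' @param timestamp_s Reconstruction timestamp carried through, seconds.
#' @return An object of class `optical_property_maps`: matrices `mua`, `musp`,
#'   logical `valid`, plus `wavelength_nm` and `timestamp_s`.
#' @export
invert_maps <- function(rmaps, lut, timestamp_s = NA_real_) {
  stopifnot(inherits(rmaps, "reflectance_maps"), inherits(lut, "sfdi_lut"))
  if (!isTRUE(all.equal(rmaps$fx, lut$fx_ac))) {
    stop("reflectance maps and LUT disagree on the AC spatial frequency",
         call. = FALSE)
  }
  dm <- dim(rmaps$rd_dc)
  sol <- invert_rd_vec(as.numeric(rmaps$rd_dc), as.numeric(rmaps$rd_ac), lut)
  mua <- matrix(sol$mua, dm[1], dm[2])
  musp <- matrix(sol$musp, dm[1], dm[2])
  valid <- rmaps$valid & is.finite(mua) & is.finite(musp)
  mua[!valid] <- NA_real_
  musp[!valid] <- NA_real_
  structure(list(mua = mua, musp = musp, valid = valid,
                 wavelength_nm = rmaps$wavelength_nm,
                 timestamp_s = timestamp_s),
            class = "optical_property_maps")
}

#' @export
print.optical_property_maps <- function(x, ...) {
  cat(sprintf(
    "<optical_property_maps> %g nm, %dx%d px, %.1f%% valid, median mua %.4g, musp %.3g mm^-1\n",
    x$wavelength_nm, nrow(x$mua), ncol(x$mua), 100 * mean(x$valid),
    median(x$mua, na.rm = TRUE), median(x$musp, na.rm = TRUE)))
  invisible(x)
}

#' @rdname tidy.rapidsfdi
#' @method tidy optical_property_maps
#' @export
tidy.optical_property_maps <- function(x, ...) {
  tibble::tibble(
    row = as.integer(row(x$mua)), col = as.integer(col(x$mua)),
    mua = as.numeric(x$mua), musp = as.numeric(x$musp),
    valid = as.logical(x$valid), wavelength_nm = x$wavelength_nm,
    timestamp_s = x$timestamp_s
  )
}

#' Persist / load a lookup table (JSON)
#'
#' @param lut An `sfdi_lut`.
#' @param path File path.
#' @return `read_lut` returns the `sfdi_lut`; `write_lut` returns `path`
#'   invisibly.
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "sfdi_lut"))
  obj <- lut
  obj$rd_dc <- as.numeric(lut$rd_dc)
  obj$rd_ac <- as.numeric(lut$rd_ac)
  obj$dims <- dim(lut$rd_dc)
  class(obj) <- NULL
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$rd_dc <- matrix(obj$rd_dc, obj$dims[1], obj$dims[2])
  obj$rd_ac <- matrix(obj$rd_ac, obj$dims[1], obj$dims[2])
  obj$dims <- NULL
  structure(obj, class = "sfdi_lut")
}
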