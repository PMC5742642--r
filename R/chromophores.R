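# Unit bridge, kept in exactly one place:
# mua[mm^-1] = ln(10) * eps[cm^-1/M] * c[M] / 10
#            = ln(10) * 1e-7 * eps * c[uM]
# (the ln(10) factor converts decadic extinction to a Napierian absorption
# coefficient; /10 converts cm^-1 to mm^-1; concentrations are reported in uM)
EXTINCTION_TO_MUA_MM_PER_UM <- log(10) * 1e-7

#' Load a hemoglobin extinction-coefficient table
#'
#' Reads a CSV with columns `wavelength_nm`, `eps_hbo2`, `eps_hb` (molar
#' extinction coefficients, cm^-1 M^-1). The packaged default is a transcribed
#' subset of the standard Prahl/van Assendelft compilation covering the
#' 650-900 nm window of the three-LED system.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return A tibble with attributes `source_id`.
#' @export
extinction_table <- function(path = system.file("extdata",
                                                "hb_extinction_prahl.csv",
                                                package = "rapidsfdi")) {
  tbl <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  stopifnot(all(c("wavelength_nm", "eps_hbo2", "eps_hb") %in% names(tbl)))
  if (any(tbl$eps_hbo2 <= 0) || any(tbl$eps_hb <= 0)) {
    stop("extinction coefficients must be strictly positive", call. = FALSE)
  }
  if (is.unsorted(tbl$wavelength_nm, strictly = TRUE)) {
    stop("extinction table wavelengths must be strictly increasing", call. = FALSE)
  }
  attr(tbl, "source_id") <- "prahl-omlc-hemoglobin (transcribed subset)"
  tbl
}

#' Extinction coefficients at the acquisition wavelengths
#'
#' Exact-match lookup where possible; otherwise linear interpolation, flagged
#' in the `interpolated` column.
#'
#' @param table An [extinction_table()].
#' @param wavelengths_nm Wavelengths to evaluate, nm (must lie within the
#'   table's span).
#' @return Tibble with `wavelength_nm`, `eps_hbo2`, `eps_hb`, `interpolated`.
#' @export
extinction_at <- function(table, wavelengths_nm) {
  if (any(wavelengths_nm < min(table$wavelength_nm)) ||
      any(wavelengths_nm > max(table$wavelength_nm))) {
    stop("wavelength outside the extinction table span", call. = FALSE)
  }
  tibble::tibble(
    wavelength_nm = as.numeric(wavelengths_nm),
    eps_hbo2 = approx(table$wavelength_nm, table$eps_hbo2, wavelengths_nm)$y,
    eps_hb = approx(table$wavelength_nm, table$eps_hb, wavelengths_nm)$y,
    interpolated = !(wavelengths_nm %in% table$wavelength_nm)
  )
}

#' Forward absorption spectrum from hemoglobin concentrations
#'
#' Beer-Lambert composition `mua(lambda) = 2.303 (ctHbO2 epsHbO2 + ctHb epsHb)`
#' with the unit bridge handled internally (concentrations in uM, extinction
#' in cm^-1 M^-1, mua in mm^-1). Used by the simulator and by unmixing
#' residual checks, so both directions share one definition.
#'
#' @param ct_hbo2,ct_hb Concentrations, uM (scalars, vectors or matrices).
#' @param eps Extinction rows from [extinction_at()] (one row per wavelength).
#' @return List of mua values (mm^-1), one element per wavelength, shaped like
#'   the inputs.
#' @export
mua_from_chromophores <- function(ct_hbo2, ct_hb, eps) {
  lapply(seq_len(nrow(eps)), function(i) {
    EXTINCTION_TO_MUA_MM_PER_UM *
      (eps$eps_hbo2[i] * ct_hbo2 + eps$eps_hb[i] * ct_hb)
  })
}

#' Spectral unmixing of absorption maps into hemoglobin concentrations
#'
#' Per-pixel linear least squares of the Beer-Lambert system across
#' wavelengths: with three wavelengths and two chromophores the system is
#' overdetermined and the residual map is retained as a quality channel.
#' Negative concentrations are flagged in the validity mask but reported
#' unclipped (an optional nonnegative solve is available), preserving
#' linearity and diagnosability.
#'
#' @param mua_maps Named list of mua matrices (mm^-1), one per wavelength, or
#'   a single matrix with pixels in rows and wavelengths in columns.
#' @param wavelengths_nm Wavelengths corresponding to `mua_maps` entries.
#' @param table An [extinction_table()].
#' @param nonneg If `TRUE`, re-solve flagged pixels under a nonnegativity
#'   constraint (active-set on the 2-variable problem).
#' @return Object of class `chromophore_maps`: `ct_hbo2`, `ct_hb` (uM),
#'   `sto2`, `residual` (RMS mua residual, mm^-1), `valid`.
#' @examples
#' eps <- extinction_at(extinction_table(), c(655, 730, 850))
#' mua <- mua_from_chromophores(85, 40, eps)
#' unmix(lapply(mua, function(m) matrix(m, 1, 1)), c(655, 730, 850))
#' @export
unmix <- function(mua_maps, wavelengths_nm, table = extinction_table(),
                  nonneg = FALSE) {
  stopifnot(length(mua_maps) == length(wavelengths_nm),
            length(wavelengths_nm) >= 2)
  eps <- extinction_at(table, wavelengths_nm)
  E <- EXTINCTION_TO_MUA_MM_PER_UM * cbind(eps$eps_hbo2, eps$eps_hb)
  if (qr(E)$rank < 2) {
    stop("extinction matrix is rank deficient at these wavelengths", call. = FALSE)
  }
  dm <- dim(mua_maps[[1]])
  Y <- do.call(cbind, lapply(mua_maps, as.numeric))  # pixels x wavelengths
  # least squares via the pseudoinverse of the (nwl x 2) extinction matrix
  pinv <- solve(crossprod(E), t(E))
  C <- Y %*% t(pinv)                                 # pixels x 2
  fitted <- C %*% t(E)
  residual <- sqrt(rowMeans((Y - fitted)^2))
  neg <- C[, 1] < 0 | C[, 2] < 0
  if (nonneg && any(neg, na.rm = TRUE)) {
    for (k in which(neg)) {
      c1 <- max(sum(E[, 1] * Y[k, ]) / sum(E[, 1]^2), 0)  # ctHb = 0 branch
      c2 <- max(sum(E[, 2] * Y[k, ]) / sum(E[, 2]^2), 0)  # ctHbO2 = 0 branch
      r1 <- sum((Y[k, ] - E[, 1] * c1)^2)
      r2 <- sum((Y[k, ] - E[, 2] * c2)^2)
      C[k, ] <- if (r1 <= r2) c(c1, 0) else c(0, c2)
    }
    neg <- rep(FALSE, nrow(C))
    residual <- sqrt(rowMeans((Y - C %*% t(E))^2))
  }
  valid <- apply(is.finite(Y), 1, all) & !neg
  shape <- function(v) matrix(v, dm[1], dm[2])
  ct_hbo2 <- shape(C[, 1]); ct_hb <- shape(C[, 2])
  structure(list(ct_hbo2 = ct_hbo2, ct_hb = ct_hb,
                 sto2 = oxygen_saturation(ct_hbo2, ct_hb),
                 residual = shape(residual), valid = shape(valid),
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 timestamp_s = NA_real_),
            class = "chromophore_maps")
}

#' Hemoglobin oxygen saturation map
#'
#' `StO2 = ctHbO2 / (ctHbO2 + ctHb)`, elementwise; undefined (NaN) where the
#' total hemoglobin is not positive.
#'
#' @param ct_hbo2,ct_hb Concentration maps, uM.
#' @return Matrix of saturations in [0, 1] (NaN where undefined).
#' @export
oxygen_saturation <- function(ct_hbo2, ct_hb) {
  tot <- ct_hbo2 + ct_hb
  out <- ct_hbo2 / tot
  out[!is.finite(tot) | tot <= 0] <- NaN
  out
}

#' @export
print.chromophore_maps <- function(x, ...) {
  cat(sprintf(
    "<chromophore_maps> %dx%d px, median ctHbO2 %.3g uM, ctHb %.3g uM, StO2 %.3f\n",
    nrow(x$ct_hbo2), ncol(x$ct_hbo2), median(x$ct_hbo2, na.rm = TRUE),
    median(x$ct_hb, na.rm = TRUE), median(x$sto2, na.rm = TRUE)))
  invisible(x)
}

#' @rdname tidy.rapidsfdi
#' @method tidy chromophore_maps
#' @export
tidy.chromophore_maps <- function(x, ...) {
  tibble::tibble(
    row = as.integer(row(x$ct_hbo2)), col = as.integer(col(x$ct_hbo2)),
    ct_hbo2 = as.numeric(x$ct_hbo2), ct_hb = as.numeric(x$ct_hb),
    sto2 = as.numeric(x$sto2), residual = as.numeric(x$residual),
    valid = as.logical(x$valid), timestamp_s = x$timestamp_s
  )
}
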