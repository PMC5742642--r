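#' Write / read a raw frame stack (multi-page TIFF + JSON sidecar)
#'
#' Pixels are stored as 16-bit camera counts in a multi-page TIFF; the
#' acquisition configuration and timing go to a JSON sidecar next to it.
#' The round trip is bit exact for integer-valued stacks in [0, 65535] (the
#' renderer's quantized output); non-integer intensities are rejected rather
#' than silently rounded.
#'
#' @param stack A [frame_stack()].
#' @param path TIFF path; the sidecar is `<path>.json`.
#' @return `write_frame_stack` returns `path` invisibly; `read_frame_stack`
#'   the reconstructed [frame_stack()].
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  px <- stack$pixels
  if (any(px != round(px)) || any(px < 0) || any(px > 65535)) {
    stop("frame stack must hold integer counts in [0, 65535] for 16-bit storage",
         call. = FALSE)
  }
  pages <- lapply(seq_len(dim(px)[1]), function(i) px[i, , , drop = TRUE] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  cfg <- stack$config
  sidecar <- list(
    format = "rapidsfdi-framestack", version = 1L,
    config = unclass(cfg),
    n_frames = dim(px)[1],
    t0_s = stack$tags$timestamp_s[1]
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(side$format, "rapidsfdi-framestack")) {
    stop("not a rapidsfdi frame-stack sidecar", call. = FALSE)
  }
  cf <- side$config
  cfg <- acq_config(cf$wavelengths_nm, cf$fx_ac, cf$phases_deg,
                    cf$camera_rate_hz, cf$pixel_pitch_mm, cf$image_shape)
  d <- dim(pages[[1]])
  px <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) px[i, , ] <- round(pages[[i]] * 65535)
  frame_stack(px, cfg, t0_s = side$t0_s)
}

#' Write / read calibrated reflectance maps (float TIFF + JSON sidecar)
#'
#' Two 32-bit float pages (rd_dc, rd_ac); invalid pixels are stored as NaN.
#' Float32 storage: values round-trip at single precision.
#'
#' @param rmaps A `reflectance_maps` object.
#' @param path TIFF path; sidecar is `<path>.json`.
#' @return `write_reflectance_maps` returns `path` invisibly;
#'   `read_reflectance_maps` the object.
#' @export
write_reflectance_maps <- function(rmaps, path) {
  stopifnot(inherits(rmaps, "reflectance_maps"))
  tiff::writeTIFF(list(rmaps$rd_dc, rmaps$rd_ac), path, bits.per.sample = 32L,
                  compression = "none")
  jsonlite::write_json(
    list(format = "rapidsfdi-reflectance", version = 1L,
         wavelength_nm = rmaps$wavelength_nm, fx = rmaps$fx),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_reflectance_maps
#' @export
read_reflectance_maps <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rd_dc <- pages[[1]]; rd_ac <- pages[[2]]
  structure(list(rd_dc = rd_dc, rd_ac = rd_ac,
                 valid = is.finite(rd_dc) & is.finite(rd_ac),
                 wavelength_nm = side$wavelength_nm, fx = side$fx),
            class = "reflectance_maps")
}

#' Write / read event annotations (JSON)
#'
#' @param events An [event_annotations()] tibble.
#' @param path JSON path.
#' @return `write_events` returns `path` invisibly; `read_events` the
#'   annotations.
#' @export
write_events <- function(events, path) {
  jsonlite::write_json(setNames(as.list(events$time_s), events$event), path,
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(event_annotations, as.list(ev))
}
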