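#' Pipeline configuration
#'
#' Bundles everything the processing pipeline needs beyond the raw stacks:
#' the acquisition description, lookup table, extinction table, baseline
#' window and analysis controls. Validated eagerly so failures surface before
#' any computation.
#'
#' @param acquisition An [acq_config()].
#' @param lut An [build_lut()] table (or path to one written by [write_lut()]).
#' @param extinction_path CSV path for the extinction table.
#' @param baseline_window_s `c(t0, t1)` seconds defining "baseline".
#' @param roi Logical ROI matrix (default: central 50% box).
#' @param vessel_mask Optional logical matrix for the unphysical-scattering
#'   rule.
#' @param musp_mask_threshold Percent threshold of [mask_unphysical()].
#' @param hr_band_bpm Heart-rate search band.
#' @param seed Integer seed for any stochastic stage.
#' @param output_dir Optional directory; stage outputs are persisted there.
#' @return Object of class `pipeline_config` (schema id `rapidsfdi-pipeline/1`).
#' @export
pipeline_config <- function(acquisition = acq_config(), lut = NULL,
                            extinction_path = system.file(
                              "extdata", "hb_extinction_prahl.csv",
                              package = "rapidsfdi"),
                            baseline_window_s = c(270, 288), roi = NULL,
                            vessel_mask = NULL, musp_mask_threshold = 10,
                            hr_band_bpm = c(120, 420), seed = 1L,
                            output_dir = NULL) {
  stopifnot(inherits(acquisition, "acq_config"))
  if (is.character(lut)) lut <- read_lut(lut)
  if (is.null(lut)) lut <- build_lut(fx_ac = acquisition$fx_ac)
  stopifnot(inherits(lut, "sfdi_lut"))
  if (!file.exists(extinction_path)) {
    stop(sprintf("extinction table not found: %s", extinction_path), call. = FALSE)
  }
  if (is.null(roi)) {
    nr <- acquisition$image_shape[1]; nc <- acquisition$image_shape[2]
    roi <- matrix(FALSE, nr, nc)
    roi[(nr %/% 4):(3 * nr %/% 4), (nc %/% 4):(3 * nc %/% 4)] <- TRUE
  }
  structure(list(schema = "rapidsfdi-pipeline/1", acquisition = acquisition,
                 lut = lut, extinction_path = extinction_path,
                 baseline_window_s = baseline_window_s, roi = roi,
                 vessel_mask = vessel_mask,
                 musp_mask_threshold = musp_mask_threshold,
                 hr_band_bpm = hr_band_bpm, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' Persists the scalar fields of a [pipeline_config()] (acquisition settings,
#' baseline window, thresholds, seed, LUT/extinction paths). Matrices (ROI,
#' vessel masks) and in-memory LUTs are referenced by path, not embedded:
#' `lut_path` must point to a table written with [write_lut()].
#'
#' @param config A [pipeline_config()] (for writing).
#' @param path YAML file path.
#' @param lut_path Path of the lookup table to reference (written alongside
#'   if the config holds an in-memory LUT).
#' @return `read_pipeline_config` returns a [pipeline_config()];
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path, lut_path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(lut_path)) {
    lut_path <- paste0(tools::file_path_sans_ext(path), "_lut.json")
    write_lut(config$lut, lut_path)
  }
  acq <- config$acquisition
  yaml::write_yaml(list(
    schema = config$schema,
    acquisition = list(
      wavelengths_nm = acq$wavelengths_nm, fx_ac = acq$fx_ac,
      phases_deg = acq$phases_deg, camera_rate_hz = acq$camera_rate_hz,
      pixel_pitch_mm = acq$pixel_pitch_mm, image_shape = acq$image_shape),
    lut_path = lut_path,
    extinction_path = config$extinction_path,
    baseline_window_s = config$baseline_window_s,
    musp_mask_threshold = config$musp_mask_threshold,
    hr_band_bpm = config$hr_band_bpm,
    seed = config$seed,
    output_dir = config$output_dir
  ), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!identical(y$schema, "rapidsfdi-pipeline/1")) {
    stop("unrecognized pipeline config schema", call. = FALSE)
  }
  if (!file.exists(y$lut_path)) {
    stop(sprintf("lookup table not found: %s", y$lut_path), call. = FALSE)
  }
  a <- y$acquisition
  pipeline_config(
    acquisition = acq_config(a$wavelengths_nm, a$fx_ac, a$phases_deg,
                             a$camera_rate_hz, a$pixel_pitch_mm,
                             unlist(a$image_shape)),
    lut = y$lut_path, extinction_path = y$extinction_path,
    baseline_window_s = unlist(y$baseline_window_s),
    musp_mask_threshold = y$musp_mask_threshold,
    hr_band_bpm = unlist(y$hr_band_bpm), seed = y$seed,
    output_dir = y$output_dir
  )
}

log_stage <- function(log_path, stage, ...) {
  entry <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             list(...))
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE, digits = 6)
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
  invisible(entry)
}

# demodulate one cycle's frames array (fpc x rows x cols) without any
# container construction; hot path shared by both pipeline drivers
cycle_modulation <- function(frames, config) {
  n_ph <- length(config$phases_deg)
  out <- lapply(seq_along(config$wavelengths_nm), function(iw) {
    base <- (iw - 1L) * (1L + n_ph)
    dc <- extract_dc(frames[base + 1L, , , drop = TRUE])
    ac <- demodulate_three_phase(frames[base + 2L, , , drop = TRUE],
                                 frames[base + 3L, , , drop = TRUE],
                                 frames[base + 4L, , , drop = TRUE])
    modulation_maps(dc, ac, config$wavelengths_nm[iw], config$fx_ac)
  })
  names(out) <- paste0("wl", config$wavelengths_nm)
  out
}

# demodulate + calibrate + invert + unmix one cycle; shared by the
# file-based pipeline and the streaming simulator driver
process_cycle <- function(frames, config, phantom_mod, phantom_props, lut, eps,
                          timestamp_s) {
  mods <- cycle_modulation(frames, config)
  wls <- config$wavelengths_nm
  opt <- lapply(seq_along(wls), function(iw) {
    rm <- calibrate(mods[[iw]], phantom_mod[[iw]],
                    phantom_props[[paste0("wl", wls[iw])]])
    invert_maps(rm, lut, timestamp_s = timestamp_s)
  })
  names(opt) <- paste0("wl", wls)
  mua_maps <- lapply(opt, `[[`, "mua")
  chrom <- unmix(mua_maps, wls, table = attr(eps, "full_table"))
  chrom$timestamp_s <- timestamp_s
  list(optical = opt, chrom = chrom,
       dc655 = mods[[which.min(abs(wls - 655))]]$m_dc)
}

#' Run the SFDI processing pipeline on raw stacks
#'
#' Executes the full chain demodulate -> calibrate -> invert -> unmix ->
#' dynamics on a tissue frame stack against a phantom reference stack. One
#' reconstruction per acquisition cycle, timestamped at the cycle midpoint.
#' Emits a JSON-lines structured log of per-stage timing and validity counts
#' when an output directory is configured, and persists stage outputs there.
#'
#' @param raw A [frame_stack()] or path readable by [read_frame_stack()].
#' @param phantom Phantom [frame_stack()] (or path); must carry known
#'   properties as attribute `props_per_wl`, or supply `phantom_props`.
#' @param config A [pipeline_config()].
#' @param phantom_props Named list (`wl<nm>`) of [optical_props()] overriding
#'   the stack attribute.
#' @param events Optional [event_annotations()]; enables phase metrics.
#' @return List of class `sfdi_result`: `roi_series` (long tibble with
#'   percent changes), `dc_series`, `heart_rate`, `phase_metrics` (or NULL),
#'   `chromophores` (last cycle), `optical` (last cycle), `times_s`,
#'   `validity` (per-cycle valid-pixel fraction), `config`.
#' @export
run_pipeline <- function(raw, phantom, config, phantom_props = NULL,
                         events = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(raw)) {
    if (!file.exists(raw)) stop(sprintf("raw stack not found: %s", raw), call. = FALSE)
    raw <- read_frame_stack(raw)
  }
  if (is.character(phantom)) {
    if (!file.exists(phantom)) {
      stop(sprintf("phantom stack not found: %s", phantom), call. = FALSE)
    }
    phantom <- read_frame_stack(phantom)
  }
  if (is.null(phantom_props)) phantom_props <- attr(phantom, "props_per_wl")
  if (is.null(phantom_props)) {
    stop("phantom optical properties missing (attribute or argument)", call. = FALSE)
  }
  log_path <- NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    log_path <- file.path(config$output_dir, "pipeline_log.jsonl")
  }
  acq <- raw$config
  fpc <- frames_per_cycle(acq)
  n_cycles <- dim(raw$pixels)[1] %/% fpc
  cycle_period <- fpc / acq$camera_rate_hz
  t0 <- raw$tags$timestamp_s[1]
  times <- t0 + (seq_len(n_cycles) - 1) * cycle_period + cycle_period / 2

  t_stage <- system.time(
    phantom_mod <- demodulate_stack(phantom, cycle = "mean"))["elapsed"]
  log_stage(log_path, "phantom_reference", elapsed_s = unname(t_stage))

  eps <- extinction_at(extinction_table(config$extinction_path),
                       acq$wavelengths_nm)
  attr(eps, "full_table") <- extinction_table(config$extinction_path)

  wl655 <- paste0("wl", acq$wavelengths_nm[which.min(abs(acq$wavelengths_nm - 655))])
  series_rows <- vector("list", n_cycles)
  dc_mean <- numeric(n_cycles)
  validity <- numeric(n_cycles)
  last <- NULL
  t_loop <- system.time({
    for (cyc in seq_len(n_cycles)) {
      frames_cyc <- raw$pixels[((cyc - 1) * fpc + 1):(cyc * fpc), , ,
                               drop = FALSE]
      res <- process_cycle(frames_cyc, acq, phantom_mod, phantom_props,
                           config$lut, eps, times[cyc])
      musp_map <- res$optical[[wl655]]$musp
      validity[cyc] <- mean(res$chrom$valid & res$optical[[wl655]]$valid)
      series_rows[[cyc]] <- dplyr::bind_rows(
        roi_stats_row(res$chrom$ct_hbo2, times[cyc], config$roi, "ct_hbo2"),
        roi_stats_row(res$chrom$ct_hb, times[cyc], config$roi, "ct_hb"),
        roi_stats_row(res$chrom$sto2, times[cyc], config$roi, "sto2"),
        roi_stats_row(musp_map, times[cyc], config$roi, "musp")
      )
      dc_mean[cyc] <- mean(res$dc655[config$roi], na.rm = TRUE)
      last <- res
    }
  })["elapsed"]
  log_stage(log_path, "reconstruction", elapsed_s = unname(t_loop),
            n_cycles = n_cycles, mean_valid_frac = mean(validity))

  roi_tbl <- dplyr::bind_rows(series_rows)
  pct_tbl <- tryCatch(
    percent_change(roi_tbl, config$baseline_window_s),
    error = function(e) {
      log_stage(log_path, "percent_change_skipped", reason = conditionMessage(e))
      roi_tbl
    })
  dc_series <- tibble::tibble(time_s = times, intensity = dc_mean)
  rate <- acq$camera_rate_hz / fpc
  hr <- tryCatch(
    heart_rate_fft(dc_series$intensity, fs_hz = rate,
                   band_bpm = config$hr_band_bpm),
    error = function(e) NULL)
  pm <- NULL
  if (!is.null(events) && "pct" %in% names(pct_tbl)) {
    pm <- tryCatch(phase_metrics(pct_tbl, events), error = function(e) {
      log_stage(log_path, "phase_metrics_skipped", reason = conditionMessage(e))
      NULL
    })
  }
  if (!is.null(config$output_dir)) {
    utils::write.csv(pct_tbl, file.path(config$output_dir, "roi_series.csv"),
                     row.names = FALSE)
    if (!is.null(pm)) {
      utils::write.csv(pm, file.path(config$output_dir, "phase_metrics.csv"),
                       row.names = FALSE)
    }
    log_stage(log_path, "outputs_written", dir = config$output_dir)
  }
  structure(list(roi_series = pct_tbl, dc_series = dc_series, heart_rate = hr,
                 phase_metrics = pm, chromophores = last$chrom,
                 optical = last$optical, times_s = times, validity = validity,
                 config = config),
            class = "sfdi_result")
}

roi_stats_row <- function(map, time_s, roi, quantity) {
  v <- map[roi]
  v <- v[is.finite(v)]
  tibble::tibble(time_s = time_s, quantity = quantity, roi_id = "roi1",
                 mean = mean(v), sd = sd(v), n_valid = length(v))
}

#' Streamed end-to-end synthetic experiment
#'
#' Renders a [scene_truth()] cycle by cycle and processes each cycle through
#' the full pipeline immediately (demodulate, calibrate, invert, unmix, ROI
#' reduce), so multi-minute experiments run in constant memory without
#' materializing the raw stack. Returns recovered and ground-truth ROI series
#' on the same reconstruction time grid, ready for landmark comparison.
#'
#' @param scene A [scene_truth()].
#' @param config An [acq_config()] matching the scene.
#' @param lut An [build_lut()] table.
#' @param roi Logical ROI matrix (default: central box clear of vessels).
#' @param source_power,noise,seed Rendering controls.
#' @param quantize Quantize rendered frames to 16-bit camera counts (the
#'   physical default). Disable for idealized sampling-limit studies.
#' @param phantom_props [optical_props()] of the calibration phantom.
#' @param table Extinction table.
#' @return List: `recovered` (long ROI tibble), `truth` (matching truth
#'   tibble), `dc_series`, `times_s`, `events`, `scene`.
#' @export
process_experiment <- function(scene, config, lut = build_lut(),
                               roi = NULL, source_power = 1e5,
                               noise = noise_model(), seed = 5L,
                               quantize = TRUE,
                               phantom_props = optical_props(0.01, 1.0),
                               table = extinction_table()) {
  stopifnot(inherits(scene, "scene_truth"))
  nr <- scene$shape[1]; nc <- scene$shape[2]
  if (is.null(roi)) {
    roi <- matrix(FALSE, nr, nc)
    roi[(nr %/% 4):(3 * nr %/% 4), (nc %/% 4):(3 * nc %/% 4)] <- TRUE
    roi <- roi & !scene$vessel_mask
  }
  fpc <- frames_per_cycle(config)
  cycle_period <- fpc / config$camera_rate_hz
  n_cycles <- floor(scene$program$duration_s / cycle_period)
  times <- (seq_len(n_cycles) - 1) * cycle_period + cycle_period / 2

  phantom <- render_phantom_stack(config, phantom_props,
                                  source_power = source_power, noise = noise,
                                  seed = seed + 1L)
  phantom_mod <- demodulate_stack(phantom, cycle = "mean")
  pprops <- attr(phantom, "props_per_wl")
  eps <- extinction_at(table, config$wavelengths_nm)
  attr(eps, "full_table") <- table
  interp <- scene_interp(scene)
  wl_idx <- which.min(abs(config$wavelengths_nm - 655))
  px_roi <- which(roi)

  set.seed(seed)
  series_rows <- vector("list", n_cycles)
  dc_mean <- numeric(n_cycles)
  mini <- acq_config(config$wavelengths_nm, config$fx_ac, config$phases_deg,
                     config$camera_rate_hz, config$pixel_pitch_mm,
                     c(nr, nc))
  plan <- cycle_plan(mini, eps)
  for (cyc in seq_len(n_cycles)) {
    t0 <- (cyc - 1) * cycle_period
    frames <- render_cycle_frames(scene, mini, interp, plan, t0, source_power,
                                  noise, prop_bounds = NULL,
                                  quantize = quantize)
    res <- process_cycle(frames, mini, phantom_mod, pprops, lut, eps, times[cyc])
    musp_map <- res$optical[[wl_idx]]$musp
    series_rows[[cyc]] <- dplyr::bind_rows(
      roi_stats_row(res$chrom$ct_hbo2, times[cyc], roi, "ct_hbo2"),
      roi_stats_row(res$chrom$ct_hb, times[cyc], roi, "ct_hb"),
      roi_stats_row(res$chrom$sto2, times[cyc], roi, "sto2"),
      roi_stats_row(musp_map, times[cyc], roi, "musp")
    )
    dc_mean[cyc] <- mean(res$dc655[px_roi])
  }
  list(
    recovered = dplyr::bind_rows(series_rows),
    truth = truth_roi_series(scene, roi, times),
    dc_series = tibble::tibble(time_s = times, intensity = dc_mean),
    times_s = times,
    events = scene$program$events,
    roi = roi,
    scene = scene
  )
}
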