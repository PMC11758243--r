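#' Write a frame stack to disk
#'
#' Canonical container: multi-page grayscale TIFF (8-bit when the camera
#' depth is 8 or less, 16-bit otherwise) plus a JSON sidecar
#' (`<path>.json`) holding timing, camera model and any extra metadata.
#' Raw little-endian binary is supported for large synthetic runs; raw
#' files are unreadable without their sidecar.
#'
#' @param stack A [frame_stack()].
#' @param path Output file path.
#' @param format `"tiff"` or `"raw"`.
#' @param extra Named list merged into the sidecar (e.g. simulation
#'   parameters, seed).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, format = c("tiff", "raw"), extra = list()) {
  if (!inherits(stack, "frame_stack")) stop("`stack` must be a frame_stack", call. = FALSE)
  format <- match.arg(format)
  bits <- if (stack$camera$bit_depth <= 8) 8L else 16L
  nf <- n_frames(stack)
  if (format == "tiff") {
    scale <- 2^bits - 1
    pages <- lapply(seq_len(nf), function(t) stack$frames[, , t] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
  } else {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.integer(stack$frames), con, size = bits / 8, endian = "little")
  }
  sidecar <- c(
    list(
      format = format,
      shape = dim(stack$frames),
      bits_per_sample = bits,
      frame_rate = stack$frame_rate,
      exposure_T = stack$exposure_T,
      channel_id = stack$channel_id,
      camera = unclass(stack$camera)
    ),
    extra
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a frame stack from disk
#'
#' Lossless counterpart of [write_stack()]. The JSON sidecar supplies the
#' shape, sample format and acquisition metadata; raw binary cannot be
#' read without it.
#'
#' @param path Stack file path (TIFF or raw binary).
#' @param sidecar Sidecar path; default `<path>.json`.
#' @return A [frame_stack()] with the sidecar attached as attribute
#'   `sidecar`.
#' @export
read_stack <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop(sprintf("I/O error: no such file: %s", path), call. = FALSE)
  if (!file.exists(sidecar)) {
    stop(sprintf("format error: missing sidecar for %s", path), call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  if (identical(meta$format, "raw")) {
    n <- prod(shape)
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    v <- readBin(con, "integer", n = n, size = meta$bits_per_sample / 8,
                 signed = FALSE, endian = "little")
    if (length(v) != n) stop("format error: raw file shorter than sidecar shape", call. = FALSE)
    frames <- array(v, dim = shape)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != shape[3] || !all(dim(pages[[1]]) == shape[1:2])) {
      stop("format error: TIFF shape does not match sidecar", call. = FALSE)
    }
    frames <- array(0L, dim = shape)
    for (t in seq_along(pages)) frames[, , t] <- pages[[t]]
  }
  cam <- camera_model(gain_e_per_dn = meta$camera$gain_e_per_dn,
                      read_noise_dn = meta$camera$read_noise_dn,
                      bit_depth = meta$camera$bit_depth)
  fs <- frame_stack(frames, frame_rate = meta$frame_rate,
                    exposure_T = meta$exposure_T, camera = cam,
                    channel_id = meta$channel_id)
  attr(fs, "sidecar") <- meta
  fs
}

#' Load a recording configuration
#'
#' Reads a JSON or YAML configuration describing a recording/processing
#' run: channel file paths, camera model, timing, baseline window, output
#' directory and seed. The recording duration is capped at `max_duration`
#' (default 180 s, the acquisition cap of the instrument workflow);
#' processing beyond the cap truncates with a warning.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `recording_config` list with defaults filled in.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error: no such config: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  recording_config(cfg)
}

#' @rdname read_config
#' @param cfg Named list of configuration fields.
#' @export
recording_config <- function(cfg = list()) {
  defaults <- list(
    channels = character(0),
    camera = list(gain_e_per_dn = 2, read_noise_dn = 1.5, bit_depth = 8),
    exposure_T = 6e-3,
    frame_rate = 40,
    baseline_window = c(0, 5),
    max_duration = 180,
    subject = "unknown",
    trial = 1,
    out = ".",
    seed = 1,
    signal = "cbfi",
    threshold = 0.6
  )
  cfg <- utils::modifyList(defaults, cfg)
  cfg$baseline_window <- as.numeric(unlist(cfg$baseline_window))
  if (length(cfg$baseline_window) != 2L) {
    stop("config: baseline_window must be two numbers", call. = FALSE)
  }
  stopifnot_scalar(cfg$max_duration, "max_duration", positive = TRUE)
  structure(cfg, class = "recording_config")
}

# Enforce the recording-duration cap on a stack: truncate with a warning.
cap_duration <- function(stack, max_duration) {
  nf <- n_frames(stack)
  dur <- nf / stack$frame_rate
  limit <- floor(max_duration * stack$frame_rate + 1e-9)
  if (nf > limit) {
    warning(sprintf(
      "recording of %.1f s exceeds the %.0f s cap; truncating to %d frames",
      dur, max_duration, limit), call. = FALSE)
    stack$frames <- stack$frames[, , seq_len(limit), drop = FALSE]
  }
  stack
}

#' Write per-channel and cross-channel results
#'
#' Writes the analysis outputs of a processed scene: one CSV per channel
#' (contrast terms, CBFI, mean intensity, CBVI), the labeled correlation
#' matrix CSV, the pair summary CSV, the grouping JSON and a provenance
#' sidecar (config hash, seed, package version, invalid-sample counts).
#' Outputs are deterministic: the same configuration and seed reproduce
#' byte-identical files.
#'
#' @param set A `channel_set` from [process_scene()].
#' @param outdir Output directory (created if needed).
#' @param result Optional `correlation_result`; computed from `set` when
#'   `NULL` and at least two channels are present.
#' @param threshold Grouping threshold passed to [group_channels()].
#' @param config Optional `recording_config` recorded in the provenance.
#' @param seed Seed recorded in the provenance.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(set, outdir, result = NULL, threshold = 0.6,
                          config = NULL, seed = NULL) {
  if (!inherits(set, "channel_set")) stop("`set` must be a channel_set", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  invalid_counts <- integer(0)
  for (label in names(set$flow)) {
    fl <- set$flow[[label]]
    vol <- set$volume[[label]]
    ct <- attr(fl, "contrast")
    df <- data.frame(
      time_s = fl$time_s,
      k_raw_sq = if (!is.null(ct)) ct$k_raw_sq else NA_real_,
      k_shot_sq = if (!is.null(ct)) ct$k_shot_sq else NA_real_,
      k_quant_sq = if (!is.null(ct)) ct$k_quant_sq else NA_real_,
      k_cam_sq = if (!is.null(ct)) ct$k_cam_sq else NA_real_,
      k_adj_sq = if (!is.null(ct)) ct$k_adj_sq else 1 / fl$cbfi,
      cbfi = fl$cbfi,
      cbfi_norm = fl$cbfi_normalized,
      valid = fl$valid,
      mean_intensity_dn = vol$mean_intensity,
      cbvi_linear = vol$cbvi_linear,
      cbvi_log = vol$cbvi_log,
      i0 = vol$i0
    )
    f <- file.path(outdir, sprintf("%s_traces.csv", label))
    utils::write.csv(df, f, row.names = FALSE)
    files <- c(files, f)
    invalid_counts[label] <- sum(!fl$valid)
  }
  if (is.null(result) && length(set$flow) >= 2L) {
    result <- correlation_matrix(set)
  }
  grouping <- NULL
  if (!is.null(result)) {
    fm <- file.path(outdir, "correlation_matrix.csv")
    utils::write.csv(as.data.frame(result$matrix), fm)
    fp <- file.path(outdir, "pair_summary.csv")
    utils::write.csv(result$pairs, fp, row.names = FALSE)
    grouping <- group_channels(result, threshold)
    fg <- file.path(outdir, "grouping.json")
    jsonlite::write_json(list(threshold = threshold, groups = grouping),
                         fg, auto_unbox = TRUE, pretty = TRUE)
    files <- c(files, fm, fp, fg)
  }
  prov <- list(
    package = "scosflow",
    version = as.character(utils::packageVersion("scosflow")),
    seed = seed,
    invalid_samples = as.list(invalid_counts),
    n_channels = length(set$flow)
  )
  if (!is.null(config)) {
    cfg_file <- file.path(outdir, "config_used.json")
    jsonlite::write_json(unclass(config), cfg_file, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    prov$config_md5 <- unname(tools::md5sum(cfg_file))
    files <- c(files, cfg_file)
  }
  fprov <- file.path(outdir, "provenance.json")
  jsonlite::write_json(prov, fprov, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, fprov))
}

#' Write a simulated scene to a directory
#'
#' One TIFF + sidecar per channel, plus the ground-truth relative-flow
#' waveform per channel (`CSV: time_s, relative_flow`) and a scene-level
#' JSON recording the simulation parameters and seed.
#'
#' @param stacks A `scene_stacks` from [simulate_scene()].
#' @param outdir Output directory.
#' @param params The [speckle_params()] used.
#' @param camera The [camera_model()] used.
#' @return Character vector of stack files written, invisibly.
#' @export
write_scene <- function(stacks, outdir, params, camera) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  scene <- attr(stacks, "scene")
  waveforms <- attr(stacks, "waveforms")
  files <- character(0)
  for (label in names(stacks)) {
    f <- file.path(outdir, sprintf("%s.tiff", label))
    write_stack(stacks[[label]], f)
    wf <- waveforms[[label]]
    utils::write.csv(
      data.frame(time_s = wf$time_s, relative_flow = wf$relative_flow),
      file.path(outdir, sprintf("%s_waveform.csv", label)), row.names = FALSE)
    files <- c(files, f)
  }
  meta <- list(
    params = unclass(params),
    camera = unclass(camera),
    seed = scene$seed,
    n_channels = scene$n_channels,
    labels = scene$labels,
    transmission = scene$transmission,
    altered_channels = scene$altered_channels
  )
  jsonlite::write_json(meta, file.path(outdir, "scene.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}
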