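#' Raw squared speckle contrast of one frame
#'
#' `K_raw^2 = sigma^2(I) / mu^2(I)` over the masked pixels, with the
#' population variance (divide by N): at the pixel counts of whole-frame
#' SCOS the sample/population distinction is negligible and the population
#' form matches the moment definition of the contrast.
#'
#' @param frame Numeric matrix of intensities (DN).
#' @param mask Optional logical matrix selecting pixels; default all.
#' @return Squared contrast (dimensionless scalar).
#' @examples
#' compute_raw_contrast(matrix(c(0, 2, 0, 2), 2))  # 1
#' @export
compute_raw_contrast <- function(frame, mask = NULL) {
  if (!is.numeric(frame) || length(frame) == 0L) {
    stop("degenerate input: `frame` must be a non-empty numeric array", call. = FALSE)
  }
  v <- if (is.null(mask)) as.numeric(frame) else {
    if (!identical(dim(mask), dim(frame))) stop("mask/frame shape mismatch", call. = FALSE)
    as.numeric(frame[mask])
  }
  if (length(v) == 0L) stop("degenerate input: empty mask", call. = FALSE)
  mu <- mean(v)
  if (mu <= 0) stop("degenerate input: mean intensity must be > 0", call. = FALSE)
  n <- length(v)
  pop_var <- sum((v - mu)^2) / n
  pop_var / mu^2
}

#' Instrumental variance terms of the squared contrast
#'
#' The three noise contributions subtracted from the raw squared contrast,
#' in the standard camera-calibration forms (all in DN, `mu` the masked
#' mean intensity):
#' shot noise `1/(gain * mu)` (Poisson variance propagated through the
#' conversion gain), quantization `(1/12)/mu^2` (uniform quantization
#' variance of one DN step), and camera read+dark noise
#' `read_noise^2 / mu^2`.
#'
#' @param frame Numeric matrix (DN).
#' @param camera A [camera_model()].
#' @param mask Optional logical matrix.
#' @return Named list `k_shot_sq`, `k_quant_sq`, `k_cam_sq`.
#' @export
compute_noise_contrasts <- function(frame, camera, mask = NULL) {
  if (!inherits(camera, "camera_model")) stop("`camera` must be a camera_model", call. = FALSE)
  v <- if (is.null(mask)) as.numeric(frame) else as.numeric(frame[mask])
  if (length(v) == 0L) stop("degenerate input: empty mask", call. = FALSE)
  mu <- mean(v)
  if (mu <= 0) stop("degenerate input: mean intensity must be > 0", call. = FALSE)
  list(
    k_shot_sq = 1 / (camera$gain_e_per_dn * mu),
    k_quant_sq = (1 / 12) / mu^2,
    k_cam_sq = camera$read_noise_dn^2 / mu^2
  )
}

#' Noise-corrected squared contrast
#'
#' `K_adj^2 = K_raw^2 - K_shot^2 - K_quant^2 - K_cam^2`. When the
#' subtraction is non-positive (noise terms at or above the measured
#' contrast) the sample is flagged invalid and excluded downstream rather
#' than clamped, since `1/K_adj^2` would otherwise explode.
#'
#' @param k_raw_sq,k_shot_sq,k_quant_sq,k_cam_sq Non-negative numeric
#'   vectors (recycled to a common length).
#' @return List with `k_adj_sq` and logical `valid`.
#' @examples
#' adjust_contrast(0.05, 0.01, 0.001, 0.004)   # 0.035, valid
#' adjust_contrast(0.005, 0.006, 0, 0)         # invalid
#' @export
adjust_contrast <- function(k_raw_sq, k_shot_sq, k_quant_sq, k_cam_sq) {
  args <- list(k_raw_sq, k_shot_sq, k_quant_sq, k_cam_sq)
  if (any(vapply(args, function(a) any(is.na(a)) || any(a < 0), logical(1)))) {
    stop("all contrast terms must be non-negative", call. = FALSE)
  }
  k_adj <- k_raw_sq - k_shot_sq - k_quant_sq - k_cam_sq
  list(k_adj_sq = k_adj, valid = k_adj > 0)
}

#' Cerebral blood flow index from a contrast trace
#'
#' `CBFI(t) = 1 / K_adj^2(t)` on valid samples, plus a normalized version
#' divided by the mean CBFI over the baseline window, so the normalized
#' index averages 1 at baseline.
#'
#' @param trace A `contrast_trace` data frame (from [process_stack()]), or
#'   any data frame with columns `time_s`, `k_adj_sq`, `valid`.
#' @param baseline_window Numeric `c(start, end)` in seconds (inclusive).
#' @return A `flow_trace` data frame: `time_s`, `cbfi`, `cbfi_normalized`,
#'   `valid`.
#' @export
compute_cbfi <- function(trace, baseline_window = c(0, 5)) {
  req <- c("time_s", "k_adj_sq", "valid")
  if (!is.data.frame(trace) || !all(req %in% names(trace))) {
    stop("`trace` must have columns time_s, k_adj_sq, valid", call. = FALSE)
  }
  if (length(baseline_window) != 2L || baseline_window[2] < baseline_window[1]) {
    stop("`baseline_window` must be c(start, end) with end >= start", call. = FALSE)
  }
  cbfi <- ifelse(trace$valid, 1 / trace$k_adj_sq, NA_real_)
  in_win <- trace$time_s >= baseline_window[1] & trace$time_s <= baseline_window[2]
  base <- cbfi[in_win & trace$valid]
  if (length(base) == 0L) {
    stop("baseline error: no valid samples in the baseline window", call. = FALSE)
  }
  out <- data.frame(
    time_s = trace$time_s,
    cbfi = cbfi,
    cbfi_normalized = cbfi / mean(base),
    valid = trace$valid
  )
  class(out) <- c("flow_trace", "data.frame")
  attr(out, "baseline_window") <- baseline_window
  out
}

#' Process a frame stack into contrast and flow traces
#'
#' Applies, frame by frame: the raw squared contrast, the three
#' instrumental variance terms, the noise correction, and the CBFI with
#' baseline normalization. Saturated pixels (DN = max_dn) are excluded
#' from the statistics by default and the saturated fraction is recorded.
#'
#' @param stack A [frame_stack()].
#' @param camera A [camera_model()]; defaults to the stack's camera.
#' @param baseline_window `c(start, end)` seconds for CBFI normalization.
#' @param mask Optional logical matrix applied to every frame (combined
#'   with the saturation mask).
#' @param exclude_saturated Drop pixels at the saturation level
#'   (default TRUE).
#' @return List with `contrast` (a `contrast_trace` data frame: `time_s`,
#'   `k_raw_sq`, `k_shot_sq`, `k_quant_sq`, `k_cam_sq`, `k_adj_sq`,
#'   `valid`) and `flow` (a `flow_trace`). The mean saturated-pixel
#'   fraction is attached as attribute `saturated_fraction`.
#' @export
process_stack <- function(stack, camera = NULL, baseline_window = c(0, 5),
                          mask = NULL, exclude_saturated = TRUE) {
  if (!inherits(stack, "frame_stack")) stop("`stack` must be a frame_stack", call. = FALSE)
  if (is.null(camera)) camera <- stack$camera
  if (!inherits(camera, "camera_model")) stop("`camera` must be a camera_model", call. = FALSE)
  nf <- n_frames(stack)
  times <- frame_times(stack)
  k_raw <- k_shot <- k_quant <- k_cam <- numeric(nf)
  sat_frac <- numeric(nf)
  for (t in seq_len(nf)) {
    fr <- stack$frames[, , t]
    m <- if (is.null(mask)) array(TRUE, dim = dim(fr)) else mask
    if (exclude_saturated) {
      sat <- fr >= camera$max_dn
      sat_frac[t] <- mean(sat[m])
      m <- m & !sat
    }
    k_raw[t] <- compute_raw_contrast(fr, m)
    nz <- compute_noise_contrasts(fr, camera, m)
    k_shot[t] <- nz$k_shot_sq
    k_quant[t] <- nz$k_quant_sq
    k_cam[t] <- nz$k_cam_sq
  }
  adj <- adjust_contrast(k_raw, k_shot, k_quant, k_cam)
  contrast <- data.frame(
    time_s = times, k_raw_sq = k_raw, k_shot_sq = k_shot,
    k_quant_sq = k_quant, k_cam_sq = k_cam,
    k_adj_sq = adj$k_adj_sq, valid = adj$valid
  )
  class(contrast) <- c("contrast_trace", "data.frame")
  attr(contrast, "saturated_fraction") <- mean(sat_frac)
  flow <- compute_cbfi(contrast, baseline_window)
  list(contrast = contrast, flow = flow)
}
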