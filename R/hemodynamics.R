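#' Channel mean-intensity trace
#'
#' Per-frame spatial mean intensity over the (optionally masked) frame, in
#' the camera grayscale unit (DN). This is the attenuation signal the
#' blood-volume indices are derived from.
#'
#' @param stack A [frame_stack()].
#' @param mask Optional logical matrix.
#' @return Data frame `time_s`, `mean_intensity`.
#' @export
channel_mean_intensity <- function(stack, mask = NULL) {
  if (!inherits(stack, "frame_stack")) stop("`stack` must be a frame_stack", call. = FALSE)
  nf <- n_frames(stack)
  mu <- numeric(nf)
  for (t in seq_len(nf)) {
    fr <- stack$frames[, , t]
    v <- if (is.null(mask)) fr else {
      if (sum(mask) == 0L) stop("degenerate input: empty mask", call. = FALSE)
      fr[mask]
    }
    mu[t] <- mean(v)
  }
  data.frame(time_s = frame_times(stack), mean_intensity = mu)
}

#' Baseline intensity I0
#'
#' Arithmetic mean of the channel mean-intensity trace over the baseline
#' window — the reference the volume indices are measured against.
#'
#' @param trace Data frame with `time_s` and `mean_intensity`.
#' @param baseline_window `c(start, end)` seconds (inclusive); must lie
#'   within the recording.
#' @return Scalar baseline intensity in DN.
#' @export
compute_baseline_intensity <- function(trace, baseline_window = c(0, 5)) {
  if (!is.data.frame(trace) || !all(c("time_s", "mean_intensity") %in% names(trace))) {
    stop("`trace` must have columns time_s and mean_intensity", call. = FALSE)
  }
  if (length(baseline_window) != 2L || baseline_window[2] < baseline_window[1]) {
    stop("baseline error: window must be c(start, end) with end >= start", call. = FALSE)
  }
  if (baseline_window[1] > max(trace$time_s)) {
    stop("baseline error: window lies beyond the recording", call. = FALSE)
  }
  idx <- trace$time_s >= baseline_window[1] & trace$time_s <= baseline_window[2]
  if (!any(idx)) stop("baseline error: no samples in the baseline window", call. = FALSE)
  mean(trace$mean_intensity[idx])
}

#' Linear cerebral blood volume index
#'
#' `CBVI(t) = 2 - mu(I(t)) / I0`: equals 1 at baseline, rises when the
#' transmitted intensity drops (more absorbing blood in the sampled
#' volume). First-order (linear) form of the attenuation index.
#'
#' @param mean_intensity Numeric vector of per-frame mean intensities (DN),
#'   or a data frame with a `mean_intensity` column.
#' @param i0 Baseline intensity (DN), > 0.
#' @return Numeric vector of linear CBVI values.
#' @export
compute_cbvi_linear <- function(mean_intensity, i0) {
  if (is.data.frame(mean_intensity)) mean_intensity <- mean_intensity$mean_intensity
  stopifnot_scalar(i0, "i0", positive = TRUE)
  2 - mean_intensity / i0
}

#' Logarithmic cerebral blood volume index
#'
#' `dCBVI(t) = log10(I0 / mu(I(t)))`: 0 at baseline, exact attenuation
#' form preferable for large intensity excursions. Non-positive intensities
#' yield `NA` (flagged, not fatal).
#'
#' @inheritParams compute_cbvi_linear
#' @return Numeric vector of log CBVI values (`NA` where `mu <= 0`).
#' @export
compute_cbvi_log <- function(mean_intensity, i0) {
  if (is.data.frame(mean_intensity)) mean_intensity <- mean_intensity$mean_intensity
  stopifnot_scalar(i0, "i0", positive = TRUE)
  ifelse(mean_intensity > 0, log10(i0 / mean_intensity), NA_real_)
}

#' Volume trace of a frame stack
#'
#' Convenience wrapper: mean-intensity trace, baseline intensity, and both
#' blood-volume indices in one data frame.
#'
#' @param stack A [frame_stack()].
#' @param baseline_window `c(start, end)` seconds.
#' @param mask Optional logical matrix.
#' @return A `volume_trace` data frame: `time_s`, `mean_intensity`,
#'   `cbvi_linear`, `cbvi_log`, with `i0` as an attribute (and repeated in
#'   the `i0` column for file output).
#' @export
process_volume <- function(stack, baseline_window = c(0, 5), mask = NULL) {
  tr <- channel_mean_intensity(stack, mask)
  i0 <- compute_baseline_intensity(tr, baseline_window)
  out <- data.frame(
    time_s = tr$time_s,
    mean_intensity = tr$mean_intensity,
    cbvi_linear = compute_cbvi_linear(tr$mean_intensity, i0),
    cbvi_log = compute_cbvi_log(tr$mean_intensity, i0),
    i0 = i0
  )
  class(out) <- c("volume_trace", "data.frame")
  attr(out, "i0") <- i0
  attr(out, "baseline_window") <- baseline_window
  out
}
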