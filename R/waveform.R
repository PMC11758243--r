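#' Shape parameters of the synthetic cardiac beat
#'
#' Each beat is the sum of a baseline of 1 and two asymmetric Gaussian
#' bumps: a dominant systolic upstroke and a smaller dicrotic bump after
#' it. Positions and widths are expressed as fractions of the beat period,
#' amplitudes as fractions of baseline flow.
#'
#' @param sys_amp,sys_t,sys_wl,sys_wr Systolic peak amplitude, position,
#'   and left/right widths (beat fractions).
#' @param dic_amp,dic_t,dic_wl,dic_wr Same for the dicrotic bump.
#' @return A list of class `cardiac_shape`.
#' @export
cardiac_shape <- function(sys_amp = 0.45, sys_t = 0.16, sys_wl = 0.06, sys_wr = 0.14,
                          dic_amp = 0.14, dic_t = 0.46, dic_wl = 0.045, dic_wr = 0.10) {
  p <- list(sys_amp = sys_amp, sys_t = sys_t, sys_wl = sys_wl, sys_wr = sys_wr,
            dic_amp = dic_amp, dic_t = dic_t, dic_wl = dic_wl, dic_wr = dic_wr)
  for (nm in names(p)) stopifnot_scalar(p[[nm]], nm)
  if (any(unlist(p[c("sys_wl", "sys_wr", "dic_wl", "dic_wr")]) <= 0)) {
    stop("bump widths must be > 0", call. = FALSE)
  }
  structure(p, class = "cardiac_shape")
}

# Raw (un-normalized) beat template evaluated at beat phase phi in [0, 1).
beat_template <- function(phi, shape) {
  bump <- function(phi, mu, wl, wr, amp) {
    d <- ((phi - mu + 0.5) %% 1) - 0.5   # wrapped phase distance
    w <- ifelse(d < 0, wl, wr)
    amp * exp(-0.5 * (d / w)^2)
  }
  1 + bump(phi, shape$sys_t, shape$sys_wl, shape$sys_wr, shape$sys_amp) +
      bump(phi, shape$dic_t, shape$dic_wl, shape$dic_wr, shape$dic_amp)
}

#' Generate a cardiac-like relative-flow waveform
#'
#' Produces a strictly positive, periodic relative-flow multiplier sampled
#' at frame times. Each beat shows one dominant systolic peak and one
#' secondary dicrotic bump. The waveform is normalized so its mean over the
#' whole beats contained in the recording equals 1, i.e. the baseline flow
#' is the average flow.
#'
#' @param heart_rate Beats per minute, in (30, 200).
#' @param duration Recording duration in seconds.
#' @param frame_rate Sampling rate in Hz (the camera frame rate).
#' @param shape A [cardiac_shape()] object.
#' @param phase Initial beat phase in [0, 1); shifts the waveform without
#'   changing its statistics. Useful for decorrelating channels.
#' @param seed Optional integer seed, reserved for stochastic beat-to-beat
#'   variability extensions; the default waveform is deterministic and the
#'   seed only fixes the RNG state for reproducibility of such extensions.
#' @return A `flow_waveform`: list with `time_s`, `relative_flow`,
#'   `heart_rate`, `frame_rate`, `shape`.
#' @examples
#' wf <- cardiac_waveform(heart_rate = 60, duration = 5, frame_rate = 40)
#' length(wf$relative_flow)  # 200 samples
#' mean(wf$relative_flow)    # 1 over whole beats
#' @export
cardiac_waveform <- function(heart_rate = 60, duration, frame_rate = 40,
                             shape = cardiac_shape(), phase = 0, seed = NULL) {
  stopifnot_scalar(heart_rate, "heart_rate", positive = TRUE)
  if (heart_rate <= 30 || heart_rate >= 200) {
    stop("`heart_rate` must be in (30, 200) bpm", call. = FALSE)
  }
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(frame_rate, "frame_rate", positive = TRUE)
  stopifnot_scalar(phase, "phase")
  if (!inherits(shape, "cardiac_shape")) stop("`shape` must be a cardiac_shape", call. = FALSE)

  with_seed(seed, {
    n <- floor(duration * frame_rate + 1e-9)
    if (n < 1) stop("`duration` too short for one sample", call. = FALSE)
    time_s <- (seq_len(n) - 1) / frame_rate
    f0 <- heart_rate / 60
    raw <- beat_template((time_s * f0 + phase) %% 1, shape)
    # normalize over the whole beats contained in the recording so that the
    # discrete mean over complete beats is exactly 1
    period <- 60 / heart_rate
    n_beats <- floor(duration / period + 1e-9)
    norm_idx <- if (n_beats >= 1) time_s < n_beats * period - 1e-12 else rep(TRUE, n)
    rel <- raw / mean(raw[norm_idx])
    structure(
      list(time_s = time_s, relative_flow = rel, heart_rate = heart_rate,
           frame_rate = frame_rate, shape = shape),
      class = "flow_waveform"
    )
  })
}

#' Constant (steady-flow) waveform
#'
#' Convenience companion to [cardiac_waveform()] for steady-state runs:
#' relative flow identically 1, so the decorrelation time stays at its
#' baseline value for the whole recording.
#'
#' @param duration Duration in seconds.
#' @param frame_rate Sampling rate in Hz.
#' @return A `flow_waveform` with `relative_flow` all 1.
#' @export
steady_waveform <- function(duration, frame_rate = 40) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(frame_rate, "frame_rate", positive = TRUE)
  n <- max(1L, floor(duration * frame_rate + 1e-9))
  structure(
    list(time_s = (seq_len(n) - 1) / frame_rate, relative_flow = rep(1, n),
         heart_rate = NA_real_, frame_rate = frame_rate, shape = NULL),
    class = "flow_waveform"
  )
}

# Relative flow at arbitrary times, linearly interpolated; constant
# extrapolation at the ends.
waveform_at <- function(waveform, times) {
  if (length(waveform$time_s) == 1L) return(rep(waveform$relative_flow, length(times)))
  stats::approx(waveform$time_s, waveform$relative_flow, xout = times,
                rule = 2)$y
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat("<flow_waveform>\n")
  cat(sprintf("  %d samples @ %g Hz | heart rate: %s bpm | flow range [%.3f, %.3f]\n",
              length(x$relative_flow), x$frame_rate,
              ifelse(is.na(x$heart_rate), "steady", format(x$heart_rate)),
              min(x$relative_flow), max(x$relative_flow)))
  invisible(x)
}
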