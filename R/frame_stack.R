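#' Frame stack container
#'
#' A time-ordered sequence of 2-D intensity frames from one channel,
#' stored as an integer array `[rows, cols, frames]` in digital numbers
#' (DN), together with timing and camera metadata.
#'
#' @param frames Integer array `[rows, cols, n_frames]` (a single matrix is
#'   promoted to one frame).
#' @param frame_rate Frames per second (Hz).
#' @param exposure_T Exposure time (s).
#' @param camera A [camera_model()].
#' @param channel_id Label for the channel.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate, exposure_T, camera,
                        channel_id = "ch1") {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a [rows, cols, n] array", call. = FALSE)
  }
  if (dim(frames)[3] < 1) stop("frame count must be >= 1", call. = FALSE)
  stopifnot_scalar(frame_rate, "frame_rate", positive = TRUE)
  stopifnot_scalar(exposure_T, "exposure_T", positive = TRUE)
  if (!inherits(camera, "camera_model")) {
    stop("`camera` must be a camera_model", call. = FALSE)
  }
  if (min(frames) < 0 || max(frames) > camera$max_dn) {
    stop("frame intensities must lie in [0, max_dn]", call. = FALSE)
  }
  structure(
    list(frames = frames, frame_rate = frame_rate, exposure_T = exposure_T,
         camera = camera, channel_id = channel_id),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("<frame_stack>\n")
  cat(sprintf("  channel %s: %d frames of %d x %d @ %g FPS, T = %g ms, %d-bit\n",
              x$channel_id, d[3], d[1], d[2], x$frame_rate,
              1000 * x$exposure_T, x$camera$bit_depth))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A `frame_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  dim(stack$frames)[3]
}

#' Per-frame timestamps of a stack
#' @param stack A `frame_stack`.
#' @return Numeric vector, `frame_index / frame_rate` starting at 0.
#' @export
frame_times <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  (seq_len(n_frames(stack)) - 1) / stack$frame_rate
}
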