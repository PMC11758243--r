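#' Dynamic-speckle simulation parameters
#'
#' Physical and sampling parameters of the synthetic speckle forward model.
#' Defaults describe a desk-scale stand-in for the six-channel instrument:
#' 256 x 256 frames at 40 frames per second, 6 ms exposure, a
#' speckle-to-pixel length ratio of 0.5 (about four speckles per pixel) and
#' a mean level of 100 DN on an 8-bit scale.
#'
#' @param tau_c Field decorrelation time in seconds at baseline flow.
#'   `Inf` is the static sentinel: the speckle pattern is frozen for the
#'   whole recording.
#' @param exposure_T Exposure time in seconds; must not exceed the frame
#'   period `1/frame_rate`.
#' @param sp_ratio One-dimensional speckle-to-pixel length ratio in
#'   (0, 2]. Values below 1 mean several speckles are averaged inside one
#'   pixel, which lowers the contrast ceiling.
#' @param beta Residual coherence factor in (0, 1] applied on top of the
#'   spatial-averaging loss; 1 means the only ceiling loss is the
#'   speckle-to-pixel averaging set by `sp_ratio`.
#' @param mean_level Target mean intensity in DN (before sensor noise).
#' @param frame_shape Integer vector `c(rows, cols)`.
#' @param frame_rate Frames per second (Hz).
#' @param vol_coupling Dimensionless coupling between relative flow and
#'   mean transmitted intensity: the per-frame mean level is
#'   `mean_level * (1 - vol_coupling * (relative_flow - 1))`, emulating
#'   increased absorption when blood volume rises with flow. Set 0 to
#'   decouple volume from flow.
#' @return An object of class `speckle_params`.
#' @examples
#' speckle_params(tau_c = 3e-3)
#' speckle_params(tau_c = Inf)   # static scatterers
#' @export
speckle_params <- function(tau_c,
                           exposure_T = 6e-3,
                           sp_ratio = 0.5,
                           beta = 1,
                           mean_level = 100,
                           frame_shape = c(256L, 256L),
                           frame_rate = 40,
                           vol_coupling = 0.15) {
  if (!is.numeric(tau_c) || length(tau_c) != 1L || is.na(tau_c) || tau_c <= 0) {
    stop("`tau_c` must be a single number > 0 (Inf = static)", call. = FALSE)
  }
  stopifnot_scalar(exposure_T, "exposure_T", positive = TRUE)
  stopifnot_scalar(sp_ratio, "sp_ratio", positive = TRUE)
  if (sp_ratio > 2) stop("`sp_ratio` must be in (0, 2]", call. = FALSE)
  stopifnot_scalar(beta, "beta", positive = TRUE)
  if (beta > 1) stop("`beta` must be in (0, 1]", call. = FALSE)
  stopifnot_scalar(mean_level, "mean_level", positive = TRUE)
  stopifnot_scalar(frame_rate, "frame_rate", positive = TRUE)
  if (exposure_T > 1 / frame_rate + 1e-12) {
    stop("`exposure_T` must not exceed the frame period 1/frame_rate", call. = FALSE)
  }
  if (length(frame_shape) != 2L || any(frame_shape < 2) ||
      any(frame_shape != round(frame_shape))) {
    stop("`frame_shape` must be two integers >= 2", call. = FALSE)
  }
  stopifnot_scalar(vol_coupling, "vol_coupling")
  structure(
    list(
      tau_c = tau_c,
      exposure_T = exposure_T,
      sp_ratio = sp_ratio,
      beta = beta,
      mean_level = mean_level,
      frame_shape = as.integer(frame_shape),
      frame_rate = frame_rate,
      vol_coupling = vol_coupling
    ),
    class = "speckle_params"
  )
}

#' @export
print.speckle_params <- function(x, ...) {
  cat("<speckle_params>\n")
  cat(sprintf("  tau_c: %g s | T: %g s | %g FPS | frames %d x %d\n",
              x$tau_c, x$exposure_T, x$frame_rate,
              x$frame_shape[1], x$frame_shape[2]))
  cat(sprintf("  s/p: %g | beta: %g | mean level: %g DN | vol coupling: %g\n",
              x$sp_ratio, x$beta, x$mean_level, x$vol_coupling))
  invisible(x)
}
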