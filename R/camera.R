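#' Camera sensor model
#'
#' Describes the sensor parameters that determine the three instrumental
#' variance terms subtracted from the raw squared speckle contrast: the
#' conversion gain (shot noise), the bit depth (quantization noise) and the
#' read/dark noise standard deviation (camera noise). The same model drives
#' the sensor stage of the speckle simulator, so corrections and forward
#' model share one parameterization.
#'
#' @param gain_e_per_dn Conversion gain in electrons per digital number
#'   (DN). `Inf` disables shot noise in the simulator and makes the shot
#'   correction zero (useful as a noise-free reference).
#' @param read_noise_dn Standard deviation of the combined readout and dark
#'   noise, in DN.
#' @param bit_depth Bits per pixel; the saturation level is
#'   `2^bit_depth - 1` DN.
#' @return An object of class `camera_model`.
#' @examples
#' camera_model()                      # 8-bit board camera defaults
#' camera_model(bit_depth = 16)        # high-dynamic-range variant
#' @export
camera_model <- function(gain_e_per_dn = 2, read_noise_dn = 1.5, bit_depth = 8) {
  if (!is.numeric(gain_e_per_dn) || length(gain_e_per_dn) != 1L ||
      is.na(gain_e_per_dn) || gain_e_per_dn <= 0) {
    stop("`gain_e_per_dn` must be a single number > 0 (Inf allowed)", call. = FALSE)
  }
  stopifnot_scalar(read_noise_dn, "read_noise_dn")
  if (read_noise_dn < 0) stop("`read_noise_dn` must be >= 0", call. = FALSE)
  stopifnot_scalar(bit_depth, "bit_depth", positive = TRUE)
  if (bit_depth != round(bit_depth) || bit_depth < 1 || bit_depth > 16) {
    stop("`bit_depth` must be an integer between 1 and 16", call. = FALSE)
  }
  structure(
    list(
      gain_e_per_dn = gain_e_per_dn,
      read_noise_dn = read_noise_dn,
      bit_depth = as.integer(bit_depth),
      max_dn = 2^as.integer(bit_depth) - 1
    ),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat("<camera_model>\n")
  cat(sprintf("  gain: %g e-/DN | read+dark noise: %g DN | %d-bit (max %d DN)\n",
              x$gain_e_per_dn, x$read_noise_dn, x$bit_depth, x$max_dn))
  invisible(x)
}
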