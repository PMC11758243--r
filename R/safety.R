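#' Laser skin-exposure safety check
#'
#' Average irradiance of a beam spread over a uniform circular spot,
#' compared against the maximum permissible exposure (MPE). The default
#' limit, 3.28 mW/mm^2, is the ANSI skin MPE at 808 nm; the instrument's
#' 67 mW over a 5.5-mm spot evaluates to about 2.82 mW/mm^2 and passes.
#'
#' @param power_mw Optical power in mW (>= 0).
#' @param spot_diameter_mm Illumination spot diameter in mm (> 0).
#' @param mpe_mw_per_mm2 Irradiance limit in mW/mm^2.
#' @return A `safety_check`: list with the inputs, the computed
#'   `density_mw_per_mm2` and a logical `pass`.
#' @examples
#' power_density_check(67, 5.5)    # ~2.82 mW/mm^2, pass
#' @export
power_density_check <- function(power_mw, spot_diameter_mm,
                                mpe_mw_per_mm2 = 3.28) {
  stopifnot_scalar(power_mw, "power_mw")
  if (power_mw < 0) stop("`power_mw` must be >= 0", call. = FALSE)
  stopifnot_scalar(spot_diameter_mm, "spot_diameter_mm", positive = TRUE)
  stopifnot_scalar(mpe_mw_per_mm2, "mpe_mw_per_mm2", positive = TRUE)
  density <- power_mw / (pi * (spot_diameter_mm / 2)^2)
  structure(
    list(power_mw = power_mw, spot_diameter_mm = spot_diameter_mm,
         mpe_mw_per_mm2 = mpe_mw_per_mm2,
         density_mw_per_mm2 = density, pass = density <= mpe_mw_per_mm2),
    class = "safety_check"
  )
}

#' @export
print.safety_check <- function(x, ...) {
  cat(sprintf("Laser safety: %.4g mW over %.3g mm spot -> %.4g mW/mm^2 (MPE %.4g): %s\n",
              x$power_mw, x$spot_diameter_mm, x$density_mw_per_mm2,
              x$mpe_mw_per_mm2, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Speckle-per-pixel count to speckle-to-pixel length ratio
#'
#' Converts a two-dimensional count of speckles per pixel into the
#' one-dimensional speckle-to-pixel length ratio: `s/p = 1/sqrt(n)`.
#' Four speckles per pixel corresponds to s/p = 0.5.
#'
#' @param n_speckles_per_pixel Speckles per pixel (> 0).
#' @return The s/p length ratio.
#' @examples
#' speckles_per_pixel_to_sp_ratio(4)   # 0.5
#' @export
speckles_per_pixel_to_sp_ratio <- function(n_speckles_per_pixel) {
  stopifnot_scalar(n_speckles_per_pixel, "n_speckles_per_pixel", positive = TRUE)
  1 / sqrt(n_speckles_per_pixel)
}
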