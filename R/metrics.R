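# Wavefront deltas and dioptric metrics.

#' Wavefront change between two surface coefficient vectors
#'
#' The corneal wavefront change caused by reshaping the anterior surface is
#' the surface coefficient difference scaled by the refractive index step
#' across the interface:
#' \deqn{\Delta z_n = (c_{n,\mathrm{post}} - c_{n,\mathrm{pre}}) \times (n' - n)}
#' with n' - n = 0.376 (air to stroma). The LD/HD delta is obtained by
#' applying the exact linear basis conversion to the Zernike delta, which by
#' linearity equals converting first and subtracting after. Both spherical
#' equivalents (from the Zernike and from the LD/HD defocus coefficient) are
#' attached.
#'
#' @param pre_c,post_c [zernike_vector()] surface coefficients (micrometers)
#'   over the same zone.
#' @param constants A [refractive_constants()] object.
#' @return An object of class `wavefront_delta` with fields `dz`
#'   ([zernike_vector()], micrometers), `dg` ([ldhd_vector()]), `zone`,
#'   `dse_zernike` and `dse_ldhd` (diopters).
#' @export
wavefront_delta <- function(pre_c, post_c, constants = refractive_constants()) {
  stopifnot(inherits(pre_c, "zernike_vector"), inherits(post_c, "zernike_vector"),
            inherits(constants, "refractive_constants"))
  if (abs(pre_c$zone$diameter_mm - post_c$zone$diameter_mm) > 1e-12) {
    stop("pre and post coefficient vectors refer to different zones (",
         pre_c$zone$diameter_mm, " vs ", post_c$zone$diameter_mm, " mm)")
  }
  zone <- pre_c$zone
  d <- (post_c$coeffs - pre_c$coeffs) * constants$delta_n
  dz <- zernike_vector(d[1], d[2], d[3], d[4], zone = zone)
  dg <- zernike_to_ldhd(dz)
  structure(list(dz = dz, dg = dg, zone = zone,
                 dse_zernike = spherical_equivalent(dz$coeffs[["c2"]], zone),
                 dse_ldhd = spherical_equivalent(dg$coeffs[["g2"]], zone)),
            class = "wavefront_delta")
}

#' @export
print.wavefront_delta <- function(x, ...) {
  cat(sprintf("<wavefront_delta> zone %.4g mm\n", x$zone$diameter_mm))
  cat(sprintf("  dz (um): %8.4f %8.4f %8.4f %8.4f\n", x$dz$coeffs[1],
              x$dz$coeffs[2], x$dz$coeffs[3], x$dz$coeffs[4]))
  cat(sprintf("  dg (um): %8.4f %8.4f %8.4f %8.4f\n", x$dg$coeffs[1],
              x$dg$coeffs[2], x$dg$coeffs[3], x$dg$coeffs[4]))
  cat(sprintf("  dSE: %+.2f D (Zernike), %+.2f D (LD/HD)\n",
              x$dse_zernike, x$dse_ldhd))
  invisible(x)
}

#' Spherical equivalent of a defocus coefficient
#'
#' Dioptric defocus equivalent of a unit-RMS defocus coefficient (Zernike
#' c2 or LD/HD g2) in micrometers over a zone of diameter S (mm):
#' \deqn{SE = \frac{4 \sqrt{3}\, c_2^0}{(S/2)^2}}
#' Positive SE is an increase of corneal power; a +D hyperopic correction
#' yields a positive delta-SE equal to D when computed from the LD/HD
#' defocus delta.
#'
#' @param c2_um Defocus coefficient in micrometers.
#' @param zone An [optical_zone()] or a diameter in mm.
#' @return Diopters.
#' @examples
#' spherical_equivalent(2.59, 6)  # ~ +2.00 D
#' @export
spherical_equivalent <- function(c2_um, zone) {
  zone <- as_optical_zone(zone)
  4 * sqrt(3) * c2_um / (zone$diameter_mm / 2)^2
}

#' Subjective refraction shift from a corneal power change
#'
#' An increase in corneal power moves the eye's refraction toward myopia,
#' so the refraction-direction reading is the negated power change: a
#' negative delta-SE (power loss) is a hyperopic shift (positive value).
#'
#' @param dse_diopters Corneal power change in diopters.
#' @return Refraction shift in diopters.
#' @export
refraction_shift <- function(dse_diopters) {
  -dse_diopters
}
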