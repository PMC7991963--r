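#' Conic corneal surface
#'
#' Represents a rotationally symmetric corneal profile as a conic section
#' with apical radius of curvature `R` (mm) and conic constant (asphericity)
#' `Q`. `Q = 0` is a sphere, `Q < 0` a prolate ellipse (flattening toward the
#' periphery, `Q = -1` a paraboloid), `Q > 0` an oblate ellipse.
#'
#' @param apical_radius_mm Apical radius of curvature in mm; must be > 0.
#' @param asphericity_q Dimensionless conic constant Q.
#' @return An object of class `conic_surface`.
#' @examples
#' conic_surface(7.8, -0.2)
#' @export
conic_surface <- function(apical_radius_mm, asphericity_q = 0) {
  stopifnot(is.numeric(apical_radius_mm), length(apical_radius_mm) == 1L,
            is.finite(apical_radius_mm),
            is.numeric(asphericity_q), length(asphericity_q) == 1L,
            is.finite(asphericity_q))
  if (apical_radius_mm <= 0) {
    stop("apical_radius_mm must be positive, got ", apical_radius_mm)
  }
  structure(list(apical_radius_mm = apical_radius_mm,
                 asphericity_q = asphericity_q),
            class = "conic_surface")
}

#' @export
print.conic_surface <- function(x, ...) {
  cat(sprintf("<conic_surface> R = %.4g mm, Q = %+.4g\n",
              x$apical_radius_mm, x$asphericity_q))
  invisible(x)
}

#' Optical zone
#'
#' The analysis/ablation zone of diameter `S` (mm). Its half-diameter `S/2`
#' is the normalization radius mapping physical radius r (mm) to the unit
#' disc coordinate rho = 2r/S used by the polynomial bases.
#'
#' @param diameter_mm Zone diameter S in mm; must be > 0.
#' @return An object of class `optical_zone`.
#' @examples
#' optical_zone(6)
#' @export
optical_zone <- function(diameter_mm) {
  stopifnot(is.numeric(diameter_mm), length(diameter_mm) == 1L,
            is.finite(diameter_mm))
  if (diameter_mm <= 0) stop("zone diameter must be positive, got ", diameter_mm)
  structure(list(diameter_mm = diameter_mm), class = "optical_zone")
}

#' @export
print.optical_zone <- function(x, ...) {
  cat(sprintf("<optical_zone> S = %.4g mm\n", x$diameter_mm))
  invisible(x)
}

as_optical_zone <- function(zone) {
  if (inherits(zone, "optical_zone")) return(zone)
  optical_zone(zone)
}

#' Refractive constants
#'
#' Indices used to convert a corneal elevation change into an optical path
#' (wavefront) change: air n = 1 in front of the cornea, stromal index
#' n' = 1.376 behind the ablated surface. The wavefront scaling factor is
#' their difference, n' - n = 0.376.
#'
#' @param n_air Refractive index of air (default 1).
#' @param n_stroma Refractive index of the corneal stroma (default 1.376).
#' @return An object of class `refractive_constants` with fields `n_air`,
#'   `n_stroma`, `delta_n`.
#' @export
refractive_constants <- function(n_air = 1, n_stroma = 1.376) {
  stopifnot(is.numeric(n_air), is.numeric(n_stroma),
            n_stroma > n_air, n_air > 0)
  structure(list(n_air = n_air, n_stroma = n_stroma,
                 delta_n = n_stroma - n_air),
            class = "refractive_constants")
}

#' Sagittal elevation of a conic surface
#'
#' Axial depth z(r) of the surface below the apex plane at radial distance
#' r from the axis, positive toward the retina:
#' \deqn{z(r) = \frac{r^2}{R\,(1 + \sqrt{1 - (1+Q)\,r^2/R^2})}}
#' This form is numerically stable near the apex and reduces to the sphere
#' sagitta for Q = 0 and to the paraboloid r^2/(2R) for Q = -1.
#'
#' @param surface A [conic_surface()].
#' @param r_mm Radial distance(s) from the apex in mm; vectorized.
#' @return Elevation in mm (same length as `r_mm`).
#' @examples
#' sagitta(conic_surface(7.8, 0), 3)            # sphere: 7.8 - sqrt(7.8^2 - 9)
#' sagitta(conic_surface(7.8, -1), 3)           # paraboloid: 9 / 15.6
#' @export
sagitta <- function(surface, r_mm) {
  stopifnot(inherits(surface, "conic_surface"), is.numeric(r_mm))
  if (any(r_mm < 0)) stop("radial distance must be nonnegative")
  R <- surface$apical_radius_mm
  Q <- surface$asphericity_q
  arg <- 1 - (1 + Q) * r_mm^2 / R^2
  if (any(arg <= 0)) {
    stop(sprintf(paste0("conic surface (R = %.4g, Q = %+.4g) is not defined ",
                        "out to r = %.4g mm: zone exceeds the conic's valid extent"),
                 R, Q, max(r_mm[arg <= 0])))
  }
  r_mm^2 / (R * (1 + sqrt(arg)))
}

#' Check that a conic surface covers an optical zone
#'
#' @param surface A [conic_surface()].
#' @param zone An [optical_zone()] or a diameter in mm.
#' @return `TRUE` invisibly; errors if the sagitta is undefined anywhere on
#'   the closed zone.
#' @export
validate_zone_coverage <- function(surface, zone) {
  zone <- as_optical_zone(zone)
  sagitta(surface, zone$diameter_mm / 2)
  invisible(TRUE)
}

#' Post-operative apical radius from a paraxial defocus correction
#'
#' The intended defocus correction D (diopters, at the corneal plane) changes
#' the paraxial surface power (n' - n)/R, giving
#' \deqn{1/R_1 = 1/R_0 + D/(n' - n)} with the radii in meters. A hyperopic
#' correction (D > 0) steepens the apex (R1 < R0); a myopic correction
#' (D < 0) flattens it (R1 > R0).
#'
#' @param r0_mm Pre-operative apical radius in mm.
#' @param d_diopters Intended defocus correction D in diopters.
#' @param constants A [refractive_constants()] object.
#' @return Post-operative apical radius R1 in mm.
#' @examples
#' postop_radius(7.8, +2)    # 7.49 mm
#' postop_radius(7.8, -10)   # 9.84 mm
#' @export
postop_radius <- function(r0_mm, d_diopters, constants = refractive_constants()) {
  stopifnot(is.numeric(r0_mm), r0_mm > 0, is.numeric(d_diopters),
            inherits(constants, "refractive_constants"))
  # radii in meters: 1/R1 = 1/R0 + D/delta_n; in mm the D term is D/(1000*dn)
  inv_r1 <- 1 / r0_mm + d_diopters / (1000 * constants$delta_n)
  if (inv_r1 <= 0) {
    stop(sprintf("correction D = %.4g D flattens R0 = %.4g mm to nonpositive power",
                 d_diopters, r0_mm))
  }
  1 / inv_r1
}

#' Ablation profile between two conic surfaces
#'
#' The tissue removed over the optical zone is the vertical gap between the
#' pre- and post-operative conics plus a centering offset t0 (the ablation
#' depth at the zone center). When `central_depth_um` is `NULL`, t0 is chosen
#' so the thickness is nonnegative with minimum exactly zero on the zone.
#' The thickness map is diagnostic; it does not enter the coefficient math.
#'
#' @param pre,post [conic_surface()] objects (pre- and post-operative).
#' @param zone An [optical_zone()] or a diameter in mm.
#' @param central_depth_um Optional central ablation depth t0 in micrometers.
#' @return An object of class `ablation_profile` with the auto-computed or
#'   supplied `central_depth_um`.
#' @export
ablation_profile <- function(pre, post, zone, central_depth_um = NULL) {
  stopifnot(inherits(pre, "conic_surface"), inherits(post, "conic_surface"))
  zone <- as_optical_zone(zone)
  validate_zone_coverage(pre, zone)
  validate_zone_coverage(post, zone)
  gap <- function(r) 1000 * (sagitta(post, r) - sagitta(pre, r))
  if (is.null(central_depth_um)) {
    r <- seq(0, zone$diameter_mm / 2, length.out = 513L)
    central_depth_um <- -min(gap(r))
  }
  prof <- structure(list(pre = pre, post = post, zone = zone,
                         central_depth_um = central_depth_um),
                    class = "ablation_profile")
  r <- seq(0, zone$diameter_mm / 2, length.out = 513L)
  if (min(gap(r)) + central_depth_um < -1e-9) {
    stop("ablation thickness is negative on the zone with t0 = ",
         central_depth_um, " um")
  }
  prof
}

#' Ablation thickness at a radial position
#'
#' @param profile An [ablation_profile()].
#' @param r_mm Radial distance(s) in mm, within the zone.
#' @return Tissue depth in micrometers.
#' @export
ablation_thickness <- function(profile, r_mm) {
  stopifnot(inherits(profile, "ablation_profile"))
  if (any(r_mm > profile$zone$diameter_mm / 2 + 1e-12)) {
    stop("r exceeds the optical zone half-diameter")
  }
  1000 * (sagitta(profile$post, r_mm) - sagitta(profile$pre, r_mm)) +
    profile$central_depth_um
}
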