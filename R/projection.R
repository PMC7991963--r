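# Scalar-product projection of radial functions onto the Zernike basis.
#
# The projection is a fixed-order Gauss-Legendre quadrature (64 nodes on
# rho in [0, 1] with the area weight folded in), so every coefficient is
# deterministic and bit-stable; no adaptive tolerances.

quadrature_rule <- local({
  cache <- list()
  function(n_nodes = 64L) {
    key <- as.character(n_nodes)
    if (is.null(cache[[key]])) {
      gl <- pracma::gaussLegendre(n_nodes, 0, 1)
      zmat <- sapply(c(0, 2, 4, 6), function(n)
        eval_radial_poly(zernike_mode(n), gl$x))
      cache[[key]] <<- list(rho = gl$x, w = gl$w, zmat = zmat)
    }
    cache[[key]]
  }
})

#' Project a radial function onto the Zernike modes over a zone
#'
#' Computes the rotationally symmetric Zernike coefficients of a radial
#' profile W(r) over a zone of diameter S by scalar products:
#' \deqn{c_n = 2 \int_0^1 W(\rho S/2)\, Z_n(\rho)\, \rho\, d\rho,\quad
#'       n \in \{0, 2, 4, 6\}.}
#' The quadrature is exact (to rounding) for polynomial integrands of the
#' degrees that occur here; for a conic surface the order-6 fit is an
#' approximation and [reconstruction_residual_rms()] reports the remainder.
#'
#' @param fn Function mapping physical radius r (mm) on \[0, S/2\] to
#'   elevation or phase in micrometers; must accept a vector.
#' @param zone An [optical_zone()] or a diameter in mm.
#' @param n_nodes Number of Gauss-Legendre nodes (default 64).
#' @return A [zernike_vector()] in micrometers.
#' @examples
#' project_radial(function(r) rep(5, length(r)), optical_zone(6))  # pure piston
#' @export
project_radial <- function(fn, zone, n_nodes = 64L) {
  stopifnot(is.function(fn))
  zone <- as_optical_zone(zone)
  q <- quadrature_rule(n_nodes)
  vals <- fn(q$rho * zone$diameter_mm / 2)
  stopifnot(length(vals) == length(q$rho), all(is.finite(vals)))
  cc <- as.numeric(crossprod(q$zmat, 2 * q$w * q$rho * vals))
  zernike_vector(cc[1], cc[2], cc[3], cc[4], zone = zone)
}

#' Project a conic surface onto the Zernike modes
#'
#' Convenience wrapper: projects the sagittal elevation of a conic corneal
#' surface (converted from mm to micrometers) over the zone.
#'
#' @param surface A [conic_surface()].
#' @param zone An [optical_zone()] or a diameter in mm.
#' @param n_nodes Number of quadrature nodes.
#' @return A [zernike_vector()] of the surface elevation in micrometers.
#' @export
project_conic <- function(surface, zone, n_nodes = 64L) {
  stopifnot(inherits(surface, "conic_surface"))
  zone <- as_optical_zone(zone)
  validate_zone_coverage(surface, zone)
  project_radial(function(r) 1000 * sagitta(surface, r), zone,
                 n_nodes = n_nodes)
}

#' Project a pre/post surface pair with one quadrature rule
#'
#' Both conics are projected over the same zone with the identical
#' deterministic quadrature so their difference is free of rule mismatch.
#'
#' @param pre,post [conic_surface()] objects.
#' @param zone An [optical_zone()] or a diameter in mm.
#' @param n_nodes Number of quadrature nodes.
#' @return A list with [zernike_vector()] elements `pre` and `post`.
#' @export
project_surface_pair <- function(pre, post, zone, n_nodes = 64L) {
  zone <- as_optical_zone(zone)
  list(pre = project_conic(pre, zone, n_nodes = n_nodes),
       post = project_conic(post, zone, n_nodes = n_nodes))
}

#' RMS residual of the order-6 fit
#'
#' The n <= 6 expansion of a conic surface truncates its Taylor series; this
#' reports the root-mean-square (over the disc) of the difference between
#' the radial function and its reconstruction from the fitted coefficients.
#'
#' @param fn Radial function of r (mm) returning micrometers.
#' @param coeffs The [zernike_vector()] returned by [project_radial()].
#' @return RMS residual in micrometers.
#' @export
reconstruction_residual_rms <- function(fn, coeffs) {
  stopifnot(inherits(coeffs, "zernike_vector"))
  q <- quadrature_rule(64L)
  resid <- fn(q$rho * coeffs$zone$diameter_mm / 2) -
    eval_wavefront(coeffs, q$rho)
  sqrt(sum(2 * q$w * q$rho * resid^2))
}
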