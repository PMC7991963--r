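# Rotationally symmetric polynomial bases on the unit disc.
#
# Both bases are expressed in the even monomials (1, rho^2, rho^4, rho^6) and
# all inner products use the area-weighted form <f, g> = 2 * int_0^1 f g rho drho,
# so that <f, f> is the mean square of f over the disc (unit RMS = norm 1).

#' Radial polynomial in even monomials
#'
#' A polynomial `a0 + a2*rho^2 + a4*rho^4 + a6*rho^6` on the unit disc radius
#' rho in \[0, 1\].
#'
#' @param monomial_coeffs Numeric length-4 vector of coefficients of
#'   (1, rho^2, rho^4, rho^6).
#' @return An object of class `radial_poly`.
#' @export
radial_poly <- function(monomial_coeffs) {
  stopifnot(is.numeric(monomial_coeffs), length(monomial_coeffs) == 4L,
            all(is.finite(monomial_coeffs)))
  structure(list(monomial_coeffs = as.numeric(monomial_coeffs)),
            class = "radial_poly")
}

#' Evaluate a radial polynomial
#'
#' @param poly A [radial_poly()].
#' @param rho Unit-disc radii in \[0, 1\]; vectorized.
#' @return Numeric vector of polynomial values.
#' @export
eval_radial_poly <- function(poly, rho) {
  stopifnot(inherits(poly, "radial_poly"))
  a <- poly$monomial_coeffs
  a[1] + a[2] * rho^2 + a[3] * rho^4 + a[4] * rho^6
}

#' Unit-disc inner product of two radial polynomials
#'
#' `<f, g> = 2 * integral_0^1 f(rho) g(rho) rho drho`, evaluated exactly from
#' the monomial coefficients (the product has only even powers).
#'
#' @param f,g [radial_poly()] objects.
#' @return The inner product (mean of f*g over the disc).
#' @export
radial_inner_product <- function(f, g) {
  a <- f$monomial_coeffs
  b <- g$monomial_coeffs
  # coefficient of rho^(2k) in f*g contributes 2/(2k+2) = 1/(k+1)
  prod_coeffs <- numeric(7L)  # powers rho^0 .. rho^12 (even only)
  for (i in 1:4) for (j in 1:4) {
    prod_coeffs[i + j - 1L] <- prod_coeffs[i + j - 1L] + a[i] * b[j]
  }
  sum(prod_coeffs / seq_len(7L))
}

#' Rotationally symmetric Zernike mode
#'
#' The unit-RMS radial Zernike polynomials of azimuthal frequency zero:
#' piston Z0 = 1, defocus Z2 = sqrt(3)(2 rho^2 - 1), primary spherical
#' aberration Z4 = sqrt(5)(6 rho^4 - 6 rho^2 + 1), and secondary spherical
#' aberration Z6 = sqrt(7)(20 rho^6 - 30 rho^4 + 12 rho^2 - 1).
#'
#' @param order Radial order, one of 0, 2, 4, 6.
#' @return A [radial_poly()] with unit RMS over the unit disc.
#' @examples
#' eval_radial_poly(zernike_mode(4), 1)  # sqrt(5)
#' @export
zernike_mode <- function(order) {
  switch(as.character(order),
         "0" = radial_poly(c(1, 0, 0, 0)),
         "2" = radial_poly(sqrt(3) * c(-1, 2, 0, 0)),
         "4" = radial_poly(sqrt(5) * c(1, -6, 6, 0)),
         "6" = radial_poly(sqrt(7) * c(-1, 12, -30, 20)),
         stop("unsupported radial order ", order,
              " (rotationally symmetric modes 0, 2, 4, 6 only)"))
}

#' High-degree LD/HD modes G4 and G6
#'
#' The high-degree modes of the low-degree/high-degree decomposition contain
#' no constant or quadratic monomials. They are built by Gram-Schmidt
#' orthonormalization of the monomial sequence (rho^4, rho^6) under the
#' unit-disc inner product: G4 spans rho^4 alone and G6 is the rho^6
#' direction orthogonalized against G4. The construction is performed
#' numerically at call time, not from hard-coded closed forms.
#'
#' @return A list with elements `g4` and `g6`, each a [radial_poly()] of
#'   unit RMS, mutually orthogonal, with zero constant and rho^2 monomials.
#' @export
build_hd_modes <- function() {
  v4 <- radial_poly(c(0, 0, 1, 0))                       # rho^4
  g4 <- radial_poly(v4$monomial_coeffs /
                      sqrt(radial_inner_product(v4, v4)))
  v6 <- radial_poly(c(0, 0, 0, 1))                       # rho^6
  proj <- radial_inner_product(v6, g4)
  w <- radial_poly(v6$monomial_coeffs - proj * g4$monomial_coeffs)
  g6 <- radial_poly(w$monomial_coeffs /
                      sqrt(radial_inner_product(w, w)))
  list(g4 = g4, g6 = g6)
}

#' Full LD/HD mode set
#'
#' The low-degree members G0 and G2 share the analytic structure of their
#' Zernike counterparts (G0 = Z0, G2 = Z2); the high-degree members come
#' from [build_hd_modes()].
#'
#' @return A list of [radial_poly()] objects `g0`, `g2`, `g4`, `g6`.
#' @export
ldhd_modes <- function() {
  hd <- build_hd_modes()
  list(g0 = zernike_mode(0), g2 = zernike_mode(2),
       g4 = hd$g4, g6 = hd$g6)
}

# 4x4 monomial matrices (rows = monomials 1, rho^2, rho^4, rho^6; columns =
# modes of order 0, 2, 4, 6) and the derived conversion matrices, built once
# at load time by monomial collection: M_G g = M_Z c  =>  g = M_G^{-1} M_Z c.
basis_matrices <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mz <- sapply(c(0, 2, 4, 6),
                   function(n) zernike_mode(n)$monomial_coeffs)
      gm <- ldhd_modes()
      mg <- sapply(gm, function(p) p$monomial_coeffs)
      z2g <- solve(mg, mz)
      cache <<- list(zernike = mz, ldhd = mg,
                     z_to_g = z2g, g_to_z = solve(z2g))
    }
    cache
  }
})

#' Zernike coefficient vector
#'
#' Rotationally symmetric Zernike coefficients (micrometers) over a stated
#' optical zone. Coefficients are zone-specific: the same surface projected
#' over a different zone has different coefficients.
#'
#' @param c0,c2,c4,c6 Coefficients of Z0, Z2, Z4, Z6 in micrometers.
#' @param zone The [optical_zone()] (or diameter in mm) the coefficients
#'   refer to.
#' @return An object of class `zernike_vector`.
#' @export
zernike_vector <- function(c0 = 0, c2 = 0, c4 = 0, c6 = 0, zone) {
  zone <- as_optical_zone(zone)
  v <- c(c0 = unname(c0), c2 = unname(c2), c4 = unname(c4), c6 = unname(c6))
  stopifnot(all(is.finite(v)))
  structure(list(coeffs = v, zone = zone), class = "zernike_vector")
}

#' LD/HD coefficient vector
#'
#' Coefficients (micrometers) of the low-degree/high-degree modes G0, G2,
#' G4, G6 over a stated optical zone.
#'
#' @param g0,g2,g4,g6 Coefficients in micrometers.
#' @param zone The [optical_zone()] (or diameter in mm).
#' @return An object of class `ldhd_vector`.
#' @export
ldhd_vector <- function(g0 = 0, g2 = 0, g4 = 0, g6 = 0, zone) {
  zone <- as_optical_zone(zone)
  v <- c(g0 = unname(g0), g2 = unname(g2), g4 = unname(g4), g6 = unname(g6))
  stopifnot(all(is.finite(v)))
  structure(list(coeffs = v, zone = zone), class = "ldhd_vector")
}

#' @export
print.zernike_vector <- function(x, ...) {
  cat(sprintf("<zernike_vector> zone %.4g mm: c0=%.4f c2=%.4f c4=%.4f c6=%.4f um\n",
              x$zone$diameter_mm, x$coeffs[1], x$coeffs[2], x$coeffs[3],
              x$coeffs[4]))
  invisible(x)
}

#' @export
print.ldhd_vector <- function(x, ...) {
  cat(sprintf("<ldhd_vector> zone %.4g mm: g0=%.4f g2=%.4f g4=%.4f g6=%.4f um\n",
              x$zone$diameter_mm, x$coeffs[1], x$coeffs[2], x$coeffs[3],
              x$coeffs[4]))
  invisible(x)
}

#' Convert Zernike coefficients to LD/HD coefficients
#'
#' The conversion is exact and linear: the wavefront polynomial is expanded
#' in monomials and regrouped so that the low-degree part (g0, g2) carries
#' all constant and rho^2 content (the paraxial curvature matching of the
#' wavefront) and the high-degree part (g4, g6) carries all rho^4 and rho^6
#' content. In closed form: g6 = (10/3) c6; g4 = 6 c4 - (40/3) sqrt(7/5) c6;
#' g2 = c2 - sqrt(15) c4 + 2 sqrt(21) c6.
#'
#' @param z A [zernike_vector()].
#' @return An [ldhd_vector()] over the same zone describing the same
#'   wavefront polynomial.
#' @examples
#' zernike_to_ldhd(zernike_vector(c4 = -0.4, zone = 6))
#' @export
zernike_to_ldhd <- function(z) {
  stopifnot(inherits(z, "zernike_vector"))
  g <- as.numeric(basis_matrices()$z_to_g %*% z$coeffs)
  ldhd_vector(g[1], g[2], g[3], g[4], zone = z$zone)
}

#' Convert LD/HD coefficients to Zernike coefficients
#'
#' Exact inverse of [zernike_to_ldhd()].
#'
#' @param g An [ldhd_vector()].
#' @return A [zernike_vector()] over the same zone.
#' @export
ldhd_to_zernike <- function(g) {
  stopifnot(inherits(g, "ldhd_vector"))
  z <- as.numeric(basis_matrices()$g_to_z %*% g$coeffs)
  zernike_vector(z[1], z[2], z[3], z[4], zone = g$zone)
}

#' Evaluate a coefficient vector as a wavefront over the unit disc
#'
#' Sums coefficient-weighted modes at the given unit-disc radii; used for
#' the pointwise-reconstruction identities between the two bases.
#'
#' @param x A [zernike_vector()] or [ldhd_vector()].
#' @param rho Unit-disc radii in \[0, 1\].
#' @return Wavefront values in micrometers.
#' @export
eval_wavefront <- function(x, rho) {
  m <- if (inherits(x, "zernike_vector")) basis_matrices()$zernike
       else if (inherits(x, "ldhd_vector")) basis_matrices()$ldhd
       else stop("x must be a zernike_vector or ldhd_vector")
  mono <- as.numeric(m %*% x$coeffs)
  mono[1] + mono[2] * rho^2 + mono[3] * rho^4 + mono[4] * rho^6
}
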