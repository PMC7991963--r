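# Independent oracles used across the suite.

# Unit-disc inner product by adaptive quadrature (independent of the
# package's exact monomial arithmetic and fixed Gauss-Legendre rule).
integrate_inner <- function(f, g) {
  stats::integrate(function(rho) 2 * f(rho) * g(rho) * rho, 0, 1,
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Closed-form sagitta references.
sphere_sag <- function(R, r) R - sqrt(R^2 - r^2)
parabola_sag <- function(R, r) r^2 / (2 * R)

# Truncated Taylor expansion of the conic sagitta in mm:
# z(r) = r^2/(2R) + (1+Q) r^4/(8 R^3) + (1+Q)^2 r^6/(16 R^5)
#        + 5 (1+Q)^3 r^8/(128 R^7) + ...
conic_taylor_coeffs <- function(R, Q) {
  c(a2 = 1 / (2 * R), a4 = (1 + Q) / (8 * R^3), a6 = (1 + Q)^2 / (16 * R^5),
    a8 = 5 * (1 + Q)^3 / (128 * R^7))
}
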