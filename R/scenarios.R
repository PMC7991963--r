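# Scenario engine: single ablation plans, the target-asphericity solver, and
# the sweep experiments (spherical corrections, optical-zone sizes,
# asphericity changes, and the presbyopia table).

#' Ablation plan
#'
#' A planned correction: intended paraxial defocus D over a zone S on a
#' pre-operative conic cornea, with the post-operative asphericity set
#' either directly (`target_q1`), through a target change in fourth-order
#' Zernike spherical aberration (`target_dz4_um`, solved numerically), or
#' left at Q0 (conventional, non-custom profile).
#'
#' @param preop A [conic_surface()] (R0, Q0).
#' @param d_correction Intended defocus correction D in diopters.
#' @param zone An [optical_zone()] or a diameter in mm.
#' @param target_q1 Optional target post-operative asphericity Q1.
#' @param target_dz4_um Optional target change in the fourth-order Zernike
#'   wavefront coefficient (micrometers); mutually exclusive with
#'   `target_q1`.
#' @return An object of class `ablation_plan`.
#' @export
ablation_plan <- function(preop, d_correction = 0, zone = 6,
                          target_q1 = NULL, target_dz4_um = NULL) {
  stopifnot(inherits(preop, "conic_surface"), is.numeric(d_correction))
  zone <- as_optical_zone(zone)
  if (!is.null(target_q1) && !is.null(target_dz4_um)) {
    stop("supply at most one of target_q1 and target_dz4_um")
  }
  structure(list(preop = preop, d_correction = d_correction, zone = zone,
                 target_q1 = target_q1, target_dz4_um = target_dz4_um),
            class = "ablation_plan")
}

#' Solve the post-operative asphericity for a target SA change
#'
#' Finds the post-operative conic constant Q1 such that the change in the
#' fourth-order Zernike wavefront coefficient equals the target:
#' \deqn{0.376 \times [\,c_4(R_1, Q_1, S) - c_4(R_0, Q_0, S)\,] =
#'       \Delta z_4^{0,\mathrm{target}}}
#' where R1 follows from the paraxial correction D. The objective is
#' monotone increasing in Q1 on the physical range, so a bracketing root
#' finder on Q1 in \[-3, +1\] is used.
#'
#' @param preop A [conic_surface()].
#' @param d_correction Paraxial correction D in diopters.
#' @param zone An [optical_zone()] or a diameter in mm.
#' @param dz4_target_um Target change in the fourth-order Zernike wavefront
#'   coefficient, micrometers.
#' @param constants A [refractive_constants()] object.
#' @param bracket Search interval for Q1 (default c(-3, 1)).
#' @param tol Convergence tolerance on Q1 (default 1e-10).
#' @return The solved Q1 (scalar).
#' @examples
#' solve_q1_for_target_dz4(conic_surface(7.8, -0.2), 2, 6, -0.40)  # ~ -0.82
#' @export
solve_q1_for_target_dz4 <- function(preop, d_correction, zone, dz4_target_um,
                                    constants = refractive_constants(),
                                    bracket = c(-3, 1), tol = 1e-10) {
  stopifnot(inherits(preop, "conic_surface"))
  zone <- as_optical_zone(zone)
  r1 <- postop_radius(preop$apical_radius_mm, d_correction, constants)
  c4_pre <- project_conic(preop, zone)$coeffs[["c4"]]
  objective <- function(q1) {
    c4_post <- project_conic(conic_surface(r1, q1), zone)$coeffs[["c4"]]
    constants$delta_n * (c4_post - c4_pre) - dz4_target_um
  }
  flo <- objective(bracket[1])
  fhi <- objective(bracket[2])
  if (flo * fhi > 0) {
    stop(sprintf(paste0("target dz4 = %.4g um not bracketable for Q1 in ",
                        "[%.3g, %.3g] (R0 = %.4g, Q0 = %+.4g, D = %.4g, S = %.4g)"),
                 dz4_target_um, bracket[1], bracket[2], preop$apical_radius_mm,
                 preop$asphericity_q, d_correction, zone$diameter_mm))
  }
  stats::uniroot(objective, bracket, f.lower = flo, f.upper = fhi,
                 tol = tol)$root
}

#' Run one ablation plan
#'
#' Composes the pipeline: paraxial post-op radius from D, pre/post conic
#' pair, scalar-product Zernike projection over the zone, wavefront delta
#' with the 0.376 index step, LD/HD conversion, and both dioptric
#' spherical-equivalent readings.
#'
#' @param plan An [ablation_plan()].
#' @param constants A [refractive_constants()] object.
#' @return An object of class `scenario_result`: the plan echo (D, S, R0,
#'   Q0, R1, Q1, dQ), the [wavefront_delta()], and the derived diopter
#'   columns.
#' @examples
#' run_plan(ablation_plan(conic_surface(8.5, 0.5), d_correction = 0,
#'                        zone = 6, target_q1 = -0.5))
#' @export
run_plan <- function(plan, constants = refractive_constants()) {
  stopifnot(inherits(plan, "ablation_plan"))
  preop <- plan$preop
  zone <- plan$zone
  r1 <- postop_radius(preop$apical_radius_mm, plan$d_correction, constants)
  q1 <- if (!is.null(plan$target_q1)) {
    plan$target_q1
  } else if (!is.null(plan$target_dz4_um)) {
    solve_q1_for_target_dz4(preop, plan$d_correction, zone,
                            plan$target_dz4_um, constants)
  } else {
    preop$asphericity_q
  }
  postop <- conic_surface(r1, q1)
  pair <- project_surface_pair(preop, postop, zone)
  delta <- wavefront_delta(pair$pre, pair$post, constants)
  structure(list(d_correction = plan$d_correction,
                 zone = zone,
                 preop = preop, postop = postop,
                 dq = q1 - preop$asphericity_q,
                 delta = delta,
                 dse_zernike = delta$dse_zernike,
                 dse_ldhd = delta$dse_ldhd,
                 shift_zernike = refraction_shift(delta$dse_zernike),
                 shift_ldhd = refraction_shift(delta$dse_ldhd)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(paste0("<scenario_result> D = %+.2f D, S = %.4g mm, ",
                     "R0 = %.4g, Q0 = %+.3g -> R1 = %.4g, Q1 = %+.3g\n"),
              x$d_correction, x$zone$diameter_mm,
              x$preop$apical_radius_mm, x$preop$asphericity_q,
              x$postop$apical_radius_mm, x$postop$asphericity_q))
  print(x$delta)
  invisible(x)
}

#' Flatten scenario results to a data frame
#'
#' One row per result with the fixed column set used by the CSV reports:
#' `D, S, R0, Q0, R1, Q1, dQ, dz0, dz2, dz4, dz6, dg0, dg2, dg4, dg6,
#' dSE_z, dSE_g, shift_z, shift_g` (micrometers for coefficients, diopters
#' for the last four).
#'
#' @param results A `scenario_result` or a list of them.
#' @return A `data.frame`.
#' @export
scenario_table <- function(results) {
  if (inherits(results, "scenario_result")) results <- list(results)
  stopifnot(length(results) > 0,
            all(vapply(results, inherits, logical(1), "scenario_result")))
  rows <- lapply(results, function(x) {
    data.frame(D = x$d_correction,
               S = x$zone$diameter_mm,
               R0 = x$preop$apical_radius_mm,
               Q0 = x$preop$asphericity_q,
               R1 = x$postop$apical_radius_mm,
               Q1 = x$postop$asphericity_q,
               dQ = x$dq,
               dz0 = x$delta$dz$coeffs[["c0"]],
               dz2 = x$delta$dz$coeffs[["c2"]],
               dz4 = x$delta$dz$coeffs[["c4"]],
               dz6 = x$delta$dz$coeffs[["c6"]],
               dg0 = x$delta$dg$coeffs[["g0"]],
               dg2 = x$delta$dg$coeffs[["g2"]],
               dg4 = x$delta$dg$coeffs[["g4"]],
               dg6 = x$delta$dg$coeffs[["g6"]],
               dSE_z = x$dse_zernike,
               dSE_g = x$dse_ldhd,
               shift_z = x$shift_zernike,
               shift_g = x$shift_ldhd)
  })
  do.call(rbind, rows)
}

#' Spherical-correction sweep (conventional ablations)
#'
#' Conventional, non-custom spherically based profiles: both the pre- and
#' post-operative asphericities are zero (Q0 = Q1 = 0) and the correction D
#' is swept, by default from -10 D (myopic) to +6 D (hyperopic) in 1 D
#' steps.
#'
#' @param r0_mm Pre-operative apical radius, mm (default 7.8).
#' @param d_values Corrections in diopters.
#' @param zone An [optical_zone()] or a diameter in mm (default 6).
#' @param constants A [refractive_constants()] object.
#' @return A list of `scenario_result` objects, one per D.
#' @export
run_spherical_sweep <- function(r0_mm = 7.8, d_values = seq(-10, 6, by = 1),
                                zone = 6, constants = refractive_constants()) {
  zone <- as_optical_zone(zone)
  lapply(d_values, function(d) {
    run_plan(ablation_plan(conic_surface(r0_mm, 0), d_correction = d,
                           zone = zone, target_q1 = 0), constants)
  })
}

#' Optical-zone sweep
#'
#' Repeats one spherical correction over a range of zone diameters, by
#' default 5.0 to 8.0 mm in 0.5 mm steps for a -6 D correction, to expose
#' how the Zernike-derived SE grows with zone size while the LD/HD-derived
#' SE stays at the intended correction.
#'
#' @param r0_mm Pre-operative apical radius, mm.
#' @param d_correction Correction in diopters (default -6).
#' @param s_values Zone diameters in mm.
#' @param q0 Pre- and post-operative asphericity (default 0, conventional).
#' @param constants A [refractive_constants()] object.
#' @return A list of `scenario_result` objects, one per S.
#' @export
run_zone_sweep <- function(r0_mm = 7.8, d_correction = -6,
                           s_values = seq(5, 8, by = 0.5), q0 = 0,
                           constants = refractive_constants()) {
  lapply(s_values, function(s) {
    run_plan(ablation_plan(conic_surface(r0_mm, q0), d_correction = d_correction,
                           zone = optical_zone(s), target_q1 = q0), constants)
  })
}

#' Asphericity sweep at constant apical radius
#'
#' Custom aspheric profiles that change the conic constant by dQ while
#' leaving the paraxial curvature untouched (D = 0, R1 = R0). These are the
#' oblate-correction (Q0 = +0.5, dQ < 0) and hyperprolate-correction
#' (Q0 = -0.8, dQ > 0) experiments; the LD/HD defocus delta is identically
#' zero for every row while the Zernike defocus delta varies with dQ.
#'
#' @param preop A [conic_surface()].
#' @param dq_values Asphericity changes Q1 - Q0.
#' @param zone An [optical_zone()] or a diameter in mm.
#' @param constants A [refractive_constants()] object.
#' @return A list of `scenario_result` objects, one per dQ.
#' @export
run_asphericity_sweep <- function(preop, dq_values, zone = 6,
                                  constants = refractive_constants()) {
  stopifnot(inherits(preop, "conic_surface"))
  zone <- as_optical_zone(zone)
  lapply(dq_values, function(dq) {
    run_plan(ablation_plan(preop, d_correction = 0, zone = zone,
                           target_q1 = preop$asphericity_q + dq), constants)
  })
}

#' Presbyopia table: hyperopic corrections with a fixed SA target
#'
#' Custom aspheric ablations for presbyopia in hyperopes: each hyperopic
#' correction D is combined with a post-operative asphericity Q1 solved so
#' that the fourth-order Zernike wavefront coefficient changes by a fixed
#' amount (default -0.40 micrometers, an increase of corneal prolateness
#' that extends depth of focus).
#'
#' @param r0_mm Pre-operative apical radius, mm (default 7.8).
#' @param q0 Pre-operative asphericity (default -0.2).
#' @param zone An [optical_zone()] or a diameter in mm (default 6).
#' @param d_values Hyperopic corrections in diopters (default +2, +4, +6).
#' @param dz4_target_um Target fourth-order Zernike wavefront change,
#'   micrometers (default -0.40).
#' @param constants A [refractive_constants()] object.
#' @return A list of `scenario_result` objects, one per D.
#' @examples
#' scenario_table(presbyopia_table())[, c("D", "Q1", "R1", "dz2", "dg2")]
#' @export
presbyopia_table <- function(r0_mm = 7.8, q0 = -0.2, zone = 6,
                             d_values = c(2, 4, 6), dz4_target_um = -0.40,
                             constants = refractive_constants()) {
  zone <- as_optical_zone(zone)
  lapply(d_values, function(d) {
    run_plan(ablation_plan(conic_surface(r0_mm, q0), d_correction = d,
                           zone = zone, target_dz4_um = dz4_target_um),
             constants)
  })
}
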