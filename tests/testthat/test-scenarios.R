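test_that("a null plan produces a zero delta row", {
  res <- run_plan(ablation_plan(conic_surface(7.8, -0.2), d_correction = 0,
                                zone = 6))
  tab <- scenario_table(res)
  expect_equal(unname(unlist(tab[, c("dz0", "dz2", "dz4", "dz6",
                                     "dg0", "dg2", "dg4", "dg6",
                                     "dSE_z", "dSE_g")])),
               rep(0, 10), tolerance = 1e-12)
  expect_equal(tab$R1, tab$R0)
  expect_equal(tab$Q1, tab$Q0)
})

test_that("asphericity-only plans reproduce the oblate-cornea scenario", {
  # flat oblate cornea (R0 = 8.5, Q0 = +0.5), D = 0, 6 mm zone
  preop <- conic_surface(8.5, 0.5)
  res <- run_asphericity_sweep(preop, dq_values = seq(-0.1, -1, by = -0.1))
  tab <- scenario_table(res)
  expect_lt(abs(tab$dz2[1] - (-0.21)), 0.005)             # dQ = -0.1, printed precision
  expect_equal(tab$shift_z[10], 1.55, tolerance = 0.03)   # dQ = -1
  # a pure asphericity change leaves the LD/HD defocus at zero up to the
  # order-6 truncation leakage, far below the Zernike-side variation
  expect_lt(max(abs(tab$dg2)), 0.02)
  expect_gt(min(abs(tab$dz2)) / max(abs(tab$dg2)), 10)
  # deltas vary monotonically with dQ
  for (col in c("dz2", "dz4", "dz6", "dg4", "dg6")) {
    expect_true(all(diff(tab[[col]]) < 0) || all(diff(tab[[col]]) > 0))
  }
})

test_that("hyperprolate-cornea scenario reproduces the published shifts", {
  preop <- conic_surface(7.3, -0.8)
  res <- run_asphericity_sweep(preop, dq_values = seq(0.1, 0.8, by = 0.1))
  tab <- scenario_table(res)
  expect_lt(abs(tab$dz2[1] - 0.29), 0.005)                 # dQ = +0.1, printed precision
  expect_lt(abs(tab$shift_z[1] - (-0.23)), 0.005)
  expect_equal(tab$dz2[8], 2.49, tolerance = 0.01)         # dQ = +0.8
  expect_equal(tab$shift_z[8], -1.92, tolerance = 0.01)
  expect_lt(max(abs(tab$dg2)), 0.02)
})

test_that("spherical sweep: SA sign pattern and LD/HD SE fidelity", {
  res <- run_spherical_sweep(7.8, d_values = seq(-10, 6, by = 1), zone = 6)
  tab <- scenario_table(res)
  myopic <- tab$D < 0
  hyperopic <- tab$D > 0
  expect_true(all(tab$dz4[myopic] < 0) && all(tab$dg4[myopic] < 0))
  expect_true(all(tab$dz4[hyperopic] > 0) && all(tab$dg4[hyperopic] > 0))
  expect_lt(max(abs(tab$dSE_g - tab$D)), 0.01)
  # Zernike SE magnitude always overshoots the intended correction
  nz <- tab$D != 0
  expect_true(all(abs(tab$dSE_z[nz]) > abs(tab$D[nz])))
})

test_that("zone sweep: SA deltas scale as S^4 and S^6 to leading order", {
  s_values <- seq(5, 8, by = 0.5)
  res <- run_zone_sweep(7.8, d_correction = -6, s_values = s_values)
  tab <- scenario_table(res)
  # LD/HD SE stays at the intended correction up to truncation leakage,
  # while the Zernike SE overestimate grows steadily with the zone diameter
  expect_lt(max(abs(tab$dSE_g - (-6))), 0.05)
  excess <- abs(tab$dSE_z) - 6
  expect_true(all(diff(excess) > 0))
  expect_gt(min(excess) / max(abs(tab$dSE_g + 6)), 5)
  # log-log slopes: 4 and 6 from the leading S^4 / S^6 terms, with a known
  # positive bias from the next-order term of the conic series (up to ~28%
  # of the leading term at S = 8 on this geometry)
  slope4 <- stats::coef(stats::lm(log(abs(tab$dz4)) ~ log(s_values)))[2]
  slope6 <- stats::coef(stats::lm(log(abs(tab$dz6)) ~ log(s_values)))[2]
  expect_gt(slope4, 4); expect_lt(slope4, 4.5)
  expect_gt(slope6, 6); expect_lt(slope6, 6.7)
})

test_that("Q1 solver hits the SA target and recovers parameters", {
  preop <- conic_surface(7.8, -0.2)
  cst <- refractive_constants()
  # fixed point: zero target with no correction returns Q0
  expect_equal(solve_q1_for_target_dz4(preop, 0, 6, 0), -0.2,
               tolerance = 1e-8)
  # published presbyopia rows
  expect_equal(solve_q1_for_target_dz4(preop, 2, 6, -0.40), -0.82,
               tolerance = 0.005)
  expect_equal(solve_q1_for_target_dz4(preop, 4, 6, -0.40), -0.84,
               tolerance = 0.005)
  # recovery loop: pick Q1, measure its dz4, re-solve
  c4_pre <- project_conic(preop, 6)$coeffs[["c4"]]
  for (q1 in c(-1.5, -0.9, -0.3, 0.2, 0.5)) {
    for (D in c(0, 3)) {
      r1 <- postop_radius(7.8, D, cst)
      dz4 <- 0.376 * (project_conic(conic_surface(r1, q1), 6)$coeffs[["c4"]] -
                        c4_pre)
      expect_lt(abs(solve_q1_for_target_dz4(preop, D, 6, dz4) - q1), 1e-6)
    }
  }
  # unreachable target fails loudly
  expect_error(solve_q1_for_target_dz4(preop, 0, 6, -50), "not bracketable")
})

test_that("presbyopia table reproduces all published columns", {
  tab <- scenario_table(presbyopia_table())
  # columns: D, Q1, R1, dz2, dg2, dSE_z, dSE_g
  published <- data.frame(
    D = c(2, 4, 6),
    Q1 = c(-0.82, -0.84, -0.86),
    R1 = c(7.49, 7.20, 6.94),
    dz2 = c(1.12, 3.72, 6.32),
    dg2 = c(2.59, 5.19, 7.78),
    dSE_z = c(0.86, 2.86, 4.86),
    dSE_g = c(2.00, 4.00, 6.00))
  for (col in names(published)) {
    expect_equal(tab[[col]], published[[col]], tolerance = 0.02,
                 label = paste("column", col))
  }
  # the SA target is met exactly in every row
  expect_equal(tab$dz4, rep(-0.40, 3), tolerance = 1e-8)
  # accompanying LD/HD SA change
  expect_equal(tab$dg4, rep(-2.27, 3), tolerance = 0.01)
})

test_that("every scenario row reconstructs identically in both bases", {
  rows <- c(run_spherical_sweep(7.8, d_values = c(-10, -6, 3, 6)),
            run_asphericity_sweep(conic_surface(8.5, 0.5), c(-0.3, -0.8)),
            presbyopia_table(d_values = 4))
  rho <- seq(0, 1, length.out = 101)
  for (x in rows) {
    expect_lt(max(abs(eval_wavefront(x$delta$dz, rho) -
                        eval_wavefront(x$delta$dg, rho))), 1e-9)
  }
})

test_that("plan validation rejects conflicting targets", {
  expect_error(ablation_plan(conic_surface(7.8, 0), target_q1 = 0,
                             target_dz4_um = -0.4), "at most one")
})
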