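geo <- default_geometry()
mat <- default_materials()

test_that("the unstressed reference state has zero residual; pure pressure shifts it by -P", {
  expect_equal(pressure_residual(geo$A, 1, 0, geo, mat), 0)
  expect_equal(pressure_residual(geo$A, 1, mmHg_to_kPa(80), geo, mat),
               -mmHg_to_kPa(80))
  expect_equal(residual_deformed_frame(geo$A, 1, mmHg_to_kPa(50), geo, mat),
               -mmHg_to_kPa(50), tolerance = 1e-10)
})

test_that("pressure residual matches the dense trapezoid oracle", {
  # frozen from an independent scipy evaluation of the same balance
  expect_equal(pressure_residual(1.05 * geo$A, 1, 0, geo, mat),
               0.5738510924360325, tolerance = 1e-9)
  for (st in list(c(1.05 * geo$A, 1, 0), c(1.2 * geo$A, 1.4, 10),
                  c(0.9 * geo$A, 1.8, 5))) {
    expect_equal(pressure_residual(st[1], st[2], st[3], geo, mat),
                 trapz_residual(st[1], st[2], st[3], geo, mat),
                 tolerance = 1e-6)
  }
})

test_that("reference-frame and deformed-frame residuals agree", {
  set.seed(11)
  for (i in 1:10) {
    a <- runif(1, 0.8, 1.3) * geo$A
    g <- runif(1, 1, 2)
    P <- runif(1, 0, mmHg_to_kPa(110))
    expect_equal(pressure_residual(a, g, P, geo, mat),
                 residual_deformed_frame(a, g, P, geo, mat),
                 tolerance = 1e-6)
  }
})

test_that("the solver reproduces oracle roots and is self-consistent", {
  c0 <- solve_configuration(1, 0, geo, mat)
  expect_equal(c(c0$a, c0$b, c0$c, c0$d), c(geo$A, geo$B, geo$C, geo$D),
               tolerance = 1e-9)
  # frozen from bisection on an independent scipy residual
  c110 <- solve_configuration(1, mmHg_to_kPa(110), geo, mat)
  expect_equal(c110$a, 2.5882344373921162, tolerance = 1e-7)
  c15 <- solve_configuration(1.5, 0, geo, mat)
  expect_equal(c15$a, 1.9757611362131111, tolerance = 1e-7)
  # the grown intima is confined by the outer layers
  expect_lt(c15$a, 1.5 * geo$A)
  for (cfg in list(c0, c110, c15)) {
    expect_lt(abs(pressure_residual(cfg$a, cfg$g, cfg$P_kPa, geo, mat)), 1e-8)
  }
})

test_that("solved lumen radius increases with pressure at fixed growth", {
  a_vals <- vapply(c(0, 30, 60, 90, 110), function(P)
    solve_configuration(1.2, mmHg_to_kPa(P), geo, mat)$a, numeric(1))
  expect_true(all(diff(a_vals) > 0))
})

test_that("warm-started solves agree with cold solves", {
  cold <- solve_configuration(1.8, mmHg_to_kPa(80), geo, mat)
  warm <- solve_configuration(1.8, mmHg_to_kPa(80), geo, mat,
                              a_init = 0.9 * cold$a)
  expect_equal(warm$a, cold$a, tolerance = 1e-8)
})

test_that("stress profile satisfies boundary conditions, interface continuity and the equilibrium ODE", {
  cfg <- solve_configuration(1.3, mmHg_to_kPa(80), geo, mat)
  prof <- stress_profile(cfg, mat, n_points = 400)
  expect_equal(prof$Trr_kPa[1], -cfg$P_kPa, tolerance = 1e-6)
  expect_equal(prof$Trr_kPa[nrow(prof)], 0, tolerance = 1e-6)
  # radial stress continuous across both interfaces
  for (lay in list(c("intima", "media"), c("media", "adventitia"))) {
    left <- prof[prof$layer == lay[1], ]
    right <- prof[prof$layer == lay[2], ]
    expect_equal(left$Trr_kPa[nrow(left)], right$Trr_kPa[1], tolerance = 1e-6)
  }
  # d(Trr)/dr = (Ttheta - Trr)/r at layer-interior midpoints
  for (lay in c("intima", "media", "adventitia")) {
    p <- prof[prof$layer == lay, ]
    fd <- diff(p$Trr_kPa) / diff(p$r_mm)
    rhs <- (p$Ttheta_kPa - p$Trr_kPa) / p$r_mm
    rhs_mid <- (rhs[-1] + rhs[-length(rhs)]) / 2
    scale <- max(abs(rhs_mid), 1)
    expect_lt(max(abs(fd - rhs_mid)) / scale, 1e-4)
  }
})

test_that("unsolved configurations are rejected by the stress profile", {
  cfg <- configuration(1.3 * geo$A, 1, 0, geo)
  expect_error(stress_profile(cfg, mat), "not in equilibrium")
})

test_that("the reference stress state is stress-free", {
  cfg <- solve_configuration(1, 0, geo, mat)
  prof <- stress_profile(cfg, mat, n_points = 60)
  expect_lt(max(abs(prof$Trr_kPa)), 1e-8)
  expect_lt(max(abs(prof$Ttheta_kPa)), 1e-8)
})
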