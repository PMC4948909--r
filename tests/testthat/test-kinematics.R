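test_that("reference geometry is built from lumen area and thicknesses", {
  g <- reference_geometry(pi, 0.01, 0.32, 0.34)
  expect_equal(c(g$A, g$B, g$C, g$D), c(1, 1.01, 1.33, 1.67))
  expect_equal(reference_geometry(12)$A, sqrt(12 / pi))
  expect_equal(reference_geometry(5)$A, sqrt(5 / pi))
  expect_error(reference_geometry(-1), "positive")
  expect_error(reference_geometry(12, 0), "positive")
})

test_that("growth factor follows the exponential law and the rate identity", {
  expect_equal(growth_factor(0, 0.5), 1)
  expect_equal(growth_factor(2, 0.5), exp(0.5))
  expect_equal(growth_factor(4, 0.5), exp(1))
  expect_error(growth_factor(-1), "non-negative")
  # volumetric production rate Trace(Fg^-1 dFg/dt) = 2 g'/g = Gamma
  Gamma <- 0.5; t <- 1.7; h <- 1e-6
  gdot <- (growth_factor(t + h, Gamma) - growth_factor(t - h, Gamma)) / (2 * h)
  expect_equal(2 * gdot / growth_factor(t, Gamma), Gamma, tolerance = 1e-8)
})

test_that("outer radii follow incompressibility and conserve layer areas", {
  geo <- default_geometry()
  expect_equal(unname(radii_from_lumen(geo$A, 1, geo)),
               c(geo$B, geo$C, geo$D))
  g11 <- reference_geometry(pi, 0.01, 0.32, 0.34)
  expect_equal(unname(radii_from_lumen(1, 2, g11)["b"]), sqrt(1.0804))
  set.seed(42)
  for (i in 1:20) {
    a <- runif(1, 0.3, 4); g <- runif(1, 1, 6)
    r <- radii_from_lumen(a, g, geo)
    expect_equal(pi * (r[["b"]]^2 - a^2), g^2 * pi * (geo$B^2 - geo$A^2),
                 tolerance = 1e-12)
    expect_equal(r[["c"]]^2 - r[["b"]]^2, geo$C^2 - geo$B^2, tolerance = 1e-12)
    expect_equal(r[["d"]]^2 - r[["c"]]^2, geo$D^2 - geo$C^2, tolerance = 1e-12)
    expect_true(all(diff(c(a, r)) > 0))
  }
})

test_that("stretch field jumps by g at the IEL and matches its endpoints", {
  geo <- default_geometry()
  set.seed(7)
  for (i in 1:20) {
    a <- runif(1, 0.5, 3); g <- runif(1, 1, 4)
    cfg <- configuration(a, g, 0, geo)
    eps <- 1e-9
    # F = Fe Fg with Fg jumping from diag(g, g) to I across the IEL, while
    # the deformation map r(R) stays continuous: the elastic hoop stretch
    # must jump by exactly the growth factor
    expect_equal(g * stretch_field(cfg, geo$B - eps),
                 stretch_field(cfg, geo$B + eps), tolerance = 1e-6)
    expect_equal(stretch_field(cfg, geo$A), a / (g * geo$A))
    expect_equal(stretch_field(cfg, geo$D), cfg$d / geo$D)
  }
  cfg <- configuration(geo$A, 1, 0, geo)
  R <- seq(geo$A, geo$D, length.out = 50)
  expect_equal(stretch_field(cfg, R), rep(1, 50))
  expect_error(stretch_field(cfg, geo$D + 1), "outside")
})

test_that("deformation map is monotone with the morphoelastic radial derivative", {
  geo <- default_geometry()
  cfg <- configuration(1.7, 2.2, 0, geo)
  r_of <- function(R) ifelse(R <= geo$B,
                             sqrt(cfg$a^2 + cfg$g^2 * (R^2 - geo$A^2)),
                             sqrt(cfg$b^2 + R^2 - geo$B^2))
  R_in <- seq(geo$A, geo$B, length.out = 30)
  R_out <- seq(geo$B, geo$D, length.out = 60)
  expect_true(all(diff(r_of(c(R_in, R_out[-1]))) > 0))
  h <- 1e-7
  fd <- (r_of(R_in[5:25] + h) - r_of(R_in[5:25] - h)) / (2 * h)
  expect_equal(fd, cfg$g^2 * R_in[5:25] / r_of(R_in[5:25]), tolerance = 1e-6)
  fd <- (r_of(R_out[5:55] + h) - r_of(R_out[5:55] - h)) / (2 * h)
  expect_equal(fd, R_out[5:55] / r_of(R_out[5:55]), tolerance = 1e-6)
})

test_that("morphometrics satisfy their defining identities and limits", {
  geo <- default_geometry()
  cfg <- configuration(1.5, 2, 0, geo)
  m <- morphometrics(cfg)
  expect_equal(m$plaque_area, m$iel_area - m$lumen_area)
  expect_equal(m$stenosis, m$plaque_area / m$iel_area)
  # grown plaque area is g^2 times the reference intima area, any pressure
  g11 <- reference_geometry(pi, 0.01, 0.32, 0.34)
  m2 <- morphometrics(configuration(1, 2, 0, g11))
  expect_equal(m2$plaque_area, 4 * pi * (1.01^2 - 1), tolerance = 1e-12)
  # healthy limit: ungrown reference state has the baseline thin-intima stenosis
  m0 <- morphometrics(configuration(geo$A, 1, 0, geo))
  expect_equal(m0$stenosis, (geo$B^2 - geo$A^2) / geo$B^2)
  # near-occlusion limit
  mocc <- morphometrics(configuration(1e-8, 2, 0, geo))
  expect_gt(mocc$stenosis, 0.999)
})

test_that("stenosis is invariant to a common rescaling of all radii", {
  geo <- default_geometry()
  cfg <- configuration(1.4, 1.8, 0, geo)
  for (kappa in c(0.5, 2, 3.7)) {
    geo2 <- structure(lapply(unclass(geo), function(x) kappa * x),
                      class = "reference_geometry")
    cfg2 <- configuration(kappa * 1.4, 1.8, 0, geo2)
    expect_equal(morphometrics(cfg2)$stenosis, morphometrics(cfg)$stenosis,
                 tolerance = 1e-12)
  }
})
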