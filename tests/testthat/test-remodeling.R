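test_that("trajectories start at the baseline stenosis and grow the plaque monotonically", {
  cv <- cached_curve(12, P_mmHg = 0)
  geo <- default_geometry()
  expect_equal(cv$stenosis_fraction[1], (geo$B^2 - geo$A^2) / geo$B^2,
               tolerance = 1e-9)
  expect_true(all(diff(cv$stenosis_fraction) > 0))
  expect_true(all(diff(cv$plaque_area_mm2) > 0))
  expect_true(all(diff(cv$iel_area_mm2) > 0))
  expect_gte(max(cv$stenosis_fraction), 0.9)
})

test_that("curves against stenosis are invariant to the growth rate", {
  geo <- default_geometry()
  mat <- default_materials()
  c1 <- simulate_remodeling(geo, mat, P_mmHg = 0, Gamma = 0.25, n_steps = 80)
  c2 <- simulate_remodeling(geo, mat, P_mmHg = 0, Gamma = 0.5, n_steps = 80)
  expect_equal(c1$stenosis_fraction, c2$stenosis_fraction, tolerance = 1e-10)
  expect_equal(c1$lumen_area_mm2, c2$lumen_area_mm2, tolerance = 1e-8)
  # Gamma only rescales the clock
  expect_equal(c1$t_years, 2 * c2$t_years, tolerance = 1e-10)
})

test_that("critical stenosis detection recovers an analytic parabola vertex", {
  S <- seq(0.01, 0.9, length.out = 80)
  cv <- fake_curve(S, 1 - (S - 0.2)^2)
  cs <- critical_stenosis(cv)
  expect_true(cs$present)
  expect_equal(cs$S_star, 0.2, tolerance = 1e-4)
  # monotone data has no interior maximum
  mono <- critical_stenosis(fake_curve(S, 2 - S))
  expect_false(mono$present)
  expect_true(is.na(mono$S_star))
  expect_error(critical_stenosis(fake_curve(S[1:5], S[1:5])), "at least 10")
})

test_that("compensation slope behaves on analytic curves", {
  S <- seq(0.01, 0.5, length.out = 50)
  flat <- fake_curve(S, rep(10, 50))
  expect_equal(compensation_slope(flat, plaque_area_window = 5), 0,
               tolerance = 1e-10)
  expect_error(compensation_slope(flat, plaque_area_window = 1e-6),
               "fewer than 2")
})

test_that("in-vivo curves shrink the lumen from the outset", {
  cv <- cached_curve(12, P_mmHg = 110)
  expect_true(all(diff(cv$lumen_area_mm2) < 1e-9))
  expect_lt(compensation_slope(cv), 0)
})

test_that("at fixed stenosis the in-vivo lumen area increases with pressure", {
  c50 <- cached_curve(12, P_mmHg = 50)
  c110 <- cached_curve(12, P_mmHg = 110)
  S_common <- seq(0.1, 0.8, by = 0.1)
  L50 <- approx(c50$stenosis_fraction, c50$lumen_area_mm2, S_common)$y
  L110 <- approx(c110$stenosis_fraction, c110$lumen_area_mm2, S_common)$y
  expect_true(all(L110 > L50))
})

test_that("ex-vivo and in-vivo geometry differ as expected at matched growth", {
  geo <- default_geometry()
  mat <- default_materials()
  tab <- exvivo_invivo_table(1.5, geo, mat, P_invivo_mmHg = 80)
  rel <- setNames(tab$relation, tab$metric)
  expect_equal(rel[["iel_area_mm2"]], "smaller")
  expect_equal(rel[["lumen_area_mm2"]], "smaller")
  expect_equal(rel[["plaque_area_mm2"]], "same")
  expect_equal(rel[["stenosis_fraction"]], "larger")
  pl <- tab[tab$metric == "plaque_area_mm2", ]
  expect_equal(pl$exvivo, pl$invivo, tolerance = 1e-10)
  # at g = 1 the unpressurized state is the reference; pressure dilates
  tab1 <- exvivo_invivo_table(1, geo, mat, P_invivo_mmHg = 80)
  expect_equal(tab1$exvivo[tab1$metric == "lumen_area_mm2"], 12,
               tolerance = 1e-7)
  expect_equal(rel <- tab1$relation[tab1$metric == "lumen_area_mm2"], "smaller")
})

test_that("trajectory CSV round trip preserves the curve", {
  cv <- cached_curve(12, P_mmHg = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(cv, path)
  back <- read_trajectory(path)
  expect_s3_class(back, "remodeling_curve")
  expect_equal(back$lumen_area_mm2, cv$lumen_area_mm2, tolerance = 1e-10)
  expect_equal(back$stenosis_fraction, cv$stenosis_fraction, tolerance = 1e-10)
})
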