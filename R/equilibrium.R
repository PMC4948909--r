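# Nonlinear equilibrium of the pressurized, grown three-layer cylinder.
#
# The balance integral over each layer splits into a Neo-Hookean part, which
# has a closed form under the substitution u = R^2, and (for media and
# adventitia) a fiber exponential part that is integrated numerically. The
# closed form matters near lumen collapse, where alpha^-4 in the thin intima
# spans many decades and defeats adaptive quadrature.

# int_{u1}^{u2} mu * (1/u - s^2 u / (m + s u)^2) du,
# the Neo-Hookean contribution 2*mu*(1 - alpha^-4) dR/R with u = R^2 and
# alpha^2 = (m + s u) / (s u).
.nh_layer_integral <- function(mu, m, s, u1, u2) {
  f <- function(u) log(u) - log(m + s * u) - m / (m + s * u)
  mu * (f(u2) - f(u1))
}

.layer_quad <- function(fun, lower, upper, rel_tol, layer) {
  out <- tryCatch(
    stats::integrate(fun, lower, upper, rel.tol = rel_tol, abs.tol = 1e-12),
    error = function(e)
      stop(sprintf("quadrature failed in the %s over [%.6g, %.6g]: %s",
                   layer, lower, upper, conditionMessage(e)), call. = FALSE))
  out$value
}

# fiber part of the reference-frame integrand over [R1, R2];
# alpha(R) = sqrt(1 + mprime / R^2) with mprime = b^2 - B^2
.fiber_layer_integral <- function(params, mprime, R1, R2, rel_tol, layer) {
  if (params$eta == 0) return(0)
  f <- function(R) {
    alpha <- sqrt(1 + mprime / R^2)
    .cap_check(params, alpha)
    fg <- fiber_terms(params, alpha)
    4 * params$eta * fg$F * .fiber_exp(params, fg$G) / R
  }
  .layer_quad(f, R1, R2, rel_tol, layer)
}

#' Pressure-balance residual (reference frame)
#'
#' The net of the luminal pressure against the integrated radial-stress
#' build-up across the three layers, expressed over the reference radial
#' coordinate:
#' `-P + int_A^B 2 mu1 (1 - alpha^-4) dR/R + int_B^C {...media...} dR/R +
#'  int_C^D {...adventitia...} dR/R`,
#' with the elastic stretch profile of [stretch_field()]. A zero residual is
#' mechanical equilibrium; the residual is empirically strictly increasing in
#' `a`, which the root solver exploits.
#'
#' @param a trial deformed lumen radius, mm (> 0).
#' @param g growth factor.
#' @param P_kPa luminal pressure, kPa.
#' @param geometry a [reference_geometry()] object.
#' @param materials a [wall_materials()] object.
#' @param rel_tol relative quadrature tolerance for the fiber terms.
#' @return residual in kPa.
#' @export
#' @examples
#' geo <- reference_geometry(12)
#' pressure_residual(geo$A, 1, 0, geo, wall_materials())  # 0: reference state
pressure_residual <- function(a, g, P_kPa, geometry, materials,
                              rel_tol = 1e-10) {
  stopifnot(inherits(geometry, "reference_geometry"),
            inherits(materials, "wall_materials"))
  if (a <= 0) stop("'a' must be positive")
  A <- geometry$A; B <- geometry$B; C <- geometry$C; D <- geometry$D
  b2 <- a^2 + g^2 * (B^2 - A^2)
  mp <- b2 - B^2
  I1 <- .nh_layer_integral(materials$intima$mu, a^2 - g^2 * A^2, g^2, A^2, B^2)
  I2 <- .nh_layer_integral(materials$media$mu, mp, 1, B^2, C^2) +
    .fiber_layer_integral(materials$media, mp, B, C, rel_tol, "media")
  I3 <- .nh_layer_integral(materials$adventitia$mu, mp, 1, C^2, D^2) +
    .fiber_layer_integral(materials$adventitia, mp, C, D, rel_tol, "adventitia")
  -P_kPa + I1 + I2 + I3
}

#' Pressure-balance residual (deformed frame)
#'
#' The same balance expressed with deformed-frame integrals of
#' [deformed_integrand()] over `dr/r`. Since `dr/r = alpha^-2 dR/R` the two
#' forms are identical analytically; this one is retained purely as a
#' cross-validation oracle for [pressure_residual()].
#'
#' @inheritParams pressure_residual
#' @return residual in kPa.
#' @export
residual_deformed_frame <- function(a, g, P_kPa, geometry, materials,
                                    rel_tol = 1e-10) {
  stopifnot(inherits(geometry, "reference_geometry"),
            inherits(materials, "wall_materials"))
  if (a <= 0) stop("'a' must be positive")
  r <- radii_from_lumen(a, g, geometry)
  b <- r[["b"]]; cc <- r[["c"]]; d <- r[["d"]]
  m2 <- g^2 * geometry$A^2 - a^2     # intima: alpha^2 = r^2 / (r^2 + m2)
  mp <- b^2 - geometry$B^2           # outer:  alpha^2 = r^2 / (r^2 - mp)
  I1 <- .layer_quad(function(r) {
    alpha <- sqrt(r^2 / (r^2 + m2))
    deformed_integrand(materials$intima, alpha) / r
  }, a, b, rel_tol, "intima")
  I2 <- .layer_quad(function(r) {
    alpha <- sqrt(r^2 / (r^2 - mp))
    deformed_integrand(materials$media, alpha) / r
  }, b, cc, rel_tol, "media")
  I3 <- .layer_quad(function(r) {
    alpha <- sqrt(r^2 / (r^2 - mp))
    deformed_integrand(materials$adventitia, alpha) / r
  }, cc, d, rel_tol, "adventitia")
  -P_kPa + I1 + I2 + I3
}

#' Solver settings
#'
#' @param rel_tol relative quadrature tolerance per layer.
#' @param root_tol absolute tolerance on the lumen radius root, mm.
#' @param expand geometric bracket expansion factor.
#' @param max_iter maximum bracketing iterations.
#' @param check_monotone if `TRUE`, probe the residual on a coarse grid across
#'   the bracket and warn if it is not non-decreasing (root multiplicity
#'   would make the returned equilibrium non-unique).
#' @return object of class `solver_settings`.
#' @export
solver_settings <- function(rel_tol = 1e-10, root_tol = 1e-10, expand = 1.1,
                            max_iter = 200, check_monotone = FALSE) {
  stopifnot(rel_tol > 0, root_tol > 0, expand > 1, max_iter >= 10)
  structure(list(rel_tol = rel_tol, root_tol = root_tol, expand = expand,
                 max_iter = max_iter, check_monotone = check_monotone),
            class = "solver_settings")
}

#' Solve the equilibrium configuration at given growth and pressure
#'
#' Finds the deformed lumen radius `a` at which [pressure_residual()]
#' vanishes, brackets the root and refines it with Brent's method. The outer
#' radii then follow kinematically via [radii_from_lumen()].
#'
#' Bracketing walks outward from `1.05 * g * A` (or from `a_init` when warm
#' starting along a trajectory). Probe evaluations that overflow the fiber
#' exponential (arbitrarily large positive stress) are treated as `+Inf`,
#' which has the correct sign for the monotone residual; the final bracket
#' endpoints are always finite.
#'
#' @param g growth factor (>= 1 for grown states).
#' @param P_kPa luminal pressure, kPa (>= 0).
#' @param geometry a [reference_geometry()] object.
#' @param materials a [wall_materials()] object.
#' @param settings a [solver_settings()] object.
#' @param a_init optional warm-start guess for the root, mm.
#' @return a [configuration()] with attribute `residual` (kPa at the root).
#' @export
#' @examples
#' geo <- reference_geometry(12)
#' solve_configuration(1, mmHg_to_kPa(80), geo, wall_materials())
solve_configuration <- function(g, P_kPa, geometry, materials,
                                settings = solver_settings(), a_init = NULL) {
  stopifnot(inherits(geometry, "reference_geometry"),
            inherits(materials, "wall_materials"),
            inherits(settings, "solver_settings"))
  if (g <= 0) stop("'g' must be positive")
  if (P_kPa < 0) stop("'P_kPa' must be non-negative")
  probe <- function(a)
    tryCatch(pressure_residual(a, g, P_kPa, geometry, materials,
                               rel_tol = settings$rel_tol),
             error = function(e) Inf)
  it <- 0L
  hi <- if (is.null(a_init)) 1.05 * g * geometry$A else 1.2 * a_init
  v_hi <- probe(hi)
  while (is.finite(v_hi) && v_hi < 0 && it < settings$max_iter) {
    hi <- hi * settings$expand
    v_hi <- probe(hi)
    it <- it + 1L
  }
  if (is.finite(v_hi) && v_hi < 0)
    stop(sprintf(paste0("no sign change found while expanding the bracket ",
                        "(g = %.4g, P = %.4g kPa); residual at a = %.6g mm ",
                        "is %.6g kPa"), g, P_kPa, hi, v_hi))
  # pull the upper end back onto the finite branch if it overflowed
  while (!is.finite(v_hi) && it < settings$max_iter) {
    cand <- hi * 0.98
    v <- probe(cand)
    if (is.finite(v) && v < 0) break  # narrow finite band; keep hi, bisect below
    hi <- cand; v_hi <- v
    it <- it + 1L
  }
  if (!is.finite(v_hi)) {
    # bisect between a point below (finite) and hi (+Inf) on finiteness
    lo_f <- hi * 0.98
    for (k in seq_len(60)) {
      mid <- (lo_f + hi) / 2
      v <- probe(mid)
      if (is.finite(v) && v > 0) { hi <- mid; v_hi <- v; break }
      if (is.finite(v)) lo_f <- mid else hi <- mid
    }
    if (!is.finite(v_hi))
      stop(sprintf("could not find a finite positive residual near a = %.6g mm (g = %.4g)",
                   hi, g))
  }
  lo <- hi * 0.95
  v_lo <- probe(lo)
  while (!(is.finite(v_lo) && v_lo < 0) && it < settings$max_iter) {
    lo <- lo * 0.95
    v_lo <- probe(lo)
    it <- it + 1L
  }
  if (!(is.finite(v_lo) && v_lo < 0))
    stop(sprintf(paste0("no sign change found while lowering the bracket ",
                        "(g = %.4g, P = %.4g kPa); residual at a = %.6g mm ",
                        "is %.6g kPa"), g, P_kPa, lo, v_lo))
  if (settings$check_monotone) {
    grid <- seq(lo, hi, length.out = 5)
    vals <- vapply(grid, probe, numeric(1))
    fin <- is.finite(vals)
    if (any(diff(vals[fin]) < 0))
      warning(sprintf("pressure residual is not monotone across [%.5g, %.5g] mm; the returned root may not be unique",
                      lo, hi))
  }
  root <- stats::uniroot(probe, lower = lo, upper = hi,
                         f.lower = v_lo, f.upper = v_hi,
                         tol = settings$root_tol)
  cfg <- configuration(root$root, g, P_kPa, geometry)
  attr(cfg, "residual") <- probe(root$root)
  cfg
}

#' Radial and hoop Cauchy stress profiles
#'
#' Evaluates the radial Cauchy stress `T_rr(r)` across the deformed wall by
#' the piecewise deformed-frame integrals, anchored at `T_rr(a) = -P` on the
#' intima branch and `T_rr(d) = 0` on the adventitia branch (continuity of
#' the two anchors at the interfaces holds because the configuration is in
#' equilibrium, and is a useful numerical check). The hoop stress follows
#' from `T_theta = T_rr + alpha * d(omega)/d(alpha)`.
#'
#' @param config a solved [configuration()] (the pressure residual is checked
#'   and must be below `check_tol`).
#' @param materials a [wall_materials()] object.
#' @param n_points grid points across the wall.
#' @param rel_tol quadrature tolerance.
#' @param check_tol equilibrium tolerance (kPa) used to reject unsolved
#'   configurations.
#' @return data frame of class `stress_profile` with columns `r_mm`,
#'   `Trr_kPa`, `Ttheta_kPa`, `layer`.
#' @export
stress_profile <- function(config, materials, n_points = 200,
                           rel_tol = 1e-10, check_tol = 1e-4) {
  stopifnot(inherits(config, "configuration"),
            inherits(materials, "wall_materials"), n_points >= 9)
  res <- pressure_residual(config$a, config$g, config$P_kPa, config$geometry,
                           materials, rel_tol = rel_tol)
  if (abs(res) > check_tol)
    stop(sprintf("configuration is not in equilibrium (residual %.3g kPa); solve it first",
                 res))
  a <- config$a; b <- config$b; cc <- config$c; d <- config$d
  m2 <- config$g^2 * config$geometry$A^2 - a^2
  mp <- b^2 - config$geometry$B^2
  alpha_in <- function(r) sqrt(r^2 / (r^2 + m2))
  alpha_out <- function(r) sqrt(r^2 / (r^2 - mp))
  n_lay <- pmax(3L, round(n_points * c(diff1 = b - a, diff2 = cc - b,
                                       diff3 = d - cc) / (d - a)))
  r_in <- seq(a, b, length.out = n_lay[1])
  r_me <- seq(b, cc, length.out = n_lay[2])
  r_ad <- seq(cc, d, length.out = n_lay[3])

  int_in <- function(r) if (r == a) 0 else
    .layer_quad(function(x) deformed_integrand(materials$intima, alpha_in(x)) / x,
                a, r, rel_tol, "intima")
  int_me <- function(r) if (r == cc) 0 else
    .layer_quad(function(x) deformed_integrand(materials$media, alpha_out(x)) / x,
                r, cc, rel_tol, "media")
  int_ad <- function(r) if (r == d) 0 else
    .layer_quad(function(x) deformed_integrand(materials$adventitia, alpha_out(x)) / x,
                r, d, rel_tol, "adventitia")
  I_ad_full <- int_ad(cc)

  Trr_in <- -config$P_kPa + vapply(r_in, int_in, numeric(1))
  Trr_me <- -I_ad_full - vapply(r_me, int_me, numeric(1))
  Trr_ad <- -vapply(r_ad, int_ad, numeric(1))

  out <- data.frame(
    r_mm = c(r_in, r_me, r_ad),
    Trr_kPa = c(Trr_in, Trr_me, Trr_ad),
    Ttheta_kPa = c(
      Trr_in + deformed_integrand(materials$intima, alpha_in(r_in)),
      Trr_me + deformed_integrand(materials$media, alpha_out(r_me)),
      Trr_ad + deformed_integrand(materials$adventitia, alpha_out(r_ad))),
    layer = rep(c("intima", "media", "adventitia"), times = n_lay),
    stringsAsFactors = FALSE)
  class(out) <- c("stress_profile", "data.frame")
  out
}
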