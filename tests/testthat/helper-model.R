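# Shared fixtures: default coronary model, cached trajectories, and
# independent numerical oracles used by several test files.

default_geometry <- function(area = 12) reference_geometry(area)
default_materials <- function() wall_materials()

# trajectories are expensive; simulate each (area, pressure) once per run
.curve_cache <- new.env(parent = emptyenv())
cached_curve <- function(area, P_mmHg = 0, n_steps = 400) {
  key <- sprintf("a%g_P%g_n%d", area, P_mmHg, n_steps)
  if (is.null(.curve_cache[[key]]))
    .curve_cache[[key]] <- simulate_remodeling(
      reference_geometry(area), wall_materials(),
      P_mmHg = P_mmHg, n_steps = n_steps)
  .curve_cache[[key]]
}

# dense fixed-grid trapezoid evaluation of the reference-frame pressure
# balance; deliberately routes through reference_integrand() and
# stretch_field() rather than the closed-form/adaptive path under test
trapz_residual <- function(a, g, P_kPa, geometry, materials, n = 1e4) {
  b2 <- a^2 + g^2 * (geometry$B^2 - geometry$A^2)
  # per-layer stretch from the deformation map; the elastic stretch jumps at
  # R = B, so each layer must use its own branch at shared endpoints
  alpha_intima <- function(R) sqrt(a^2 + g^2 * (R^2 - geometry$A^2)) / (g * R)
  alpha_outer <- function(R) sqrt(b2 + R^2 - geometry$B^2) / R
  layer_int <- function(layer, alpha_fun, R1, R2) {
    R <- seq(R1, R2, length.out = n)
    y <- reference_integrand(layer, alpha_fun(R)) / R
    sum((y[-1] + y[-n]) / 2 * diff(R))
  }
  -P_kPa +
    layer_int(materials$intima, alpha_intima, geometry$A, geometry$B) +
    layer_int(materials$media, alpha_outer, geometry$B, geometry$C) +
    layer_int(materials$adventitia, alpha_outer, geometry$C, geometry$D)
}

# independent Reinsch matrices from the textbook definitions, used by the
# brute-force spline objective oracle
oracle_spline_matrices <- function(x) {
  n <- length(x); h <- diff(x)
  Q <- matrix(0, n, n - 2); R <- matrix(0, n - 2, n - 2)
  for (j in 2:(n - 1)) {
    Q[j - 1, j - 1] <- 1 / h[j - 1]
    Q[j, j - 1] <- -(1 / h[j - 1] + 1 / h[j])
    Q[j + 1, j - 1] <- 1 / h[j]
    R[j - 1, j - 1] <- (h[j - 1] + h[j]) / 3
    if (j < n - 1) R[j - 1, j] <- R[j, j - 1] <- h[j] / 6
  }
  list(Q = Q, R = R)
}

# objective of the penalized spline problem for candidate knot values f
oracle_spline_objective <- function(f, x, y, k) {
  qr_ <- oracle_spline_matrices(x)
  gam <- solve(qr_$R, crossprod(qr_$Q, f))
  k * sum((y - f)^2) + (1 - k) * as.numeric(t(gam) %*% qr_$R %*% gam)
}

# a remodeling_curve-shaped object from analytic (S, L) samples
fake_curve <- function(S, L) {
  out <- data.frame(
    t_years = seq_along(S), g = seq_along(S), P_mmHg = 0,
    a_mm = sqrt(L / pi), b_mm = sqrt(L / pi / (1 - S)),
    c_mm = NA_real_, d_mm = NA_real_,
    lumen_area_mm2 = L, iel_area_mm2 = L / (1 - S),
    plaque_area_mm2 = L * S / (1 - S), stenosis_fraction = S)
  class(out) <- c("remodeling_curve", "data.frame")
  out
}
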