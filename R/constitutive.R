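#' Neo-Hookean layer parameters
#'
#' Constructor for the constitutive description of the intima, modeled as an
#' incompressible Neo-Hookean solid with strain energy `W = mu * (I1 - 3)`.
#' Note the convention: the modulus multiplies `(I1 - 3)` directly, with no
#' factor of 1/2.
#'
#' @param mu shear-like modulus, kPa. Must be positive.
#' @return an object of class `neo_hookean`.
#' @seealso [fiber_reinforced()], [wall_materials()]
#' @export
#' @examples
#' neo_hookean(mu = 5)
neo_hookean <- function(mu) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("'mu' must be a single positive number (kPa)")
  structure(list(mu = mu), class = c("neo_hookean", "wall_layer"))
}

#' Fiber-reinforced exponential (HGO-type) layer parameters
#'
#' Constructor for the media/adventitia constitutive description: an isotropic
#' Neo-Hookean ground matrix plus an exponential term coupling the isotropic
#' and fiber invariants, which models the severe strain-stiffening of
#' collagen-reinforced arterial tissue:
#' `W = mu*(I1 - 3) + (eta/beta) * (exp(beta * Q) - 1)` with
#' `Q = (1 - rho)*(I1 - 3)^2 + rho*(I4 - 1)^2` and
#' `I4 = alpha^2 cos^2(phi) + sin^2(phi)` for a single symmetric fiber family
#' at angle `phi` to the circumferential direction.
#'
#' The fiber angle is stored in degrees, as tabulated in the experimental
#' literature, and converted to radians at this single point.
#'
#' @param mu ground-matrix modulus, kPa (> 0).
#' @param eta fiber stiffness scale, kPa (>= 0).
#' @param beta dimensionless exponential stiffening rate (> 0).
#' @param rho dimensionless weight in \[0, 1\] between the isotropic and fiber
#'   contributions inside the exponent.
#' @param phi_deg fiber angle in degrees, in \[0, 90\].
#' @param stretch_cap diagnostic cap on the circumferential stretch allowed in
#'   the exponential evaluation path (default 3). `exp(beta * Q)` overflows
#'   double precision well below physically meaningful stresses for stretches
#'   of this size (the equilibrium states of the model stay below ~1.7), so a
#'   stretch beyond the cap raises an error rather than returning `Inf`.
#' @return an object of class `fiber_reinforced`.
#' @export
#' @examples
#' fiber_reinforced(mu = 1.27, eta = 21.60, beta = 8.21, rho = 0.25, phi_deg = 20.61)
fiber_reinforced <- function(mu, eta, beta, rho, phi_deg, stretch_cap = 3) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu > 0,
            is.numeric(eta), length(eta) == 1L, eta >= 0,
            is.numeric(beta), length(beta) == 1L, beta > 0,
            is.numeric(rho), length(rho) == 1L, rho >= 0, rho <= 1,
            is.numeric(phi_deg), length(phi_deg) == 1L,
            phi_deg >= 0, phi_deg <= 90,
            is.numeric(stretch_cap), stretch_cap > 1)
  structure(list(mu = mu, eta = eta, beta = beta, rho = rho,
                 phi_deg = phi_deg, phi = phi_deg * pi / 180,
                 stretch_cap = stretch_cap),
            class = c("fiber_reinforced", "wall_layer"))
}

#' Three-layer wall material set
#'
#' Bundles the constitutive parameters of intima, media and adventitia. The
#' default is the coronary parameter set used throughout the package: an
#' intima modulus of 5 kPa and media/adventitia parameters from biaxial tests
#' on healthy human coronary layers.
#'
#' @param intima a [neo_hookean()] object.
#' @param media,adventitia [fiber_reinforced()] objects.
#' @return an object of class `wall_materials`.
#' @export
#' @examples
#' wall_materials()  # coronary defaults
wall_materials <- function(intima = neo_hookean(mu = 5),
                           media = fiber_reinforced(mu = 1.27, eta = 21.60,
                                                    beta = 8.21, rho = 0.25,
                                                    phi_deg = 20.61),
                           adventitia = fiber_reinforced(mu = 7.56, eta = 38.57,
                                                         beta = 85.03, rho = 0.55,
                                                         phi_deg = 67.0)) {
  stopifnot(inherits(intima, "neo_hookean"),
            inherits(media, "fiber_reinforced"),
            inherits(adventitia, "fiber_reinforced"))
  structure(list(intima = intima, media = media, adventitia = adventitia),
            class = "wall_materials")
}

#' @export
print.wall_materials <- function(x, ...) {
  cat("Three-layer wall materials (kPa, degrees)\n")
  cat(sprintf("  intima     : Neo-Hookean, mu = %g\n", x$intima$mu))
  for (nm in c("media", "adventitia")) {
    l <- x[[nm]]
    cat(sprintf("  %-10s : fiber-reinforced, mu = %g, eta = %g, beta = %g, rho = %g, phi = %g\n",
                nm, l$mu, l$eta, l$beta, l$rho, l$phi_deg))
  }
  invisible(x)
}

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha <= 0))
    stop("stretch 'alpha' must be positive and finite")
}

#' Fiber invariant terms F and G
#'
#' The two auxiliary functions of circumferential stretch that appear in the
#' radial-stress integrand of a fiber-reinforced layer:
#' `F = (1-rho)(alpha^2 + alpha^-2 - 2)(1 - alpha^-4) +
#'      rho (alpha^2 cos^2 phi + sin^2 phi - 1) cos^2 phi` and
#' `G = (1-rho)(alpha^2 + alpha^-2 - 2)^2 +
#'      rho (alpha^2 cos^2 phi + sin^2 phi - 1)^2`.
#' Both vanish at `alpha = 1`; `G >= 0` always.
#'
#' @param params a [fiber_reinforced()] object.
#' @param alpha circumferential elastic stretch (vectorized, > 0).
#' @return list with numeric components `F` and `G`.
#' @export
#' @examples
#' m <- wall_materials()$media
#' fiber_terms(m, 1.1)
fiber_terms <- function(params, alpha) {
  stopifnot(inherits(params, "fiber_reinforced"))
  .check_alpha(alpha)
  c2 <- cos(params$phi)^2
  iso <- alpha^2 + alpha^-2 - 2
  fib <- alpha^2 * c2 + sin(params$phi)^2 - 1
  list(F = (1 - params$rho) * iso * (1 - alpha^-4) + params$rho * fib * c2,
       G = (1 - params$rho) * iso^2 + params$rho * fib^2)
}

.fiber_exp <- function(params, G) {
  # overflow guard lives with the only exponential in the model
  exp(params$beta * G)
}

.cap_check <- function(params, alpha) {
  if (any(alpha > params$stretch_cap))
    stop(sprintf("circumferential stretch %.4g exceeds the stretch cap %.3g for the exponential fiber term",
                 max(alpha), params$stretch_cap))
}

#' Strain-energy density as a function of circumferential stretch
#'
#' For an incompressible layer deforming in-plane (axial stretch 1, radial
#' stretch `alpha^-1`), the strain energy reduces to a function of the hoop
#' stretch alone: `mu*(alpha^2 + alpha^-2 - 2)` for the Neo-Hookean intima,
#' plus `(eta/beta)*(exp(beta*G) - 1)` for fiber-reinforced layers. Zero if
#' and only if `alpha = 1`.
#'
#' @param layer a `neo_hookean` or `fiber_reinforced` object.
#' @param alpha circumferential elastic stretch (vectorized, > 0).
#' @return energy density, kPa.
#' @export
#' @examples
#' energy_density(neo_hookean(5), 2)  # 11.25 kPa
energy_density <- function(layer, alpha) UseMethod("energy_density")

#' @export
energy_density.neo_hookean <- function(layer, alpha) {
  .check_alpha(alpha)
  layer$mu * (alpha^2 + alpha^-2 - 2)
}

#' @export
energy_density.fiber_reinforced <- function(layer, alpha) {
  .check_alpha(alpha)
  .cap_check(layer, alpha)
  G <- fiber_terms(layer, alpha)$G
  layer$mu * (alpha^2 + alpha^-2 - 2) +
    layer$eta / layer$beta * (.fiber_exp(layer, G) - 1)
}

#' Reference-frame radial-stress integrand
#'
#' The factor multiplying `dR/R` in the reference-frame form of the
#' pressure-balance integral: `2*mu*(1 - alpha^-4)` for a Neo-Hookean layer,
#' plus `4*eta*F*exp(beta*G)` for fiber-reinforced layers. Vanishes at
#' `alpha = 1`.
#'
#' @inheritParams energy_density
#' @return integrand value, kPa.
#' @export
reference_integrand <- function(layer, alpha) UseMethod("reference_integrand")

#' @export
reference_integrand.neo_hookean <- function(layer, alpha) {
  .check_alpha(alpha)
  2 * layer$mu * (1 - alpha^-4)
}

#' @export
reference_integrand.fiber_reinforced <- function(layer, alpha) {
  .check_alpha(alpha)
  .cap_check(layer, alpha)
  fg <- fiber_terms(layer, alpha)
  2 * layer$mu * (1 - alpha^-4) + 4 * layer$eta * fg$F * .fiber_exp(layer, fg$G)
}

#' Deformed-frame radial-stress integrand
#'
#' The factor multiplying `dr/r` in the deformed-frame radial-stress integral:
#' `2*mu*(alpha^2 - alpha^-2)` for a Neo-Hookean layer, plus
#' `4*eta*alpha^2*F*exp(beta*G)` for fiber-reinforced layers. Because
#' `dr/r = alpha^-2 dR/R`, this equals `alpha^2` times
#' [reference_integrand()] pointwise, so the two frames integrate to the same
#' stress. This is also `alpha * d(energy)/d(alpha)`, the hoop-radial stress
#' difference `T_theta - T_rr`.
#'
#' @inheritParams energy_density
#' @return integrand value, kPa.
#' @export
deformed_integrand <- function(layer, alpha) UseMethod("deformed_integrand")

#' @export
deformed_integrand.neo_hookean <- function(layer, alpha) {
  .check_alpha(alpha)
  2 * layer$mu * (alpha^2 - alpha^-2)
}

#' @export
deformed_integrand.fiber_reinforced <- function(layer, alpha) {
  .check_alpha(alpha)
  .cap_check(layer, alpha)
  fg <- fiber_terms(layer, alpha)
  2 * layer$mu * (alpha^2 - alpha^-2) +
    4 * layer$eta * alpha^2 * fg$F * .fiber_exp(layer, fg$G)
}
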