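#' Reference (unstressed) three-layer geometry
#'
#' Builds the radii `A < B < C < D` of the unstressed configuration from a
#' reference lumen area and the three layer thicknesses. Defaults are the
#' coronary values used throughout: a thin healthy intima (0.01 mm), media
#' 0.32 mm and adventitia 0.34 mm.
#'
#' @param reference_lumen_area lumen area in the unstressed state, mm^2.
#' @param intima_thickness,media_thickness,adventitia_thickness layer
#'   thicknesses, mm.
#' @return an object of class `reference_geometry` with fields `A`, `B`, `C`,
#'   `D` (mm).
#' @export
#' @examples
#' reference_geometry(12)
reference_geometry <- function(reference_lumen_area,
                               intima_thickness = 0.01,
                               media_thickness = 0.32,
                               adventitia_thickness = 0.34) {
  vals <- c(reference_lumen_area, intima_thickness, media_thickness,
            adventitia_thickness)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("lumen area and all thicknesses must be positive")
  A <- sqrt(reference_lumen_area / pi)
  B <- A + intima_thickness
  C <- B + media_thickness
  D <- C + adventitia_thickness
  structure(list(A = A, B = B, C = C, D = D), class = "reference_geometry")
}

#' @export
print.reference_geometry <- function(x, ...) {
  cat(sprintf("Reference geometry (mm): A = %.5f, B = %.5f, C = %.5f, D = %.5f\n",
              x$A, x$B, x$C, x$D))
  cat(sprintf("  lumen area %.4f mm^2, wall thickness %.3f mm\n",
              pi * x$A^2, x$D - x$A))
  invisible(x)
}

#' Intimal growth factor at time t
#'
#' Uniform isotropic in-plane growth of the intima at constant volumetric
#' rate `Gamma` gives the growth stretch `g(t) = exp(Gamma * t / 2)`: the
#' in-plane growth tensor is `diag(g, g)` so the volumetric production rate
#' `Trace(Fg^-1 dFg/dt) = 2 * g'/g = Gamma` is constant.
#'
#' @param t time in years (>= 0, vectorized).
#' @param Gamma intimal volumetric growth rate, 1/year (default 0.5).
#' @return growth factor `g >= 1`.
#' @export
#' @examples
#' growth_factor(2, Gamma = 0.5)  # exp(0.5)
growth_factor <- function(t, Gamma = 0.5) {
  if (any(!is.finite(t)) || any(t < 0)) stop("'t' must be non-negative")
  if (!is.numeric(Gamma) || Gamma <= 0) stop("'Gamma' must be positive")
  exp(Gamma * t / 2)
}

#' Outer deformed radii from the deformed lumen radius
#'
#' Incompressibility of every layer ties the deformed interface radii to the
#' lumen radius `a` and the growth factor `g`:
#' `b^2 = a^2 + g^2 (B^2 - A^2)`, `c^2 = b^2 + C^2 - B^2`,
#' `d^2 = b^2 + D^2 - B^2`. The grown intima occupies `g^2` times its
#' reference area; the media and adventitia conserve theirs.
#'
#' @param a deformed lumen radius, mm (> 0).
#' @param g growth factor (>= 1 for grown states; any positive value accepted).
#' @param geometry a [reference_geometry()] object.
#' @return named numeric vector `c(b =, c =, d =)` in mm.
#' @export
radii_from_lumen <- function(a, g, geometry) {
  stopifnot(inherits(geometry, "reference_geometry"))
  if (any(a <= 0) || any(g <= 0)) stop("'a' and 'g' must be positive")
  b2 <- a^2 + g^2 * (geometry$B^2 - geometry$A^2)
  c(b = sqrt(b2),
    c = sqrt(b2 + geometry$C^2 - geometry$B^2),
    d = sqrt(b2 + geometry$D^2 - geometry$B^2))
}

#' Solved mechanical configuration (constructor)
#'
#' A configuration records deformed radii at a growth factor and pressure for
#' a given reference geometry. Usually produced by [solve_configuration()];
#' this constructor only enforces the kinematic identities.
#'
#' @param a deformed lumen radius, mm.
#' @param g growth factor.
#' @param P_kPa luminal pressure, kPa.
#' @param geometry a [reference_geometry()] object.
#' @return object of class `configuration` with fields `a`, `b`, `c`, `d`,
#'   `g`, `P_kPa`, `geometry`.
#' @export
configuration <- function(a, g, P_kPa, geometry) {
  r <- radii_from_lumen(a, g, geometry)
  structure(list(a = a, b = unname(r["b"]), c = unname(r["c"]),
                 d = unname(r["d"]), g = g, P_kPa = P_kPa,
                 geometry = geometry),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  m <- morphometrics(x)
  cat(sprintf("Configuration at g = %.4f, P = %.4f kPa (%.1f mmHg)\n",
              x$g, x$P_kPa, kPa_to_mmHg(x$P_kPa)))
  cat(sprintf("  radii (mm): a = %.5f, b = %.5f, c = %.5f, d = %.5f\n",
              x$a, x$b, x$c, x$d))
  cat(sprintf("  lumen %.4f mm^2, plaque %.4f mm^2, stenosis %.2f%%\n",
              m$lumen_area, m$plaque_area, 100 * m$stenosis))
  invisible(x)
}

#' Elastic circumferential stretch profile
#'
#' The hoop elastic stretch as a function of the reference radial coordinate:
#' inside the grown intima `alpha = sqrt(a^2 + g^2 (R^2 - A^2)) / (g R)`, and
#' in the (ungrown) media/adventitia `alpha = sqrt(b^2 + R^2 - B^2) / R`.
#' The deformation map `r(R)` is continuous at `R = B`, but the elastic
#' stretch jumps there by the growth factor (`g * alpha(B-) = alpha(B+)`)
#' because the growth tensor is discontinuous across the IEL; values at
#' `R = B` use the intima branch.
#'
#' @param config a `configuration` object.
#' @param R reference radial coordinate(s), mm, in `[A, D]`.
#' @return stretch values, dimensionless.
#' @export
stretch_field <- function(config, R) {
  stopifnot(inherits(config, "configuration"))
  geo <- config$geometry
  if (any(R < geo$A - 1e-12) || any(R > geo$D + 1e-12))
    stop("'R' outside the reference wall [A, D]")
  a <- config$a; g <- config$g; b <- config$b
  ifelse(R <= geo$B,
         sqrt(a^2 + g^2 * (R^2 - geo$A^2)) / (g * R),
         sqrt(b^2 + R^2 - geo$B^2) / R)
}

#' Morphometric summary of a configuration
#'
#' Lumen area `pi a^2`, IEL area `pi b^2` (area enclosed by the internal
#' elastic lamina, i.e. the intima/media interface in the deformed state),
#' plaque area (their difference) and stenosis fraction
#' (plaque area / IEL area).
#'
#' @param config a `configuration` object.
#' @return list with `lumen_area`, `iel_area`, `plaque_area` (mm^2) and
#'   `stenosis` (fraction in `[0, 1)`).
#' @export
morphometrics <- function(config) {
  stopifnot(inherits(config, "configuration"))
  lumen <- pi * config$a^2
  iel <- pi * config$b^2
  list(lumen_area = lumen, iel_area = iel, plaque_area = iel - lumen,
       stenosis = (iel - lumen) / iel)
}
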