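#' Simulate a remodeling trajectory
#'
#' Drives intimal growth quasi-statically: the growth factor is stepped along
#' a geometric grid (equivalently, uniform in time) from `g = 1` and the
#' equilibrium configuration is re-solved at each step with the luminal
#' pressure held fixed. The trajectory stops at the first grid point whose
#' stenosis reaches `s_max` (default 0.9; the model is not trusted near total
#' occlusion).
#'
#' Plotted against stenosis, the curve is invariant to the growth rate
#' `Gamma`: the rate only sets the time stamps.
#'
#' @param geometry a [reference_geometry()] object.
#' @param materials a [wall_materials()] object.
#' @param P_mmHg luminal pressure in mmHg (0 for the ex-vivo/unloaded state).
#' @param Gamma intimal growth rate, 1/year (time stamps only).
#' @param n_steps number of growth grid points.
#' @param s_max stenosis at which the trajectory is truncated.
#' @param g_max optional upper growth factor; by default estimated so that
#'   the stenosis range reaches `s_max`.
#' @param settings a [solver_settings()] object.
#' @return data frame of class `remodeling_curve` with columns `t_years`,
#'   `g`, `P_mmHg`, `a_mm`, `b_mm`, `c_mm`, `d_mm`, `lumen_area_mm2`,
#'   `iel_area_mm2`, `plaque_area_mm2`, `stenosis_fraction`.
#' @export
#' @examples
#' \donttest{
#' geo <- reference_geometry(12)
#' cv <- simulate_remodeling(geo, wall_materials(), P_mmHg = 0, n_steps = 50)
#' head(cv)
#' }
simulate_remodeling <- function(geometry, materials, P_mmHg = 0, Gamma = 0.5,
                                n_steps = 400, s_max = 0.9, g_max = NULL,
                                settings = solver_settings()) {
  stopifnot(inherits(geometry, "reference_geometry"),
            inherits(materials, "wall_materials"),
            P_mmHg >= 0, Gamma > 0, n_steps >= 2, s_max > 0, s_max < 1)
  P_kPa <- mmHg_to_kPa(P_mmHg)
  if (is.null(g_max)) {
    # stenosis ~ g^2 dB2 / (A^2 + g^2 dB2) if the lumen held its reference
    # radius; the true lumen shrinks late on, so this overshoots and the
    # trajectory is truncated at s_max instead.
    dB2 <- geometry$B^2 - geometry$A^2
    g_max <- sqrt(s_max / (1 - s_max) * geometry$A^2 / dB2)
  }
  if (g_max <= 1) stop("'g_max' must exceed 1")
  gs <- exp(seq(0, log(g_max), length.out = n_steps))
  rows <- vector("list", n_steps)
  a_prev <- NULL
  for (i in seq_along(gs)) {
    cfg <- solve_configuration(gs[i], P_kPa, geometry, materials,
                               settings = settings, a_init = a_prev)
    a_prev <- cfg$a
    m <- morphometrics(cfg)
    rows[[i]] <- data.frame(
      t_years = 2 * log(gs[i]) / Gamma, g = gs[i], P_mmHg = P_mmHg,
      a_mm = cfg$a, b_mm = cfg$b, c_mm = cfg$c, d_mm = cfg$d,
      lumen_area_mm2 = m$lumen_area, iel_area_mm2 = m$iel_area,
      plaque_area_mm2 = m$plaque_area, stenosis_fraction = m$stenosis)
    if (m$stenosis >= s_max) { rows <- rows[seq_len(i)]; break }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("remodeling_curve", "data.frame")
  attr(out, "geometry") <- geometry
  out
}

#' @export
print.remodeling_curve <- function(x, ...) {
  cat(sprintf("Remodeling curve: %d states, P = %g mmHg, stenosis %.3f-%.3f\n",
              nrow(x), x$P_mmHg[1], min(x$stenosis_fraction),
              max(x$stenosis_fraction)))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("  ... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}

#' Plot a remodeling curve
#'
#' Lumen area against stenosis fraction, the standard representation of
#' compensatory (outward) versus inward remodeling.
#'
#' @param x a `remodeling_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.remodeling_curve <- function(x, ...) {
  graphics::plot(x$stenosis_fraction, x$lumen_area_mm2, type = "l",
                 xlab = "stenosis fraction", ylab = "lumen area (mm²)", ...)
}

#' Locate the critical stenosis of a remodeling curve
#'
#' The critical stenosis `S*` is the interior maximum of the lumen-area
#' curve `L = f(S)`: `f'(S*) = 0`, `f''(S*) < 0`. The grid maximum is refined
#' on a monotone (shape-preserving) cubic interpolant by golden-section
#' search between the neighbouring grid points. A maximum is reported only
#' if it sits at least two grid points away from both curve ends; otherwise
#' the curve is treated as monotone over the simulated range and the maximum
#' is declared absent.
#'
#' @param curve a `remodeling_curve` (>= 10 samples).
#' @return object of class `critical_stenosis` with fields `S_star` and
#'   `L_at_S_star` (both `NA` when absent) and logical `present`.
#' @export
critical_stenosis <- function(curve) {
  stopifnot(inherits(curve, "remodeling_curve"))
  S <- curve$stenosis_fraction
  L <- curve$lumen_area_mm2
  if (length(S) < 10) stop("need at least 10 samples to locate a maximum")
  i <- which.max(L)
  absent <- structure(list(S_star = NA_real_, L_at_S_star = NA_real_,
                           present = FALSE), class = "critical_stenosis")
  if (i <= 2L || i >= length(S) - 1L) return(absent)
  f <- stats::splinefun(S, L, method = "monoH.FC")
  opt <- stats::optimize(f, lower = S[i - 1L], upper = S[i + 1L],
                         maximum = TRUE, tol = 1e-10)
  h <- max(1e-6, 1e-4 * (S[i + 1L] - S[i - 1L]))
  curv <- (f(opt$maximum + h) - 2 * f(opt$maximum) + f(opt$maximum - h)) / h^2
  if (!is.finite(curv) || curv >= 0) return(absent)
  structure(list(S_star = opt$maximum, L_at_S_star = opt$objective,
                 present = TRUE), class = "critical_stenosis")
}

#' @export
print.critical_stenosis <- function(x, ...) {
  if (x$present)
    cat(sprintf("Critical stenosis: S* = %.4f (%.1f%%), lumen area %.4f mm^2\n",
                x$S_star, 100 * x$S_star, x$L_at_S_star))
  else
    cat("No interior maximum: lumen area is monotone over the simulated range\n")
  invisible(x)
}

#' Early-stage compensation slope
#'
#' Least-squares slope of lumen area against plaque area over the early part
#' of a trajectory. Glagov-style "over-compensation" shows up as a slope
#' greater than +1 (the lumen gains more area than the plaque deposits); a
#' negative slope means the lumen shrinks from the outset. The window is
#' expressed either as a plaque-area ceiling (`plaque_area_window`, default
#' 0.5 mm^2) or, alternatively, as a stenosis ceiling (`stenosis_window`,
#' e.g. 0.2 to mimic restricting to mildly stenotic samples).
#'
#' @param curve a `remodeling_curve`.
#' @param plaque_area_window plaque-area ceiling, mm^2.
#' @param stenosis_window optional stenosis ceiling; when given it replaces
#'   the plaque-area window.
#' @return slope in mm^2 lumen per mm^2 plaque.
#' @export
compensation_slope <- function(curve, plaque_area_window = 0.5,
                               stenosis_window = NULL) {
  stopifnot(inherits(curve, "remodeling_curve"))
  sel <- if (is.null(stenosis_window))
    curve$plaque_area_mm2 <= plaque_area_window
  else curve$stenosis_fraction <= stenosis_window
  if (sum(sel) < 2) stop("window contains fewer than 2 trajectory points")
  fit <- stats::lm(lumen_area_mm2 ~ plaque_area_mm2, data = curve[sel, ])
  unname(stats::coef(fit)[2])
}

#' Ex-vivo versus in-vivo geometry at matched growth
#'
#' Solves the unpressurized (`P = 0`, ex-vivo/post-mortem) and pressurized
#' (in-vivo) states at the same growth factor and tabulates the comparison.
#' Incompressibility makes the plaque area identical in the two states, so
#' depressurization shrinks the IEL and lumen and raises the measured
#' stenosis.
#'
#' @param g growth factor (>= 1).
#' @param geometry a [reference_geometry()] object.
#' @param materials a [wall_materials()] object.
#' @param P_invivo_mmHg in-vivo luminal pressure, mmHg.
#' @param settings a [solver_settings()] object.
#' @return data frame of class `exvivo_invivo` with one row per metric
#'   (IEL area, lumen area, plaque area, stenosis) and columns `exvivo`,
#'   `invivo`, `relation` (`"smaller"`, `"larger"` or `"same"`, describing
#'   the ex-vivo value relative to in-vivo).
#' @export
exvivo_invivo_table <- function(g, geometry, materials, P_invivo_mmHg = 80,
                                settings = solver_settings()) {
  stopifnot(g >= 1, P_invivo_mmHg > 0)
  ex <- morphometrics(solve_configuration(g, 0, geometry, materials, settings))
  iv <- morphometrics(solve_configuration(g, mmHg_to_kPa(P_invivo_mmHg),
                                          geometry, materials, settings))
  rel <- function(e, i, tol = 1e-9) {
    if (abs(e - i) <= tol * max(abs(e), abs(i), 1)) "same"
    else if (e < i) "smaller" else "larger"
  }
  out <- data.frame(
    metric = c("iel_area_mm2", "lumen_area_mm2", "plaque_area_mm2",
               "stenosis_fraction"),
    exvivo = c(ex$iel_area, ex$lumen_area, ex$plaque_area, ex$stenosis),
    invivo = c(iv$iel_area, iv$lumen_area, iv$plaque_area, iv$stenosis),
    stringsAsFactors = FALSE)
  out$relation <- mapply(rel, out$exvivo, out$invivo)
  class(out) <- c("exvivo_invivo", "data.frame")
  attr(out, "g") <- g
  attr(out, "P_invivo_mmHg") <- P_invivo_mmHg
  out
}

#' Write a remodeling trajectory to CSV
#'
#' @param curve a `remodeling_curve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(curve, path) {
  stopifnot(inherits(curve, "remodeling_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Read a remodeling trajectory from CSV
#'
#' @param path CSV file written by [write_trajectory()].
#' @return a `remodeling_curve` data frame.
#' @export
read_trajectory <- function(path) {
  out <- utils::read.csv(path)
  need <- c("t_years", "g", "P_mmHg", "a_mm", "b_mm", "c_mm", "d_mm",
            "lumen_area_mm2", "iel_area_mm2", "plaque_area_mm2",
            "stenosis_fraction")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("trajectory file lacks columns: ", paste(miss, collapse = ", "))
  class(out) <- c("remodeling_curve", "data.frame")
  out
}
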