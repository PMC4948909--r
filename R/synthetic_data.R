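# Synthetic cohorts of (stenosis, lumen area) observations emulating
# histology-style point clouds: many vessels, each observed once at a random
# disease stage, with measurement noise on the lumen area.

#' Cohort specification
#'
#' Defines the sampling distributions for a synthetic cross-sectional cohort.
#' Each vessel draws an initial (unstressed) lumen area, a growth rate, and a
#' single observation time; the model is then grown to that time and the
#' observed (stenosis, lumen area) pair recorded with additive Gaussian noise
#' on the area. Defaults: 150 vessels, initial areas uniform on 5-15 mm^2,
#' growth rate log-normal with median 0.5/year, observation time uniform on
#' 0-14 years (which spreads stenoses over roughly 0.01-0.85), noise SD
#' 1 mm^2. The observation is truncated at a stenosis of `s_cap` because the
#' model is not trusted near total occlusion. The in-vivo mode draws a
#' per-vessel pressure uniform on 50-110 mmHg and redraws the observation
#' time until stenosis is at least `s_min` (default 0.10, mimicking older
#' clinical cohorts that contain essentially no early-stage plaques).
#'
#' @param n_vessels number of vessels (> 0).
#' @param area_range range of initial reference lumen areas, mm^2.
#' @param gamma_meanlog,gamma_sdlog log-normal parameters of the growth rate
#'   (1/year); the default median is 0.5/year.
#' @param time_range observation-time range, years.
#' @param sigma_L observation noise SD on lumen area, mm^2 (>= 0).
#' @param pressure_mode `"exvivo"` (P = 0) or `"invivo"` (P uniform on
#'   `pressure_range`).
#' @param pressure_range in-vivo pressure range, mmHg.
#' @param s_min minimum observed stenosis (in-vivo mode only; `NULL` for the
#'   mode default).
#' @param s_cap truncation stenosis for the observation.
#' @param seed integer RNG seed; all draws flow from one generator.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_vessels = 150, area_range = c(5, 15),
                        gamma_meanlog = log(0.5), gamma_sdlog = 0.3,
                        time_range = c(0, 14), sigma_L = 1,
                        pressure_mode = c("exvivo", "invivo"),
                        pressure_range = c(50, 110), s_min = NULL,
                        s_cap = 0.85, seed = 1L) {
  pressure_mode <- match.arg(pressure_mode)
  stopifnot(n_vessels > 0, sigma_L >= 0, length(area_range) == 2,
            area_range[1] > 0, diff(area_range) >= 0,
            length(time_range) == 2, time_range[1] >= 0,
            s_cap > 0, s_cap < 1)
  if (is.null(s_min)) s_min <- if (pressure_mode == "invivo") 0.10 else 0
  structure(list(n_vessels = as.integer(n_vessels), area_range = area_range,
                 gamma_meanlog = gamma_meanlog, gamma_sdlog = gamma_sdlog,
                 time_range = time_range, sigma_L = sigma_L,
                 pressure_mode = pressure_mode,
                 pressure_range = pressure_range, s_min = s_min,
                 s_cap = s_cap, seed = as.integer(seed)),
            class = "cohort_spec")
}

# grow one vessel to growth factor g_target, warm-starting the equilibrium
# solve along a geometric ladder in g; stops early at the stenosis cap
.grow_to <- function(g_target, P_kPa, geometry, materials, settings, s_cap) {
  n <- max(2L, ceiling(log(max(g_target, 1.0001)) / log(1.25)) + 1L)
  gs <- exp(seq(0, log(max(g_target, 1.0001)), length.out = n))
  cfg <- solve_configuration(gs[1], P_kPa, geometry, materials, settings)
  for (g in gs[-1]) {
    nxt <- solve_configuration(g, P_kPa, geometry, materials, settings,
                               a_init = cfg$a)
    if (morphometrics(nxt)$stenosis > s_cap) break
    cfg <- nxt
  }
  cfg
}

#' Generate a synthetic cohort
#'
#' Draws vessels according to a [cohort_spec()], grows each to its observation
#' time by solving the equilibrium model, and returns one observed
#' (stenosis, lumen area) sample per vessel together with the per-vessel
#' ground truth. Deterministic for a fixed spec seed.
#'
#' @param spec a [cohort_spec()].
#' @param materials a [wall_materials()] object.
#' @param intima_thickness,media_thickness,adventitia_thickness reference
#'   layer thicknesses passed to [reference_geometry()], mm.
#' @param settings a [solver_settings()] object.
#' @return data frame of class `remodeling_cohort` with columns `vessel`,
#'   `area0_mm2`, `Gamma_per_year`, `t_years`, `g`, `P_mmHg`,
#'   `stenosis_fraction`, `lumen_area_true_mm2`, `lumen_area_mm2` (noisy;
#'   floored at 0.01 mm^2 so areas stay positive).
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(n_vessels = 10, seed = 7))
#' head(cohort)
#' }
generate_cohort <- function(spec, materials = wall_materials(),
                            intima_thickness = 0.01, media_thickness = 0.32,
                            adventitia_thickness = 0.34,
                            settings = solver_settings()) {
  stopifnot(inherits(spec, "cohort_spec"))
  rng <- .with_seed(spec$seed)
  on.exit(rng(), add = TRUE)
  rows <- vector("list", spec$n_vessels)
  for (v in seq_len(spec$n_vessels)) {
    area <- stats::runif(1, spec$area_range[1], spec$area_range[2])
    Gamma <- stats::rlnorm(1, spec$gamma_meanlog, spec$gamma_sdlog)
    P_mmHg <- if (spec$pressure_mode == "invivo")
      stats::runif(1, spec$pressure_range[1], spec$pressure_range[2]) else 0
    geo <- reference_geometry(area, intima_thickness, media_thickness,
                              adventitia_thickness)
    for (try in seq_len(50L)) {
      t_obs <- stats::runif(1, spec$time_range[1], spec$time_range[2])
      cfg <- .grow_to(growth_factor(t_obs, Gamma), mmHg_to_kPa(P_mmHg),
                      geo, materials, settings, spec$s_cap)
      m <- morphometrics(cfg)
      if (m$stenosis >= spec$s_min) break
    }
    noisy <- m$lumen_area + stats::rnorm(1, 0, spec$sigma_L)
    rows[[v]] <- data.frame(
      vessel = v, area0_mm2 = area, Gamma_per_year = Gamma,
      t_years = 2 * log(cfg$g) / Gamma, g = cfg$g, P_mmHg = P_mmHg,
      stenosis_fraction = m$stenosis,
      lumen_area_true_mm2 = m$lumen_area,
      lumen_area_mm2 = max(noisy, 0.01))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("remodeling_cohort", "data.frame")
  attr(out, "spec") <- spec
  out
}

# run a block with a private RNG state; returns a restore function
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write (stenosis, lumen area) samples to CSV
#'
#' Writes the two-column analysis schema `stenosis_fraction,
#' lumen_area_mm2`. Any data frame containing those columns is accepted; the
#' round trip through [read_fixture()] is lossless to full double precision.
#'
#' @param samples data frame with columns `stenosis_fraction` and
#'   `lumen_area_mm2`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(samples, path) {
  need <- c("stenosis_fraction", "lumen_area_mm2")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(samples)[, need]
  # full precision so the round trip is exact to ~1e-16 relative
  df$stenosis_fraction <- sprintf("%.17g", df$stenosis_fraction)
  df$lumen_area_mm2 <- sprintf("%.17g", df$lumen_area_mm2)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read (stenosis, lumen area) samples from CSV
#'
#' Reads the schema written by [write_fixture()]. Stenosis values coded in
#' percent (any value > 1.5) are detected and divided by 100 with a warning.
#' Rows with missing or non-numeric entries raise an error naming the lines.
#'
#' @param path CSV path.
#' @return data frame with columns `stenosis_fraction`, `lumen_area_mm2`.
#' @export
read_fixture <- function(path) {
  df <- utils::read.csv(path, colClasses = NA)
  need <- c("stenosis_fraction", "lumen_area_mm2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fixture lacks columns: ", paste(miss, collapse = ", "))
  df <- df[, need]
  for (col in need) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (nrow(df) > 0 && length(bad))
      stop(sprintf("malformed values in column '%s' at data line(s) %s",
                   col, paste(bad, collapse = ", ")))
    df[[col]] <- vals
  }
  if (nrow(df) > 0 && any(df$stenosis_fraction > 1.5)) {
    warning("stenosis values look percent-coded (> 1.5); dividing by 100")
    df$stenosis_fraction <- df$stenosis_fraction / 100
  }
  if (nrow(df) > 0 &&
      (any(df$stenosis_fraction < 0) || any(df$stenosis_fraction >= 1) ||
       any(df$lumen_area_mm2 <= 0)))
    stop("samples must satisfy 0 <= stenosis < 1 and lumen area > 0")
  df
}
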