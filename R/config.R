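#' Read material and geometry parameters from a key = value config file
#'
#' Parses a minimal TOML-like file of `key = value` lines (comments with `#`,
#' section headers in brackets ignored). Recognized keys mirror the standard
#' parameter symbols: `mu1`, `mu2`, `eta2`, `beta2`, `phi2_deg`, `rho2`,
#' `mu3`, `eta3`, `beta3`, `phi3_deg`, `rho3` for the materials, and
#' optionally `intima_thickness`, `media_thickness`, `adventitia_thickness`
#' (mm). Missing keys keep the package defaults.
#'
#' @param path config file path.
#' @return list with components `materials` (a [wall_materials()]) and
#'   `thicknesses` (named numeric vector, mm).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("cannot parse config line: ", ln)
    val <- suppressWarnings(as.numeric(trimws(parts[2])))
    if (is.na(val)) stop("non-numeric value in config line: ", ln)
    kv[[trimws(parts[1])]] <- val
  }
  known <- c("mu1", "mu2", "eta2", "beta2", "phi2_deg", "rho2",
             "mu3", "eta3", "beta3", "phi3_deg", "rho3",
             "intima_thickness", "media_thickness", "adventitia_thickness")
  unknown <- setdiff(names(kv), known)
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  gv <- function(key, default) if (!is.null(kv[[key]])) kv[[key]] else default
  materials <- wall_materials(
    intima = neo_hookean(gv("mu1", 5)),
    media = fiber_reinforced(gv("mu2", 1.27), gv("eta2", 21.60),
                             gv("beta2", 8.21), gv("rho2", 0.25),
                             gv("phi2_deg", 20.61)),
    adventitia = fiber_reinforced(gv("mu3", 7.56), gv("eta3", 38.57),
                                  gv("beta3", 85.03), gv("rho3", 0.55),
                                  gv("phi3_deg", 67.0)))
  list(materials = materials,
       thicknesses = c(intima = gv("intima_thickness", 0.01),
                       media = gv("media_thickness", 0.32),
                       adventitia = gv("adventitia_thickness", 0.34)))
}
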