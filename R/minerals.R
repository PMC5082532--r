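#' @useDynLib ferromin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif setNames approx
#' @importFrom utils head tail
"_PACKAGE"

#' Gas constant in kJ mol^-1 K^-1
#'
#' Used throughout the free-energy module. Named `gas_R` to avoid collision
#' with the titration ratio R (mol NaOH per mol total Fe).
#'
#' @export
gas_R <- 8.31446e-3

#' Define an iron mineral species by its per-formula stoichiometry
#'
#' The five minerals that can form during room-temperature co-precipitation
#' of mixed ferrous/ferric sulfate solutions are described by their counts of
#' ferrous iron, ferric iron and consumed hydroxide per formula unit.
#' Schwertmannite carries a sulfate substitution parameter `z`: per iron,
#' hydroxide consumption is `3 - 2*z`.
#'
#' @param name Species name (free text for custom species).
#' @param fe2,fe3 Ferrous / ferric iron atoms per formula unit.
#' @param oh Hydroxide ions consumed per formula unit.
#' @param z_sulfate Sulfate substitution per Fe (schwertmannite only).
#' @return An object of class `mineral_species`.
#' @export
mineral_species <- function(name, fe2, fe3, oh, z_sulfate = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (fe2 < 0 || fe3 < 0 || oh < 0)
    stop("stoichiometric counts must be >= 0", call. = FALSE)
  if (fe2 + fe3 <= 0)
    stop("species must contain iron (fe2 + fe3 > 0)", call. = FALSE)
  structure(
    list(name = name, fe2 = fe2, fe3 = fe3, oh = oh, z_sulfate = z_sulfate),
    class = "mineral_species"
  )
}

#' @export
print.mineral_species <- function(x, ...) {
  v <- mineral_vertex(x)
  cat(sprintf("<mineral_species> %s: Fe2+ %g, Fe3+ %g, OH %g per formula (X = %.4g, R = %.4g)\n",
              x$name, x$fe2, x$fe3, x$oh, v$X, v$R))
  invisible(x)
}

#' Registry of the default co-precipitation minerals
#'
#' Returns the five-species registry: ferrous hydroxide Fe(OH)2, sulfate
#' green rust Fe(II)4Fe(III)2(OH)12SO4, magnetite Fe(II)Fe(III)2O4 (8 OH
#' consumed per formula), goethite FeOOH, and schwertmannite
#' FeO(OH)(1-2z)(SO4)z per iron with `z_sulfate` defaulting to 1/8 (OH/Fe =
#' 2.75). Goethite is registered for diagram completeness but is not in the
#' default end-point decomposition candidate set.
#'
#' @param z_sulfate Schwertmannite sulfate substitution per Fe; the default
#'   1/8 is the only value for which the precipitation reaction balances with
#'   an OH/Fe ratio of 2.75.
#' @return Named list of `mineral_species`.
#' @export
mineral_registry <- function(z_sulfate = 1/8) {
  stopifnot(z_sulfate >= 0, z_sulfate < 1.5)
  list(
    ferrous_hydroxide = mineral_species("ferrous_hydroxide", 1, 0, 2),
    green_rust        = mineral_species("green_rust",        4, 2, 12),
    magnetite         = mineral_species("magnetite",         1, 2, 8),
    goethite          = mineral_species("goethite",          0, 1, 3),
    schwertmannite    = mineral_species("schwertmannite",    0, 1,
                                        3 - 2 * z_sulfate,
                                        z_sulfate = z_sulfate)
  )
}

resolve_species <- function(species, registry = mineral_registry()) {
  if (inherits(species, "mineral_species")) return(species)
  if (is.character(species) && length(species) == 1L) {
    if (!species %in% names(registry))
      stop(sprintf("unknown mineral species '%s'", species), call. = FALSE)
    return(registry[[species]])
  }
  stop("species must be a mineral_species or a registry name", call. = FALSE)
}

#' Mass-balance diagram vertex of a mineral
#'
#' Each mineral maps to a point (X, R) on the mass-balance diagram: X is the
#' ferric fraction of its iron, and R the hydroxide consumed per mole of
#' iron. Vertices are exact rationals of the stoichiometric coefficients,
#' e.g. magnetite (2/3, 8/3), ferrous hydroxide (0, 2), and schwertmannite
#' at z = 1/8 (1, 2.75).
#'
#' @param species A `mineral_species` or a registry name.
#' @param registry Registry used to look up character names.
#' @return List with elements `X` and `R`.
#' @export
mineral_vertex <- function(species, registry = mineral_registry()) {
  sp <- resolve_species(species, registry)
  fe <- sp$fe2 + sp$fe3
  list(X = sp$fe3 / fe, R = sp$oh / fe)
}

#' Ferric molar fraction X from concentrations
#'
#' X = \[Fe3+\] / (\[Fe3+\] + \[Fe2+\]); invariant under common scaling of
#' the two concentrations, so any consistent unit works.
#'
#' @param fe3_conc,fe2_conc Ferric / ferrous concentrations (same units).
#' @return X in \[0, 1\].
#' @export
x_ratio <- function(fe3_conc, fe2_conc) {
  if (fe3_conc < 0 || fe2_conc < 0)
    stop("concentrations must be >= 0", call. = FALSE)
  total <- fe3_conc + fe2_conc
  if (total == 0) stop("total iron concentration is zero", call. = FALSE)
  fe3_conc / total
}

#' Effective base-addition rate in R per minute
#'
#' Converts a syringe-pump flow of NaOH into the dimensionless titration rate
#' dR/dt: (flow x base concentration) / (solution volume x total iron
#' concentration). The standard experimental geometry, 50 uL/min of 1 M NaOH
#' into 20 mL at 50 mM total iron, gives 0.05 R per minute.
#'
#' @param flow_uL_min NaOH flow in uL/min.
#' @param base_conc_M NaOH concentration in mol/L.
#' @param solution_volume_mL Reaction volume in mL.
#' @param fe_total_mM Total iron concentration in mmol/L.
#' @return Rate in R units per minute.
#' @export
base_rate <- function(flow_uL_min, base_conc_M, solution_volume_mL, fe_total_mM) {
  vals <- c(flow_uL_min, base_conc_M, solution_volume_mL, fe_total_mM)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all inputs to base_rate must be positive", call. = FALSE)
  # uL/min * mol/L = nmol? work in consistent micromoles:
  # flow_uL_min * base_conc_M  -> umol OH per minute
  # solution_volume_mL * fe_total_mM -> umol Fe total
  (flow_uL_min * base_conc_M) / (solution_volume_mL * fe_total_mM)
}

#' Serialize / deserialize a mineral registry
#'
#' The registry round-trips through YAML (or JSON, by extension) so users can
#' extend or amend the species set without touching code.
#'
#' @param registry Named list of `mineral_species`.
#' @param path Output / input file (`.yaml`/`.yml` or `.json`).
#' @return `read_registry` returns a named list of `mineral_species`.
#' @export
write_registry <- function(registry, path) {
  rows <- lapply(registry, function(sp)
    list(name = sp$name, fe2 = sp$fe2, fe3 = sp$fe3, oh = sp$oh,
         z_sulfate = if (is.na(sp$z_sulfate)) NULL else sp$z_sulfate))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(rows, path)
  }
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  rows <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  out <- lapply(rows, function(r)
    mineral_species(r$name, r$fe2, r$fe3, r$oh,
                    z_sulfate = if (is.null(r$z_sulfate)) NA_real_ else r$z_sulfate))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
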