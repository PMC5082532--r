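#' Synthesis parameters for a three-plateau titration curve
#'
#' The generated curve is a sum of two logistic steps between three plateau
#' pH levels; the steps are centred at the theoretical equivalence points
#' implied by X and the end-point mineral mixture. Plateau defaults
#' (2.5, 7.0, 12.5) reflect the qualitative shape of room-temperature
#' co-precipitation logs, the third matching the pH 12.5 end of titration.
#'
#' @param plateau_pH Numeric length 3, strictly increasing plateau levels.
#' @param step_sharpness Logistic step scale in R units (> 0); smaller is
#'   sharper.
#' @param noise_sd Gaussian pH noise standard deviation (>= 0).
#' @param end_fractions Named numeric of iron-molar fractions at the second
#'   equivalence point (default the equal green-rust/magnetite split used for
#'   protein-mediated ferrous-rich runs is *not* assumed; see
#'   [simulate_titration()]).
#' @param dpH_plateau2 Additive ("protein") effect: second plateau lowered by
#'   this many pH units when enabled.
#' @param dR_E2 Additive effect: second step occurs this many R units
#'   earlier when enabled.
#' @param protein_x_max Additive effects apply only for X at or below this
#'   value (protein activity is a ferrous-rich-regime effect).
#' @return List of class `synth_params`.
#' @export
synth_params <- function(plateau_pH = c(2.5, 7.0, 12.5),
                         step_sharpness = 0.02,
                         noise_sd = 0.02,
                         end_fractions = NULL,
                         dpH_plateau2 = 0.4,
                         dR_E2 = 0.15,
                         protein_x_max = 0.4) {
  stopifnot(length(plateau_pH) == 3)
  if (!all(diff(plateau_pH) > 0))
    stop("plateau_pH must be strictly increasing", call. = FALSE)
  if (step_sharpness <= 0) stop("step_sharpness must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(plateau_pH = plateau_pH, step_sharpness = step_sharpness,
                 noise_sd = noise_sd, end_fractions = end_fractions,
                 dpH_plateau2 = dpH_plateau2, dR_E2 = dR_E2,
                 protein_x_max = protein_x_max),
            class = "synth_params")
}

#' Theoretical equivalence-point positions E1 and E2
#'
#' E1 follows the schwertmannite line R = 2.75 X (ferric oxyhydroxide
#' precipitation in the first plateau). E2 is the total base consumed by the
#' end-point mineral mixture: the fraction-weighted sum of the candidate
#' vertices' R values. The fractions must conserve ferric iron, i.e. their
#' X-weighted sum must reproduce the input X.
#'
#' @param X Ferric molar fraction in \[0, 1\].
#' @param end_fractions Named numeric of iron-molar fractions (names from the
#'   mineral registry) summing to 1.
#' @param registry Mineral registry.
#' @param tol Tolerance on the ferric-conservation check.
#' @return List with `E1_R` and `E2_R`.
#' @export
theoretical_breakpoints <- function(X, end_fractions,
                                    registry = mineral_registry(),
                                    tol = 1e-6) {
  stopifnot(X >= 0, X <= 1)
  f <- unlist(end_fractions)
  if (abs(sum(f) - 1) > tol)
    stop("end_fractions must sum to 1", call. = FALSE)
  verts <- lapply(names(f), mineral_vertex, registry = registry)
  Xs <- vapply(verts, `[[`, 0, "X")
  Rs <- vapply(verts, `[[`, 0, "R")
  implied_X <- sum(f * Xs)
  if (abs(implied_X - X) > max(tol, 1e-9))
    stop(sprintf("end_fractions imply X = %.6g but input X = %.6g (ferric iron not conserved)",
                 implied_X, X), call. = FALSE)
  list(E1_R = 2.75 * X, E2_R = sum(f * Rs))
}

#' Simulate a three-plateau pH titration curve
#'
#' Generates a pH logger record on a uniform time grid: R increases linearly
#' at `rate` R/min with one sample per `cadence_s` seconds, and pH follows a
#' sum of two logistic steps centred at the theoretical E1 and E2 positions
#' with Gaussian logger noise. When `protein = TRUE` and X does not exceed
#' `params$protein_x_max`, the second plateau is lowered by
#' `params$dpH_plateau2` and the second step moved earlier by `params$dR_E2`,
#' emulating additive-mediated earlier onset of mixed-valence mineral
#' formation. Deterministic for a fixed seed.
#'
#' @param X Ferric molar fraction.
#' @param params A [synth_params()] object.
#' @param seed Integer RNG seed.
#' @param end_fractions Named fractions at E2; default is the equal
#'   green-rust/magnetite split at the given X (all remaining iron as ferrous
#'   hydroxide), which is feasible for X <= 2/3.
#' @param protein Logical; apply additive effects.
#' @param rate Base-addition rate, R units per minute.
#' @param cadence_s Sampling interval in seconds.
#' @param fe_total_mM Total iron concentration recorded in metadata.
#' @param R_max Final R value of the run.
#' @return Object of class `titration_curve`: list with `samples` (tibble
#'   time_s, R, pH) and `meta`.
#' @export
simulate_titration <- function(X, params = synth_params(), seed = 1L,
                               end_fractions = NULL, protein = FALSE,
                               rate = 0.05, cadence_s = 3,
                               fe_total_mM = 50, R_max = 3.5) {
  stopifnot(inherits(params, "synth_params"), X >= 0, X <= 1)
  if (is.null(end_fractions)) end_fractions <- params$end_fractions
  if (is.null(end_fractions))
    end_fractions <- default_end_fractions(X)
  bp <- theoretical_breakpoints(X, end_fractions)
  E1 <- bp$E1_R
  E2 <- bp$E2_R
  p <- params$plateau_pH
  dpH <- 0
  if (protein && X <= params$protein_x_max) {
    E2 <- E2 - params$dR_E2
    dpH <- params$dpH_plateau2
  }
  if (E2 <= E1)
    stop("degenerate curve: E2 <= E1 for these parameters", call. = FALSE)
  dR <- rate * cadence_s / 60
  R <- seq(0, R_max, by = dR)
  time_s <- seq_along(R) * cadence_s - cadence_s
  s <- params$step_sharpness
  # plateau2 is lowered by dpH; both steps land on the shifted level
  p2 <- p[2] - dpH
  pH <- p[1] +
    (p2 - p[1]) * stats::plogis((R - E1) / s) +
    (p[3] - p2) * stats::plogis((R - E2) / s)
  set.seed(seed)
  pH <- pH + rnorm(length(R), sd = params$noise_sd)
  pH <- pmin(pmax(pH, 0), 14)
  new_titration_curve(
    tibble::tibble(time_s = time_s, R = R, pH = pH),
    meta = list(X = X, fe_total_mM = fe_total_mM, rate = rate,
                additive = if (protein) "protein" else "control",
                seed = as.integer(seed),
                E1_R = E1, E2_R = E2,
                end_fractions = as.list(unlist(end_fractions)))
  )
}

#' Default end-point mineral mixture at a given X
#'
#' For ferrous-rich runs (X <= 0.5) the green-rust and magnetite iron
#' fractions are set equal (each consuming half the ferric iron) with the
#' balance as ferrous hydroxide; for 0.5 < X <= 2/3 no ferrous hydroxide
#' remains and the green-rust/magnetite split is fixed by ferric
#' conservation. The two regimes agree at X = 0.5, so the rule is continuous
#' over the whole mass-balance mineral regime.
#'
#' @param X Ferric molar fraction in \[0, 2/3\].
#' @return Named list of iron-molar fractions.
#' @export
default_end_fractions <- function(X) {
  stopifnot(X >= 0, X <= 2/3 + 1e-12)
  if (X <= 0.5) {
    list(ferrous_hydroxide = 1 - 2 * X, green_rust = X, magnetite = X)
  } else {
    list(ferrous_hydroxide = 0, green_rust = 2 - 3 * X, magnetite = 3 * X - 1)
  }
}

new_titration_curve <- function(samples, meta) {
  stopifnot(all(c("time_s", "R", "pH") %in% names(samples)))
  if (is.unsorted(samples$R))
    stop("R must be nondecreasing", call. = FALSE)
  if (any(samples$pH < 0 | samples$pH > 14))
    stop("pH outside [0, 14]", call. = FALSE)
  structure(list(samples = tibble::as_tibble(samples), meta = meta),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("<titration_curve> %d samples, X = %s, %s\n",
              nrow(x$samples),
              format(x$meta$X %||% NA), x$meta$additive %||% "unlabelled"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a titration curve as delimited text
#'
#' CSV with columns `time_s,R,pH` (plus optional `Eh_mV` redox channel) and
#' the run metadata embedded as a single `# meta: {json}` comment line, so a
#' curve round-trips losslessly through one file.
#'
#' @param curve A `titration_curve`.
#' @param path File path.
#' @return `read_curve` returns a `titration_curve`.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  meta_json <- jsonlite::toJSON(curve$meta, auto_unbox = TRUE, digits = NA)
  writeLines(paste0("# meta: ", meta_json), con)
  utils::write.csv(as.data.frame(curve$samples), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  meta <- list()
  meta_idx <- grep("^# meta: ", lines)
  if (length(meta_idx)) {
    meta <- jsonlite::fromJSON(sub("^# meta: ", "", lines[meta_idx[1]]),
                               simplifyVector = TRUE)
  }
  body <- lines[!grepl("^#", lines)]
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  header <- strsplit(body[1], ",")[[1]]
  required <- c("time_s", "R", "pH")
  missing_cols <- setdiff(required, header)
  if (length(missing_cols))
    stop(sprintf("missing column(s) %s in %s",
                 paste(missing_cols, collapse = ", "), path), call. = FALSE)
  nfield <- length(header)
  rows <- strsplit(body[-1], ",")
  bad <- which(lengths(rows) != nfield)
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s",
                 which(!grepl("^#", lines))[bad[1] + 1L], path), call. = FALSE)
  mat <- do.call(rbind, rows)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  for (cn in header) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v))
      stop(sprintf("non-numeric value in column '%s' of %s", cn, path),
           call. = FALSE)
    df[[cn]] <- v
  }
  if (is.unsorted(df$R))
    stop(sprintf("non-monotone R in %s", path), call. = FALSE)
  new_titration_curve(df, meta = meta)
}
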