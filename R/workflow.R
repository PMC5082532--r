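fmt_num <- function(x) {
  # pinned 6-significant-digit formatting so reruns are byte-identical
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

write_table_pinned <- function(df, path) {
  out <- as.data.frame(df)
  for (cn in names(out))
    if (is.numeric(out[[cn]])) out[[cn]] <- fmt_num(out[[cn]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

write_json_pinned <- function(x, path) {
  pin <- function(v) {
    if (is.list(v)) lapply(v, pin)
    else if (is.numeric(v))
      ifelse(is.na(v), NA_real_, suppressWarnings(as.numeric(fmt_num(v))))
    else v
  }
  jsonlite::write_json(pin(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Workflow configuration
#'
#' Bundles the inputs of one of the three analysis workflows: `titration`
#' (synthetic control/additive pH curves, equivalence detection, run deltas
#' and mineral-fraction decomposition), `binding` (toy Monte Carlo ion
#' simulation, binding statistics, RDF and free-energy profile), or `csp`
#' (synthetic apo/holo shift tables, perturbation table, hotspot ranking).
#' Every stochastic stage draws from the single integer `seed`, which is
#' mandatory: a config without one fails validation rather than silently
#' using ambient RNG state.
#'
#' @param workflow One of "titration", "binding", "csp".
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed (required).
#' @param params Named list of stage parameter overrides; unknown names are
#'   rejected. Titration: X, protein, noise_sd, dpH_plateau2, dR_E2.
#'   Binding: depths, n_sweeps, sample_every, n_sites, cutoff, bin_width,
#'   r_max. CSP: hotspot_residues, effect_size, noise_sd, k.
#' @return List of class `run_config`.
#' @export
run_config <- function(workflow, out_dir, seed, params = list()) {
  workflow <- match.arg(workflow, c("titration", "binding", "csp"))
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("config validation: an explicit integer seed is required",
         call. = FALSE)
  allowed <- switch(workflow,
    titration = c("X", "protein", "noise_sd", "dpH_plateau2", "dR_E2"),
    binding = c("depths", "n_sweeps", "sample_every", "n_sites", "cutoff",
                "bin_width", "r_max"),
    csp = c("hotspot_residues", "effect_size", "noise_sd", "k"))
  bad <- setdiff(names(params), allowed)
  if (length(bad))
    stop("unknown parameter(s) for ", workflow, " workflow: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(workflow = workflow, out_dir = out_dir,
                 seed = as.integer(seed), params = params),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(x$workflow, x$out_dir, x$seed, x$params %||% list())
}

#' Execute an analysis workflow
#'
#' Runs the configured stages in order, writes every artifact with pinned
#' 6-significant-digit numeric formatting (so a rerun with the same config
#' reproduces files byte-for-byte), and returns a manifest of outputs with
#' md5 checksums. A stage failure halts the run with the failing stage
#' named; artifacts already written are retained.
#'
#' @param config A [run_config()].
#' @return Tibble manifest (file, md5) with attribute `log`.
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  seed <- config$seed
  files <- character(0)
  log <- c(sprintf("ferromin %s workflow, seed %d",
                   config$workflow, seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  out <- function(name) file.path(config$out_dir, name)

  if (config$workflow == "titration") {
    X <- p$X %||% 0.2
    sp <- synth_params(noise_sd = p$noise_sd %||% 0.02,
                       dpH_plateau2 = p$dpH_plateau2 %||% 0.4,
                       dR_E2 = p$dR_E2 %||% 0.15)
    ctrl <- stage("simulate", simulate_titration(X, sp, seed = seed))
    addv <- stage("simulate", simulate_titration(X, sp, seed = seed + 1L,
                                                 protein = TRUE))
    files <- c(files, write_curve(ctrl, out("control.csv")),
               write_curve(addv, out("protein.csv")))
    pts_c <- stage("detect", detect_equivalence(ctrl))
    pts_a <- stage("detect", detect_equivalence(addv))
    delta <- stage("compare", compare_runs(list(curve = ctrl, points = pts_c),
                                           list(curve = addv, points = pts_a)))
    files <- c(files, write_json_pinned(
      list(control = unclass(pts_c)[c("E1_R", "E2_R", "Estar_R", "pH_at_Estar")],
           protein = unclass(pts_a)[c("E1_R", "E2_R", "Estar_R", "pH_at_Estar")],
           delta = unclass(delta)[c("dpH_at_Estar", "dE2_R", "X")]),
      out("points.json")))
    tab <- stage("massbalance", fraction_table(list(
      list(X = X, points = pts_c, label = "control"),
      list(X = X, points = pts_a, label = "protein"))))
    files <- c(files, write_table_pinned(tab, out("fractions.csv")))
    log <- c(log, sprintf("X = %g; E2 control %.4f, protein %.4f",
                          X, pts_c$E2_R, pts_a$E2_R))
  } else if (config$workflow == "binding") {
    n_sites <- p$n_sites %||% 1L
    depths <- rep_len(p$depths %||% -6.7, n_sites)
    model <- if (n_sites == 1L) {
      site_model(matrix(20, 1, 3), depths)
    } else {
      m <- deev_site_model()
      m$well_depth <- rep_len(depths, nrow(m$positions))
      m
    }
    traj <- stage("simulate", simulate_ion(
      model, n_sweeps = p$n_sweeps %||% 200000L,
      sample_every = p$sample_every %||% 10L, seed = seed))
    files <- c(files, write_xyz(traj, out("traj.xyz")))
    rec <- stage("binding", binding_series(traj, cutoff = p$cutoff %||% 3.0))
    occ <- stage("binding", site_occupancy(rec))
    files <- c(files, write_table_pinned(occ, out("occupancy.csv")))
    prof <- stage("rdf", rdf(traj, bin_width = p$bin_width %||% 0.05,
                             r_max = p$r_max %||% 15))
    fe <- stage("free_energy", free_energy(prof))
    wb <- stage("well", well_and_barrier(fe))
    files <- c(files, write_table_pinned(fe, out("profile.csv")),
               write_json_pinned(
                 list(bound_fraction = rec$bound_fraction,
                      acceptance = traj$acceptance,
                      well = if (wb$has_well) wb$well else NULL,
                      barrier = if (wb$has_well) wb$barrier else NULL,
                      desorption_barrier = wb$desorption_barrier,
                      has_well = wb$has_well),
                 out("binding.json")))
    log <- c(log, sprintf("bound fraction %.4f, acceptance %.2f",
                          rec$bound_fraction, traj$acceptance))
  } else { # csp
    pair <- stage("synth", synth_shift_tables(
      hotspot_residues = p$hotspot_residues %||% c(11L, 12L, 13L, 15L),
      effect_size = p$effect_size %||% 0.05,
      noise_sd = p$noise_sd %||% 0.005, seed = seed))
    files <- c(files, write_shift_table(pair$apo, out("apo.tsv")),
               write_shift_table(pair$holo, out("holo.tsv")))
    tab <- stage("delta", delta_shifts(pair$apo, pair$holo))
    hs <- stage("rank", rank_hotspots(tab, k = p$k %||% 4L))
    files <- c(files, write_table_pinned(tab, out("csp.csv")),
               write_json_pinned(
                 list(top = head(hs$ranked$residue, p$k %||% 4L),
                      clusters = hs$clusters),
                 out("hotspots.json")))
    log <- c(log, sprintf("top residues: %s",
                          paste(head(hs$ranked$residue, 4), collapse = ",")))
  }
  manifest <- tibble::tibble(file = basename(files),
                             md5 = unname(tools::md5sum(files)))
  writeLines(log, file.path(config$out_dir, "run.log"))
  attr(manifest, "log") <- log
  manifest
}

#' Generate the bundled example datasets
#'
#' Writes one fixture set per workflow: a control/protein titration pair at
#' X = 0.2, a 12-start toy ion-binding ensemble (short runs), and an
#' apo/holo shift-table pair, each with a plain-text GROUND_TRUTH file
#' recording the generating parameters. Reproducible for a fixed seed.
#'
#' @param output_dir Target directory.
#' @param seed Integer seed.
#' @return Invisible character vector of written files.
#' @export
make_fixtures <- function(output_dir, seed = 1L) {
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  if (file.access(output_dir, 2) != 0)
    stop("output_dir is not writable", call. = FALSE)
  files <- character(0)
  gt <- c(sprintf("seed: %d", seed))

  tdir <- file.path(output_dir, "titration")
  dir.create(tdir, showWarnings = FALSE)
  sp <- synth_params()
  ctrl <- simulate_titration(0.2, sp, seed = seed)
  prot <- simulate_titration(0.2, sp, seed = seed + 1L, protein = TRUE)
  files <- c(files, write_curve(ctrl, file.path(tdir, "control_X0.2.csv")),
             write_curve(prot, file.path(tdir, "protein_X0.2.csv")))
  gt <- c(gt, "titration: X = 0.2, end fractions FH 0.6 / GR 0.2 / M 0.2,",
          sprintf("  control E1 = %.4f, E2 = %.4f; protein dpH = %.2f, dE2 = %.2f",
                  ctrl$meta$E1_R, ctrl$meta$E2_R, sp$dpH_plateau2, sp$dR_E2))

  bdir <- file.path(output_dir, "binding")
  dir.create(bdir, showWarnings = FALSE)
  model <- deev_site_model()
  ens <- batch_ensemble(model, n_starts = 12L,
                        seeds = seed + seq_len(12L) - 1L,
                        n_sweeps = 20000L, sample_every = 10L)
  for (i in seq_along(ens))
    files <- c(files, write_xyz(ens[[i]],
                                file.path(bdir, sprintf("traj_%02d.xyz", i))))
  gt <- c(gt, "binding: 12-site DEEV-like cluster, depths as deev_site_model(),",
          "  width 2.5 A, box 40 A, 20000 sweeps sampled every 10")

  cdir <- file.path(output_dir, "csp")
  dir.create(cdir, showWarnings = FALSE)
  pair <- synth_shift_tables(seed = seed)
  files <- c(files, write_shift_table(pair$apo, file.path(cdir, "apo.tsv")),
             write_shift_table(pair$holo, file.path(cdir, "holo_fe2.tsv")))
  gt <- c(gt, "csp: hotspots 11,12,13,15 at +0.05 ppm, noise 0.005 ppm")

  gt_path <- file.path(output_dir, "GROUND_TRUTH.txt")
  writeLines(gt, gt_path)
  invisible(c(files, gt_path))
}
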