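#' Site model for the toy ion-binding simulator
#'
#' A cluster of fixed oxygen sites in a periodic cubic box, each carrying an
#' attractive Gaussian well: U(r) = sum_k -|depth_k| exp(-d_k^2 / (2 w_k^2))
#' with d_k the minimum-image distance to site k. Gaussian wells give
#' closed-form ground truth for free-energy recovery tests, unlike a full
#' force field.
#'
#' @param positions Numeric matrix (n x 3) of site coordinates in Angstrom,
#'   inside the box.
#' @param well_depth Numeric vector of well depths in kJ/mol (<= 0).
#' @param well_width Gaussian widths in Angstrom (> 0); recycled.
#' @param box_edge Cubic box edge in Angstrom.
#' @param ids Site identifiers.
#' @param charge_label "Fe2" or "Fe3".
#' @return Object of class `site_model`.
#' @export
site_model <- function(positions, well_depth, well_width = 2.5,
                       box_edge = 40, ids = NULL, charge_label = "Fe2") {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, box_edge > 0)
  n <- nrow(positions)
  well_depth <- rep_len(well_depth, n)
  well_width <- rep_len(well_width, n)
  if (any(well_depth > 0)) stop("well depths must be <= 0 (attractive)", call. = FALSE)
  if (any(well_width <= 0)) stop("well widths must be > 0", call. = FALSE)
  if (any(positions < 0) || any(positions >= box_edge))
    stop("site positions must lie inside the box [0, box_edge)", call. = FALSE)
  if (is.null(ids)) ids <- paste0("O", seq_len(n))
  stopifnot(!anyDuplicated(ids))
  charge_label <- match.arg(charge_label, c("Fe2", "Fe3"))
  structure(list(positions = positions, well_depth = well_depth,
                 well_width = well_width, box_edge = box_edge,
                 ids = as.character(ids), charge_label = charge_label),
            class = "site_model")
}

#' @export
print.site_model <- function(x, ...) {
  cat(sprintf("<site_model> %d sites, box %g A, %s, depths [%g, %g] kJ/mol\n",
              nrow(x$positions), x$box_edge, x$charge_label,
              min(x$well_depth), max(x$well_depth)))
  invisible(x)
}

#' Default oxygen-site geometry for the DEEV acid cluster
#'
#' A synthetic 12-site cluster of carboxylate and backbone-carbonyl-like
#' oxygen positions around the box centre, standing in for the acidic DEEV
#' region of the Mms6 C-terminal peptide. This is a documented fixture
#' geometry, not a claim about the real peptide conformation.
#'
#' @param well_depth Depths in kJ/mol (recycled over the 12 sites).
#' @param well_width Gaussian width in Angstrom.
#' @param box_edge Box edge in Angstrom.
#' @param charge_label "Fe2" or "Fe3".
#' @return A `site_model` with 12 sites.
#' @export
deev_site_model <- function(well_depth = c(-4, -4, -10, -9, -11, -6.7,
                                           -6.7, -4, -5, -5, -4, -4),
                            well_width = 2.5, box_edge = 40,
                            charge_label = "Fe2") {
  c0 <- box_edge / 2
  # two pseudo-carboxylate oxygen pairs, backbone carbonyls along a short
  # chain, spaced a few Angstrom apart around the centre
  offs <- rbind(
    c(-5.0,  1.2,  0.0), c(-4.2, -1.0,  0.8),   # D-like carboxylate pair
    c(-1.5,  2.0, -0.5), c(-0.8,  0.2,  1.5),   # E12-like pair
    c( 0.6, -1.8,  0.3),                        # bridging carbonyl E12-E13
    c( 2.2,  1.5, -1.0), c( 3.0, -0.5,  0.9),   # E13-like pair
    c( 4.5,  0.8,  0.2),                        # backbone carbonyl
    c(-2.8, -2.5, -1.2), c( 1.8,  3.0,  1.0),   # solvent-exposed carbonyls
    c( 5.5, -2.0, -0.8), c(-6.2,  0.5, -1.5)
  )
  ids <- c("D11_OD1", "D11_OD2", "E12_OE1", "E12_OE2", "CO_E12_E13",
           "E13_OE1", "E13_OE2", "CO_E13", "CO_D11", "CO_V14",
           "CO_E15", "CO_K")
  site_model(sweep(offs, 2, c(c0, c0, c0), `+`), well_depth, well_width,
             box_edge, ids = ids, charge_label = charge_label)
}

#' Metropolis Monte Carlo simulation of a single ion
#'
#' Samples the equilibrium distribution of one ion in the periodic box of a
#' [site_model()] at the given temperature. Proposals are uniform in a cube
#' of edge `step_size`; acceptance follows the Metropolis rule on the
#' Gaussian-well energy. Deterministic for a fixed seed.
#'
#' @param model A `site_model`.
#' @param temperature Kelvin (> 0).
#' @param n_sweeps Number of MC proposal moves.
#' @param sample_every Record the ion position every this many sweeps.
#' @param start_site Site id to start at, `"random"` for a uniform random
#'   point, or a numeric length-3 coordinate.
#' @param seed Integer RNG seed.
#' @param step_size Proposal cube edge in Angstrom. The Gaussian-well
#'   landscape is smooth on this scale, so acceptance stays high for any
#'   reasonable step; the default trades a small acceptance loss for fast
#'   decorrelation across the box (setting it to the box edge at zero well
#'   depth gives independent uniform samples).
#' @return Object of class `ion_trajectory`: `frames` (n x 3 matrix),
#'   `model`, `acceptance`, `sample_every`, `seed`.
#' @export
simulate_ion <- function(model, temperature = 300, n_sweeps = 200000L,
                         sample_every = 10L, start_site = "random",
                         seed = 1L, step_size = 1.5) {
  stopifnot(inherits(model, "site_model"), temperature > 0, n_sweeps >= 1)
  set.seed(seed)
  if (is.numeric(start_site) && length(start_site) == 3L) {
    start <- start_site
  } else if (identical(start_site, "random")) {
    start <- runif(3, 0, model$box_edge)
  } else {
    idx <- match(start_site, model$ids)
    if (is.na(idx))
      stop(sprintf("start_site '%s' not in model", start_site), call. = FALSE)
    start <- model$positions[idx, ]
  }
  res <- .mc_ion_run(model$positions, model$well_depth, model$well_width,
                     model$box_edge, temperature, as.numeric(start),
                     as.integer(n_sweeps), as.integer(sample_every),
                     step_size)
  structure(list(frames = res$frames, model = model,
                 acceptance = res$acceptance,
                 temperature = temperature,
                 sample_every = as.integer(sample_every),
                 seed = as.integer(seed)),
            class = "ion_trajectory")
}

#' @export
print.ion_trajectory <- function(x, ...) {
  cat(sprintf("<ion_trajectory> %d frames, %d sites, acceptance %.2f\n",
              nrow(x$frames), nrow(x$model$positions), x$acceptance))
  invisible(x)
}

#' Ensemble of trajectories from multiple starting sites
#'
#' Runs one trajectory per starting configuration, mirroring production
#' protocols that launch an ion from each candidate binding site. For a
#' ferric ion (`charge_label = "Fe3"`), all well depths are scaled by
#' `fe3_depth_scale` (> 1), modelling the stronger, less specific binding of
#' the more highly charged ion.
#'
#' @param model A `site_model`.
#' @param n_starts Number of trajectories (<= number of sites unless
#'   `random_starts`).
#' @param seeds Integer vector of per-trajectory seeds, length >= n_starts.
#' @param fe3_depth_scale Depth multiplier applied when the model is
#'   labelled Fe3.
#' @param random_starts Start from uniform random points instead of sites.
#' @param ... Passed to [simulate_ion()].
#' @return List of `ion_trajectory`.
#' @export
batch_ensemble <- function(model, n_starts = 12L, seeds = seq_len(n_starts),
                           fe3_depth_scale = 1.5, random_starts = FALSE, ...) {
  if (length(seeds) < n_starts)
    stop("seed list shorter than n_starts", call. = FALSE)
  if (!random_starts && n_starts > length(model$ids))
    stop("n_starts exceeds available sites; set random_starts = TRUE",
         call. = FALSE)
  if (model$charge_label == "Fe3") {
    stopifnot(fe3_depth_scale > 0)
    model$well_depth <- model$well_depth * fe3_depth_scale
  }
  lapply(seq_len(n_starts), function(i) {
    start <- if (random_starts) "random" else model$ids[i]
    simulate_ion(model, start_site = start, seed = seeds[i], ...)
  })
}

#' Pool an ensemble of trajectories for aggregate analysis
#'
#' Concatenates the frames of trajectories sharing one site model into a
#' single `ion_trajectory`, the way production analyses combine independent
#' runs before computing an aggregate RDF: each run searches a different
#' part of configurational space and the pooled histogram approximates the
#' equilibrium distribution far better than any single run.
#'
#' @param trajectories List of `ion_trajectory` objects with identical site
#'   models.
#' @return A pooled `ion_trajectory`.
#' @export
pool_trajectories <- function(trajectories) {
  stopifnot(length(trajectories) >= 1)
  ref <- trajectories[[1]]
  for (tr in trajectories[-1]) {
    stopifnot(inherits(tr, "ion_trajectory"))
    if (max(abs(tr$model$positions - ref$model$positions)) > 1e-9 ||
        tr$model$box_edge != ref$model$box_edge)
      stop("trajectories must share one site model", call. = FALSE)
  }
  ref$frames <- do.call(rbind, lapply(trajectories, `[[`, "frames"))
  ref$acceptance <- mean(vapply(trajectories, `[[`, 0, "acceptance"))
  ref$seed <- NA_integer_
  ref
}

#' Write / read an ion trajectory in multi-frame XYZ format
#'
#' Each frame holds the fixed oxygen sites (element `O`) followed by the ion
#' (element `FE`); the comment line records the box edge and frame index.
#' Coordinates round-trip to 1e-6 Angstrom.
#'
#' @param traj An `ion_trajectory`.
#' @param path File path.
#' @return `read_xyz` returns an `ion_trajectory` (site depths/widths are
#'   not stored in XYZ; they are restored as NA-depth placeholders unless a
#'   `model` is supplied).
#' @param model Optional `site_model` to attach on read (checked against the
#'   stored site coordinates).
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "ion_trajectory"))
  m <- traj$model
  natoms <- nrow(m$positions) + 1L
  con <- file(path, "w")
  on.exit(close(con))
  site_lines <- sprintf("O %.6f %.6f %.6f",
                        m$positions[, 1], m$positions[, 2], m$positions[, 3])
  for (i in seq_len(nrow(traj$frames))) {
    writeLines(as.character(natoms), con)
    writeLines(sprintf("box_edge=%.6f frame=%d", m$box_edge, i), con)
    writeLines(site_lines, con)
    writeLines(sprintf("FE %.6f %.6f %.6f",
                       traj$frames[i, 1], traj$frames[i, 2],
                       traj$frames[i, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path, model = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty XYZ file", call. = FALSE)
  natoms <- suppressWarnings(as.integer(lines[1]))
  if (is.na(natoms) || natoms < 2)
    stop("malformed XYZ: bad atom count on line 1", call. = FALSE)
  block <- natoms + 2L
  if (length(lines) %% block != 0L)
    stop(sprintf("malformed XYZ: length not a multiple of frame size (frame %d truncated)",
                 length(lines) %/% block + 1L), call. = FALSE)
  n_frames <- length(lines) %/% block
  box_edge <- as.numeric(sub(".*box_edge=([0-9.eE+-]+).*", "\\1", lines[2]))
  frames <- matrix(NA_real_, n_frames, 3)
  sites <- NULL
  for (i in seq_len(n_frames)) {
    off <- (i - 1L) * block
    cnt <- suppressWarnings(as.integer(lines[off + 1L]))
    if (is.na(cnt) || cnt != natoms)
      stop(sprintf("inconsistent atom count at frame %d", i), call. = FALSE)
    atoms <- lines[(off + 3L):(off + 2L + natoms)]
    parts <- strsplit(trimws(atoms), "\\s+")
    if (any(lengths(parts) != 4L))
      stop(sprintf("malformed atom record at frame %d", i), call. = FALSE)
    el <- vapply(parts, `[[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop(sprintf("non-numeric coordinate at frame %d", i), call. = FALSE)
    ion_idx <- which(el == "FE")
    if (length(ion_idx) != 1L)
      stop(sprintf("frame %d must contain exactly one FE atom", i), call. = FALSE)
    frames[i, ] <- xyz[ion_idx, ]
    if (i == 1L) sites <- xyz[el == "O", , drop = FALSE]
  }
  if (is.null(model)) {
    model <- site_model(sites, well_depth = rep(0, nrow(sites)),
                        well_width = 1, box_edge = box_edge)
    model$well_depth <- rep(NA_real_, nrow(sites))
  } else {
    stopifnot(inherits(model, "site_model"))
    if (max(abs(model$positions - sites)) > 1e-5)
      stop("supplied model sites do not match XYZ sites", call. = FALSE)
  }
  structure(list(frames = frames, model = model, acceptance = NA_real_,
                 temperature = NA_real_, sample_every = NA_integer_,
                 seed = NA_integer_),
            class = "ion_trajectory")
}
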