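# Independent oracles used across the suite.

# Brute-force simplex grid search for the lever-rule decomposition: minimise
# the reconstruction residual of (X, R) over iron fractions on a grid.
grid_decompose_oracle <- function(X, R, step = 0.002,
                                  candidates = c("ferrous_hydroxide",
                                                 "green_rust", "magnetite")) {
  verts <- lapply(candidates, mineral_vertex)
  Xi <- vapply(verts, `[[`, 0, "X")
  Ri <- vapply(verts, `[[`, 0, "R")
  f1 <- seq(0, 1, by = step)
  grid <- expand.grid(f1 = f1, f2 = f1)
  grid <- grid[grid$f1 + grid$f2 <= 1 + 1e-12, ]
  f3 <- 1 - grid$f1 - grid$f2
  resid <- abs(grid$f1 * Xi[1] + grid$f2 * Xi[2] + f3 * Xi[3] - X) +
    abs(grid$f1 * Ri[1] + grid$f2 * Ri[2] + f3 * Ri[3] - R)
  i <- which.min(resid)
  stats::setNames(c(grid$f1[i], grid$f2[i], f3[i]), candidates)
}

# Exact expected tail-normalised g(r) for a single Gaussian well centred on
# one site: numerical integration of the Boltzmann factor over each bin.
boltzmann_g_oracle <- function(breaks, depth, width, temperature = 300,
                               tail_window) {
  RT <- gas_R * temperature
  g_at <- function(r) exp(-(-abs(depth) * exp(-r^2 / (2 * width^2))) / RT)
  centres <- (head(breaks, -1) + tail(breaks, -1)) / 2
  # bin-average of the Boltzmann factor weighted by r^2 (shell volume)
  gbar <- vapply(seq_len(length(breaks) - 1L), function(i) {
    num <- stats::integrate(function(r) g_at(r) * r^2, breaks[i], breaks[i + 1])$value
    den <- stats::integrate(function(r) r^2, breaks[i], breaks[i + 1])$value
    num / den
  }, 0)
  in_tail <- centres >= tail_window[1] & centres <= tail_window[2]
  gbar / mean(gbar[in_tail])
}

# Uniform-box Monte Carlo oracle for the mean nearest-site distance under
# minimum-image convention.
uniform_nearest_oracle <- function(sites, box_edge, n = 1e6, seed = 999) {
  set.seed(seed)
  pts <- matrix(runif(3 * n, 0, box_edge), ncol = 3)
  dmin <- rep(Inf, n)
  for (k in seq_len(nrow(sites))) {
    d <- sweep(pts, 2, sites[k, ], `-`)
    d <- d - box_edge * round(d / box_edge)
    dmin <- pmin(dmin, sqrt(rowSums(d^2)))
  }
  mean(dmin)
}

# Build an ion_trajectory directly from a frame matrix (bypasses the
# simulator so analysis code can be tested on hand-built configurations).
manual_trajectory <- function(frames, sites, box_edge = 40,
                              well_depth = NULL) {
  sites <- as.matrix(sites)
  if (is.null(well_depth)) well_depth <- rep(0, nrow(sites))
  model <- site_model(sites, well_depth, well_width = 1, box_edge = box_edge)
  structure(list(frames = as.matrix(frames), model = model,
                 acceptance = NA_real_, temperature = 300,
                 sample_every = 1L, seed = NA_integer_),
            class = "ion_trajectory")
}

# Pooled ensemble of single-site runs used by RDF / recovery tests.
single_site_ensemble <- function(depth, n_starts = 12, n_sweeps = 2e6,
                                 width = 2.5, seed_base = 100,
                                 step_size = 1.5, sample_every = 2) {
  m <- site_model(matrix(20, 1, 3), depth, well_width = width)
  pool_trajectories(lapply(seq_len(n_starts), function(i)
    simulate_ion(m, n_sweeps = n_sweeps, sample_every = sample_every,
                 seed = seed_base + i, step_size = step_size)))
}
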