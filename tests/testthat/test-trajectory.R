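test_that("binding classification counts frames within the 3 A cutoff", {
  # single site at the centre; frames at chosen minimum-image distances
  site <- matrix(20, 1, 3)
  frames <- cbind(20 + c(2.9, 3.2, 2.4, 5.0), 20, 20)
  tr <- manual_trajectory(frames, site)
  rec <- binding_series(tr)
  expect_equal(rec$bound_fraction, 0.5)
  expect_equal(unname(rec$bound_any), c(TRUE, FALSE, TRUE, FALSE))
  # boundary convention: exactly 3.0 A counts as bound (closed interval)
  tr3 <- manual_trajectory(cbind(23, 20, 20), site)
  expect_equal(binding_series(tr3)$bound_fraction, 1)
  # distances are minimum-image: a 37 A direct gap wraps to 3 A
  wrap <- manual_trajectory(cbind(1, 20, 20), matrix(c(38, 20, 20), 1))
  expect_equal(unname(binding_series(wrap)$distances[1, 1]), 3)
  expect_true(binding_series(wrap)$bound_any[1])
  nowrap <- binding_series(wrap, periodic = FALSE)
  expect_equal(unname(nowrap$distances[1, 1]), 37)
  expect_error(binding_series(manual_trajectory(frames[0, , drop = FALSE],
                                                site)),
               "empty")
  # bound fraction never increases as the cutoff tightens
  m <- site_model(site, -8)
  sim <- simulate_ion(m, n_sweeps = 2e5, sample_every = 5, seed = 3)
  bf <- vapply(c(5, 4, 3, 2, 1), function(ct)
    binding_series(sim, cutoff = ct)$bound_fraction, 0)
  expect_true(all(diff(bf) <= 0))
})

test_that("site occupancy and categories follow the bound-frame counts", {
  # hand-built flags: 100 bound frames, site A in 56, B in 20, C in 5
  sites <- rbind(c(10, 10, 10), c(20, 20, 20), c(30, 30, 30))
  frames <- matrix(35, 120, 3) # 20 unbound frames far from every site
  frames[1:56, ] <- rep(c(10, 10, 11), each = 56)
  frames[57:76, ] <- rep(c(20, 20, 21), each = 20)
  frames[77:81, ] <- rep(c(30, 30, 31), each = 5)
  frames[82:100, ] <- rep(c(10, 11, 10), each = 19) # more site-A frames
  tr <- manual_trajectory(frames, sites)
  rec <- binding_series(tr)
  expect_equal(sum(rec$bound_any), 100)
  occ <- site_occupancy(rec, thresholds = c(high = 0.4, medium = 0.15))
  expect_equal(occ$occupancy, c(0.75, 0.20, 0.05))
  expect_equal(occ$category, c("high", "medium", "low"))
  # a record with no bound frames yields all-zero occupancy
  none <- binding_series(manual_trajectory(matrix(35, 5, 3), sites))
  expect_equal(site_occupancy(none)$occupancy, rep(0, 3))
})

test_that("co-binding is a conditional probability with flagged degeneracy", {
  sites <- rbind(c(10, 10, 10), c(20, 20, 20))
  # 50 frames bound to A; in 45 of them also within cutoff of B impossible
  # with distinct fixed sites, so use overlapping sites 2 A apart
  sites <- rbind(A = c(20, 20, 20), B = c(22, 20, 20))
  frames <- rbind(
    matrix(rep(c(21, 20, 20), 45), ncol = 3, byrow = TRUE), # binds both
    matrix(rep(c(17.5, 20, 20), 5), ncol = 3, byrow = TRUE), # A only
    matrix(rep(c(35, 35, 35), 10), ncol = 3, byrow = TRUE)   # unbound
  )
  tr <- manual_trajectory(frames, sites)
  rec <- binding_series(tr)
  cb <- co_binding(rec, "O1", "O2")
  expect_equal(cb$p, 0.9)
  expect_equal(cb$n_a, 50)
  expect_true(cb$defined)
  # b bound whenever a bound
  expect_equal(co_binding(rec, "O2", "O1")$p, 1.0)
  # conditioning on a never-bound site is undefined, not zero
  far_rec <- binding_series(manual_trajectory(matrix(35, 4, 3), sites))
  cb0 <- co_binding(far_rec, "O1", "O2")
  expect_true(is.na(cb0$p) && !cb0$defined)
  expect_error(co_binding(rec, "O1", "O9"), "unknown site")
})

test_that("rdf concentrates a delta-like trajectory into one bin", {
  site <- matrix(20, 1, 3)
  # 500 frames pinned at 2.87 A (mid-bin, away from bin edges) plus tail
  # frames so normalization is defined
  set.seed(1)
  u <- matrix(rnorm(3 * 500), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  tail_r <- runif(500, 12.2, 14.8)
  frames <- rbind(sweep(u[1:500, ] * 2.87, 2, c(20, 20, 20), `+`),
                  sweep(u * tail_r, 2, c(20, 20, 20), `+`))
  prof <- rdf(manual_trajectory(frames, site), r_max = 15)
  below <- prof$r < 12
  expect_equal(sum(prof$counts[below]), 500)
  hot <- which(prof$counts == 500)
  expect_length(hot, 1)
  expect_lt(abs(prof$r[hot] - 2.87), 0.05)
  expect_true(all(prof$counts[below][-hot] == 0))
  expect_error(rdf(manual_trajectory(frames, site), r_max = 25),
               "half the box")
})

test_that("uniform sampling gives a flat tail-normalised rdf", {
  m <- site_model(matrix(20, 1, 3), 0)
  tr <- simulate_ion(m, n_sweeps = 2e6, sample_every = 1, seed = 5,
                     step_size = 40)
  prof <- rdf(tr, r_max = 15, tail_window = c(12, 15))
  mid <- prof$r >= 5 & prof$r <= 12
  expect_lt(max(abs(prof$g[mid] - 1)), 0.15)
  expect_lt(abs(mean(prof$g[mid]) - 1), 0.02)
  # tail-normalisation invariant: mean g over the tail window is unity
  in_tail <- prof$r >= 12 & prof$r <= 15
  shell_w <- (prof$r + 0.025)^3 - (prof$r - 0.025)^3
  tail_mean <- sum(prof$g[in_tail] * shell_w[in_tail]) / sum(shell_w[in_tail])
  expect_equal(tail_mean, 1, tolerance = 0.02)
})

test_that("sampled g(r) matches the numeric Boltzmann oracle for one well", {
  tr <- single_site_ensemble(-6.7, n_starts = 8, n_sweeps = 1e6,
                             seed_base = 300)
  prof <- rdf(tr, r_max = 15)
  breaks <- seq(0, 15, by = 0.05)
  oracle <- boltzmann_g_oracle(breaks, -6.7, 2.5, tail_window = c(12, 15))
  ok <- prof$counts >= 100 & prof$r < 10
  expect_gt(sum(ok), 50)
  lnerr <- abs(log(prof$g[ok]) - log(oracle[ok]))
  expect_lt(stats::quantile(lnerr, 0.9), 0.25) # within ~0.6 kJ/mol
  expect_lt(mean(lnerr), 0.1)
})

test_that("free energy is the Boltzmann inversion with absent undefined bins", {
  RT <- gas_R * 300
  prof <- tibble::tibble(r = c(1, 2, 3, 4), g = c(1, exp(1), 0, exp(6.7 / RT)))
  fe <- free_energy(prof, temperature = 300)
  expect_equal(fe$A[1], 0)
  expect_equal(fe$A[2], -RT)
  expect_equal(fe$A[2], -2.494, tolerance = 1e-3)
  expect_true(is.na(fe$A[3])) # zero g: absent, never +/-Inf
  expect_equal(fe$A[4], -6.7)
  expect_equal(fe$A[4] / RT, -2.7, tolerance = 0.01)
  expect_error(free_energy(tibble::tibble(r = 1, g = -0.1)), "negative")
  # sparse bins are masked once counts are known
  prof$counts <- c(1000, 10, 1000, 1000)
  fe2 <- free_energy(prof, min_count = 25)
  expect_true(is.na(fe2$A[2]))
  # round trip: exp(-A/RT) reproduces g wherever A is defined
  ok <- !is.na(fe$A)
  expect_equal(exp(-fe$A[ok] / RT), prof$g[ok], tolerance = 1e-12)
})

test_that("well and barrier annotation reproduces the desorption arithmetic", {
  r <- seq(2, 6, by = 0.05)
  # smooth profile: -6.7 kJ/mol well at 2.85 A, +3.5 kJ/mol bump at 3.5 A
  A <- -6.7 * exp(-(r - 2.85)^2 / 0.04) + 3.5 * exp(-(r - 3.5)^2 / 0.04)
  wb <- well_and_barrier(tibble::tibble(r = r, A = A))
  expect_true(wb$has_well)
  expect_equal(wb$well$depth, -6.7, tolerance = 1e-3)
  expect_equal(wb$well$r_min, 2.85)
  expect_equal(wb$barrier$height, 3.5, tolerance = 1e-3)
  expect_equal(wb$barrier$r_barrier, 3.5)
  expect_equal(wb$desorption_barrier, 10.2, tolerance = 1e-3)
  # monotone rise back to the tail: barrier height zero
  wb2 <- well_and_barrier(tibble::tibble(r = r, A = seq(-5, 0, length.out = length(r))))
  expect_equal(wb2$desorption_barrier, 5.0)
  expect_equal(wb2$barrier$height, 0)
  # no negative minimum: flagged, not an error
  wb3 <- well_and_barrier(tibble::tibble(r = r, A = abs(r - 4)))
  expect_false(wb3$has_well)
  expect_true(is.na(wb3$desorption_barrier))
})

test_that("per-site profiles preserve ordering and additivity", {
  sites <- rbind(c(14, 20, 20), c(26, 20, 20))
  m <- site_model(sites, c(-11, -4), well_width = 2.5)
  tr <- pool_trajectories(lapply(1:10, function(i)
    simulate_ion(m, n_sweeps = 1e6, sample_every = 2, seed = 500 + i,
                 step_size = 2, start_site = "random")))
  profs <- per_site_profiles(tr, r_max = 10, min_count = 25)
  wb1 <- well_and_barrier(profs$O1)
  wb2 <- well_and_barrier(profs$O2)
  expect_true(wb1$has_well && wb2$has_well)
  expect_lt(wb1$well$depth, wb2$well$depth) # deeper site recovers deeper
  # aggregate histogram equals the sum of per-site histograms
  agg <- rdf(tr, r_max = 10)
  expect_equal(agg$counts, profs$O1$counts + profs$O2$counts)
  # a site that is never approached within r_max yields an empty profile flag
  far <- manual_trajectory(matrix(c(20, 20, 20), 10, 3, byrow = TRUE),
                           rbind(c(20, 20, 22), c(2, 2, 2)))
  pf <- per_site_profiles(far, r_max = 5)
  expect_s3_class(pf$O2, "empty_profile")
})
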