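test_that("schwertmannite residual is the signed distance from R = 2.75 X", {
  expect_equal(schwertmannite_residual(0.55, 0.2), 0)
  expect_equal(schwertmannite_residual(2.75 * 0.33, 0.33), 0)
  expect_equal(schwertmannite_residual(1.0, 0.2), 0.45)
})

test_that("decompose_E2 is exact at vertices and on convex combinations", {
  dec <- decompose_E2(2/3, 8/3)
  expect_equal(dec$fractions$magnetite, 1)
  expect_equal(dec$fractions$ferrous_hydroxide, 0)
  # round trip fractions -> point -> fractions on random simplex draws
  set.seed(42)
  verts <- lapply(c("ferrous_hydroxide", "green_rust", "magnetite"),
                  mineral_vertex)
  for (i in 1:50) {
    f <- as.numeric(stats::rexp(3)); f <- f / sum(f)
    X <- sum(f * vapply(verts, `[[`, 0, "X"))
    R <- sum(f * vapply(verts, `[[`, 0, "R"))
    back <- decompose_E2(X, R)
    expect_lt(max(abs(unlist(back$fractions) - f)), 1e-9)
  }
})

test_that("decompose_E2 agrees with the simplex grid-search oracle", {
  dec <- decompose_E2(0.3, 2.2)
  expect_equal(unlist(dec$fractions),
               c(ferrous_hydroxide = 0.4, green_rust = 0.3, magnetite = 0.3))
  oracle <- grid_decompose_oracle(0.3, 2.2, step = 0.001)
  expect_equal(unname(unlist(dec$fractions)), unname(oracle),
               tolerance = 0.001)
  # random in-region points
  set.seed(7)
  for (i in 1:100) {
    f <- as.numeric(stats::rexp(3)); f <- f / sum(f)
    X <- f[2] / 3 + f[3] * 2 / 3
    R <- 2 * f[1] + 2 * f[2] + 8 / 3 * f[3]
    dec <- decompose_E2(X, R)
    oracle <- grid_decompose_oracle(X, R, step = 0.002)
    # the L1 grid argmin can sit one full step from the exact solution
    expect_lt(max(abs(unlist(dec$fractions) - oracle)), 2 * 0.002 + 1e-9)
  }
})

test_that("out-of-region points and degenerate geometry are flagged", {
  bad <- decompose_E2(0.05, 3.5) # far above the FH-GR-M triangle
  expect_s3_class(bad, "decompose_failure")
  expect_match(bad$message, "outside candidate region")
  expect_error(
    decompose_E2(0.3, 2.2, candidates = c("ferrous_hydroxide",
                                          "ferrous_hydroxide", "magnetite")),
    "degenerate")
  expect_error(decompose_E2(0.3, 2.2, candidates = c("green_rust",
                                                     "magnetite")),
               "three candidate")
})

test_that("equal_pair_solve forces the ferric split the lever rule implies", {
  sol <- equal_pair_solve(0.2)
  expect_equal(unlist(sol$fractions),
               c(ferrous_hydroxide = 0.6, green_rust = 0.2, magnetite = 0.2))
  expect_equal(unlist(equal_pair_solve(0)$fractions)[["ferrous_hydroxide"]], 1)
  expect_equal(unlist(equal_pair_solve(0.4)$fractions),
               c(ferrous_hydroxide = 0.2, green_rust = 0.4, magnetite = 0.4))
  # the solution's implied E2 point decomposes back to itself
  pt <- sol$point
  back <- decompose_E2(pt[["X"]], pt[["R"]])
  expect_equal(unlist(back$fractions), unlist(sol$fractions), tolerance = 1e-9)
  expect_error(equal_pair_solve(0.6), "no feasible")
  expect_error(equal_pair_solve(0.2, pair = c("ferrous_hydroxide", "magnetite"),
                                third = "green_rust"),
               "ferric iron")
})

test_that("fraction_table matches generator truth and tolerates failures", {
  expect_equal(nrow(fraction_table(list())), 0)
  tab <- fraction_table(list(list(X = 2/3, points = 8/3, label = "vertex")))
  expect_equal(tab$percent[tab$species == "magnetite"], 100)
  # synthetic control/additive pair recovered from detected E2 positions
  sp <- synth_params(noise_sd = 0)
  cv <- simulate_titration(0.2, sp, seed = 1)
  pts <- detect_equivalence(cv)
  tab <- fraction_table(list(list(X = 0.2, points = pts, label = "control")))
  expect_equal(tab$percent[tab$species == "ferrous_hydroxide"], 60,
               tolerance = 0.01)
  expect_equal(tab$percent[tab$species == "magnetite"], 20, tolerance = 0.05)
  # a failing row is reported, not fatal
  tab <- fraction_table(list(list(X = 0.05, points = 3.5, label = "bad"),
                             list(X = 2/3, points = 8/3, label = "ok")))
  expect_true(all(is.na(tab$percent[tab$label == "bad"])))
  expect_match(tab$note[tab$label == "bad"][1], "outside")
  expect_equal(tab$percent[tab$label == "ok" & tab$species == "magnetite"], 100)
})

test_that("pipeline closure: simulate, detect, decompose recovers fractions", {
  sp0 <- synth_params(noise_sd = 0)
  for (X in c(0.2, 0.3, 0.4, 0.5, 0.6)) {
    truth <- unlist(default_end_fractions(X))
    cv <- simulate_titration(X, sp0, seed = 1)
    pts <- detect_equivalence(cv)
    # X >= 0.5 mixtures sit on the triangle boundary, so grid-snap error in
    # the detected E2 needs a clamping tolerance of its own size
    dec <- decompose_E2(X, pts$E2_R, tol = 0.01)
    expect_lt(max(abs(unlist(dec$fractions) - truth)), 0.02)
  }
})
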