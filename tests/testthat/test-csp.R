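toy_set <- function(rows, metal = "none", pH = 5.66) {
  shift_set(tibble::as_tibble(rows), metal = metal, pH = pH)
}

test_that("delta_shifts is zero on identical sets and averages sidechains", {
  pair <- synth_shift_tables(effect_size = 0, noise_sd = 0, seed = 1)
  tab <- delta_shifts(pair$apo, pair$apo)
  expect_true(all(abs(tab$amide_delta) < 1e-12, na.rm = TRUE))
  expect_true(all(abs(tab$mean_sidechain_delta) < 1e-12, na.rm = TRUE))
  # hand mean: HB 1.90 -> 1.95 (+0.05), HG 2.20 -> 2.30 (+0.10) => 0.075
  apo <- toy_set(data.frame(residue = c(6, 6), code = "E",
                            atom = c("HB", "HG"), ppm = c(1.90, 2.20)))
  holo <- toy_set(data.frame(residue = c(6, 6), code = "E",
                             atom = c("HB", "HG"), ppm = c(1.95, 2.30)),
                  metal = "Fe2")
  tab <- delta_shifts(apo, holo)
  expect_equal(tab$mean_sidechain_delta[6], 0.075)
  expect_equal(tab$n_sidechain_atoms[6], 2)
  # residues with nothing observed are absent, not zero
  expect_true(is.na(tab$mean_sidechain_delta[1]))
})

test_that("atoms lost to paramagnetic broadening are excluded and counted", {
  apo <- toy_set(data.frame(residue = c(6, 6, 6), code = "E",
                            atom = c("HN", "HB", "HG"),
                            ppm = c(8.42, 2.01, 2.31)))
  holo <- toy_set(data.frame(residue = c(6, 6), code = "E",
                             atom = c("HN", "HB"), ppm = c(8.50, 2.06)),
                  metal = "Fe2")
  tab <- delta_shifts(apo, holo)
  expect_equal(tab$mean_sidechain_delta[6], 0.05) # HG dropped
  expect_equal(tab$n_sidechain_atoms[6], 1)
  expect_equal(tab$n_missing_sidechain[6], 1)
  expect_equal(tab$amide_delta[6], 0.08)
})

test_that("uncontrolled conditions are refused", {
  pair <- synth_shift_tables(seed = 2)
  drift <- pair$holo
  drift$condition$pH <- 5.8
  expect_error(delta_shifts(pair$apo, drift), "pH")
  other <- pair$holo
  other$sequence <- "KSRDIESAQSDEEVELRDAA"
  expect_error(delta_shifts(pair$apo, other), "sequence")
  expect_error(shift_set(data.frame(residue = 1, code = "A", atom = "HA",
                                    ppm = 4.3)),
               "code mismatch")
  expect_error(shift_set(data.frame(residue = 25, code = "A", atom = "HA",
                                    ppm = 4.3)),
               "outside peptide")
})

test_that("random-coil deviations match hand statistics", {
  ref <- random_coil_reference()
  # a set exactly at reference deviates by zero
  pair <- synth_shift_tables(effect_size = 0, noise_sd = 0,
                             apo_jitter_sd = 0, seed = 1)
  rc <- random_coil_deviation(pair$apo)
  expect_equal(unname(rc$summary["max_abs"]), 0)
  expect_equal(unname(rc$summary["mean_abs"]), 0)
  # toy 3-residue deviations {0.01, -0.03, 0.05}
  ha_ref <- function(code) ref$ppm[ref$code == code & ref$atom == "HA"]
  rows <- data.frame(residue = c(1, 2, 3), code = c("K", "S", "R"),
                     atom = "HA",
                     ppm = c(ha_ref("K") + 0.01, ha_ref("S") - 0.03,
                             ha_ref("R") + 0.05))
  rc <- random_coil_deviation(toy_set(rows))
  expect_equal(unname(rc$summary["max_abs"]), 0.05)
  expect_equal(unname(rc$summary["mean_abs"]), 0.03)
  expect_equal(rc$per_residue$deviation, c(0.01, -0.03, 0.05))
  # a missing reference entry names the residue type
  slim <- ref[ref$code != "S", ]
  expect_error(random_coil_deviation(toy_set(rows), reference = slim), "S")
})

test_that("hotspot ranking finds the DEEVE-like cluster pattern", {
  pair <- synth_shift_tables(hotspot_residues = c(11L, 12L, 13L, 15L),
                             effect_size = 0.05, noise_sd = 0.002, seed = 9)
  tab <- delta_shifts(pair$apo, pair$holo)
  hs <- rank_hotspots(tab, k = 4)
  expect_setequal(head(hs$ranked$residue, 4), c(11, 12, 13, 15))
  expect_equal(hs$clusters, list(11:13, 15L))
  # secondary weaker site appears at k = 5
  pair2 <- synth_shift_tables(hotspot_residues = c(11L, 12L, 13L, 15L, 6L),
                              effect_size = c(0.05, 0.05, 0.05, 0.05, 0.02),
                              noise_sd = 0.002, seed = 9)
  hs5 <- rank_hotspots(delta_shifts(pair2$apo, pair2$holo), k = 5)
  expect_setequal(head(hs5$ranked$residue, 5), c(6, 11, 12, 13, 15))
  # single perturbed residue: itself, cluster of one
  pair1 <- synth_shift_tables(hotspot_residues = 13L, effect_size = 0.1,
                              noise_sd = 0, seed = 1)
  hs1 <- rank_hotspots(delta_shifts(pair1$apo, pair1$holo), k = 1)
  expect_equal(hs1$ranked$residue[1], 13)
  expect_equal(hs1$clusters, list(13L))
  # all-zero table: stable index order, no clusters
  pair0 <- synth_shift_tables(effect_size = 0, noise_sd = 0, seed = 1)
  hs0 <- rank_hotspots(delta_shifts(pair0$apo, pair0$holo), k = 4)
  expect_equal(head(hs0$ranked$residue, 4), 1:4)
  expect_equal(hs0$clusters, list())
})

test_that("synthetic shift tables honour effect scaling and determinism", {
  fe2 <- synth_shift_tables(effect_size = 0.05, noise_sd = 0, seed = 3)
  fe3 <- synth_shift_tables(effect_size = 0.01, noise_sd = 0, seed = 3,
                            metal = "Fe3")
  m2 <- max(abs(delta_shifts(fe2$apo, fe2$holo)$mean_sidechain_delta),
            na.rm = TRUE)
  m3 <- max(abs(delta_shifts(fe3$apo, fe3$holo)$mean_sidechain_delta),
            na.rm = TRUE)
  expect_equal(m2 / m3, 5, tolerance = 1e-6)
  a <- synth_shift_tables(seed = 8)
  b <- synth_shift_tables(seed = 8)
  expect_identical(a$holo$entries, b$holo$entries)
  expect_error(synth_shift_tables(hotspot_residues = 0), "residue index")
})

test_that("shift tables round-trip through TSV with condition metadata", {
  pair <- synth_shift_tables(seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_shift_table(pair$holo, path)
  back <- read_shift_table(path)
  expect_equal(back$entries$ppm, pair$holo$entries$ppm, tolerance = 1e-12)
  expect_equal(back$condition$metal, "Fe2")
  expect_equal(back$condition$equivalents, 3)
})
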