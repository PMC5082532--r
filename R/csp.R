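#' The C-terminal Mms6 peptide sequence
#'
#' One-letter sequence of the acid-rich C-terminal peptide (C20Mms6,
#' Ac-KSRDIESAQSDEEVELRDAL-Am); residue numbering in this package runs 1-20
#' over this sequence. The DEEVE acidic cluster spans residues 11-15.
#'
#' @export
c20mms6_sequence <- "KSRDIESAQSDEEVELRDAL"

c20_codes <- function() strsplit(c20mms6_sequence, "")[[1]]

#' Load the packaged random-coil proton shift reference
#'
#' Per residue-type, per proton random-coil shifts in ppm for unstructured
#' peptides (see the file header of
#' `system.file("extdata", "random_coil_shifts.csv", package = "ferromin")`
#' for provenance). Users with a different preferred compilation can pass
#' their own tibble of the same shape anywhere a reference is accepted.
#'
#' @return Tibble with columns code, atom, ppm.
#' @export
random_coil_reference <- function() {
  path <- system.file("extdata", "random_coil_shifts.csv",
                      package = "ferromin")
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Construct a chemical-shift assignment set
#'
#' @param entries Tibble/data.frame with columns residue (index 1-20), code
#'   (one-letter), atom (e.g. HN, HA, HB, HG), ppm.
#' @param metal One of none, Fe2, Fe3, Ca, Zn.
#' @param equivalents Metal equivalents added.
#' @param pH Sample pH.
#' @param sequence Peptide sequence the indices refer to.
#' @return Object of class `shift_set`.
#' @export
shift_set <- function(entries, metal = "none", equivalents = 0, pH = 5.66,
                      sequence = c20mms6_sequence) {
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("residue", "code", "atom", "ppm") %in% names(entries)))
  codes <- strsplit(sequence, "")[[1]]
  if (any(entries$residue < 1 | entries$residue > length(codes)))
    stop("residue index outside peptide length", call. = FALSE)
  mism <- entries$code != codes[entries$residue]
  if (any(mism))
    stop(sprintf("residue code mismatch at index %d ('%s' vs sequence '%s')",
                 entries$residue[mism][1], entries$code[mism][1],
                 codes[entries$residue[mism][1]]), call. = FALSE)
  if (anyDuplicated(entries[, c("residue", "atom")]))
    stop("duplicate (residue, atom) entries", call. = FALSE)
  metal <- match.arg(metal, c("none", "Fe2", "Fe3", "Ca", "Zn"))
  structure(list(entries = entries,
                 condition = list(metal = metal, equivalents = equivalents,
                                  pH = pH),
                 sequence = sequence),
            class = "shift_set")
}

#' @export
print.shift_set <- function(x, ...) {
  cat(sprintf("<shift_set> %d shifts, metal %s (%g eq), pH %.2f\n",
              nrow(x$entries), x$condition$metal, x$condition$equivalents,
              x$condition$pH))
  invisible(x)
}

#' Write / read a shift table as delimited text
#'
#' Tab-separated table with header `residue code atom ppm` and the condition
#' metadata on a `# condition: {json}` comment line.
#'
#' @param shifts A `shift_set`.
#' @param path File path.
#' @return `read_shift_table` returns a `shift_set`.
#' @export
write_shift_table <- function(shifts, path) {
  stopifnot(inherits(shifts, "shift_set"))
  con <- file(path, "w")
  on.exit(close(con))
  cond <- jsonlite::toJSON(c(shifts$condition, list(sequence = shifts$sequence)),
                           auto_unbox = TRUE, digits = NA)
  writeLines(paste0("# condition: ", cond), con)
  utils::write.table(as.data.frame(shifts$entries), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_shift_table
#' @export
read_shift_table <- function(path) {
  lines <- readLines(path)
  cond <- list(metal = "none", equivalents = 0, pH = NA_real_,
               sequence = c20mms6_sequence)
  ci <- grep("^# condition: ", lines)
  if (length(ci))
    cond <- utils::modifyList(cond, jsonlite::fromJSON(
      sub("^# condition: ", "", lines[ci[1]])))
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  shift_set(df, metal = cond$metal, equivalents = cond$equivalents,
            pH = cond$pH, sequence = cond$sequence)
}

#' Chemical-shift perturbations between apo and holo conditions
#'
#' Per residue: the amide-proton shift change (holo - apo for HN) and the
#' mean shift change over sidechain protons (atoms other than HN/HA)
#' observed in *both* conditions; paramagnetic broadening makes atoms vanish
#' from the holo set, so atoms missing from either side are excluded and
#' counted. Residues with no observed atoms are flagged absent (NA), never
#' reported as zero. The two sets must share the peptide sequence and agree
#' in pH within `pH_tol` -- shift changes from uncontrolled pH drift would
#' otherwise masquerade as binding.
#'
#' @param apo,holo `shift_set` objects.
#' @param pH_tol Maximum allowed pH difference between conditions.
#' @return Tibble of class `perturbation_table`: residue, code,
#'   amide_delta, mean_sidechain_delta, n_sidechain_atoms,
#'   n_missing_sidechain.
#' @export
delta_shifts <- function(apo, holo, pH_tol = 0.05) {
  stopifnot(inherits(apo, "shift_set"), inherits(holo, "shift_set"))
  if (!identical(apo$sequence, holo$sequence))
    stop("sequence mismatch between conditions", call. = FALSE)
  dpH <- abs(apo$condition$pH - holo$condition$pH)
  if (is.finite(dpH) && dpH > pH_tol)
    stop(sprintf(paste0("pH mismatch (%.3f vs %.3f): metal additions acidify ",
                        "the sample and pH must be controlled for shifts to ",
                        "reflect binding"),
                 apo$condition$pH, holo$condition$pH), call. = FALSE)
  codes <- strsplit(apo$sequence, "")[[1]]
  m <- merge(as.data.frame(apo$entries), as.data.frame(holo$entries),
             by = c("residue", "code", "atom"), all = TRUE,
             suffixes = c("_apo", "_holo"))
  m$delta <- m$ppm_holo - m$ppm_apo
  rows <- lapply(seq_along(codes), function(i) {
    mi <- m[m$residue == i, , drop = FALSE]
    sc <- mi[!mi$atom %in% c("HN", "HA"), , drop = FALSE]
    amide <- mi$delta[mi$atom == "HN"]
    tibble::tibble(
      residue = i, code = codes[i],
      amide_delta = if (length(amide) && !is.na(amide[1])) amide[1] else NA_real_,
      mean_sidechain_delta = if (any(!is.na(sc$delta)))
        mean(sc$delta, na.rm = TRUE) else NA_real_,
      n_sidechain_atoms = sum(!is.na(sc$delta)),
      n_missing_sidechain = sum(is.na(sc$delta))
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("perturbation_table", class(out))
  out
}

#' Deviation of observed Halpha shifts from random-coil values
#'
#' For each residue with an observed HA shift, deviation = observed minus
#' the random-coil reference for that residue type; an unstructured peptide
#' shows only small deviations. The summary reports the largest absolute
#' deviation, the mean absolute deviation and its standard deviation.
#'
#' @param shifts A `shift_set`.
#' @param reference Tibble with columns code, atom, ppm covering every
#'   residue type present (default the packaged table).
#' @return List with `per_residue` (tibble residue, code, deviation) and
#'   `summary` (max_abs, mean_abs, sd_abs).
#' @export
random_coil_deviation <- function(shifts, reference = random_coil_reference()) {
  stopifnot(inherits(shifts, "shift_set"))
  ha <- shifts$entries[shifts$entries$atom == "HA", , drop = FALSE]
  ref_ha <- reference[reference$atom == "HA", , drop = FALSE]
  missing_code <- setdiff(unique(ha$code), ref_ha$code)
  if (length(missing_code))
    stop("no random-coil HA reference for residue type(s): ",
         paste(missing_code, collapse = ", "), call. = FALSE)
  ref_map <- stats::setNames(ref_ha$ppm, ref_ha$code)
  dev <- ha$ppm - ref_map[ha$code]
  per <- tibble::tibble(residue = ha$residue, code = ha$code,
                        deviation = as.numeric(dev))
  list(per_residue = per,
       summary = c(max_abs = max(abs(dev)), mean_abs = mean(abs(dev)),
                   sd_abs = stats::sd(abs(dev))))
}

#' Rank perturbation hotspots and report contiguous clusters
#'
#' Residues are ranked by absolute mean sidechain perturbation, ties broken
#' by absolute amide perturbation and then residue index (absent values rank
#' last). The top-k residues are grouped into maximal runs of adjacent
#' sequence positions, the pattern by which acidic binding clusters such as
#' DEEVE reveal themselves.
#'
#' @param table A `perturbation_table` from [delta_shifts()].
#' @param k Number of top residues to report.
#' @return List with `ranked` (tibble, all residues in rank order) and
#'   `clusters` (list of integer vectors of adjacent top-k residues).
#' @export
rank_hotspots <- function(table, k = 4L) {
  stopifnot(nrow(table) > 0)
  sc <- abs(table$mean_sidechain_delta)
  am <- abs(table$amide_delta)
  sc[is.na(sc)] <- -Inf
  am[is.na(am)] <- -Inf
  ord <- order(-sc, -am, table$residue)
  ranked <- table[ord, ]
  top_rows <- seq_len(min(k, nrow(ranked)))
  # only residues with a genuine nonzero perturbation can form clusters;
  # an all-zero table keeps stable index order and reports none
  signal <- pmax(sc[ord][top_rows], am[ord][top_rows]) > 0
  top <- sort(ranked$residue[top_rows][signal])
  clusters <- if (length(top)) {
    unname(split(top, cumsum(c(1, diff(top) != 1))))
  } else list()
  list(ranked = ranked, clusters = clusters)
}

#' Synthetic apo/holo shift-table pair with a perturbation hotspot
#'
#' The apo set sits at the random-coil reference for the peptide (plus a
#' small reproducible jitter emulating assignment scatter); the holo set
#' adds the specified perturbation to every observed proton of the hotspot
#' residues plus Gaussian noise everywhere. Deterministic for a fixed seed.
#'
#' @param hotspot_residues Integer residue indices to perturb (default the
#'   DEEVE acidic residues 11, 12, 13, 15).
#' @param effect_size Perturbation in ppm applied to hotspot protons;
#'   recycled over hotspot residues.
#' @param noise_sd Gaussian noise sd in ppm on every holo proton.
#' @param seed Integer seed.
#' @param metal Holo condition label.
#' @param apo_jitter_sd Scatter of apo shifts about the reference.
#' @param pH Shared condition pH.
#' @return List with elements `apo` and `holo` (`shift_set`s).
#' @export
synth_shift_tables <- function(hotspot_residues = c(11L, 12L, 13L, 15L),
                               effect_size = 0.05, noise_sd = 0.005,
                               seed = 1L, metal = "Fe2",
                               apo_jitter_sd = 0.01, pH = 5.66) {
  codes <- c20_codes()
  if (any(hotspot_residues < 1 | hotspot_residues > length(codes)))
    stop("unknown residue index in hotspot_residues", call. = FALSE)
  stopifnot(all(is.finite(effect_size)), noise_sd >= 0)
  ref <- random_coil_reference()
  entries <- do.call(rbind, lapply(seq_along(codes), function(i) {
    ri <- ref[ref$code == codes[i], ]
    tibble::tibble(residue = i, code = codes[i], atom = ri$atom, ppm = ri$ppm)
  }))
  set.seed(seed)
  apo <- entries
  apo$ppm <- apo$ppm + rnorm(nrow(apo), sd = apo_jitter_sd)
  holo <- apo
  eff <- rep_len(effect_size, length(hotspot_residues))
  for (j in seq_along(hotspot_residues))
    holo$ppm[holo$residue == hotspot_residues[j]] <-
      holo$ppm[holo$residue == hotspot_residues[j]] + eff[j]
  holo$ppm <- holo$ppm + rnorm(nrow(holo), sd = noise_sd)
  list(apo = shift_set(apo, metal = "none", equivalents = 0, pH = pH),
       holo = shift_set(holo, metal = metal, equivalents = 3, pH = pH))
}
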