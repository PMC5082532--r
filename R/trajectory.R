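#' Per-frame ion-site distances and binding classification
#'
#' Computes the minimum-image distance from the ion to every oxygen site in
#' each frame and classifies frames as bound when the ion lies within
#' `cutoff` of at least one site (closed interval: a distance exactly equal
#' to the cutoff counts as bound).
#'
#' @param traj An `ion_trajectory`.
#' @param cutoff Binding cutoff in Angstrom (default 3.0).
#' @param periodic Use minimum-image distances (default); set FALSE for
#'   imported non-periodic trajectories.
#' @return List of class `binding_record`: `distances` (frames x sites
#'   matrix), `bound_any` (logical), `bound_sites` (logical matrix),
#'   `bound_fraction`, `cutoff`.
#' @export
binding_series <- function(traj, cutoff = 3.0, periodic = TRUE) {
  stopifnot(inherits(traj, "ion_trajectory"), cutoff > 0)
  if (!nrow(traj$frames)) stop("empty trajectory", call. = FALSE)
  d <- .min_image_dists(traj$frames, traj$model$positions,
                        traj$model$box_edge, periodic)
  colnames(d) <- traj$model$ids
  bound_sites <- d <= cutoff
  bound_any <- rowSums(bound_sites) > 0
  structure(list(distances = d, bound_any = bound_any,
                 bound_sites = bound_sites,
                 bound_fraction = mean(bound_any), cutoff = cutoff),
            class = "binding_record")
}

#' @export
print.binding_record <- function(x, ...) {
  cat(sprintf("<binding_record> %d frames, cutoff %.2f A, bound fraction %.3f\n",
              length(x$bound_any), x$cutoff, x$bound_fraction))
  invisible(x)
}

#' Per-site occupancy among bound frames
#'
#' Occupancy of a site is the fraction of *bound* frames in which the ion is
#' within the cutoff of that site; sites are banded into high / medium / low
#' categories by the given thresholds. With no bound frames all occupancies
#' are zero.
#'
#' @param record A `binding_record`.
#' @param thresholds Named numeric: minimum occupancy for `high` and
#'   `medium` (everything below is `low`).
#' @return Tibble with columns site, occupancy, category.
#' @export
site_occupancy <- function(record, thresholds = c(high = 0.4, medium = 0.15)) {
  stopifnot(inherits(record, "binding_record"))
  nb <- sum(record$bound_any)
  occ <- if (nb == 0) {
    rep(0, ncol(record$bound_sites))
  } else {
    colSums(record$bound_sites[record$bound_any, , drop = FALSE]) / nb
  }
  cat_of <- function(p) {
    if (p >= thresholds[["high"]]) "high"
    else if (p >= thresholds[["medium"]]) "medium"
    else "low"
  }
  tibble::tibble(site = colnames(record$bound_sites),
                 occupancy = as.numeric(occ),
                 category = unname(vapply(occ, cat_of, "")))
}

#' Conditional co-binding probability P(b bound | a bound)
#'
#' Among frames where the ion is bound to site `a`, the fraction in which it
#' is simultaneously within the cutoff of site `b` (or of *any* of several
#' `b` sites). If `a` is never bound the probability is undefined and
#' returned as NA with a flag, never as 0.
#'
#' @param record A `binding_record`.
#' @param site_a Conditioning site id.
#' @param site_b Target site id(s); bound-to-b means bound to at least one.
#' @return List with `p` (NA if undefined), `n_a`, `n_joint`, `defined`.
#' @export
co_binding <- function(record, site_a, site_b) {
  stopifnot(inherits(record, "binding_record"))
  ids <- colnames(record$bound_sites)
  missing_ids <- setdiff(c(site_a, site_b), ids)
  if (length(missing_ids))
    stop("unknown site id(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  a <- record$bound_sites[, site_a]
  b <- record$bound_sites[, site_b, drop = FALSE]
  joint <- a & (rowSums(b) > 0)
  n_a <- sum(a)
  if (n_a == 0)
    return(list(p = NA_real_, n_a = 0L, n_joint = 0L, defined = FALSE))
  list(p = sum(joint) / n_a, n_a = n_a, n_joint = sum(joint), defined = TRUE)
}

#' Radial distribution function of ion-oxygen separations
#'
#' Histograms the pooled ion-site distances over all frames (and all sites,
#' or a chosen subset), divides each bin by its spherical-shell volume, and
#' normalizes so that the mean of g over the tail window equals one; g then
#' converges to unity at large separations.
#'
#' @param traj An `ion_trajectory`.
#' @param bin_width Bin width in Angstrom.
#' @param r_max Histogram range; must not exceed half the box edge.
#' @param sites Optional site ids to restrict to (for per-site profiles).
#' @param tail_window Length-2 range used for tail normalization; default
#'   the outer 3 Angstrom below `r_max`.
#' @param periodic Minimum-image distances (default TRUE).
#' @return Tibble of class `rdf_profile` with columns `r` (bin centres),
#'   `g`, `counts`; attributes `bin_width`, `tail_window`, `tail_density`.
#' @export
rdf <- function(traj, bin_width = 0.05, r_max = NULL, sites = NULL,
                tail_window = NULL, periodic = TRUE) {
  stopifnot(inherits(traj, "ion_trajectory"), bin_width > 0)
  L <- traj$model$box_edge
  if (is.null(r_max)) r_max <- floor(L / 2)
  if (r_max > L / 2 + 1e-9)
    stop("r_max exceeds half the box edge", call. = FALSE)
  if (is.null(tail_window)) tail_window <- c(r_max - 3, r_max)
  stopifnot(tail_window[1] < tail_window[2], tail_window[2] <= r_max + 1e-9)
  d <- .min_image_dists(traj$frames, traj$model$positions, L, periodic)
  colnames(d) <- traj$model$ids
  if (!is.null(sites)) {
    missing_ids <- setdiff(sites, colnames(d))
    if (length(missing_ids))
      stop("unknown site id(s): ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    d <- d[, sites, drop = FALSE]
  }
  dv <- as.vector(d)
  breaks <- seq(0, r_max, by = bin_width)
  if (tail(breaks, 1) < r_max) breaks <- c(breaks, r_max)
  counts <- tabulate(findInterval(dv, breaks, rightmost.closed = TRUE,
                                  left.open = TRUE),
                     nbins = length(breaks) - 1L)
  centres <- (head(breaks, -1) + tail(breaks, -1)) / 2
  shell <- 4 / 3 * pi * (tail(breaks, -1)^3 - head(breaks, -1)^3)
  dens <- counts / shell
  in_tail <- centres >= tail_window[1] & centres <= tail_window[2]
  if (!any(in_tail) || sum(counts[in_tail]) == 0)
    stop("no counts in tail window; cannot normalize", call. = FALSE)
  tail_density <- sum(counts[in_tail]) / sum(shell[in_tail])
  g <- dens / tail_density
  out <- tibble::tibble(r = centres, g = g, counts = counts)
  attr(out, "bin_width") <- bin_width
  attr(out, "tail_window") <- tail_window
  attr(out, "tail_density") <- tail_density
  attr(out, "n_frames") <- nrow(traj$frames)
  class(out) <- c("rdf_profile", class(out))
  out
}

#' Boltzmann inversion of an RDF into a free-energy profile
#'
#' A(r) = -gas_R * T * ln g(r) wherever g is positive and statistically
#' usable. Bins with zero counts, or with fewer than `min_count` raw counts
#' (where the log-scale sampling error exceeds roughly 0.2 RT), get an
#' absent (NA) free energy rather than an infinite or wild value.
#'
#' @param profile An `rdf_profile` (or tibble with columns r, g and
#'   optionally counts).
#' @param temperature Kelvin.
#' @param min_count Minimum raw bin count for A to be reported; ignored if
#'   the profile carries no counts column.
#' @return Tibble of class `fe_profile` with columns r, g, counts, A
#'   (kJ/mol); attribute `temperature`.
#' @export
free_energy <- function(profile, temperature = 300, min_count = 25) {
  stopifnot(all(c("r", "g") %in% names(profile)), temperature > 0)
  if (any(profile$g < 0, na.rm = TRUE))
    stop("negative g(r)", call. = FALSE)
  A <- ifelse(is.na(profile$g) | profile$g <= 0, NA_real_,
              -gas_R * temperature * log(profile$g))
  if ("counts" %in% names(profile) && !all(is.na(profile$counts)))
    A[!is.na(profile$counts) & profile$counts < min_count] <- NA_real_
  out <- tibble::tibble(r = profile$r, g = profile$g,
                        counts = if ("counts" %in% names(profile))
                          profile$counts else NA_integer_,
                        A = A)
  attr(out, "temperature") <- temperature
  class(out) <- c("fe_profile", class(out))
  out
}

#' Locate the binding well and desorption barrier of a free-energy profile
#'
#' The well is the deepest minimum with A < 0; the barrier is the highest
#' point of the profile beyond the well (its height is zero when A rises
#' monotonically back to the tail level and never exceeds it); the total
#' desorption barrier is |well depth| plus the barrier height. A profile
#' with no negative minimum yields a "no binding well" annotation, not an
#' error.
#'
#' @param profile A `fe_profile` (columns r, A; NAs allowed and skipped).
#' @return List of class `well_barrier`: `well` (r_min, depth), `barrier`
#'   (r_barrier, height), `desorption_barrier`, `has_well`.
#' @export
well_and_barrier <- function(profile) {
  stopifnot(all(c("r", "A") %in% names(profile)))
  ok <- !is.na(profile$A)
  r <- profile$r[ok]
  A <- profile$A[ok]
  if (!length(A) || min(A) >= 0) {
    return(structure(list(has_well = FALSE, well = NULL, barrier = NULL,
                          desorption_barrier = NA_real_),
                     class = "well_barrier"))
  }
  iw <- which.min(A)
  well <- list(r_min = r[iw], depth = A[iw])
  # beyond the well: the highest point of the profile, if above tail level
  height <- 0
  r_barrier <- NA_real_
  if (iw < length(A)) {
    rest_A <- A[(iw + 1):length(A)]
    rest_r <- r[(iw + 1):length(A)]
    ib <- which.max(rest_A)
    if (rest_A[ib] > 0) {
      height <- rest_A[ib]
      r_barrier <- rest_r[ib]
    }
  }
  structure(list(has_well = TRUE, well = well,
                 barrier = list(r_barrier = r_barrier, height = height),
                 desorption_barrier = abs(well$depth) + max(height, 0)),
            class = "well_barrier")
}

#' @export
print.well_barrier <- function(x, ...) {
  if (!x$has_well) {
    cat("<well_barrier> no binding well\n")
  } else {
    cat(sprintf("<well_barrier> well %.2f kJ/mol at %.2f A; barrier +%.2f; desorption %.2f kJ/mol\n",
                x$well$depth, x$well$r_min, x$barrier$height,
                x$desorption_barrier))
  }
  invisible(x)
}

#' Per-site RDF and free-energy profiles
#'
#' Restricts the RDF to each site's own ion distances and transforms each to
#' a free-energy profile, mirroring the per-oxygen decomposition of the
#' aggregate profile. Sites never approached within `r_max` are flagged
#' empty rather than erroring.
#'
#' @param traj An `ion_trajectory`.
#' @param temperature Kelvin.
#' @param ... Passed to [rdf()] (bin_width, r_max, tail_window, periodic).
#' @param min_count Passed to [free_energy()].
#' @return Named list (per site id) of `fe_profile`s, or the string
#'   `"empty"` marker entry where a site has no tail counts.
#' @export
per_site_profiles <- function(traj, temperature = 300, min_count = 25, ...) {
  stopifnot(inherits(traj, "ion_trajectory"))
  out <- lapply(traj$model$ids, function(id) {
    prof <- tryCatch(rdf(traj, sites = id, ...), error = function(e) NULL)
    if (is.null(prof))
      return(structure(list(site = id), class = "empty_profile"))
    free_energy(prof, temperature = temperature, min_count = min_count)
  })
  names(out) <- traj$model$ids
  out
}
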