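#' Signed residual from the schwertmannite line
#'
#' First equivalence points of co-precipitation titrations lie on the line
#' R = 2.75 X (schwertmannite formation at sulfate substitution z = 1/8);
#' the residual E1_R - 2.75 X measures departure from that ideal line.
#'
#' @param E1_R Detected first equivalence point (R units).
#' @param X Ferric molar fraction.
#' @return Signed residual in R units.
#' @export
schwertmannite_residual <- function(E1_R, X) {
  stopifnot(X >= 0, X <= 1)
  E1_R - 2.75 * X
}

new_mineral_fractions <- function(fractions, point = NULL) {
  structure(list(fractions = fractions, point = point),
            class = "mineral_fractions")
}

#' @export
print.mineral_fractions <- function(x, ...) {
  cat("<mineral_fractions>\n")
  for (nm in names(x$fractions))
    cat(sprintf("  %-18s %6.2f %%\n", nm, 100 * x$fractions[[nm]]))
  invisible(x)
}

#' Decompose a titration end point into mineral iron fractions
#'
#' Lever-rule (barycentric) decomposition of a point (X, R) on the
#' mass-balance diagram into iron-molar fractions of three candidate
#' minerals: the unique solution of sum(f) = 1, sum(f * X_i) = X,
#' sum(f * R_i) = R over the candidate vertices. Fractions within `tol` of 0
#' are clamped and the rest renormalized; a fraction below `-tol` means the
#' point lies outside the candidate triangle and is reported as a structured
#' failure rather than a silent answer.
#'
#' @param X,R Coordinates of the end point (typically X from the run
#'   metadata and R from the detected E2).
#' @param candidates Character vector of three registry species names (or
#'   list of `mineral_species`). Default ferrous hydroxide, green rust,
#'   magnetite: the mineral regime for 0 <= X <= 2/3.
#' @param registry Mineral registry.
#' @param tol Clamping tolerance on fractions.
#' @return A `mineral_fractions` object; if the point is out of region, a
#'   list of class `decompose_failure` naming the violated constraint.
#' @export
decompose_E2 <- function(X, R,
                         candidates = c("ferrous_hydroxide", "green_rust",
                                        "magnetite"),
                         registry = mineral_registry(), tol = 1e-6) {
  if (length(candidates) != 3L)
    stop("exactly three candidate species required", call. = FALSE)
  sp <- lapply(candidates, resolve_species, registry = registry)
  nms <- vapply(sp, `[[`, "", "name")
  verts <- lapply(sp, mineral_vertex, registry = registry)
  A <- rbind(rep(1, 3),
             vapply(verts, `[[`, 0, "X"),
             vapply(verts, `[[`, 0, "R"))
  if (abs(det(A)) < 1e-12)
    stop("degenerate vertex geometry: candidate vertices are affinely dependent",
         call. = FALSE)
  f <- solve(A, c(1, X, R))
  names(f) <- nms
  if (any(f < -tol)) {
    viol <- nms[which.min(f)]
    return(structure(list(fractions = f, point = c(X = X, R = R),
                          violated = viol,
                          message = sprintf(
                            "point (X=%.4g, R=%.4g) outside candidate region: %s fraction %.4g < 0",
                            X, R, viol, min(f))),
                     class = "decompose_failure"))
  }
  f[abs(f) < tol] <- 0
  f <- f / sum(f)
  new_mineral_fractions(as.list(f), point = c(X = X, R = R))
}

#' @export
print.decompose_failure <- function(x, ...) {
  cat("<decompose_failure>", x$message, "\n")
  invisible(x)
}

#' Solve an end point with two mineral fractions constrained equal
#'
#' Given only X, finds the iron fractions of the default three-mineral
#' mixture under the constraint that a chosen pair of ferric-bearing
#' minerals carry equal iron fractions, with ferric conservation
#' sum(f * X_i) = X and sum(f) = 1. With the pair (green rust, magnetite)
#' the shared fraction equals X itself: at X = 0.2 the solver returns 20 %
#' magnetite, 20 % green rust, 60 % ferrous hydroxide.
#'
#' @param X Ferric molar fraction, 0 <= X <= 2/3.
#' @param pair Character length 2: the equal-fraction species (must carry
#'   ferric iron).
#' @param third The remaining species.
#' @param registry Mineral registry.
#' @return A `mineral_fractions` object.
#' @export
equal_pair_solve <- function(X, pair = c("green_rust", "magnetite"),
                             third = "ferrous_hydroxide",
                             registry = mineral_registry()) {
  stopifnot(X >= 0, X <= 2/3 + 1e-12, length(pair) == 2L)
  vp <- lapply(pair, mineral_vertex, registry = registry)
  vt <- mineral_vertex(third, registry = registry)
  Xp <- vapply(vp, `[[`, 0, "X")
  if (any(Xp <= 0))
    stop("both pair species must carry ferric iron", call. = FALSE)
  # f*(X1 + X2) + (1 - 2f)*Xt = X
  denom <- sum(Xp) - 2 * vt$X
  if (abs(denom) < 1e-12)
    stop("degenerate constraint: pair and third have equal mean X", call. = FALSE)
  f <- (X - vt$X) / denom
  ft <- 1 - 2 * f
  if (f < -1e-9 || ft < -1e-9)
    stop(sprintf("no feasible equal-pair solution at X = %.4g", X),
         call. = FALSE)
  fr <- stats::setNames(list(ft, f, f),
                        c(resolve_species(third, registry)$name,
                          resolve_species(pair[1], registry)$name,
                          resolve_species(pair[2], registry)$name))
  E2 <- ft * vt$R + f * (vp[[1]]$R + vp[[2]]$R)
  new_mineral_fractions(fr, point = c(X = X, R = E2))
}

#' Mineral-percentage table for a set of runs
#'
#' Decomposes each run's second equivalence point and assembles a
#' long-format table (X, label, species, percent). Rows whose decomposition
#' fails (out-of-region points) are reported with NA percents and the
#' failure message rather than aborting the whole table.
#'
#' @param runs List of lists with elements `X`, `points` (an
#'   `equivalence_points` or a number taken as E2_R) and `label`.
#' @param candidates,registry Passed to [decompose_E2()].
#' @return Tibble with columns X, label, species, percent, note.
#' @export
fraction_table <- function(runs,
                           candidates = c("ferrous_hydroxide", "green_rust",
                                          "magnetite"),
                           registry = mineral_registry()) {
  if (!length(runs))
    return(tibble::tibble(X = numeric(), label = character(),
                          species = character(), percent = numeric(),
                          note = character()))
  out <- lapply(runs, function(run) {
    E2 <- if (inherits(run$points, "equivalence_points")) run$points$E2_R
          else as.numeric(run$points)
    dec <- decompose_E2(run$X, E2, candidates = candidates,
                        registry = registry)
    if (inherits(dec, "decompose_failure")) {
      tibble::tibble(X = run$X, label = run$label,
                     species = names(dec$fractions),
                     percent = NA_real_, note = dec$message)
    } else {
      tibble::tibble(X = run$X, label = run$label,
                     species = names(dec$fractions),
                     percent = unname(100 * unlist(dec$fractions)),
                     note = "")
    }
  })
  do.call(rbind, out)
}
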