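#' Smoothed dpH/dR gradient of a titration curve
#'
#' Savitzky-Golay local-polynomial smoothing differentiates the pH record on
#' the (uniform) R grid, damping logger noise before step detection.
#'
#' @param curve A `titration_curve`.
#' @param window Odd filter window length in samples (> `poly_order`).
#' @param poly_order Local polynomial order.
#' @param deriv 0 for the smoothed pH itself, 1 for dpH/dR.
#' @return Numeric vector on the curve's R grid.
#' @export
smooth_gradient <- function(curve, window = 11L, poly_order = 3L, deriv = 1L) {
  stopifnot(inherits(curve, "titration_curve"))
  n <- nrow(curve$samples)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (window <= poly_order) stop("window must exceed poly_order", call. = FALSE)
  if (window > n) stop("window larger than series", call. = FALSE)
  dR <- stats::median(diff(curve$samples$R))
  if (dR <= 0) stop("R grid must be strictly increasing", call. = FALSE)
  y <- signal::sgolayfilt(curve$samples$pH, p = poly_order, n = window,
                          m = deriv)
  if (deriv == 1L) y <- y / dR
  y
}

#' Detect equivalence points E1, E2 and the central point E*
#'
#' E1 and E2 are the R positions of the two most prominent local maxima of
#' the smoothed dpH/dR gradient (step centres). E* is the midpoint of the
#' second plateau: the span between the point after E1 and before E2 where
#' the gradient falls below `plateau_frac` of the adjacent step peak. The pH
#' at E* is read from the smoothed curve.
#'
#' @param curve A `titration_curve` with at least 50 samples spanning both
#'   steps.
#' @param window,poly_order Smoothing parameters, see [smooth_gradient()].
#' @param plateau_frac Gradient threshold for plateau boundaries, as a
#'   fraction of the adjacent step-peak height.
#' @param peak_min_ratio A gradient maximum only counts as a step if it
#'   exceeds this multiple of the median absolute gradient.
#' @return List of class `equivalence_points`: `E1_R`, `E2_R`, `Estar_R`,
#'   `pH_at_Estar`, and `diagnostics` (peak heights, plateau span, any extra
#'   peaks).
#' @export
detect_equivalence <- function(curve, window = 11L, poly_order = 3L,
                               plateau_frac = 0.2, peak_min_ratio = 3) {
  stopifnot(inherits(curve, "titration_curve"))
  R <- curve$samples$R
  if (nrow(curve$samples) < 50L)
    stop("need at least 50 samples", call. = FALSE)
  if (any(diff(R) <= 0)) {
    keep <- !duplicated(R)
    curve$samples <- curve$samples[keep, ]
    R <- curve$samples$R
    if (any(diff(R) <= 0)) stop("non-monotone R", call. = FALSE)
  }
  grad <- smooth_gradient(curve, window, poly_order, deriv = 1L)
  smooth_pH <- smooth_gradient(curve, window, poly_order, deriv = 0L)

  floor_h <- peak_min_ratio * stats::median(abs(grad))
  pk <- pracma::findpeaks(grad, minpeakheight = floor_h, minpeakdistance = window)
  if (is.null(pk) || nrow(pk) < 2L)
    stop("steps not found: fewer than two gradient peaks above threshold",
         call. = FALSE)
  # prominence proxy: peak height above its flanking minima (cols 3,4 are
  # the peak's extent); keep the two tallest
  ord <- order(pk[, 1], decreasing = TRUE)
  keep <- sort(pk[ord[1:2], 2])
  extra <- if (nrow(pk) > 2) R[pk[ord[-(1:2)], 2]] else numeric(0)
  i1 <- keep[1]; i2 <- keep[2]
  E1 <- R[i1]; E2 <- R[i2]
  h1 <- grad[i1]; h2 <- grad[i2]

  # plateau-2 boundaries: walk right from E1 until grad < plateau_frac*h1,
  # left from E2 until grad < plateau_frac*h2
  right <- i1
  while (right < i2 && grad[right] >= plateau_frac * h1) right <- right + 1L
  left <- i2
  while (left > i1 && grad[left] >= plateau_frac * h2) left <- left - 1L
  if (left <= right) { # pathological narrow plateau: fall back to midpoint
    Estar <- (E1 + E2) / 2
    span <- c(E1, E2)
  } else {
    span <- c(R[right], R[left])
    Estar <- mean(span)
  }
  pH_at_Estar <- stats::approx(R, smooth_pH, xout = Estar)$y

  structure(list(E1_R = E1, E2_R = E2, Estar_R = Estar,
                 pH_at_Estar = pH_at_Estar,
                 diagnostics = list(peak_heights = c(E1 = h1, E2 = h2),
                                    plateau_span = span,
                                    extra_peaks_R = extra)),
            class = "equivalence_points")
}

#' @export
print.equivalence_points <- function(x, ...) {
  cat(sprintf("<equivalence_points> E1 = %.4g, E* = %.4g (pH %.3f), E2 = %.4g\n",
              x$E1_R, x$Estar_R, x$pH_at_Estar, x$E2_R))
  invisible(x)
}

#' Control-vs-additive run deltas
#'
#' Differences between a control and an additive (protein) run at the same
#' X: the pH difference at the central plateau point (each run evaluated at
#' its own E*, the convention used here; set `common_R` to evaluate both
#' smoothed curves at one shared R instead) and the shift in the second
#' equivalence point.
#'
#' @param control,additive Lists with elements `curve` (a
#'   `titration_curve`) and `points` (an `equivalence_points`).
#' @param common_R Optional single R at which to evaluate both runs' pH
#'   instead of each run's own E*.
#' @return List of class `run_delta` with `dpH_at_Estar` and `dE2_R`
#'   (control minus additive).
#' @export
compare_runs <- function(control, additive, common_R = NULL) {
  Xc <- control$curve$meta$X
  Xa <- additive$curve$meta$X
  if (is.null(Xc) || is.null(Xa) || !isTRUE(all.equal(Xc, Xa)))
    stop("control and additive runs must share the same X", call. = FALSE)
  if (is.null(common_R)) {
    dpH <- control$points$pH_at_Estar - additive$points$pH_at_Estar
  } else {
    pH_at <- function(run) {
      sm <- smooth_gradient(run$curve, deriv = 0L)
      stats::approx(run$curve$samples$R, sm, xout = common_R)$y
    }
    dpH <- pH_at(control) - pH_at(additive)
  }
  structure(list(dpH_at_Estar = dpH,
                 dE2_R = control$points$E2_R - additive$points$E2_R,
                 X = Xc),
            class = "run_delta")
}
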