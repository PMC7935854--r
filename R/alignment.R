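#' Rotate dot coordinates about the display center
#'
#' Pure isometry: dot colors, counts and pairwise distances are unchanged.
#'
#' @param dots Dot tibble with `x`, `y` (degrees).
#' @param angle Rotation angle in degrees, counterclockwise.
#' @return The dot tibble with rotated coordinates.
#' @export
rotate_dots <- function(dots, angle) {
  a <- angle * pi / 180
  x <- dots$x * cos(a) - dots$y * sin(a)
  dots$y <- dots$x * sin(a) + dots$y * cos(a)
  dots$x <- x
  dots
}

#' Rotationally align trials to the memorized location
#'
#' Computes, per trial, the rotation that brings the WM sample angle onto the
#' common reference (45 degrees by convention: a sample at 120 degrees gets
#' -75), and excludes trials whose location recall is displaced from the true
#' sample position by more than `exclusion_px` pixels (Euclidean, on the
#' standard 401-pixel grid scale; converted proportionally for other grids).
#' The rotation is stored as a `rotation` column and applied lazily -- on dot
#' coordinates before rasterization -- by [fit_weight_maps()]; aligned recall
#' coordinates are added as `recall_x_aligned`, `recall_y_aligned`.
#'
#' @param trials WM-condition trials with `wm_angle`, `wm_x/wm_y` and
#'   `recall_x/recall_y`.
#' @param reference Common reference angle in degrees.
#' @param exclusion_px Recall-displacement threshold, in pixels of the grid
#'   with `exclusion_grid` pixels per 10.6 degrees.
#' @param exclusion_grid Grid size defining the pixel scale of
#'   `exclusion_px`.
#' @param display_radius Display radius in degrees.
#' @return A list of class `wm_aligned`: `trials` (kept trials, with
#'   `rotation` and aligned recall columns), `excluded` (dropped trials with
#'   their displacement), `threshold_deg`, `reference`.
#' @export
align_trials <- function(trials, reference = 45, exclusion_px = 40,
                         exclusion_grid = 401L, display_radius = 5.3) {
  if (anyNA(trials$wm_angle))
    stop("alignment requires a WM sample on every trial")
  if (anyNA(trials$recall_x) || anyNA(trials$recall_y))
    stop("missing location recall on a WM trial")
  threshold_deg <- exclusion_px * (2 * display_radius / exclusion_grid)
  disp <- sqrt((trials$recall_x - trials$wm_x)^2 +
                 (trials$recall_y - trials$wm_y)^2)
  keep <- disp <= threshold_deg
  rot <- reference - trials$wm_angle
  a <- rot * pi / 180
  out <- trials
  out$rotation <- rot
  out$displacement <- disp
  out$recall_x_aligned <- trials$recall_x * cos(a) - trials$recall_y * sin(a)
  out$recall_y_aligned <- trials$recall_x * sin(a) + trials$recall_y * cos(a)
  structure(list(trials = out[keep, ], excluded = out[!keep, ],
                 threshold_deg = threshold_deg, reference = reference,
                 n_excluded = sum(!keep)),
            class = "wm_aligned")
}

#' @export
print.wm_aligned <- function(x, ...) {
  cat(sprintf(
    "<wm_aligned> %d trials aligned to %g deg, %d excluded (> %.3f deg recall displacement)\n",
    nrow(x$trials), x$reference, x$n_excluded, x$threshold_deg))
  invisible(x)
}

#' Pseudo-align control trials with borrowed sample angles
#'
#' Rotates control trials as if each WM sample had been presented on a
#' control trial too: each control trial borrows an angle from the supplied
#' WM-trial angles (random assignment without replacement; with replacement
#' when there are more control trials than angles). Downstream angular tuning
#' of pseudo-aligned controls is a null control for alignment-locked effects.
#'
#' @param trials Control-condition trials.
#' @param wm_angles Vector of WM sample angles (degrees) to borrow.
#' @param reference Common reference angle in degrees.
#' @return A list of class `wm_aligned` (no exclusions); borrowed angles are
#'   recorded in a `pseudo_wm_angle` column.
#' @export
pseudo_align <- function(trials, wm_angles, reference = 45) {
  if (nrow(trials) == 0) stop("empty control trial set")
  if (length(wm_angles) == 0 || anyNA(wm_angles))
    stop("need a non-missing set of WM angles to borrow")
  n <- nrow(trials)
  ang <- sample(wm_angles, n, replace = n > length(wm_angles))
  out <- trials
  out$pseudo_wm_angle <- ang
  out$rotation <- reference - ang
  structure(list(trials = out, excluded = out[0, ],
                 threshold_deg = NA_real_, reference = reference,
                 n_excluded = 0L),
            class = "wm_aligned")
}
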