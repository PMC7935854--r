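#' Parameters of a simulated observer
#'
#' Bundles the generative parameters of one simulated subject: a spatial gain
#' field anchored to the memorized location, temporal (per-display) integration
#' weights, an additive color bias tied to the working-memory sample, decision
#' noise, lapses, and a noisy recall stage with optional choice-coupled color
#' errors.
#'
#' The decision stage is a logistic-noise evidence integrator. With per-display
#' evidence \eqn{E_k = \sum_{dots} color \cdot (1 + gain_k(x, y))}, the
#' probability of a "blue" choice is
#' \deqn{P(blue) = (1-\lambda)\,L\!\big(\textstyle\sum_k w_k E_k / \sigma_d +
#'   b_{wm}\,s/2\big) + \lambda/2,}
#' where \eqn{L} is the logistic function, \eqn{s = +1} when the memorized
#' color is blue and \eqn{-1} when red (WM trials only), and \eqn{\lambda} is
#' the lapse rate. Parameterized this way, `color_bias` is the log-odds
#' contrast between maintaining blue versus red -- precisely the quantity the
#' psychometric choice model estimates as \eqn{\beta_b - \beta_r}. With
#' `decision_noise = 0` the observer is the deterministic sign-of-evidence
#' ideal observer (exact ties are fair coin flips).
#'
#' The gain field is a radial Gaussian bump of peak amplitude `gain_amp` and
#' width `gain_width` (degrees), centered `gain_radial_offset` degrees from
#' fixation along the fixation-to-sample axis, active only in the display
#' positions listed in `gain_displays`.
#'
#' @param gain_amp Peak multiplicative gain (dimensionless, >= 0). 0 disables
#'   the spatial field.
#' @param gain_width Gaussian SD of the gain bump, degrees.
#' @param gain_radial_offset Distance of the bump center from fixation along
#'   the fixation-to-WM-sample axis, degrees.
#' @param gain_displays Integer subset of 1:6 in which the field is active.
#' @param temporal_weights Nonnegative weights `w_1..w_6` on the six displays.
#' @param color_bias Additive choice bias toward the memorized color, in
#'   log-odds (blue-minus-red intercept contrast).
#' @param decision_noise Scale of the logistic decision noise, in evidence
#'   (dot-count) units per unit log-odds; 0 gives the deterministic observer.
#' @param lapse Lapse rate in `[0, 0.5)`: probability the choice is replaced
#'   by a fair coin.
#' @param recall_loc_sd Isotropic SD of location-recall noise, degrees.
#' @param recall_color_error Probability `[0, 1)` that color recall errs.
#' @param crosstalk Probability `[0, 1]` that an erroneous color recall copies
#'   the decision response instead of flipping the true color.
#' @return An object of class `wm_observer` (a validated named list).
#' @examples
#' obs <- observer_params(color_bias = 0.5)
#' obs$decision_noise
#' @export
observer_params <- function(gain_amp = 0,
                            gain_width = 1.5,
                            gain_radial_offset = 2,
                            gain_displays = 1L,
                            temporal_weights = rep(1, 6),
                            color_bias = 0,
                            decision_noise = 25,
                            lapse = 0,
                            recall_loc_sd = 0.5,
                            recall_color_error = 0.069,
                            crosstalk = 0) {
  stopifnot(
    gain_amp >= 0, gain_width > 0, gain_radial_offset >= 0,
    all(gain_displays %in% 1:6),
    length(temporal_weights) == 6, all(temporal_weights >= 0),
    decision_noise >= 0,
    lapse >= 0, lapse < 0.5,
    recall_loc_sd >= 0,
    recall_color_error >= 0, recall_color_error < 1,
    crosstalk >= 0, crosstalk <= 1
  )
  structure(
    list(
      gain_amp = gain_amp, gain_width = gain_width,
      gain_radial_offset = gain_radial_offset,
      gain_displays = as.integer(gain_displays),
      temporal_weights = as.numeric(temporal_weights),
      color_bias = color_bias, decision_noise = decision_noise,
      lapse = lapse, recall_loc_sd = recall_loc_sd,
      recall_color_error = recall_color_error, crosstalk = crosstalk
    ),
    class = "wm_observer"
  )
}

#' @export
print.wm_observer <- function(x, ...) {
  cat("<wm_observer>\n")
  cat(sprintf("  gain: amp %.3g, width %.3g deg, offset %.3g deg, displays {%s}\n",
              x$gain_amp, x$gain_width, x$gain_radial_offset,
              paste(x$gain_displays, collapse = ",")))
  cat(sprintf("  temporal weights: %s\n",
              paste(format(x$temporal_weights, digits = 3), collapse = " ")))
  cat(sprintf("  color bias %.3g log-odds, decision noise %.3g, lapse %.3g\n",
              x$color_bias, x$decision_noise, x$lapse))
  cat(sprintf("  recall: location SD %.3g deg, color error %.3g, crosstalk %.3g\n",
              x$recall_loc_sd, x$recall_color_error, x$crosstalk))
  invisible(x)
}

# gain field value at dot coordinates, for WM sample at angle phi (degrees)
observer_gain <- function(obs, x, y, wm_angle) {
  if (obs$gain_amp == 0) return(rep(0, length(x)))
  phi <- wm_angle * pi / 180
  bx <- obs$gain_radial_offset * cos(phi)
  by <- obs$gain_radial_offset * sin(phi)
  obs$gain_amp * exp(-((x - bx)^2 + (y - by)^2) / (2 * obs$gain_width^2))
}
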