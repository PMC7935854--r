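#' Display geometry of the dot-stream task
#'
#' Geometry of one stimulus display: a circular area of 10.6 degrees visual
#' angle diameter containing 20 dots of 0.3 degree diameter, none overlapping
#' and all at least `edge_margin` from the outer border.
#'
#' @param display_radius Radius of the circular display area, degrees (5.3).
#' @param dot_diameter Dot diameter, degrees (0.3).
#' @param edge_margin Minimum distance between a dot's edge and the display
#'   border, degrees (0.3).
#' @param n_dots Dots per display (20).
#' @return A named list of class `wm_geometry`.
#' @export
display_geometry <- function(display_radius = 5.3, dot_diameter = 0.3,
                             edge_margin = 0.3, n_dots = 20L) {
  stopifnot(display_radius > 0, dot_diameter > 0, edge_margin >= 0,
            n_dots >= 1)
  r_allowed <- display_radius - edge_margin - dot_diameter / 2
  if (r_allowed <= 0)
    stop("infeasible geometry: no room inside the display for dot centers")
  structure(list(display_radius = display_radius, dot_diameter = dot_diameter,
                 edge_margin = edge_margin, n_dots = as.integer(n_dots),
                 r_allowed = r_allowed),
            class = "wm_geometry")
}

#' Draw signed blue-minus-red dot count differences
#'
#' Differences are drawn from a normal distribution truncated at one standard
#' deviation around its mean and rounded to the nearest integer with the same
#' parity as the total dot count. With the task defaults (mean +4 or -4,
#' SD 10, 20 dots) this yields exactly 11 realizable levels at even offsets
#' -10..+10 around the mean.
#'
#' @param n Number of draws.
#' @param mean Mean of the (pre-truncation) normal, signed dot count. May
#'   include a small constant presentation shift.
#' @param sd Standard deviation; the distribution is truncated to
#'   `[mean - sd, mean + sd]`.
#' @param n_dots Total dots per display; determines parity and feasibility.
#' @return Integer vector of signed differences.
#' @examples
#' set.seed(1)
#' table(sample_color_difference(1e4, mean = 4))
#' @export
sample_color_difference <- function(n, mean = 4, sd = 10, n_dots = 20L) {
  if (abs(mean) + sd > n_dots)
    stop(sprintf(
      "infeasible configuration: |mean| + sd = %.1f exceeds the %d-dot total",
      abs(mean) + sd, n_dots))
  x <- if (sd == 0) rep(mean, n) else
    mean + sd * qnorm(runif(n, pnorm(-1), pnorm(1)))
  round_to_parity(x, n_dots %% 2L)
}

# nearest integer of given parity (0 even, 1 odd)
round_to_parity <- function(x, parity) {
  if (parity == 0L) 2L * as.integer(round(x / 2)) else
    2L * as.integer(round((x - 1) / 2)) + 1L
}

#' Bin probabilities of the truncated-normal difference distribution
#'
#' Analytic probability of each realizable difference level under the
#' one-SD-truncated normal generative rule, obtained by integrating the
#' truncated density over each rounding bin. Used as the goodness-of-fit
#' reference for generated stimuli.
#'
#' @inheritParams sample_color_difference
#' @return A tibble with columns `level` (signed difference) and `prob`.
#' @export
color_difference_probs <- function(mean = 4, sd = 10, n_dots = 20L) {
  step <- 2 - n_dots %% 2L  # grid spacing: 2 for even totals, 1 for odd
  lo <- round_to_parity(mean - sd, n_dots %% 2L)
  hi <- round_to_parity(mean + sd, n_dots %% 2L)
  levels <- seq(lo, hi, by = step)
  z <- function(v) pmin(pmax((v - mean) / sd, -1), 1)
  denom <- pnorm(1) - pnorm(-1)
  prob <- vapply(levels, function(l) {
    (pnorm(z(l + step / 2)) - pnorm(z(l - step / 2))) / denom
  }, numeric(1))
  tibble::tibble(level = levels, prob = prob)
}

#' Place dots uniformly in the display area
#'
#' Positions are sampled uniformly in the allowed disc by rejection, enforcing
#' no overlap (pairwise center distance at least one dot diameter). Colors are
#' assigned to positions at random, independently of location.
#'
#' @param n_blue Number of blue dots; the remaining dots are red.
#' @param geometry A [display_geometry()].
#' @param max_tries Rejection-sampling cap per dot before erroring.
#' @return A tibble with columns `x`, `y` (degrees, origin at display center,
#'   x rightward, y upward) and `color` (+1 blue, -1 red).
#' @examples
#' set.seed(1)
#' place_dots(13)
#' @export
place_dots <- function(n_blue, geometry = display_geometry(),
                       max_tries = 1e4) {
  n <- geometry$n_dots
  stopifnot(n_blue >= 0, n_blue <= n)
  xy <- cpp_place_dots(1L, n, geometry$r_allowed, geometry$dot_diameter,
                       as.integer(max_tries))
  color <- rep(-1, n)
  color[sample.int(n, n_blue)] <- 1
  tibble::tibble(x = xy[, 1], y = xy[, 2], color = color)
}

#' Generate one task trial (stimuli only, responses absent)
#'
#' Draws the working-memory sample (uniform angle on a 3.8-degree circle,
#' fair-coin color; omitted in condition `"control1"`) and six independent dot
#' displays whose blue-minus-red differences are drawn around
#' `stream_mean + shift`.
#'
#' @param condition One of `"WM"`, `"control1"`, `"control2"`.
#' @param group Task framing, `"averaging"` or `"gambling"` (metadata only).
#' @param stream_mean Signed mean dot difference of the stream (+4 or -4 in
#'   the task design).
#' @param shift Constant presentation offset added to the mean (default 0;
#'   the original task inadvertently shifted all streams by 1 dot).
#' @param geometry A [display_geometry()].
#' @param sd Truncated-normal SD of the difference distribution.
#' @param wm_radius Radius of the circle on which the WM sample lies, degrees.
#' @param include_dots If `FALSE`, skip dot placement and return counts only
#'   (sufficient for purely psychometric simulations; much faster).
#' @return A list with `trial` (one-row tibble) and `dots` (tibble with
#'   `display`, `x`, `y`, `color`; `NULL` if `include_dots = FALSE`).
#' @export
generate_trial <- function(condition = c("WM", "control1", "control2"),
                           group = c("averaging", "gambling"),
                           stream_mean = 4, shift = 0,
                           geometry = display_geometry(), sd = 10,
                           wm_radius = 3.8, include_dots = TRUE) {
  condition <- match.arg(condition)
  group <- match.arg(group)
  diffs <- sample_color_difference(6L, stream_mean + shift, sd,
                                   geometry$n_dots)
  has_wm <- condition != "control1"
  wm_angle <- if (has_wm) runif(1, 0, 360) else NA_real_
  wm_color <- if (has_wm) sample(c("blue", "red"), 1) else NA_character_
  trial <- tibble::tibble(
    condition = condition, group = group,
    stream_mean = stream_mean, shift = shift,
    wm_color = wm_color, wm_angle = wm_angle,
    wm_x = if (has_wm) wm_radius * cos(wm_angle * pi / 180) else NA_real_,
    wm_y = if (has_wm) wm_radius * sin(wm_angle * pi / 180) else NA_real_
  )
  for (k in 1:6) trial[[paste0("diff_", k)]] <- diffs[k]
  dots <- NULL
  if (include_dots) {
    n <- geometry$n_dots
    xy <- cpp_place_dots(6L, n, geometry$r_allowed, geometry$dot_diameter,
                         10000L)
    color <- unlist(lapply(1:6, function(k) {
      cl <- rep(-1, n)
      cl[sample.int(n, (n + diffs[k]) / 2)] <- 1
      cl
    }))
    dots <- tibble::tibble(display = rep(1:6, each = n),
                           x = xy[, 1], y = xy[, 2], color = color)
  }
  list(trial = trial, dots = dots)
}

# per-display evidence: sum of color * (1 + gain) over dots
trial_evidence <- function(obs, trial, dots) {
  diffs <- as.numeric(trial[paste0("diff_", 1:6)])
  if (obs$gain_amp == 0 || is.null(dots) || is.na(trial$wm_angle))
    return(diffs)
  ev <- diffs
  for (k in obs$gain_displays) {
    d <- dots[dots$display == k, ]
    g <- observer_gain(obs, d$x, d$y, trial$wm_angle)
    ev[k] <- sum(d$color * (1 + g))
  }
  ev
}

#' Simulate the observer's choice on one trial
#'
#' Applies the logistic-noise evidence integration rule described in
#' [observer_params()]. The additive color bias acts only on `"WM"` trials
#' (concurrent maintenance).
#'
#' @param trial One-row trial tibble from [generate_trial()].
#' @param dots Dot tibble for the trial (needed only when the gain field is
#'   active).
#' @param observer A [observer_params()] object.
#' @return `"blue"` or `"red"`.
#' @export
simulate_choice <- function(trial, dots, observer) {
  ev <- trial_evidence(observer, trial, dots)
  dv <- sum(observer$temporal_weights * ev)
  s <- if (identical(trial$condition, "WM") && !is.na(trial$wm_color))
    ifelse(trial$wm_color == "blue", 1, -1) else 0
  p <- if (observer$decision_noise == 0) {
    base <- (dv > 0) + 0.5 * (dv == 0)
    if (s != 0 && observer$color_bias != 0 && dv == 0)
      plogis(observer$color_bias * s / 2) else base
  } else {
    plogis(dv / observer$decision_noise + observer$color_bias * s / 2)
  }
  p <- (1 - observer$lapse) * p + observer$lapse / 2
  if (runif(1) < p) "blue" else "red"
}

#' Simulate working-memory recall for one trial
#'
#' Location recall is the true sample position plus isotropic Gaussian noise.
#' Color recall is correct with probability `1 - recall_color_error`; on an
#' error, the report copies the decision response with probability `crosstalk`
#' and otherwise flips the true color. On `"control2"` trials recall precedes
#' the stream, so errors are always independent flips.
#'
#' @inheritParams simulate_choice
#' @param choice The decision response on the trial (`"blue"`/`"red"`/`NA`).
#' @return A one-row tibble with `recall_color`, `recall_x`, `recall_y`.
#' @export
simulate_recall <- function(trial, choice, observer) {
  stopifnot(!is.na(trial$wm_color))
  rx <- trial$wm_x + rnorm(1, 0, observer$recall_loc_sd)
  ry <- trial$wm_y + rnorm(1, 0, observer$recall_loc_sd)
  col <- trial$wm_color
  if (runif(1) < observer$recall_color_error) {
    coupled <- identical(trial$condition, "WM") && !is.na(choice) &&
      runif(1) < observer$crosstalk
    col <- if (coupled) choice else setdiff(c("blue", "red"), trial$wm_color)
  }
  tibble::tibble(recall_color = col, recall_x = rx, recall_y = ry)
}

#' Simulate a session of one subject
#'
#' Generates `n_trials` complete trials of one condition (stimuli, choice,
#' and -- where the condition includes a WM sample -- recall) for a single
#' simulated observer. Stream means alternate at random between the entries
#' of `stream_means`. Regeneration from the same `seed` is bit-identical.
#'
#' @param n_trials Number of trials.
#' @param observer A [observer_params()].
#' @param condition,group,shift,geometry,sd,wm_radius,include_dots As in
#'   [generate_trial()].
#' @param stream_means Candidate stream means, sampled per trial.
#' @param seed Optional integer seed.
#' @return A list of class `wm_session`: `trials` (one row per trial,
#'   including responses) and `dots` (long table keyed by `trial_id`,
#'   `display`; `NULL` without dots).
#' @examples
#' sess <- simulate_session(20, observer_params(), seed = 1)
#' head(sess$trials)
#' @export
simulate_session <- function(n_trials, observer = observer_params(),
                             condition = c("WM", "control1", "control2"),
                             group = c("averaging", "gambling"),
                             stream_means = c(-4, 4), shift = 0,
                             geometry = display_geometry(), sd = 10,
                             wm_radius = 3.8, include_dots = TRUE,
                             seed = NULL) {
  condition <- match.arg(condition)
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_trials)
  nd <- geometry$n_dots
  has_wm <- condition != "control1"

  if (max(abs(stream_means + shift)) + sd > nd)
    stop(sprintf(
      "infeasible configuration: |mean| + sd = %.1f exceeds the %d-dot total",
      max(abs(stream_means + shift)) + sd, nd))
  m <- if (length(stream_means) == 1) rep(stream_means, n) else
    sample(stream_means, n, replace = TRUE)
  z <- if (sd == 0) rep(0, 6L * n) else
    sd * qnorm(runif(6L * n, pnorm(-1), pnorm(1)))
  diffs <- matrix(round_to_parity(rep(m, each = 6L) + shift + z, nd %% 2L),
                  nrow = n, ncol = 6L, byrow = TRUE)

  wm_angle <- if (has_wm) runif(n, 0, 360) else rep(NA_real_, n)
  wm_color <- if (has_wm) sample(c("blue", "red"), n, replace = TRUE) else
    rep(NA_character_, n)

  dots <- NULL
  if (include_dots) {
    xy <- cpp_place_dots(6L * n, nd, geometry$r_allowed,
                         geometry$dot_diameter, 10000L)
    # random color assignment within each display, independent of position
    n_blue <- as.integer((nd + t(diffs)) / 2)      # display-major order
    u <- matrix(runif(6L * n * nd), nrow = nd)
    rk <- matrix(0L, nrow = nd, ncol = 6L * n)
    for (j in seq_len(6L * n)) rk[, j] <- rank(u[, j], ties.method = "first")
    color <- ifelse(rk <= rep(n_blue, each = nd), 1, -1)
    dots <- tibble::tibble(
      trial_id = rep(seq_len(n), each = 6L * nd),
      display = rep(rep(1:6, each = nd), times = n),
      x = xy[, 1], y = xy[, 2], color = as.vector(color)
    )
  }

  # evidence per display: counts, plus gain-field modulation where active
  ev <- diffs
  if (observer$gain_amp > 0 && has_wm && include_dots) {
    for (k in observer$gain_displays) {
      d <- dots[dots$display == k, ]
      g <- observer_gain(observer, d$x, d$y, rep(wm_angle, each = nd))
      ev[, k] <- rowsum(d$color * g, d$trial_id)[, 1] + diffs[, k]
    }
  }

  dv <- as.vector(ev %*% observer$temporal_weights)
  s <- if (condition == "WM") ifelse(wm_color == "blue", 1, -1) else
    rep(0, n)
  p <- if (observer$decision_noise == 0)
    (dv > 0) + 0.5 * (dv == 0) else
    plogis(dv / observer$decision_noise + observer$color_bias * s / 2)
  p <- (1 - observer$lapse) * p + observer$lapse / 2
  choice <- ifelse(runif(n) < p, "blue", "red")

  trials <- tibble::tibble(
    trial_id = seq_len(n), condition = condition, group = group,
    stream_mean = m, shift = shift, wm_color = wm_color,
    wm_angle = wm_angle,
    wm_x = if (has_wm) wm_radius * cos(wm_angle * pi / 180) else NA_real_,
    wm_y = if (has_wm) wm_radius * sin(wm_angle * pi / 180) else NA_real_
  )
  for (k in 1:6) trials[[paste0("diff_", k)]] <- diffs[, k]
  trials$choice <- choice

  if (has_wm) {
    trials$recall_x <- trials$wm_x + rnorm(n, 0, observer$recall_loc_sd)
    trials$recall_y <- trials$wm_y + rnorm(n, 0, observer$recall_loc_sd)
    err <- runif(n) < observer$recall_color_error
    coupled <- err & condition == "WM" &
      runif(n) < observer$crosstalk
    flipped <- ifelse(wm_color == "blue", "red", "blue")
    trials$recall_color <- ifelse(!err, wm_color,
                                  ifelse(coupled, choice, flipped))
  } else {
    trials$recall_color <- NA_character_
    trials$recall_x <- NA_real_
    trials$recall_y <- NA_real_
  }

  out <- list(trials = trials, dots = dots, geometry = geometry,
              observer = observer, seed = seed)
  class(out) <- "wm_session"
  out
}

#' Simulate a cohort of subjects
#'
#' Runs [simulate_session()] for each subject and binds the results with a
#' `subject` column. `observer` may be a single parameter set (shared) or a
#' list of one per subject.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials Trials per subject.
#' @param observer A [observer_params()] or list of them, one per subject.
#' @param seed Optional integer seed governing the whole cohort.
#' @inheritParams simulate_session
#' @return A list of class `wm_cohort` with `trials` and `dots` tibbles
#'   (both carrying `subject`).
#' @export
simulate_cohort <- function(n_subjects, n_trials,
                            observer = observer_params(),
                            condition = "WM", group = "averaging",
                            stream_means = c(-4, 4), shift = 0,
                            geometry = display_geometry(), sd = 10,
                            wm_radius = 3.8, include_dots = TRUE,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs_list <- if (inherits(observer, "wm_observer"))
    rep(list(observer), n_subjects) else observer
  stopifnot(length(obs_list) == n_subjects)
  sessions <- lapply(seq_len(n_subjects), function(s) {
    ss <- simulate_session(n_trials, obs_list[[s]], condition, group,
                           stream_means, shift, geometry, sd, wm_radius,
                           include_dots, seed = NULL)
    ss$trials$subject <- s
    if (!is.null(ss$dots)) ss$dots$subject <- s
    ss
  })
  out <- list(
    trials = dplyr::relocate(
      dplyr::bind_rows(lapply(sessions, `[[`, "trials")), "subject"),
    dots = if (include_dots)
      dplyr::relocate(
        dplyr::bind_rows(lapply(sessions, `[[`, "dots")), "subject")
      else NULL,
    geometry = geometry, observers = obs_list, seed = seed
  )
  class(out) <- "wm_cohort"
  out
}
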