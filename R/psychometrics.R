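#' Reverse-correlation psychometric weighting function
#'
#' For each display position (1-6) and each excess-count level (the
#' blue-minus-red count relative to the stream's generative mean, the 11 even
#' offsets -10..+10 under the task defaults), computes the relative frequency
#' with which the stream was judged blue. Empty cells are reported as missing
#' (absent rows), not zero.
#'
#' @param trials Trial tibble with `choice`, `diff_1..diff_6`, `stream_mean`,
#'   `shift`; a `subject` column, if present, is respected.
#' @return A tibble `subject?, display, level, n, p_blue`.
#' @examples
#' sess <- simulate_session(200, observer_params(), include_dots = FALSE,
#'                          seed = 1)
#' weighting_function(sess$trials)
#' @export
weighting_function <- function(trials) {
  stopifnot(!anyNA(trials$choice))
  long <- tidyr::pivot_longer(
    trials, dplyr::all_of(paste0("diff_", 1:6)),
    names_to = "display", names_prefix = "diff_", values_to = "diff"
  )
  long$display <- as.integer(long$display)
  long$level <- long$diff - long$stream_mean - long$shift
  keys <- c(if ("subject" %in% names(trials)) "subject", "display", "level")
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n = dplyr::n(),
                     p_blue = mean(.data$choice == "blue"),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
}

#' Fit the logistic choice model
#'
#' Maximum-likelihood logistic regression of choice on the excess blue-minus-
#' red dot count of each of the six stream displays,
#' \deqn{P(blue) = L\big(\beta_b c_{wm} + \beta_r (1 - c_{wm}) +
#'   \textstyle\sum_{k=1}^{6} \beta_k c_k\big),}
#' where \eqn{c_{wm}} codes the memorized color (1 blue, 0 red). On control
#' trials without a concurrent memory item a single intercept \eqn{\beta_0}
#' replaces the two color-tied intercepts. Standard errors come from the
#' observed information. Fits showing quasi-complete separation (any
#' coefficient exceeding 15 in magnitude on standardized predictors, or
#' fitted probabilities collapsing to 0/1) are flagged; flagged fits are
#' excluded from residual-based analyses downstream.
#'
#' @param trials Trial tibble (`choice`, `diff_1..diff_6`, and `wm_color`
#'   for the memory condition).
#' @param condition `"WM"` for the color-tied intercepts, `"control"` for a
#'   single intercept; inferred from `trials$condition` by default.
#' @param response Optional binary/character response vector replacing
#'   `trials$choice` (used e.g. to model recall reports with the same
#'   stimulus terms).
#' @return A `wm_psychfit` object.
#' @export
fit_choice_model <- function(trials, condition = NULL, response = NULL) {
  if (is.null(condition))
    condition <- if (all(trials$condition == "WM")) "WM" else "control"
  condition <- match.arg(condition, c("WM", "control"))
  y <- if (is.null(response)) trials$choice else response
  if (is.character(y)) y <- as.numeric(y == "blue")
  stopifnot(length(y) == nrow(trials), !anyNA(y))
  if (length(unique(y)) < 2)
    return(new_psychfit(NULL, condition, n = nrow(trials), degenerate = TRUE))
  df <- trials[paste0("diff_", 1:6)]
  names(df) <- paste0("c", 1:6)
  df$y <- y
  if (condition == "WM") {
    stopifnot(!anyNA(trials$wm_color))
    df$wm_blue <- as.numeric(trials$wm_color == "blue")
    df$wm_red <- 1 - df$wm_blue
    fml <- y ~ 0 + wm_blue + wm_red + c1 + c2 + c3 + c4 + c5 + c6
  } else {
    fml <- y ~ c1 + c2 + c3 + c4 + c5 + c6
  }
  fit <- suppressWarnings(glm(fml, family = binomial(), data = df))
  co <- coef(fit)
  xsd <- vapply(df[paste0("c", 1:6)], sd, numeric(1))
  std_mag <- c(abs(co[!grepl("^c", names(co))]),
               abs(co[paste0("c", 1:6)]) * xsd)
  separated <- !fit$converged || any(!is.finite(co)) ||
    any(std_mag > 15, na.rm = TRUE)
  new_psychfit(fit, condition, n = nrow(trials), separated = separated)
}

new_psychfit <- function(fit, condition, n, separated = FALSE,
                         degenerate = FALSE) {
  structure(list(fit = fit, condition = condition, n = n,
                 separated = separated, degenerate = degenerate),
            class = "wm_psychfit")
}

#' @export
print.wm_psychfit <- function(x, ...) {
  cat(sprintf("<wm_psychfit> %s condition, %d trials%s%s\n", x$condition,
              x$n, if (x$separated) ", SEPARATED" else "",
              if (x$degenerate) ", DEGENERATE (constant response)" else ""))
  if (!is.null(x$fit)) print(coef(x$fit))
  invisible(x)
}

#' @describeIn fit_choice_model Coefficients as a tibble (`term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`), with intercept terms named
#'   `beta_b`/`beta_r` (or `beta_0`) and slopes `beta_1..beta_6`.
#' @param x A `wm_psychfit`.
#' @param ... Unused.
#' @method tidy wm_psychfit
#' @export
tidy.wm_psychfit <- function(x, ...) {
  if (is.null(x$fit)) return(tibble::tibble())
  s <- summary(x$fit)$coefficients
  term <- rownames(s)
  term[term == "wm_blue"] <- "beta_b"
  term[term == "wm_red"] <- "beta_r"
  term[term == "(Intercept)"] <- "beta_0"
  term <- sub("^c", "beta_", term)
  tibble::tibble(term = term, estimate = s[, 1], std_error = s[, 2],
                 statistic = s[, 3], p_value = s[, 4])
}

#' @describeIn fit_choice_model One-row model summary (`n`, `log_lik`,
#'   `deviance`, `converged`, `separated`, `degenerate`, `condition`).
#' @method glance wm_psychfit
#' @export
glance.wm_psychfit <- function(x, ...) {
  tibble::tibble(
    n = x$n, condition = x$condition,
    log_lik = if (is.null(x$fit)) NA_real_ else
      as.numeric(stats::logLik(x$fit)),
    deviance = if (is.null(x$fit)) NA_real_ else x$fit$deviance,
    converged = if (is.null(x$fit)) FALSE else x$fit$converged,
    separated = x$separated, degenerate = x$degenerate
  )
}

# coefficient accessor tolerant of term naming
psych_coef <- function(x) {
  if (is.null(x$fit)) stop("degenerate psychometric fit has no coefficients")
  coef(x$fit)
}

#' Predicted choice probabilities of a psychometric fit
#'
#' @param fit A [fit_choice_model()] object.
#' @param trials Trials to predict for (same columns as used in fitting).
#' @return Numeric vector of probabilities of choosing blue.
#' @export
predict_choice <- function(fit, trials) {
  if (fit$degenerate) stop("cannot predict from a degenerate fit")
  df <- trials[paste0("diff_", 1:6)]
  names(df) <- paste0("c", 1:6)
  if (fit$condition == "WM") {
    df$wm_blue <- as.numeric(trials$wm_color == "blue")
    df$wm_red <- 1 - df$wm_blue
  }
  as.numeric(predict(fit$fit, newdata = df, type = "response"))
}

#' Additive working-memory choice-bias magnitude
#'
#' The log-odds choice-bias contrast between maintaining a blue versus a red
#' sample, \eqn{\beta_b - \beta_r}. When a control fit is supplied, its
#' neutral intercept \eqn{\beta_0} is reported alongside.
#'
#' @param fit_wm A WM-condition [fit_choice_model()].
#' @param fit_control Optional pooled-control fit.
#' @return One-row tibble with `bias`, `beta_b`, `beta_r` and (if available)
#'   `control_beta0`.
#' @export
bias_magnitude <- function(fit_wm, fit_control = NULL) {
  stopifnot(fit_wm$condition == "WM")
  if (fit_wm$separated || fit_wm$degenerate)
    stop("flagged psychometric fit: bias magnitude unavailable")
  co <- psych_coef(fit_wm)
  out <- tibble::tibble(bias = unname(co["wm_blue"] - co["wm_red"]),
                        beta_b = unname(co["wm_blue"]),
                        beta_r = unname(co["wm_red"]))
  if (!is.null(fit_control))
    out$control_beta0 <- unname(psych_coef(fit_control)["(Intercept)"])
  out
}

#' Recency slope of the per-display sensitivities
#'
#' Ordinary least-squares slope of the fitted sensitivities
#' \eqn{\beta_1..\beta_6} against display position; positive values indicate
#' stronger weighting of later stream displays (recency).
#'
#' @param fit A [fit_choice_model()] object.
#' @return The slope (log-odds per display position).
#' @export
recency_slope <- function(fit) {
  co <- psych_coef(fit)
  b <- unname(co[paste0("c", 1:6)])
  unname(coef(lm(b ~ seq_along(b)))[2])
}

#' Compare recency between conditions across subjects
#'
#' Paired t-test, across subjects, of the per-subject difference in recency
#' slope between two sets of fits (typically WM minus pooled control).
#'
#' @param fits_a,fits_b Lists of [fit_choice_model()] objects, one per
#'   subject, in matching order.
#' @return One-row tibble: `mean_diff`, `statistic`, `df`, `p_value`.
#' @export
compare_recency <- function(fits_a, fits_b) {
  stopifnot(length(fits_a) == length(fits_b), length(fits_a) >= 2)
  d <- vapply(seq_along(fits_a), function(i)
    recency_slope(fits_a[[i]]) - recency_slope(fits_b[[i]]), numeric(1))
  tt <- t.test(d)
  tibble::tibble(mean_diff = mean(d), statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value)
}

#' Per-trial choice residuals
#'
#' Observed binary response minus the probability predicted by the
#' psychometric model; the endogenous choice variability left unexplained by
#' any stimulus information. Unavailable (error) for separation-flagged fits,
#' mirroring the exclusion of perfectly separated subjects from residual
#' analyses.
#'
#' @param fit A [fit_choice_model()] object (not flagged).
#' @param trials Trials the fit was obtained on.
#' @param response Optional response vector overriding `trials$choice`.
#' @return Numeric vector of residuals in (-1, 1).
#' @export
choice_residuals <- function(fit, trials, response = NULL) {
  if (fit$separated || fit$degenerate)
    stop("flagged psychometric fit: residuals unavailable")
  y <- if (is.null(response)) trials$choice else response
  if (is.character(y)) y <- as.numeric(y == "blue")
  y - predict_choice(fit, trials)
}
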