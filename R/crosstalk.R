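#' Regression of color recall on the decision stream
#'
#' The reverse direction of interference: does the blue-red composition of
#' the intervening decision displays bias later recall of the memorized
#' color? Per subject, recall reports (blue/red) are modeled with the full
#' psychometric structure -- color-tied intercepts plus either the six
#' per-display excess counts (`pooled = FALSE`, slopes `gamma_1..gamma_6`)
#' or their per-trial mean as a single predictor (`pooled = TRUE`, the
#' pooled slope). Subjects whose recall is error-free (or otherwise
#' separates) are flagged and excluded from the group test, which is a
#' one-sample t-test of the per-subject pooled slopes against zero.
#'
#' @param trials WM trials of one or more subjects (needs `recall_color`).
#' @param pooled Use the mean excess count as a single predictor for the
#'   group-tested slope (default); per-display slopes are always reported.
#' @return A `wm_recall_bias` object: `slopes` (tibble `subject, term,
#'   estimate, std_error`), `pooled` (tibble `subject, slope, std_error,
#'   flagged`), `test` (one-row tibble), `n_flagged`.
#' @export
recall_color_regression <- function(trials, pooled = TRUE) {
  stopifnot(!anyNA(trials$wm_color))
  if (anyNA(trials$recall_color)) stop("missing color recall on a WM trial")
  if (!"subject" %in% names(trials)) trials$subject <- 1L
  per_subject <- function(tr) {
    fit6 <- fit_choice_model(tr, condition = "WM",
                             response = tr$recall_color)
    cbar <- rowMeans(tr[paste0("diff_", 1:6)])
    dfp <- tibble::tibble(y = as.numeric(tr$recall_color == "blue"),
                          wm_blue = as.numeric(tr$wm_color == "blue"),
                          wm_red = as.numeric(tr$wm_color == "red"),
                          cbar = cbar)
    fitp <- suppressWarnings(
      glm(y ~ 0 + wm_blue + wm_red + cbar, binomial(), data = dfp))
    sep_p <- !fitp$converged || any(abs(coef(fitp)[c("wm_blue", "wm_red")]) > 15) ||
      abs(coef(fitp)["cbar"]) * sd(cbar) > 15
    flagged <- fit6$separated || fit6$degenerate || sep_p
    pooled_slope <- if (pooled) unname(coef(fitp)["cbar"]) else {
      if (fit6$degenerate) NA_real_ else
        mean(psych_coef(fit6)[paste0("c", 1:6)])
    }
    pooled_se <- if (pooled)
      unname(summary(fitp)$coefficients["cbar", 2]) else NA_real_
    slopes <- if (fit6$degenerate) tibble::tibble() else {
      td <- tidy(fit6)
      td <- td[grepl("^beta_[1-6]$", td$term), ]
      tibble::tibble(subject = tr$subject[1],
                     term = sub("beta", "gamma", td$term),
                     estimate = td$estimate, std_error = td$std_error)
    }
    list(slopes = slopes,
         pooled = tibble::tibble(subject = tr$subject[1],
                                 slope = pooled_slope,
                                 std_error = pooled_se, flagged = flagged))
  }
  parts <- trials |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_map(~ per_subject(.x |>
                                     dplyr::mutate(subject = .y$subject)))
  pooled_tbl <- dplyr::bind_rows(lapply(parts, `[[`, "pooled"))
  ok <- pooled_tbl[!pooled_tbl$flagged & is.finite(pooled_tbl$slope), ]
  test <- if (nrow(ok) >= 2) {
    tt <- t.test(ok$slope)
    tibble::tibble(mean_slope = mean(ok$slope),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value,
                   n_subjects = nrow(ok))
  } else NULL
  structure(list(slopes = dplyr::bind_rows(lapply(parts, `[[`, "slopes")),
                 pooled = pooled_tbl, test = test,
                 n_flagged = sum(pooled_tbl$flagged)),
            class = "wm_recall_bias")
}

#' @export
print.wm_recall_bias <- function(x, ...) {
  cat(sprintf("<wm_recall_bias> %d subjects (%d flagged)\n",
              nrow(x$pooled), x$n_flagged))
  if (!is.null(x$test)) print(as.data.frame(x$test), digits = 3)
  invisible(x)
}

#' Regression of color recall on choice residuals
#'
#' Tests whether recall reports track endogenous choice variability: per
#' subject, a logistic regression of recall color on the trial's choice
#' residual (with color-tied intercepts), and a group t-test of the slopes
#' against zero. Subjects with flagged (separated/degenerate) fits are
#' excluded and counted.
#'
#' @param trials WM trials with `recall_color`; one or more subjects.
#' @param residuals Per-trial choice residuals aligned with `trials` rows
#'   (see [choice_residuals()]); `NA` for subjects to skip.
#' @return A list of class `wm_recall_resid`: `slopes` (tibble `subject,
#'   slope, std_error, flagged`), `test`, `n_flagged`.
#' @export
recall_vs_residuals <- function(trials, residuals) {
  stopifnot(length(residuals) == nrow(trials))
  if (!"subject" %in% names(trials)) trials$subject <- 1L
  trials$.resid <- residuals
  per_subject <- function(tr) {
    if (anyNA(tr$.resid))
      return(tibble::tibble(subject = tr$subject[1], slope = NA_real_,
                            std_error = NA_real_, flagged = TRUE))
    df <- tibble::tibble(y = as.numeric(tr$recall_color == "blue"),
                         wm_blue = as.numeric(tr$wm_color == "blue"),
                         wm_red = as.numeric(tr$wm_color == "red"),
                         r = tr$.resid)
    fit <- suppressWarnings(glm(y ~ 0 + wm_blue + wm_red + r, binomial(),
                                data = df))
    flagged <- !fit$converged ||
      any(abs(coef(fit) * c(0.5, 0.5, max(sd(df$r), 1e-12))) > 15)
    tibble::tibble(subject = tr$subject[1],
                   slope = unname(coef(fit)["r"]),
                   std_error = unname(summary(fit)$coefficients["r", 2]),
                   flagged = flagged)
  }
  slopes <- trials |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_map(~ per_subject(.x |>
                                     dplyr::mutate(subject = .y$subject))) |>
    dplyr::bind_rows()
  ok <- slopes[!slopes$flagged & is.finite(slopes$slope), ]
  test <- if (nrow(ok) >= 2) {
    tt <- t.test(ok$slope)
    tibble::tibble(mean_slope = mean(ok$slope),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value,
                   n_subjects = nrow(ok))
  } else NULL
  structure(list(slopes = slopes, test = test,
                 n_flagged = sum(slopes$flagged)),
            class = "wm_recall_resid")
}

#' Correlation of recall and choice residuals
#'
#' Applies the full psychometric model to both report types -- choice and
#' color recall -- and correlates the two per-trial residual series within
#' subject (Pearson), testing the correlations against zero across subjects.
#' Subjects whose recall model is separated (e.g. error-free recall) are
#' excluded and counted.
#'
#' @param trials WM trials of one or more subjects.
#' @return A list of class `wm_resid_cor`: `correlations` (tibble `subject,
#'   r, flagged`), `test`, `n_flagged`.
#' @export
residual_correlation <- function(trials) {
  if (!"subject" %in% names(trials)) trials$subject <- 1L
  per_subject <- function(tr) {
    fit_c <- fit_choice_model(tr, condition = "WM")
    fit_r <- fit_choice_model(tr, condition = "WM",
                              response = tr$recall_color)
    bad <- fit_c$separated || fit_c$degenerate ||
      fit_r$separated || fit_r$degenerate
    if (bad)
      return(tibble::tibble(subject = tr$subject[1], r = NA_real_,
                            flagged = TRUE))
    rc <- choice_residuals(fit_c, tr)
    rr <- choice_residuals(fit_r, tr, response = tr$recall_color)
    tibble::tibble(subject = tr$subject[1], r = stats::cor(rc, rr),
                   flagged = FALSE)
  }
  cors <- trials |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_map(~ per_subject(.x |>
                                     dplyr::mutate(subject = .y$subject))) |>
    dplyr::bind_rows()
  ok <- cors[!cors$flagged & is.finite(cors$r), ]
  test <- if (nrow(ok) >= 2) {
    tt <- t.test(ok$r)
    tibble::tibble(mean_r = mean(ok$r), statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value,
                   n_subjects = nrow(ok))
  } else NULL
  structure(list(correlations = cors, test = test,
                 n_flagged = sum(cors$flagged)),
            class = "wm_resid_cor")
}

#' Location-recall precision summaries
#'
#' Per-trial Euclidean recall error, per-subject medians, and a 2-D histogram
#' of recall positions (rotation-aligned coordinates when present, raw
#' otherwise).
#'
#' @param trials WM trials with `recall_x/recall_y` and `wm_x/wm_y`.
#' @param bins Number of histogram bins per axis.
#' @param display_radius Histogram extent, degrees.
#' @return A list of class `wm_precision`: `errors` (tibble `subject,
#'   trial_id, error`), `medians` (tibble `subject, median_error`),
#'   `histogram` (tibble `x, y, count`).
#' @export
location_precision <- function(trials, bins = 41L, display_radius = 5.3) {
  if (!"subject" %in% names(trials)) trials$subject <- 1L
  err <- sqrt((trials$recall_x - trials$wm_x)^2 +
                (trials$recall_y - trials$wm_y)^2)
  errors <- tibble::tibble(subject = trials$subject,
                           trial_id = trials$trial_id, error = err)
  medians <- errors |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(median_error = median(.data$error), .groups = "drop")
  hx <- if ("recall_x_aligned" %in% names(trials))
    trials$recall_x_aligned else trials$recall_x
  hy <- if ("recall_y_aligned" %in% names(trials))
    trials$recall_y_aligned else trials$recall_y
  brk <- seq(-display_radius, display_radius, length.out = bins + 1)
  cx <- cut(pmin(pmax(hx, -display_radius), display_radius), brk,
            include.lowest = TRUE)
  cy <- cut(pmin(pmax(hy, -display_radius), display_radius), brk,
            include.lowest = TRUE)
  counts <- as.data.frame(table(cx, cy))
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  histogram <- tibble::tibble(x = mids[as.integer(counts$cx)],
                              y = mids[as.integer(counts$cy)],
                              count = counts$Freq)
  structure(list(errors = errors, medians = medians, histogram = histogram),
            class = "wm_precision")
}

#' Median split by location-recall precision
#'
#' Splits each subject's trials at the subject's median recall error; trials
#' at or below the median go to the high-precision set. With error-free
#' recall all trials are labeled high-precision.
#'
#' @param trials WM trials (needs recall and sample coordinates).
#' @return `trials` with an added `precision_split` column
#'   (`"high"`/`"low"`).
#' @export
median_split <- function(trials) {
  if (!"subject" %in% names(trials)) trials$subject <- 1L
  err <- sqrt((trials$recall_x - trials$wm_x)^2 +
                (trials$recall_y - trials$wm_y)^2)
  trials |>
    dplyr::mutate(.err = err) |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(precision_split = ifelse(.data$.err <= median(.data$.err),
                                           "high", "low")) |>
    dplyr::ungroup() |>
    dplyr::select(-".err")
}
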