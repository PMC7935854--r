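# one-sample t tolerant of constant input (e.g. perfectly uniform maps)
safe_t <- function(x) {
  if (sd(x) == 0)
    return(list(statistic = if (mean(x) == 0) 0 else Inf * sign(mean(x)),
                p.value = if (mean(x) == 0) 1 else 0))
  tt <- t.test(x)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Angular tuning of spatial decision weight
#'
#' Partitions the display area into `n_segments` equal pie segments, with the
#' target segment centered on the (rotation-aligned) memorized location, and
#' averages each subject's in-mask weights per segment and display. The group
#' statistic is a paired t-test, per display, of the target-segment mean
#' against the mean of the remaining segments across subjects.
#'
#' Segment membership is decided by a pixel center's angle; the segment index
#' is signed (0 = target, +/-1 neighbors, ...) and profiles are summarized by
#' absolute angular distance from the target.
#'
#' @param maps A `wm_weight_maps` or list of them (per subject), computed from
#'   rotationally aligned trials (typically `M - M*`).
#' @param n_segments Number of pie segments (>= 3; the analysis standard
#'   is 11).
#' @param reference Aligned WM angle in degrees (the target segment center).
#' @return A `wm_tuning` object: `profile` (tibble `subject, display,
#'   segment, abs_distance, mean_weight`), `test` (tibble `display,
#'   mean_diff, statistic, df, p_value`; absent for a single subject),
#'   `n_segments`, `reference`.
#' @export
angular_tuning <- function(maps, n_segments = 11L, reference = 45) {
  if (inherits(maps, "wm_weight_maps")) maps <- list(maps)
  n_segments <- as.integer(n_segments)
  if (n_segments < 3L) stop("need at least 3 segments")
  G <- maps[[1]]$grid_size
  grid <- map_grid(G, G * maps[[1]]$pixel_scale / 2)
  idx <- which(grid$mask)
  theta <- atan2(grid$py[idx], grid$px[idx]) * 180 / pi
  w <- 360 / n_segments
  a <- (theta - reference + w / 2) %% 360
  seg0 <- pmin(floor(a / w), n_segments - 1)          # 0 .. n-1
  seg <- ifelse(seg0 <= n_segments %/% 2, seg0, seg0 - n_segments)  # signed
  profile <- purrr::imap_dfr(maps, function(m, s) {
    subj <- if (!is.null(m$subject)) m$subject else s
    purrr::map_dfr(1:6, function(k) {
      v <- m$beta[, , k][idx]
      mw <- tapply(v, seg, mean, na.rm = TRUE)
      tibble::tibble(subject = subj, display = k,
                     segment = as.integer(names(mw)),
                     abs_distance = abs(as.integer(names(mw))) * w,
                     mean_weight = as.numeric(mw))
    })
  })
  test <- NULL
  if (length(maps) >= 2) {
    test <- profile |>
      dplyr::group_by(.data$subject, .data$display) |>
      dplyr::summarise(
        diff = .data$mean_weight[.data$segment == 0] -
          mean(.data$mean_weight[.data$segment != 0]),
        .groups = "drop") |>
      dplyr::group_by(.data$display) |>
      dplyr::summarise(
        mean_diff = mean(.data$diff),
        statistic = safe_t(.data$diff)$statistic,
        df = dplyr::n() - 1,
        p_value = safe_t(.data$diff)$p.value,
        .groups = "drop")
  }
  structure(list(profile = profile, test = test, n_segments = n_segments,
                 reference = reference),
            class = "wm_tuning")
}

#' @export
print.wm_tuning <- function(x, ...) {
  cat(sprintf("<wm_tuning> %d segments, reference %g deg\n",
              x$n_segments, x$reference))
  if (!is.null(x$test)) print(as.data.frame(x$test), digits = 3)
  invisible(x)
}

#' @describeIn angular_tuning Group-mean tuning profile as a tibble
#'   (`display`, `segment`, `abs_distance`, `mean_weight`).
#' @param x A `wm_tuning` object.
#' @param ... Unused.
#' @method tidy wm_tuning
#' @export
tidy.wm_tuning <- function(x, ...) {
  x$profile |>
    dplyr::group_by(.data$display, .data$segment, .data$abs_distance) |>
    dplyr::summarise(mean_weight = mean(.data$mean_weight),
                     .groups = "drop")
}

#' Inter-display map stability with a rotation baseline
#'
#' Pearson correlation, over in-mask pixels, between the weight maps of every
#' pair of display positions (15 pairs), minus a center-bias baseline: the
#' mean correlation obtained after rotating each display's map independently
#' by uniform random angles (`n_rotations` draws, bilinear interpolation).
#' Radially symmetric structure shared by all maps survives random rotation
#' and is removed by the subtraction.
#'
#' @param maps A `wm_weight_maps` object.
#' @param n_rotations Number of random-rotation baseline draws.
#' @return A tibble with one row per display pair: `display_a`, `display_b`,
#'   `r_raw`, `r_baseline`, `r_corrected`.
#' @export
map_stability <- function(maps, n_rotations = 1000L) {
  stopifnot(inherits(maps, "wm_weight_maps"))
  slabs <- lapply(1:6, function(k) maps$beta[, , k])
  pairs <- utils::combn(6, 2)
  safe_cor <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    stats::cor(a[ok], b[ok])
  }
  raw <- apply(pairs, 2, function(pr)
    safe_cor(as.vector(slabs[[pr[1]]]), as.vector(slabs[[pr[2]]])))
  base_sum <- numeric(ncol(pairs))
  for (i in seq_len(n_rotations)) {
    rots <- lapply(slabs, function(s)
      cpp_rotate_map(s, runif(1, 0, 2 * pi)))
    base_sum <- base_sum + apply(pairs, 2, function(pr)
      safe_cor(as.vector(rots[[pr[1]]]), as.vector(rots[[pr[2]]])))
  }
  baseline <- base_sum / n_rotations
  tibble::tibble(display_a = pairs[1, ], display_b = pairs[2, ],
                 r_raw = raw, r_baseline = baseline,
                 r_corrected = raw - baseline)
}
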