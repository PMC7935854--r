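#' Fit per-pixel spatiotemporal decision-weight maps
#'
#' At every pixel of the (circular) display grid, the probability of a "blue"
#' choice is regressed on the pixel's smoothed pseudo-color value in each of
#' the six stream displays,
#' \deqn{P(blue) = L\big(\beta_0 + \textstyle\sum_{k=1}^{6}
#'   \beta_{x,y,k}\, c_{x,y,k}\big),}
#' by ridge-penalized maximum likelihood (L2 penalty on the six slopes, never
#' the intercept). The slope stack \eqn{\beta_{x,y,k}} is the spatiotemporal
#' weight map M. Responses may be fractional probabilities, which is how the
#' unbiased-observer map M* is computed (see [fit_null_maps()]).
#'
#' @param trials Trial tibble (one row per trial; needs `trial_id`, `choice`).
#' @param dots Long dot tibble keyed by `trial_id`, `display`.
#' @param grid_size Pixels per side (analysis standard 401; 61 is a
#'   proportionally equivalent fast setting).
#' @param kernel_width Smoothing support in pixels (default: the 20-pixel
#'   standard scaled to `grid_size`).
#' @param ridge L2 penalty on slopes; escalated tenfold (up to 4 times) for
#'   pixels whose fit does not converge. Remaining failures are returned as
#'   `NaN` and counted.
#' @param response Optional numeric response vector in `[0, 1]` overriding
#'   the binary choices (fractional-response fitting).
#' @param rotation Optional per-trial rotation (degrees counterclockwise)
#'   applied to the dot coordinates before rasterization, e.g. from
#'   [align_trials()].
#' @param geometry A [display_geometry()].
#' @param subject Optional subject identifier stored with the result.
#' @return A `wm_weight_maps` object: `beta` (`G x G x 6`, `NaN` outside the
#'   circular mask), `beta0` (`G x G` intercepts), `mask`, `pixel_scale`,
#'   `n_trials`, `n_failed`, `subject`.
#' @examples
#' sess <- simulate_session(60, observer_params(), seed = 1)
#' M <- fit_weight_maps(sess$trials, sess$dots, grid_size = 21)
#' @export
fit_weight_maps <- function(trials, dots, grid_size = 61L,
                            kernel_width = NULL, ridge = 1e-3,
                            response = NULL, rotation = NULL,
                            geometry = display_geometry(), subject = NULL) {
  if (nrow(trials) < 2) stop("need at least 2 trials")
  grid <- map_grid(grid_size, geometry$display_radius)
  kw <- if (is.null(kernel_width)) default_kernel_width(grid$grid_size)
        else as.integer(kernel_width)
  y <- if (is.null(response)) as.numeric(trials$choice == "blue") else {
    stopifnot(length(response) == nrow(trials),
              all(response >= 0 & response <= 1))
    as.numeric(response)
  }
  if (anyNA(y)) stop("missing responses")
  D <- build_design_cube(trials, dots, grid, kw, geometry, rotation)
  fit <- cpp_pixel_irls(y, D, ridge, 50L, 1e-8, 4L)
  G <- grid$grid_size
  beta <- array(NaN, c(G, G, 6))
  beta0 <- matrix(NaN, G, G)
  midx <- grid$mask_idx + 1L
  beta0[midx] <- fit$coef[1, ]
  for (k in 1:6) {
    slab <- matrix(NaN, G, G)
    slab[midx] <- fit$coef[k + 1, ]
    beta[, , k] <- slab
  }
  structure(
    list(beta = beta, beta0 = beta0, mask = grid$mask,
         pixel_scale = grid$pixel_scale, grid_size = G,
         kernel_width = kw, ridge = ridge,
         n_trials = nrow(trials), n_failed = fit$n_failed,
         subject = subject),
    class = "wm_weight_maps"
  )
}

#' Fit the spatially unbiased observer map M*
#'
#' Refits the per-pixel regressions of [fit_weight_maps()] with responses
#' derived from a spatially uninformed psychometric model
#' ([fit_choice_model()]) substituted for the observed choices. `M - M*` then
#' isolates regional over- and underweighting that the spatially blind model
#' cannot absorb.
#'
#' With `method = "simulate"` (default) the substituted responses are binary
#' choices drawn once from the model-predicted probabilities (a parametric-
#' bootstrap null). Because these refits share the binary-response likelihood
#' of M, the small away-from-zero finite-sample bias of per-pixel logistic
#' slopes cancels in `M - M*`, which keeps the group test on the difference
#' maps calibrated. `method = "fractional"` instead fits the predicted
#' probabilities directly (deterministic, no Monte-Carlo noise, but the bias
#' does not cancel and the difference maps acquire a small positive offset).
#'
#' @param psychfit A [fit_choice_model()] fit obtained on the same trials.
#' @param method `"simulate"` (parametric-bootstrap responses; uses the R
#'   random number stream) or `"fractional"`.
#' @inheritParams fit_weight_maps
#' @return A `wm_weight_maps` object (M*).
#' @export
fit_null_maps <- function(trials, dots, psychfit, grid_size = 61L,
                          kernel_width = NULL, ridge = 1e-3,
                          rotation = NULL, geometry = display_geometry(),
                          subject = NULL,
                          method = c("simulate", "fractional")) {
  method <- match.arg(method)
  p <- predict_choice(psychfit, trials)
  y <- if (method == "simulate") rbinom(length(p), 1L, p) else p
  fit_weight_maps(trials, dots, grid_size, kernel_width, ridge,
                  response = y, rotation = rotation, geometry = geometry,
                  subject = subject)
}

#' Difference of two weight-map sets
#'
#' Pixelwise `a - b` (typically `M - M*`), preserving grid metadata.
#'
#' @param a,b `wm_weight_maps` on the same grid.
#' @return A `wm_weight_maps` object whose `beta` is the difference.
#' @export
map_difference <- function(a, b) {
  stopifnot(inherits(a, "wm_weight_maps"), inherits(b, "wm_weight_maps"),
            a$grid_size == b$grid_size)
  out <- a
  out$beta <- a$beta - b$beta
  out$beta0 <- a$beta0 - b$beta0
  out$n_failed <- max(a$n_failed, b$n_failed)
  out
}

# mean over the display dimension, keeping the object shape (K = 1)
collapse_displays <- function(m) {
  out <- m
  out$beta <- array(apply(m$beta, c(1, 2), mean), c(m$grid_size,
                                                    m$grid_size, 1))
  out
}

#' Group-level pixel test with FDR correction
#'
#' One-sample two-tailed t-test against zero at every in-mask pixel across
#' subjects' maps, with Benjamini-Hochberg step-up correction over the pixels
#' of each display map at level `alpha`.
#'
#' @param maps List of `wm_weight_maps` (e.g. per-subject `M - M*`), all on
#'   the same grid.
#' @param alpha FDR level.
#' @param collapse If `TRUE`, average each subject's maps over the six
#'   display positions first and test the single collapsed map.
#' @return A `wm_group_test` object: arrays `tmap`, `pmap` and logical
#'   `sigmask` of dimension `G x G x K`, the `mask`, `alpha`, `n_subjects`,
#'   and `n_zero_variance` (pixels assigned p = 1 by convention).
#' @export
group_map_test <- function(maps, alpha = 0.05, collapse = FALSE) {
  stopifnot(length(maps) >= 2)
  if (collapse) maps <- lapply(maps, collapse_displays)
  G <- maps[[1]]$grid_size
  K <- dim(maps[[1]]$beta)[3]
  mask <- maps[[1]]$mask
  n <- length(maps)
  tmap <- array(NaN, c(G, G, K))
  pmap <- array(NaN, c(G, G, K))
  sig <- array(FALSE, c(G, G, K))
  n_zero <- 0L
  midx <- which(mask)
  for (k in seq_len(K)) {
    X <- vapply(maps, function(m) m$beta[, , k][midx], numeric(length(midx)))
    n_ok <- rowSums(is.finite(X))
    mu <- rowMeans(X, na.rm = TRUE)
    s <- apply(X, 1, sd, na.rm = TRUE)
    zero <- s == 0 | !is.finite(s) | n_ok < 2
    tval <- mu / (s / sqrt(n_ok))
    pval <- 2 * pt(-abs(tval), df = pmax(n_ok - 1, 1))
    pval[zero] <- 1
    tval[zero] <- 0
    n_zero <- n_zero + sum(zero)
    slab_t <- matrix(NaN, G, G); slab_t[midx] <- tval
    slab_p <- matrix(NaN, G, G); slab_p[midx] <- pval
    slab_s <- matrix(FALSE, G, G)
    slab_s[midx] <- fdr_reject(pval, alpha)
    tmap[, , k] <- slab_t
    pmap[, , k] <- slab_p
    sig[, , k] <- slab_s
  }
  structure(list(tmap = tmap, pmap = pmap, sigmask = sig, mask = mask,
                 alpha = alpha, n_subjects = n, collapse = collapse,
                 grid_size = G, pixel_scale = maps[[1]]$pixel_scale,
                 n_zero_variance = n_zero),
            class = "wm_group_test")
}

#' Benjamini-Hochberg step-up rejections
#'
#' Returns the rejection set of the Benjamini-Hochberg procedure at level
#' `alpha` (computed via adjusted p-values).
#'
#' @param p Vector of p-values.
#' @param alpha FDR level.
#' @return Logical vector of rejections.
#' @export
fdr_reject <- function(p, alpha = 0.05) {
  p.adjust(p, method = "BH") <= alpha
}

#' @export
print.wm_weight_maps <- function(x, ...) {
  cat(sprintf(
    "<wm_weight_maps> %dx%dx6, pixel scale %.4f deg, %d trials%s%s\n",
    x$grid_size, x$grid_size, x$pixel_scale, x$n_trials,
    if (x$n_failed > 0) sprintf(", %d unconverged pixels", x$n_failed) else "",
    if (!is.null(x$subject)) paste0(", subject ", x$subject) else ""))
  invisible(x)
}

#' @export
print.wm_group_test <- function(x, ...) {
  cat(sprintf(
    "<wm_group_test> %d subjects, alpha = %.3g (BH), %d significant pixels\n",
    x$n_subjects, x$alpha, sum(x$sigmask, na.rm = TRUE)))
  invisible(x)
}

#' @describeIn fit_weight_maps Tidy the coefficient stack into a tibble with
#'   pixel indices (`row`, `col`, 1-based), degree coordinates, display
#'   position and slope.
#' @param x A `wm_weight_maps` object.
#' @param ... Unused.
#' @method tidy wm_weight_maps
#' @export
tidy.wm_weight_maps <- function(x, ...) {
  G <- x$grid_size
  grid <- map_grid(G, G * x$pixel_scale / 2)
  idx <- which(x$mask)
  rows <- ((idx - 1L) %% G) + 1L
  cols <- ((idx - 1L) %/% G) + 1L
  purrr::map_dfr(1:6, function(k) {
    bk <- x$beta[, , k][idx]
    tibble::tibble(display = k, row = rows, col = cols,
                   x = grid$px[idx], y = grid$py[idx], beta = bk)
  })
}

#' @describeIn group_map_test Tidy the test maps into a tibble (`display`,
#'   pixel indices and coordinates, `t`, `p`, `significant`).
#' @param x A `wm_group_test` object.
#' @param ... Unused.
#' @method tidy wm_group_test
#' @export
tidy.wm_group_test <- function(x, ...) {
  G <- x$grid_size
  grid <- map_grid(G, G * x$pixel_scale / 2)
  idx <- which(x$mask)
  rows <- ((idx - 1L) %% G) + 1L
  cols <- ((idx - 1L) %/% G) + 1L
  K <- dim(x$tmap)[3]
  purrr::map_dfr(seq_len(K), function(k) {
    tk <- x$tmap[, , k][idx]
    pk <- x$pmap[, , k][idx]
    sk <- x$sigmask[, , k][idx]
    tibble::tibble(display = k, row = rows, col = cols,
                   x = grid$px[idx], y = grid$py[idx],
                   t = tk, p = pk, significant = sk)
  })
}
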