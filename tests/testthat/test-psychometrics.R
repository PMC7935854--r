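test_that("the ideal observer's weighting function is point-symmetric", {
  sess <- simulate_session(400, observer_params(decision_noise = 0),
                           include_dots = FALSE, seed = 41)
  tr <- sess$trials
  # mirror the stimulus set: negate all counts and the stream mean; the
  # deterministic observer's choice flips, so the weighting function must
  # satisfy p(level) + p(-level) = 1 exactly
  mir <- tr
  mir$stream_mean <- -tr$stream_mean
  for (k in 1:6) mir[[paste0("diff_", k)]] <- -tr[[paste0("diff_", k)]]
  mir$choice <- ifelse(tr$choice == "blue", "red", "blue")
  mir$trial_id <- tr$trial_id + nrow(tr)
  both <- dplyr::bind_rows(tr, mir)
  tot <- rowSums(as.matrix(both[paste0("diff_", 1:6)]))
  both <- both[tot != 0, ]
  wf <- weighting_function(both)
  sym <- dplyr::inner_join(wf, wf, by = c("display"),
                           relationship = "many-to-many")
  sym <- sym[sym$level.x == -sym$level.y, ]
  expect_true(nrow(sym) > 0)
  expect_equal(sym$p_blue.x + sym$p_blue.y, rep(1, nrow(sym)),
               tolerance = 1e-12)
})

test_that("an additive bias displaces the weighting function monotonically", {
  # identical RNG stream: stimuli and noise coincide, only the bias differs,
  # so biased choices dominate unbiased ones trial by trial
  s0 <- simulate_session(600, observer_params(color_bias = 0),
                         include_dots = FALSE, seed = 42)
  s1 <- simulate_session(600, observer_params(color_bias = 2),
                         include_dots = FALSE, seed = 42)
  blue0 <- s0$trials$choice == "blue"
  blue1 <- s1$trials$choice == "blue"
  on_blue <- s1$trials$wm_color == "blue"
  expect_true(all(blue1[on_blue] >= blue0[on_blue]))
  expect_true(all(blue1[!on_blue] <= blue0[!on_blue]))
  w0 <- weighting_function(s0$trials[on_blue, ])
  w1 <- weighting_function(s1$trials[on_blue, ])
  j <- dplyr::inner_join(w0, w1, by = c("display", "level"))
  expect_true(all(j$p_blue.y >= j$p_blue.x))
})

test_that("weighting function reports empty cells as missing rows", {
  sess <- simulate_session(30, observer_params(), include_dots = FALSE,
                           seed = 43)
  wf <- weighting_function(sess$trials)
  expect_true(all(wf$n > 0))
  expect_true(all(wf$p_blue >= 0 & wf$p_blue <= 1))
  expect_lte(nrow(wf), 6 * 11)
})

test_that("choice-model coefficients match a maximum-likelihood oracle", {
  tr <- toy_trials()
  fit <- fit_choice_model(tr)
  X <- cbind(as.numeric(tr$wm_color == "blue"),
             as.numeric(tr$wm_color == "red"),
             as.matrix(tr[paste0("diff_", 1:6)]))
  oracle <- logit_oracle(X, as.numeric(tr$choice == "blue"), ridge = 0)
  expect_equal(unname(coef(fit$fit)), oracle, tolerance = 1e-6)
  # control parametrization: single intercept
  tr2 <- tr; tr2$condition <- "control1"
  fit2 <- fit_choice_model(tr2)
  X2 <- cbind(1, as.matrix(tr2[paste0("diff_", 1:6)]))
  oracle2 <- logit_oracle(X2, as.numeric(tr2$choice == "blue"), ridge = 0)
  expect_equal(unname(coef(fit2$fit)), oracle2, tolerance = 1e-6)
})

test_that("bias recovery is exact in expectation and null when absent", {
  set.seed(44)
  b0 <- replicate(6, {
    sess <- simulate_session(500, observer_params(), include_dots = FALSE)
    bias_magnitude(fit_choice_model(sess$trials))$bias
  })
  expect_lt(abs(mean(b0)), 2 * sd(b0) / sqrt(6))
  b1 <- replicate(6, {
    sess <- simulate_session(2000, observer_params(color_bias = 1),
                             include_dots = FALSE)
    bias_magnitude(fit_choice_model(sess$trials))$bias
  })
  expect_equal(mean(b1), 1, tolerance = 0.15)
})

test_that("bias respects the color symmetries of the task", {
  sess <- simulate_session(800, observer_params(color_bias = 0.8),
                           include_dots = FALSE, seed = 45)
  tr <- sess$trials
  flip <- function(x) ifelse(x == "blue", "red", "blue")
  # a full global relabeling (memory sample, choices, and counts) leaves the
  # attraction toward the memorized color unchanged
  sw <- tr
  sw$wm_color <- flip(tr$wm_color)
  sw$choice <- flip(tr$choice)
  for (k in 1:6) sw[[paste0("diff_", k)]] <- -tr[[paste0("diff_", k)]]
  sw$stream_mean <- -tr$stream_mean
  b <- bias_magnitude(fit_choice_model(tr))$bias
  bs <- bias_magnitude(fit_choice_model(sw))$bias
  expect_equal(bs, b, tolerance = 1e-8)
  # relabeling only the memory sample turns attraction into repulsion:
  # the sign flips, the magnitude is preserved
  sm <- tr
  sm$wm_color <- flip(tr$wm_color)
  bm <- bias_magnitude(fit_choice_model(sm))$bias
  expect_equal(bm, -b, tolerance = 1e-8)
})

test_that("fits are invariant to trial order", {
  sess <- simulate_session(300, observer_params(), include_dots = FALSE,
                           seed = 46)
  f1 <- fit_choice_model(sess$trials)
  f2 <- fit_choice_model(sess$trials[sample(300), ])
  expect_equal(coef(f1$fit), coef(f2$fit), tolerance = 1e-10)
  # fitted likelihood is at least the null-model likelihood
  ll_null <- sum(log(0.5)) * 300
  expect_gte(as.numeric(stats::logLik(f1$fit)), ll_null)
})

test_that("recency slopes recover injected temporal-weight gradients", {
  set.seed(47)
  flat <- sapply(1:8, function(i) {
    sess <- simulate_session(400, observer_params(), include_dots = FALSE)
    recency_slope(fit_choice_model(sess$trials))
  })
  expect_lt(abs(mean(flat)), 2 * sd(flat) / sqrt(8))
  w <- seq(0.7, 1.3, length.out = 6)
  inc <- sapply(1:8, function(i) {
    sess <- simulate_session(400, observer_params(temporal_weights = w),
                             include_dots = FALSE)
    recency_slope(fit_choice_model(sess$trials))
  })
  expect_gt(mean(inc), 0)
  expect_equal(mean(inc), 0.12 / 25, tolerance = 0.5)
  cr <- compare_recency(
    lapply(1:8, function(i) {
      sess <- simulate_session(300, observer_params(temporal_weights = w),
                               include_dots = FALSE)
      fit_choice_model(sess$trials)
    }),
    lapply(1:8, function(i) {
      sess <- simulate_session(300, observer_params(), include_dots = FALSE)
      fit_choice_model(sess$trials)
    }))
  expect_gt(cr$mean_diff, 0)
})

test_that("choice residuals satisfy the maximum-likelihood identities", {
  sess <- simulate_session(600, observer_params(color_bias = 0.5),
                           include_dots = FALSE, seed = 48)
  fit <- fit_choice_model(sess$trials)
  r <- choice_residuals(fit, sess$trials)
  expect_true(all(r > -1 & r < 1))
  # score equations: residuals are orthogonal to every design column
  expect_lt(abs(sum(r)), 1e-6)
  for (k in 1:6)
    expect_lt(abs(sum(r * sess$trials[[paste0("diff_", k)]])), 1e-4)
  # residual variance matches sum p(1-p)/n
  p <- predict_choice(fit, sess$trials)
  expect_equal(mean(r^2), mean(p * (1 - p)), tolerance = 0.1)
})

test_that("separation is flagged and blocks residual analyses", {
  tr <- toy_trials()
  tr$choice <- ifelse(tr$diff_1 > 0, "blue", "red")  # separable
  fit <- fit_choice_model(tr)
  expect_true(fit$separated)
  expect_error(choice_residuals(fit, tr), "flagged")
  expect_error(bias_magnitude(fit), "flagged")
  # constant responses are degenerate
  tr$choice <- "blue"
  fit2 <- fit_choice_model(tr)
  expect_true(fit2$degenerate)
  expect_equal(nrow(tidy(fit2)), 0)
})

test_that("tidy and glance summarize the fit in broom style", {
  sess <- simulate_session(200, observer_params(), include_dots = FALSE,
                           seed = 49)
  fit <- fit_choice_model(sess$trials)
  td <- tidy(fit)
  expect_setequal(td$term, c("beta_b", "beta_r", paste0("beta_", 1:6)))
  expect_true(all(td$std_error > 0))
  gl <- glance(fit)
  expect_equal(gl$n, 200)
  expect_false(gl$separated)
})
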