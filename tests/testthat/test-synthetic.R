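test_that("color differences live on the 11-level truncated-normal grid", {
  set.seed(1)
  d <- sample_color_difference(2e4, mean = 4, sd = 10)
  expect_setequal(unique(d), seq(-6, 14, by = 2))
  expect_length(unique(d), 11)
  d2 <- sample_color_difference(2e4, mean = -4, sd = 10)
  expect_true(all(d2 >= -14 & d2 <= 6))
  # degenerate truncation
  expect_true(all(sample_color_difference(50, mean = 4, sd = 0) == 4))
  # infeasible configuration rejected
  expect_error(sample_color_difference(10, mean = 12, sd = 10), "infeasible")
})

test_that("difference frequencies match the bin-integrated truncated normal", {
  set.seed(2)
  d <- sample_color_difference(5e4, mean = 0, sd = 10)
  ref <- color_difference_probs(mean = 0, sd = 10)
  obs <- table(factor(d, levels = ref$level))
  gof <- suppressWarnings(chisq.test(obs, p = ref$prob))
  expect_gt(gof$p.value, 0.01)
  # symmetric generator: empirical mean near zero
  expect_lt(abs(mean(d)), 0.1)
})

test_that("dot placement respects geometry invariants", {
  set.seed(3)
  geom <- display_geometry()
  for (i in 1:50) {
    d <- place_dots(n_blue = sample(0:20, 1), geometry = geom)
    expect_equal(nrow(d), 20)
    dist <- as.matrix(stats::dist(cbind(d$x, d$y)))
    diag(dist) <- Inf
    expect_gte(min(dist), geom$dot_diameter)
    expect_lte(max(sqrt(d$x^2 + d$y^2)), geom$r_allowed + 1e-12)
  }
  d <- place_dots(13)
  expect_equal(sum(d$color == 1), 13)
  # single dot: no pairwise constraint to satisfy
  d1 <- place_dots(1, geometry = display_geometry(n_dots = 1L))
  expect_equal(nrow(d1), 1)
  # infeasible packing errors out with the geometry in the message
  expect_error(
    place_dots(2, geometry = display_geometry(dot_diameter = 12,
                                              display_radius = 6.5,
                                              edge_margin = 0),
               max_tries = 50),
    "placement failed")
})

test_that("trial generation honors the condition structure", {
  set.seed(4)
  wm <- generate_trial("WM")$trial
  expect_false(is.na(wm$wm_color))
  expect_false(is.na(wm$wm_angle))
  expect_equal(sqrt(wm$wm_x^2 + wm$wm_y^2), 3.8, tolerance = 1e-12)
  c1 <- generate_trial("control1")$trial
  expect_true(is.na(c1$wm_color) && is.na(c1$wm_angle))
  tr <- generate_trial("WM")
  expect_equal(nrow(tr$dots), 120)
  expect_equal(unique(table(tr$dots$display)), 20L)
  for (k in 1:6)
    expect_equal(sum(tr$dots$color[tr$dots$display == k]),
                 tr$trial[[paste0("diff_", k)]])
})

test_that("session regeneration from a seed is bit-identical", {
  a <- simulate_session(25, observer_params(), seed = 11)
  b <- simulate_session(25, observer_params(), seed = 11)
  expect_identical(a$trials, b$trials)
  expect_identical(a$dots, b$dots)
  co <- simulate_cohort(2, 10, observer_params(), seed = 12)
  co2 <- simulate_cohort(2, 10, observer_params(), seed = 12)
  expect_identical(co$trials, co2$trials)
})

test_that("the grand-mean difference tracks the stream mean", {
  set.seed(5)
  sess <- simulate_session(4000, observer_params(), stream_means = 4,
                           include_dots = FALSE)
  expect_equal(mean(as.matrix(sess$trials[paste0("diff_", 1:6)])), 4,
               tolerance = 0.15)
})

test_that("the deterministic observer is the sign-of-evidence rule", {
  set.seed(6)
  obs <- observer_params(decision_noise = 0)
  sess <- simulate_session(200, obs, include_dots = FALSE)
  tot <- rowSums(as.matrix(sess$trials[paste0("diff_", 1:6)]))
  nonzero <- tot != 0
  expect_equal(sess$trials$choice[nonzero],
               ifelse(tot[nonzero] > 0, "blue", "red"))
})

test_that("an overwhelming color bias forces the memorized color", {
  set.seed(7)
  obs <- observer_params(color_bias = 1e4)
  sess <- simulate_session(300, obs, include_dots = FALSE)
  expect_equal(sess$trials$choice, sess$trials$wm_color)
})

test_that("choice probabilities follow the logistic closed form", {
  set.seed(8)
  obs <- observer_params(decision_noise = 25)
  tr <- generate_trial("WM", stream_mean = 4)
  dv <- sum(as.numeric(tr$trial[paste0("diff_", 1:6)]))
  s <- if (tr$trial$wm_color == "blue") 1 else -1
  p_theory <- plogis(dv / 25 + obs$color_bias * s / 2)
  hits <- replicate(4000, simulate_choice(tr$trial, tr$dots, obs) == "blue")
  expect_equal(mean(hits), p_theory,
               tolerance = 3 * sqrt(p_theory * (1 - p_theory) / 4000) /
                 max(p_theory, 1e-3))
})

test_that("accuracy decreases monotonically with decision noise", {
  accs <- vapply(c(5, 25, 100), function(sn) {
    sess <- simulate_session(3000, observer_params(decision_noise = sn),
                             include_dots = FALSE, seed = 9)
    mean((sess$trials$choice == "blue") == (sess$trials$stream_mean > 0))
  }, numeric(1))
  expect_true(all(diff(accs) < 0))
})

test_that("recall reproduces the sample exactly without noise", {
  set.seed(10)
  obs <- observer_params(recall_loc_sd = 0, recall_color_error = 0)
  tr <- generate_trial("WM")
  rec <- simulate_recall(tr$trial, "blue", obs)
  expect_equal(rec$recall_x, tr$trial$wm_x)
  expect_equal(rec$recall_y, tr$trial$wm_y)
  expect_equal(rec$recall_color, tr$trial$wm_color)
})

test_that("crosstalk couples recall errors to the decision response", {
  set.seed(13)
  obs <- observer_params(recall_color_error = 0.2, crosstalk = 1)
  sess <- simulate_session(5000, obs, include_dots = FALSE)
  tr <- sess$trials
  err <- tr$recall_color != tr$wm_color
  # every erroneous recall copies the choice
  expect_true(all(tr$recall_color[err] == tr$choice[err]))
  # empirical error rate within a binomial CI of epsilon; errors can only
  # surface when the copied choice differs from the true color, so compare
  # against the observable rate 0.2 * P(choice != wm_color)
  p_mismatch <- mean(tr$choice != tr$wm_color)
  expect_equal(mean(err), 0.2 * p_mismatch,
               tolerance = 4 * sqrt(0.2 * p_mismatch / 5000) /
                 (0.2 * p_mismatch))
})
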