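test_that("rasterization paints signed colors and preserves mass", {
  # empty display: all-zero map
  empty <- tibble::tibble(x = numeric(), y = numeric(), color = numeric())
  m0 <- pseudocolor_map(empty, 61, mask_circle = FALSE)
  expect_true(all(m0 == 0))
  set.seed(20)
  d <- place_dots(13)
  raw <- pseudocolor_map(d, 61, kernel_width = 1, mask_circle = FALSE)
  expect_true(all(raw %in% c(-1, 0, 1)))
  sm <- pseudocolor_map(d, 61, mask_circle = FALSE)
  # unit-sum kernel: total signed mass preserved (interior dots)
  expect_equal(sum(sm), sum(raw), tolerance = 1e-10)
  expect_lte(max(abs(sm)), 1 + 1e-12)
  # single blue dot at center: nonnegative map, mass equals painted disc,
  # oracle: direct dense convolution of the raw image
  one <- tibble::tibble(x = 0, y = 0, color = 1)
  r1 <- pseudocolor_map(one, 61, kernel_width = 1, mask_circle = FALSE)
  s1 <- pseudocolor_map(one, 61, kernel_width = 5, mask_circle = FALSE)
  expect_true(all(s1 >= 0))
  expect_equal(sum(s1), sum(r1), tolerance = 1e-10)
  k1 <- gaussian_kernel(5)
  k2 <- outer(k1, k1)
  conv <- matrix(0, 61, 61)
  nz <- which(r1 != 0, arr.ind = TRUE)
  for (i in seq_len(nrow(nz))) {
    rr <- nz[i, 1] + (-2:2); cc <- nz[i, 2] + (-2:2)
    conv[rr, cc] <- conv[rr, cc] + r1[nz[i, 1], nz[i, 2]] * k2
  }
  expect_equal(unclass(s1), conv, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("rasterization is linear in disjoint dot sets", {
  set.seed(21)
  d <- place_dots(10)
  a <- d[1:10, ]; b <- d[11:20, ]
  ma <- pseudocolor_map(a, 61, mask_circle = FALSE)
  mb <- pseudocolor_map(b, 61, mask_circle = FALSE)
  mab <- pseudocolor_map(d, 61, mask_circle = FALSE)
  expect_equal(unclass(mab), unclass(ma + mb), tolerance = 1e-12)
})

test_that("a dot outside the display support is rejected as corrupt", {
  bad <- tibble::tibble(x = 5.4, y = 0, color = 1)
  expect_error(pseudocolor_map(bad, 61), "corrupt input")
})

test_that("pixel logistic fits match an independent optimizer oracle", {
  set.seed(22)
  sess <- simulate_session(80, observer_params(), seed = 22)
  # 5x5 grid toy problem: every in-mask pixel checked against optim/BFGS
  M <- fit_weight_maps(sess$trials, sess$dots, grid_size = 5,
                       kernel_width = 1, ridge = 1e-3)
  grid <- map_grid(5)
  D <- wmstream:::build_design_cube(sess$trials, sess$dots, grid, 1L)
  y <- as.numeric(sess$trials$choice == "blue")
  idx <- which(grid$mask)
  for (p in seq_along(idx)) {
    X <- cbind(1, D[, , p])
    oracle <- logit_oracle(X, y, ridge = 1e-3, n_free = 1)
    got <- c(M$beta0[idx[p]], vapply(1:6, function(k) M$beta[, , k][idx[p]],
                                     numeric(1)))
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("fractional-response fits match the oracle too", {
  set.seed(23)
  sess <- simulate_session(80, observer_params(), seed = 23)
  pr <- runif(80, 0.2, 0.8)
  M <- fit_weight_maps(sess$trials, sess$dots, grid_size = 5,
                       kernel_width = 1, ridge = 1e-2, response = pr)
  grid <- map_grid(5)
  D <- wmstream:::build_design_cube(sess$trials, sess$dots, grid, 1L)
  idx <- which(grid$mask)
  p1 <- idx[3]
  X <- cbind(1, D[, , 3])
  oracle <- logit_oracle(X, pr, ridge = 1e-2, n_free = 1)
  got <- c(M$beta0[p1], vapply(1:6, function(k) M$beta[, , k][p1],
                               numeric(1)))
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("pixel fits are invariant to trial order", {
  set.seed(24)
  sess <- simulate_session(60, observer_params(), seed = 24)
  M1 <- fit_weight_maps(sess$trials, sess$dots, grid_size = 21)
  o <- sample(nrow(sess$trials))
  M2 <- fit_weight_maps(sess$trials[o, ], sess$dots, grid_size = 21)
  expect_equal(M1$beta, M2$beta, tolerance = 1e-8)
})

test_that("slopes grow monotonically as the ridge vanishes on separable data", {
  set.seed(25)
  sess <- simulate_session(40, observer_params(), seed = 25)
  # separable responses: choice deterministically follows display 1's count
  sess$trials$choice <- ifelse(sess$trials$diff_1 > 0, "blue", "red")
  mags <- vapply(c(1e-1, 1e-3, 1e-5), function(eps) {
    M <- fit_weight_maps(sess$trials, sess$dots, grid_size = 5,
                         kernel_width = 1, ridge = eps)
    max(abs(M$beta[, , 1]), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mags) > 0))
})

test_that("null choices give near-zero mean weights", {
  set.seed(26)
  sess <- simulate_session(400, observer_params(), seed = 26)
  sess$trials$choice <- sample(c("blue", "red"), 400, replace = TRUE)
  M <- fit_weight_maps(sess$trials, sess$dots, grid_size = 31)
  mb <- mean(M$beta, na.rm = TRUE)
  sb <- sd(M$beta, na.rm = TRUE)
  expect_lt(abs(mb), sb / 3)
})

test_that("a hemifield observer's weight asymmetry is recovered", {
  set.seed(27)
  for (r in 1:3) {
    sess <- simulate_session(300, observer_params())
    # observer weighting only the left hemifield (x < 0) of every display
    ev <- sapply(1:6, function(k) {
      d <- sess$dots[sess$dots$display == k, ]
      rowsum((d$color * (d$x < 0))[order(d$trial_id)],
             sort(d$trial_id))[, 1]
    })
    sess$trials$choice <- ifelse(rowSums(ev) + rnorm(300, 0, 4) > 0,
                                 "blue", "red")
    M <- fit_weight_maps(sess$trials, sess$dots, grid_size = 31)
    grid <- map_grid(31)
    left <- grid$mask & grid$px < 0
    right <- grid$mask & grid$px > 0
    expect_gt(mean(apply(M$beta, 3, function(s) mean(s[left]))),
              mean(apply(M$beta, 3, function(s) mean(s[right]))))
  }
})

test_that("Benjamini-Hochberg rejections equal the step-up enumeration", {
  # printed toy vector
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.36)
  expect_equal(fdr_reject(p, 0.05), bh_oracle(p, 0.05))
  set.seed(28)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    a <- runif(1, 0.01, 0.2)
    expect_equal(fdr_reject(p, a), bh_oracle(p, a))
  }
})

test_that("the group map test is empty for all-zero maps and respects NaN", {
  zero <- matrix(0, 61, 61)
  maps <- lapply(1:5, function(s) make_maps(zero, subject = s))
  gt <- group_map_test(maps)
  expect_equal(sum(gt$sigmask), 0)
  expect_true(all(gt$pmap[gt$mask] == 1))
  expect_gt(gt$n_zero_variance, 0)
  # a NaN pixel in one subject is tolerated
  maps2 <- lapply(1:5, function(s) make_maps(matrix(rnorm(61 * 61), 61), subject = s))
  maps2[[1]]$beta[31, 31, ] <- NaN
  gt2 <- group_map_test(maps2)
  expect_true(all(is.finite(gt2$pmap[gt2$mask])))
})

test_that("tidy methods return one row per in-mask pixel and display", {
  set.seed(29)
  maps <- lapply(1:3, function(s) make_maps(matrix(rnorm(21^2), 21), grid_size = 21L, subject = s))
  td <- tidy(maps[[1]])
  expect_equal(nrow(td), sum(maps[[1]]$mask) * 6)
  gt <- group_map_test(maps)
  tg <- tidy(gt)
  expect_named(tg, c("display", "row", "col", "x", "y", "t", "p",
                     "significant"))
})
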