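# shared fixtures, built in code

# a wm_weight_maps object with prescribed per-display slabs (list of 6
# matrices or a single matrix recycled); values outside the circular mask
# are forced to NaN
make_maps <- function(slabs, grid_size = 61L, subject = NULL) {
  grid <- map_grid(grid_size)
  if (is.matrix(slabs)) slabs <- rep(list(slabs), 6)
  beta <- array(NaN, c(grid_size, grid_size, 6))
  for (k in 1:6) {
    s <- slabs[[k]]
    s[!grid$mask] <- NaN
    beta[, , k] <- s
  }
  structure(list(beta = beta, beta0 = matrix(0, grid_size, grid_size),
                 mask = grid$mask, pixel_scale = grid$pixel_scale,
                 grid_size = as.integer(grid_size), kernel_width = 3L,
                 ridge = 1e-3, n_trials = 0L, n_failed = 0L,
                 subject = subject),
            class = "wm_weight_maps")
}

# deterministic small trial table (no RNG) for optimizer oracles; built so
# the likelihood has a finite interior maximum (no separation)
toy_trials <- function() {
  base <- rbind(
    c(-6, 2, 4, -2, 8, 0), c(4, -4, 2, 6, -2, 2), c(0, 8, -6, 2, 2, -4),
    c(-2, -6, 4, 0, -8, 6), c(6, 2, -2, -4, 4, 2), c(-8, 0, 2, 4, -2, -2),
    c(2, 4, 6, -6, 0, 8), c(-4, -2, -8, 2, 6, -6), c(8, 6, 0, -2, -4, 4),
    c(2, -8, 2, 8, 2, 0), c(-6, 4, -4, -8, 0, 2), c(4, 0, 8, 2, -6, -8))
  diffs <- rbind(base, base, base)  # each stimulus seen three times ...
  n <- nrow(diffs)
  tr <- tibble::tibble(
    trial_id = seq_len(n), condition = "WM", group = "averaging",
    stream_mean = rep(c(4, -4), n / 2), shift = 0,
    wm_color = rep(rep(c("blue", "red"), each = 6), 3),
    wm_angle = rep(seq(0, 330, by = 30), 3))
  for (k in 1:6) tr[[paste0("diff_", k)]] <- diffs[, k]
  resp1 <- c("blue", "blue", "red", "red", "blue", "red",
             "blue", "red", "blue", "blue", "red", "red")
  flip <- ifelse(resp1 == "blue", "red", "blue")
  # ... once with every response flipped: both labels occur at every
  # design point, so the likelihood has a finite interior maximum
  tr$choice <- c(resp1, flip, resp1)
  tr
}

# independent penalized-likelihood oracle: brute-force damped Newton on the
# ridge-penalized logistic log-likelihood (penalty on all terms except the
# first `n_free`), written against base R linear algebra only
logit_oracle <- function(X, y, ridge = 0, n_free = 1) {
  q <- ncol(X)
  pen <- diag(c(rep(0, n_free), rep(ridge, q - n_free)), q)
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta))) + 0.5 * drop(t(b) %*% pen %*% b)
  }
  b <- rep(0, q)
  f <- nll(b)
  for (it in 1:200) {
    p <- plogis(drop(X %*% b))
    g <- -drop(crossprod(X, y - p)) + drop(pen %*% b)
    H <- crossprod(X * pmax(p * (1 - p), 1e-12), X) + pen
    step <- solve(H, g)
    lam <- 1
    repeat {
      b_new <- b - lam * step
      f_new <- nll(b_new)
      if (f_new <= f + 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    done <- max(abs(b_new - b)) < 1e-12
    b <- b_new; f <- f_new
    if (done) break
  }
  unname(b)
}

# brute-force Benjamini-Hochberg step-up: largest i with p_(i) <= i*q/m
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= (seq_len(m) / m) * q)
  rej <- rep(FALSE, m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}
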