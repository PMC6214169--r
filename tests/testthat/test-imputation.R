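test_that("RW2 precision has the second-difference structure", {
  K <- as.matrix(build_rw2_precision(5))
  ## direct construction of D'D by hand
  D <- rbind(c(1, -2, 1, 0, 0), c(0, 1, -2, 1, 0), c(0, 0, 1, -2, 1))
  expect_equal(K, t(D) %*% D, ignore_attr = TRUE)
  expect_equal(diag(K), c(1, 5, 6, 5, 1))
  expect_equal(rowSums(K), rep(0, 5))
  for (n in c(6, 17)) {
    Kn <- as.matrix(build_rw2_precision(n))
    expect_identical(Kn, t(Kn))
    line <- 2 + 0.7 * seq_len(n)
    expect_lt(abs(as.numeric(line %*% Kn %*% line)), 1e-9)
    expect_equal(qr(Kn)$rank, n - 2)
  }
  expect_error(build_rw2_precision(4), ">= 5")
})

test_that("near-zero measurement error makes the path interpolate fixes", {
  tr <- telemetry_track("a", 0:5, c(0, 3, 1, 7, 6, 2), c(5, 4, 8, 1, 0, 3))
  f <- fit_functional_path(tr, path_priors(sigma_obs = 1e-6),
                           grid_step_h = 0.5, n_mcmc = 600, burn = 100,
                           seed = 1)
  at_fix <- seq(1, 11, by = 2)
  expect_lt(max(abs(rowMeans(f$draws_x)[at_fix] - tr$x_m)), 1e-3)
  expect_lt(max(abs(rowMeans(f$draws_y)[at_fix] - tr$y_m)), 1e-3)
})

test_that("a straight-line track is recovered (RW2 null space)", {
  tr <- telemetry_track("a", 0:6, 10 * (0:6), -4 * (0:6))
  f <- fit_functional_path(tr, path_priors(sigma_obs = 1e-5),
                           grid_step_h = 0.25, n_mcmc = 2000, burn = 500,
                           seed = 2)
  expect_lt(max(abs(rowMeans(f$draws_x) - 10 * f$grid_times)), 0.1)
  expect_lt(max(abs(rowMeans(f$draws_y) + 4 * f$grid_times)), 0.1)
})

test_that("Gibbs posterior matches a numerical-integration oracle", {
  ## small 1-coordinate problem: p(s2 | y) and E[c | y] computed by
  ## integrating the banded Gaussian conditional over a dense s2 grid
  set.seed(3)
  tt <- c(0, 1, 2.5, 4, 5, 6.5, 8, 9.5, 11, 12.5, 14)
  yy <- cumsum(rnorm(length(tt), 0, 2))
  tr <- telemetry_track("a", tt, yy, rev(yy))
  so <- 0.5
  f <- fit_functional_path(tr, path_priors(sigma_obs = so), grid_step_h = 0.5,
                           n_mcmc = 50000, burn = 2000, seed = 4)
  n <- length(f$grid_times)
  K <- as.matrix(build_rw2_precision(n))
  idx <- round(tt / 0.5) + 1
  A <- matrix(0, length(tt), n); A[cbind(seq_along(tt), idx)] <- 1
  b <- crossprod(A, yy) / so^2
  W <- diag(colSums(A) / so^2)
  ## log marginal p(y | s2) up to a constant, from the Gaussian identity
  lml <- function(s2) {
    Q <- K / s2 + W
    L <- chol(Q)
    mu <- backsolve(L, forwardsolve(t(L), b))
    -(n - 2) / 2 * log(s2) - sum(log(diag(L))) + 0.5 * sum(b * mu)
  }
  s2g <- exp(seq(log(0.01), log(200), length.out = 400))
  lp <- vapply(s2g, lml, 0) + dgamma(1 / s2g, 1, 1, log = TRUE) -
    2 * log(s2g) +                      # inverse-gamma(1,1) prior density
    log(s2g)                            # measure factor for the log-spaced grid
  w <- exp(lp - max(lp)); w <- w / sum(w)
  om <- sum(s2g * w); osd <- sqrt(sum((s2g - om)^2 * w))
  gm <- mean(f$sill[, 1]); gs <- sd(f$sill[, 1])
  expect_lt(abs(gm - om) / om, 0.02)
  expect_lt(abs(gs - osd) / osd, 0.02)
  ## posterior mean of the path against the s2-marginalized dense formula
  cm <- vapply(s2g, function(s2) {
    Q <- K / s2 + W
    as.numeric(solve(Q, b))[n %/% 2]
  }, 0)
  psd <- sd(f$draws_x[n %/% 2, ])
  expect_lt(abs(mean(f$draws_x[n %/% 2, ]) - sum(cm * w)), 0.1 * psd)
})

test_that("imputation draws are partitioned and error-checked", {
  tr <- telemetry_track("a", seq(0, 24, by = 3), rnorm(9, 0, 30), rnorm(9, 0, 30))
  f <- fit_functional_path(tr, path_priors(sigma_obs = 5), n_mcmc = 300,
                           burn = 100, seed = 5)
  ps <- draw_imputed_paths(f, M = 30, fit_count = 20, score_count = 10)
  expect_length(ps, 30)
  labs <- vapply(ps, attr, "", "label")
  expect_equal(sum(labs == "fit"), 20)
  expect_equal(sum(labs == "score"), 10)
  expect_identical(labs, c(rep("fit", 20), rep("score", 10)))
  expect_true(all(diff(ps[[1]]$time_h) - 1 / 6 < 1e-12))
  two <- draw_imputed_paths(f, M = 2, fit_count = 1, score_count = 1)
  expect_false(identical(two[[1]]$x, two[[2]]$x))
  expect_error(draw_imputed_paths(f, M = 500, 400, 100), "exceeds")
  expect_error(draw_imputed_paths(f, M = 10, 5, 4), "equal M")
})

test_that("discretization conserves time and keeps rook contiguity", {
  g <- list(nrow = 30L, ncol = 30L, cell_size = 100, origin = c(0, 0))
  ## degenerate: path that never leaves one cell
  p1 <- data.frame(time_h = seq(0, 2, by = 1 / 6), x = 1510 + 0 * (0:12),
                   y = rep(1520, 13))
  s1 <- discretize_path(p1, g)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$tau_hours, 2)
  ## rook-adjacent pair: one transition, dwell split at the boundary
  p2 <- data.frame(time_h = c(0, 1 / 6), x = c(150, 250), y = c(150, 150))
  s2 <- discretize_path(p2, g)
  expect_equal(nrow(s2), 2)
  expect_equal(s2$col, c(1L, 2L))
  ## boundary at x = 200 is crossed halfway through the interval
  expect_equal(s2$tau_hours[1], 1 / 12)
  expect_equal(sum(s2$tau_hours), 1 / 6)
})

test_that("corner crossings insert one intermediate cell, x boundary first", {
  g <- list(nrow = 30L, ncol = 30L, cell_size = 100, origin = c(0, 0))
  ## exact corner: from the center of cell (1,1) to the center of (2,2)
  p <- data.frame(time_h = c(0, 1 / 6), x = c(150, 250), y = c(150, 250))
  s <- discretize_path(p, g)
  expect_equal(nrow(s), 3)
  ## x first: (1,1) -> (1,2) -> (2,2)
  expect_equal(s$row, c(1L, 1L, 2L))
  expect_equal(s$col, c(1L, 2L, 2L))
  expect_equal(s$tau_hours[2], 0)              # zero dwell in the corner cell
  expect_lt(abs(sum(s$tau_hours) - 1 / 6), 1e-9)
  ## adjacency invariant on every consecutive pair
  expect_true(all(abs(diff(s$row)) + abs(diff(s$col)) == 1))
  ## generic oblique segment against the geometric crossing times
  p3 <- data.frame(time_h = c(0, 1 / 6), x = c(110, 340), y = c(150, 230))
  s3 <- discretize_path(p3, g)
  expect_lt(abs(sum(s3$tau_hours) - 1 / 6), 1e-12)
  expect_true(all(abs(diff(s3$row)) + abs(diff(s3$col)) == 1))
  ## crossing times of the x = 200, 300 and y = 200 lines, by hand
  sx1 <- (200 - 110) / 230; sx2 <- (300 - 110) / 230; sy1 <- (200 - 150) / 80
  cr <- sort(c(sx1, sx2, sy1)) / 6
  expect_equal(s3$tau_hours, diff(c(0, cr, 1 / 6)), tolerance = 1e-12)
})

test_that("seeded imputed paths conserve time over the whole window", {
  tl <- toy_landscape(seed = 6)
  p <- simulate_ctmc_path(tl$land, c(-1, 0.3, 0.3, 0.2), c(20, 20), 72,
                          tl$roles, seed = 2)
  tr <- observe_gps(p, tl$geom, 3, 20, seed = 3)
  f <- fit_functional_path(tr, path_priors(sigma_obs = 20), n_mcmc = 400,
                           burn = 100, seed = 4)
  for (ip in draw_imputed_paths(f, 5, 4, 1)) {
    sq <- discretize_path(ip, tl$geom)
    expect_lt(abs(sum(sq$tau_hours) - 72), 1e-9)
    if (nrow(sq) > 1)
      expect_true(all(abs(diff(sq$row)) + abs(diff(sq$col)) == 1))
  }
})
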