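# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by brute force or closed form and
# never call the implementation paths they are checking.

# A small standardized landscape plus the standard role declaration.
toy_landscape <- function(seed = 1, dims = c(40, 40), n_layers = 1,
                          smoothness = 4) {
  land <- make_landscape(n_layers, dims, smoothness, seed = seed)
  roles <- ctmc_roles(motility = names(land), directional = names(land),
                      persistence = TRUE)
  list(land = land, roles = roles, geom = land[[1]])
}

# Exact cell sequence straight from a simulated event path (no imputation).
path_to_seq <- function(p, individual_id = p$individual_id, draw_index = 1L) {
  n <- length(p$event_times)
  data.frame(individual_id = individual_id, draw_index = draw_index,
             segment_id = "s1", row = p$cells[, 1], col = p$cells[, 2],
             tau_hours = c(diff(p$event_times),
                           p$duration - p$event_times[n]),
             entry_clock_hours = (p$start_clock + p$event_times) %% 24)
}

# Second, independently written latent Poisson log-likelihood (dpois-based).
pois_ll_oracle <- function(table, beta) {
  X <- as.matrix(table[, attr(table, "design_cols"), drop = FALSE])
  lam <- table$tau * exp(as.numeric(X %*% beta))
  sum(dpois(table$z, lam, log = TRUE))
}

# Brute-force kill-site rule: candidate determination over all fix pairs,
# then the greedy time-ordered merge, written independently of the package.
killsite_oracle <- function(track, night = night_window(19.5, 6.5),
                            radius_m = 200, span_days = 6, min_fixes = 2) {
  track <- track[order(track$time_h), , drop = FALSE]
  sc <- attr(track, "start_clock"); if (is.null(sc)) sc <- 0
  cl <- (sc + track$time_h) %% 24
  noct <- if (night$night_start < night$night_end)
    cl >= night$night_start & cl < night$night_end
  else cl >= night$night_start | cl < night$night_end
  idx <- which(noct)
  sites <- list()
  for (i in idx) {
    cnt <- 0L
    for (k in idx) {
      d <- sqrt((track$x_m[i] - track$x_m[k])^2 +
                (track$y_m[i] - track$y_m[k])^2)
      if (d <= radius_m && abs(track$time_h[i] - track$time_h[k]) <=
          span_days * 24) cnt <- cnt + 1L
    }
    if (cnt < min_fixes) next
    joined <- FALSE
    for (s in seq_along(sites)) {
      d <- sqrt((sites[[s]]$x - track$x_m[i])^2 +
                (sites[[s]]$y - track$y_m[i])^2)
      if (d <= radius_m) {
        if (!(i %in% sites[[s]]$members))
          sites[[s]]$members <- c(sites[[s]]$members, i)
        sites[[s]]$x <- mean(track$x_m[sites[[s]]$members])
        sites[[s]]$y <- mean(track$y_m[sites[[s]]$members])
        joined <- TRUE
        break
      }
    }
    if (joined) next
    mem <- idx[vapply(idx, function(k) {
      sqrt((track$x_m[i] - track$x_m[k])^2 +
           (track$y_m[i] - track$y_m[k])^2) <= radius_m &&
        abs(track$time_h[i] - track$time_h[k]) <= span_days * 24
    }, TRUE)]
    sites[[length(sites) + 1L]] <- list(x = mean(track$x_m[mem]),
                                        y = mean(track$y_m[mem]),
                                        members = mem)
  }
  sites
}

# Random short track for kill-site property tests: mixes day/night fixes
# over a compact area so clusters arise naturally.
random_track <- function(seed, n_max = 50) {
  set.seed(seed)
  n <- sample(5:n_max, 1)
  tr <- telemetry_track("rnd", time_h = sort(runif(n, 0, 14 * 24)),
                        x_m = runif(n, 0, 1500), y_m = runif(n, 0, 1500))
  attr(tr, "start_clock") <- 0
  tr
}

# Independent Gillespie simulator for the drift check: minimal discrete-event
# walk with rates recomputed from first principles at each step.
gillespie_oracle <- function(grad_x, cell_size, beta_dir, n_events, seed) {
  set.seed(seed)
  # single directional covariate on a constant-gradient plane:
  # d_k = -(grad . u_k) * cell_size; rates exp(beta_dir * d_k)
  dx_steps <- integer(n_events)
  d <- grad_x * cell_size
  rates <- exp(beta_dir * c(-d, d, 0, 0))  # E, W, N, S
  for (i in seq_len(n_events)) {
    k <- sample.int(4, 1, prob = rates)
    dx_steps[i] <- c(1L, -1L, 0L, 0L)[k]
  }
  mean(dx_steps)
}

# 2-D grid-integration oracle for the J = 1, intercept-only hierarchy:
# posterior over (beta, mu) with z ~ Pois(tau e^beta), beta ~ N(mu, s2b),
# mu ~ N(0, s2m). Returns marginal mean/sd of beta and mu.
hier_grid_oracle <- function(z, tau, s2b, s2m,
                             bg = seq(-5, 3, length.out = 801),
                             mg = seq(-4, 4, length.out = 801)) {
  lpb <- vapply(bg, function(b) sum(z * (log(tau) + b) - tau * exp(b)), 0)
  M <- outer(lpb, rep(1, length(mg))) +
    outer(bg, mg, function(b, m) dnorm(b, m, sqrt(s2b), log = TRUE)) +
    outer(rep(1, length(bg)), dnorm(mg, 0, sqrt(s2m), log = TRUE))
  W <- exp(M - max(M)); W <- W / sum(W)
  pb <- rowSums(W); pm <- colSums(W)
  list(beta_mean = sum(bg * pb),
       beta_sd = sqrt(sum((bg - sum(bg * pb))^2 * pb)),
       mu_mean = sum(mg * pm),
       mu_sd = sqrt(sum((mg - sum(mg * pm))^2 * pm)))
}

# Intercept-only latent table with nT transitions (chosen slot = E).
intercept_table <- function(tau, id = "a", draw = 1L) {
  nT <- length(tau)
  tab <- data.frame(individual_id = id, draw_index = draw, segment_id = "s1",
                    trans = rep(seq_len(nT), each = 4),
                    slot = rep(c("E", "W", "N", "S"), nT),
                    z = rep(c(1, 0, 0, 0), nT),
                    tau = rep(tau, each = 4), clock = 0,
                    cell_row = 5L, cell_col = 5L)
  tab[["(Intercept)"]] <- 1
  attr(tab, "design_cols") <- "(Intercept)"
  attr(tab, "roles") <- ctmc_roles(persistence = FALSE)
  class(tab) <- c("latent_table", "data.frame")
  tab
}

# Subset a latent table preserving attributes (tests-local copy).
take_rows <- function(tab, keep) {
  out <- tab[keep, , drop = FALSE]
  for (a in c("design_cols", "roles", "basis", "base_cols", "raw_cols"))
    attr(out, a) <- attr(tab, a)
  class(out) <- class(tab)
  out
}

# Batch-means Monte Carlo standard error.
mcse <- function(x, nb = 30) {
  m <- floor(length(x) / nb)
  bm <- vapply(seq_len(nb), function(i) mean(x[((i - 1) * m + 1):(i * m)]), 0)
  sd(bm) / sqrt(nb)
}
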