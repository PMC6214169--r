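test_that("the latent Poisson log-likelihood matches its closed forms", {
  ## one transition, beta = 0, tau = 0.5: log(0.5) - 4 * 0.5
  tab <- intercept_table(0.5)
  expect_equal(as.numeric(poisson_loglik(tab, 0)), log(0.5) - 2)
  ## empty table -> 0
  expect_equal(as.numeric(poisson_loglik(take_rows(tab, FALSE), 0)), 0)
  ## random tables match the independently written dpois summation
  tl <- toy_landscape(seed = 1)
  set.seed(2)
  for (i in 1:5) {
    p <- simulate_ctmc_path(tl$land, c(-1, .3, .3, .2), c(20, 20), 24,
                            tl$roles, seed = i)
    t2 <- build_latent_table(path_to_seq(p), tl$land, tl$roles)
    b <- rnorm(4, 0, 0.6)
    expect_equal(as.numeric(poisson_loglik(t2, b)), pois_ll_oracle(t2, b))
  }
  expect_error(poisson_loglik(tab, c(0, 1)), "length")
  expect_error(poisson_loglik(tab, NaN), "finite")
})

test_that("latent Poisson and direct CTMC log-likelihoods are identical", {
  tl <- toy_landscape(seed = 3)
  set.seed(4)
  for (i in 1:4) {
    p <- simulate_ctmc_path(tl$land, c(-1, .3, .3, .2), c(20, 20), 36,
                            tl$roles, seed = 10 + i)
    sq <- path_to_seq(p)
    tab <- build_latent_table(sq, tl$land, tl$roles)
    for (k in 1:4) {
      b <- rnorm(4, 0, 0.7)
      expect_lt(abs(as.numeric(poisson_loglik(tab, b)) -
                    ctmc_loglik_direct(sq, tl$land, tl$roles, b)), 1e-10)
    }
  }
  ## single transition, unit rates, tau = 1: log 1 - 4
  g <- list(nrow = 20L, ncol = 20L, cell_size = 100, origin = c(0, 0))
  flatland <- raster_stack(covariate_raster(matrix(0, 20, 20), "f",
                                            cell_size = 100))
  roles0 <- ctmc_roles(persistence = FALSE)
  sq1 <- data.frame(individual_id = "a", draw_index = 1L, segment_id = "s1",
                    row = c(10L, 10L), col = c(10L, 11L),
                    tau_hours = c(1, 0.5), entry_clock_hours = c(0, 1))
  expect_equal(ctmc_loglik_direct(sq1, flatland, roles0, 0), -4)
})

test_that("the hierarchical sampler matches a grid-integration oracle", {
  set.seed(7)
  tau <- rexp(40, 2)
  tab <- intercept_table(tau)
  o <- hier_grid_oracle(tab$z, tab$tau, s2b = 1, s2m = 0.1)
  fit <- fit_hctmc(tab, "glm", priors = hier_priors(1, 0.1),
                   schedule = mcmc_schedule(3000, 40000, 2000, 5), seed = 42)
  b <- fit$draws$beta[, 1, 1]
  expect_lt(abs(mean(b) - o$beta_mean) / abs(o$beta_mean), 0.02)
  expect_lt(abs(sd(b) - o$beta_sd) / o$beta_sd, 0.02)
  ## mu mixes via its conjugate update; compare within Monte Carlo error
  expect_lt(abs(mean(fit$draws$mu[, 1]) - o$mu_mean),
            4 * mcse(fit$draws$mu[, 1]))
})

test_that("tight regularization collapses individuals onto the mean", {
  set.seed(8)
  tab <- rbind(intercept_table(rexp(30, 2), id = "a"),
               intercept_table(rexp(25, 1), id = "b"))
  attr(tab, "design_cols") <- "(Intercept)"
  attr(tab, "roles") <- ctmc_roles(persistence = FALSE)
  class(tab) <- c("latent_table", "data.frame")
  fit <- fit_hctmc(tab, "glm", priors = hier_priors(1e-8, 0.1),
                   schedule = mcmc_schedule(2000, 8000, 1000, 5), seed = 1)
  expect_lt(max(abs(fit$draws$beta[, 1, 1] - fit$draws$mu[, 1])), 1e-2)
  expect_lt(max(abs(fit$draws$beta[, 2, 1] - fit$draws$mu[, 1])), 1e-2)
})

test_that("a Q = 1 GAM reproduces the GLM draw-for-draw", {
  tl <- toy_landscape(seed = 9)
  p <- simulate_ctmc_path(tl$land, c(-1, .3, .3, .2), c(20, 20), 48,
                          tl$roles, seed = 3)
  tab <- build_latent_table(path_to_seq(p), tl$land, tl$roles)
  sch <- mcmc_schedule(1000, 3000, 500, 5)
  glm_fit <- fit_hctmc(tab, "glm", priors = hier_priors(), schedule = sch,
                       seed = 11)
  gam_fit <- fit_hctmc(tab, "gam", Q = 1, priors = hier_priors(),
                       schedule = sch, seed = 11)
  expect_identical(unname(glm_fit$draws$mu), unname(gam_fit$draws$mu))
  expect_identical(unname(glm_fit$draws$beta), unname(gam_fit$draws$beta))
  ## identical likelihood values on identical draws
  e1 <- expand_gam(tab, cyclic_basis(1))
  b <- c(-0.9, 0.2, 0.1, 0.25)
  expect_identical(as.numeric(poisson_loglik(tab, b)),
                   as.numeric(poisson_loglik(e1, b)))
})

test_that("back-transformed curves are periodic and reduce to the GLM", {
  tl <- toy_landscape(seed = 10)
  p <- simulate_ctmc_path(tl$land, c(-1, .3, .3, .2), c(20, 20), 72,
                          tl$roles, seed = 4)
  tab <- build_latent_table(path_to_seq(p), tl$land, tl$roles)
  fit <- fit_hctmc(tab, "gam", Q = 4, priors = hier_priors(),
                   schedule = mcmc_schedule(1000, 3000, 500, 10), seed = 5)
  cur <- backtransform_curves(fit, clock_grid = c(0, 6, 12, 18, 24))
  draws <- attr(cur, "draws")
  ## curve(0) == curve(24) exactly, draw by draw, covariate by covariate
  expect_identical(draws[, 1, ], draws[, 5, ])
  expect_error(backtransform_curves(
    fit_hctmc(tab, "glm", schedule = mcmc_schedule(200, 600, 100, 5), seed = 1)),
    "GAM")
  ## Q = 1: flat curves equal to the GLM-style coefficients
  fit1 <- fit_hctmc(tab, "gam", Q = 1, priors = hier_priors(),
                    schedule = mcmc_schedule(1000, 3000, 500, 10), seed = 5)
  cur1 <- backtransform_curves(fit1, clock_grid = c(0, 12))
  flat <- cur1[cur1$clock == 0, "mean"]
  expect_equal(unname(flat), unname(colMeans(fit1$draws$mu)))
  expect_equal(cur1[cur1$clock == 0, "mean"], cur1[cur1$clock == 12, "mean"])
})

test_that("posterior predictive scores prefer the generating coefficients", {
  tl <- toy_landscape(seed = 12)
  p <- simulate_ctmc_path(tl$land, c(-1, .4, .4, .2), c(20, 20), 96,
                          tl$roles, seed = 6)
  sq <- path_to_seq(p)
  tab <- build_latent_table(sq, tl$land, tl$roles)
  fit <- fit_hctmc(tab, "glm", priors = hier_priors(),
                   schedule = mcmc_schedule(1500, 4000, 1000, 10), seed = 7)
  ## score the same rows as a held-out set
  sc1 <- posterior_predictive_score(fit, tab)
  expect_true(is.finite(sc1$score))
  ## determinism
  expect_identical(sc1$score, posterior_predictive_score(fit, tab)$score)
  ## perturbing one coefficient by +2 posterior sds must hurt the score
  worse <- fit
  shift <- 2 * sd(fit$draws$beta[, 1, 1])
  worse$draws$beta[, 1, 1] <- worse$draws$beta[, 1, 1] + shift
  sc2 <- posterior_predictive_score(worse, tab)
  expect_gt(sc2$score, sc1$score)
})

test_that("regularization selection returns the arg-min with small-value ties", {
  tl <- toy_landscape(seed = 13)
  sq <- rbind(path_to_seq(simulate_ctmc_path(tl$land, c(-1, .3, .3, .2),
                                             c(20, 20), 48, tl$roles, seed = 1,
                                             individual_id = "a"), "a", 1L),
              path_to_seq(simulate_ctmc_path(tl$land, c(-1, .3, .3, .2),
                                             c(20, 20), 48, tl$roles, seed = 2,
                                             individual_id = "a"), "a", 2L))
  tab <- build_latent_table(sq, tl$land, tl$roles)
  fit_tab <- take_rows(tab, tab$draw_index == 1)
  sco_tab <- take_rows(tab, tab$draw_index == 2)
  sch <- mcmc_schedule(500, 1500, 250, 5)
  one <- select_regularization(fit_tab, sco_tab, grid = 0.5, schedule = sch,
                               seed = 3)
  expect_equal(one$sigma2_beta, 0.5)
  expect_equal(nrow(one$scores), 1)
  ## reproducible score curve
  two <- select_regularization(fit_tab, sco_tab, grid = c(0.1, 1),
                               schedule = sch, seed = 3)
  two2 <- select_regularization(fit_tab, sco_tab, grid = c(0.1, 1),
                                schedule = sch, seed = 3)
  expect_identical(two$scores, two2$scores)
  expect_true(two$sigma2_beta %in% c(0.1, 1))
  expect_error(select_regularization(fit_tab, sco_tab, grid = numeric()),
               "non-empty")
})

test_that("one-group model comparison degenerates to the single fits", {
  tl <- toy_landscape(seed = 14)
  sq <- rbind(path_to_seq(simulate_ctmc_path(tl$land, c(-1, .3, .3, .2),
                                             c(20, 20), 48, tl$roles, seed = 1,
                                             individual_id = "a"), "a", 1L),
              path_to_seq(simulate_ctmc_path(tl$land, c(-1, .3, .3, .2),
                                             c(20, 20), 48, tl$roles, seed = 2,
                                             individual_id = "a"), "a", 2L))
  tab <- build_latent_table(sq, tl$land, tl$roles)
  fit_tab <- take_rows(tab, tab$draw_index == 1)
  sco_tab <- take_rows(tab, tab$draw_index == 2)
  sch <- mcmc_schedule(500, 1500, 250, 5)
  w <- testthat::capture_warnings(
    cmp <- compare_model_set(fit_tab, sco_tab, groups = c(a = "F"), Q = 4,
                             schedule = sch, seed = 4))
  expect_true(any(grepl("one group", w)))
  expect_equal(nrow(cmp$ranking), 4)
  s <- cmp$scores
  expect_equal(unname(s[3]), unname(s["GLM-all"]))
  expect_equal(unname(s[4]), unname(s["GAM-all"]))
})

test_that("sampler summaries and methods behave", {
  set.seed(20)
  tab <- intercept_table(rexp(30, 2))
  fit <- fit_hctmc(tab, "glm", schedule = mcmc_schedule(500, 2000, 500, 5),
                   seed = 2)
  s <- summary(fit)
  expect_s3_class(s, "summary.hctmc_fit")
  expect_equal(nrow(s$population), 1)
  expect_named(coef(fit), "(Intercept)")
  expect_equal(dim(coef(fit, "individual")), c(1, 1))
  expect_output(print(fit), "Hierarchical CTMC")
  f <- tempfile(fileext = ".csv")
  write_draws(fit, f)
  d <- read.csv(f)
  expect_setequal(unique(d$level), c("mu", "phi", "a"))
})
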