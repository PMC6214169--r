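#' Priors for the hierarchical Poisson movement model
#'
#' Individual coefficient vectors are drawn from
#' `beta_j ~ N(mu, sigma2_beta * diag(phi))` with `phi_1 = 1` and
#' `log phi_p ~ N(0, phi_var)` for `p >= 2`, and
#' `mu ~ N(0, sigma2_mu * I)`. Both `sigma2_beta` (selected a priori, e.g.
#' by [select_regularization()]) and `sigma2_mu` act as regularization
#' scales shrinking unimportant effects toward zero.
#'
#' @param sigma2_beta individual-level regularization scale (default 1).
#' @param sigma2_mu population-mean prior variance (default 0.1).
#' @param phi_var prior variance of `log phi_p` (default 0.04).
#' @return an object of class `hier_priors`.
#' @export
hier_priors <- function(sigma2_beta = 1, sigma2_mu = 0.1, phi_var = 0.04) {
  if (sigma2_beta <= 0 || sigma2_mu <= 0 || phi_var <= 0)
    stop_invalid("all prior scales must be positive")
  structure(list(sigma2_beta = sigma2_beta, sigma2_mu = sigma2_mu,
                 phi_var = phi_var), class = "hier_priors")
}

#' MCMC schedule
#'
#' Adaptive proposal tuning runs over the first `adapt` iterations and the
#' tuned scales are then frozen; `main` further iterations are run, the
#' first `burn` discarded and every `thin`-th retained. The defaults mirror
#' a full production run; reduce them for exploration.
#'
#' @param adapt,main,burn,thin iteration counts (burn < main).
#' @return an object of class `mcmc_schedule`.
#' @export
mcmc_schedule <- function(adapt = 50000, main = 100000, burn = 10000,
                          thin = 10) {
  if (burn >= main) stop_invalid("burn must be < main")
  if (thin < 1) stop_invalid("thin must be >= 1")
  structure(list(adapt = as.integer(adapt), main = as.integer(main),
                 burn = as.integer(burn), thin = as.integer(thin)),
            class = "mcmc_schedule")
}

## Per-individual stacked matrices from a latent table, with the
## multiple-imputation weight 1 / (number of fit imputations pooled).
split_design <- function(table) {
  cols <- attr(table, "design_cols")
  ids <- unique(table$individual_id)
  out <- lapply(ids, function(id) {
    tj <- table[table$individual_id == id, , drop = FALSE]
    M <- length(unique(tj$draw_index))
    list(X = as.matrix(tj[, cols, drop = FALSE]), z = tj$z, tau = tj$tau,
         w = 1 / M, M = M)
  })
  names(out) <- ids
  out
}

#' Fit the hierarchical CTMC movement model by MCMC
#'
#' The central model-fitting function. Latent Poisson rows (pooled over the
#' fit-set imputations; each imputation's log-likelihood enters with weight
#' `1/M_fit`, the process-imputation average) are modeled as
#' `z ~ Poisson(tau * exp(x' beta_j))` with the hierarchy of
#' [hier_priors()]. Sampling is blocked random-walk Metropolis for each
#' individual coefficient vector and each `phi_p`, with the exact Gaussian
#' full-conditional update for `mu`; proposal scales adapt toward 0.23
#' (vector blocks) / 0.44 (scalar blocks) acceptance during the adaptation
#' phase only.
#'
#' For `model = "gam"` the design is Kronecker-expanded with a cyclic cubic
#' spline basis of dimension `Q` ([cyclic_basis()], [expand_gam()]) so every
#' coefficient varies over the 24 h clock; `Q = 1` reproduces the GLM
#' exactly.
#'
#' @param table a `latent_table` of fit-set rows (one or more individuals
#'   and imputations). Apply [center_scale()] first if per-individual
#'   scaling is wanted.
#' @param model `"glm"` or `"gam"`.
#' @param Q cyclic-basis dimension for the GAM (ignored for the GLM).
#' @param priors a [hier_priors()].
#' @param schedule an [mcmc_schedule()].
#' @param seed integer seed (all randomness flows through R's RNG).
#' @param scaling optional scaling report from [center_scale()], stored for
#'   reuse on score tables.
#' @return an object of class `hctmc_fit` with posterior draw arrays
#'   `draws$beta` (draws x J x P), `draws$mu`, `draws$phi`, plus metadata.
#' @export
fit_hctmc <- function(table, model = c("glm", "gam"), Q = 6,
                      priors = hier_priors(), schedule = mcmc_schedule(),
                      seed = NULL, scaling = NULL) {
  model <- match.arg(model)
  basis <- NULL
  if (model == "gam") {
    if (is.null(attr(table, "basis"))) {
      basis <- cyclic_basis(Q)
      table <- expand_gam(table, basis)
    } else {
      basis <- attr(table, "basis")
    }
  }
  des <- split_design(table)
  if (!length(des)) stop_invalid("no individuals in table")
  for (d in des)
    if (!nrow(d$X)) stop_invalid("an individual has no transitions")
  res <- with_seed(seed, {
    cpp_mcmc_hier(lapply(des, `[[`, "X"), lapply(des, `[[`, "z"),
                  lapply(des, `[[`, "tau"),
                  vapply(des, `[[`, 0, "w"),
                  priors$sigma2_beta, priors$sigma2_mu, priors$phi_var,
                  schedule$adapt, schedule$main, schedule$burn, schedule$thin)
  })
  ids <- names(des)
  cols <- attr(table, "design_cols")
  dimnames(res$beta) <- list(NULL, ids, cols)
  dimnames(res$mu) <- list(NULL, cols)
  dimnames(res$phi) <- list(NULL, cols)
  warn <- NULL
  if (any(res$accept_beta < 0.1 | res$accept_beta > 0.6))
    warn <- c(warn, "some individual-block acceptance rates outside [0.1, 0.6] at freeze")
  structure(list(model_kind = toupper(model),
                 draws = list(beta = res$beta, mu = res$mu, phi = res$phi),
                 individuals = ids, design_cols = cols, basis = basis,
                 base_cols = attr(table, "base_cols") %||% cols,
                 priors = priors, schedule = schedule, seed = seed,
                 accept = list(beta = as.numeric(res$accept_beta),
                               phi = as.numeric(res$accept_phi)),
                 scales = list(beta = as.numeric(res$scale_beta),
                               phi = as.numeric(res$scale_phi)),
                 n_clipped = res$n_clipped, n_kept = res$n_kept,
                 scaling = scaling, warnings = warn,
                 call = match.call()),
            class = "hctmc_fit")
}

#' Posterior predictive score on held-out imputations
#'
#' The negative log pointwise predictive density, averaged over the score
#' imputations: for each latent row the Poisson density of `z` is averaged
#' over the thinned posterior draws of that individual's coefficients, its
#' log is summed over rows within an imputation, and the negated sum is
#' averaged over imputations. Lower is better.
#'
#' @param fit an `hctmc_fit`.
#' @param score_table a `latent_table` of score-set rows, built with the same
#'   scaling report (and, for a GAM, the same basis) as the fit.
#' @param floor_log per-draw log-density floor (default -700).
#' @return an object of class `score_report` with `score`, `per_individual`,
#'   and `model`.
#' @export
posterior_predictive_score <- function(fit, score_table, floor_log = -700) {
  stopifnot(inherits(fit, "hctmc_fit"))
  if (fit$model_kind == "GAM" && is.null(attr(score_table, "basis")))
    score_table <- expand_gam(score_table, fit$basis)
  cols <- attr(score_table, "design_cols")
  if (!identical(cols, fit$design_cols))
    stop_invalid("score table design does not match the fit")
  per <- data.frame(individual_id = character(), score = numeric())
  total <- 0
  for (id in unique(score_table$individual_id)) {
    if (!id %in% fit$individuals)
      stop_invalid("individual ", id, " not in the fit")
    tj <- score_table[score_table$individual_id == id, , drop = FALSE]
    B <- fit$draws$beta[, id, , drop = FALSE]
    dim(B) <- c(dim(fit$draws$beta)[1L], length(cols))
    X <- as.matrix(tj[, cols, drop = FALSE])
    lppd <- cpp_row_lppd(X, tj$z, tj$tau, B, 35, floor_log)
    imps <- unique(tj$draw_index)
    sc <- -sum(vapply(imps, function(m) sum(lppd[tj$draw_index == m]), 0)) /
      length(imps)
    per <- rbind(per, data.frame(individual_id = id, score = sc))
    total <- total + sc
  }
  structure(list(model = fit$model_kind, score = total, per_individual = per),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report %s: posterior predictive score %.4f (lower is better)>\n",
              x$model, x$score))
  invisible(x)
}

#' Select the regularization scale by posterior predictive score
#'
#' Fits the model at each candidate `sigma2_beta`, scores it on the held-out
#' imputations, and returns the arg-min (ties broken toward the smaller
#' value, i.e. stronger shrinkage).
#'
#' @param fit_table,score_table fit- and score-set `latent_table`s.
#' @param grid positive candidate values (default `c(0.01, 0.1, 1, 10)`).
#' @param model,Q,priors,schedule,seed as in [fit_hctmc()] (a reduced
#'   schedule is customary here).
#' @return list with `sigma2_beta` (chosen), `scores` (data.frame), and
#'   `fits` (the per-candidate `hctmc_fit`s).
#' @export
select_regularization <- function(fit_table, score_table,
                                  grid = c(0.01, 0.1, 1, 10),
                                  model = "glm", Q = 6,
                                  priors = hier_priors(),
                                  schedule = mcmc_schedule(), seed = NULL) {
  if (!length(grid) || any(grid <= 0))
    stop_invalid("grid must be non-empty and positive")
  grid <- sort(grid)
  fits <- vector("list", length(grid))
  scores <- numeric(length(grid))
  for (i in seq_along(grid)) {
    pr <- priors
    pr$sigma2_beta <- grid[i]
    fits[[i]] <- fit_hctmc(fit_table, model = model, Q = Q, priors = pr,
                           schedule = schedule, seed = seed)
    scores[i] <- posterior_predictive_score(fits[[i]], score_table)$score
  }
  best <- which(scores == min(scores))[1L]   # grid sorted: ties -> smaller
  list(sigma2_beta = grid[best],
       scores = data.frame(sigma2_beta = grid, score = scores),
       fits = fits, best = best)
}

#' Back-transform GAM coefficients to time-varying coefficient curves
#'
#' For each base covariate `p`, the population-level varying coefficient at
#' clock time `t` is `sum_q mu_alpha[p, q] * w_q(t)` per posterior draw;
#' pointwise posterior means and 2.5/97.5 percentiles are returned. Curves
#' are exactly periodic: `curve(0) == curve(24)` for every draw.
#'
#' @param fit a GAM `hctmc_fit`.
#' @param clock_grid clock times (hours) at which to evaluate (default every
#'   15 min over `[0, 24]`).
#' @param individual optional individual id; default population level.
#' @return data.frame `covariate`, `clock`, `mean`, `lo95`, `hi95`, with the
#'   per-draw curves in `attr(, "draws")` (draws x time x covariate).
#' @export
backtransform_curves <- function(fit, clock_grid = seq(0, 24, by = 0.25),
                                 individual = NULL) {
  stopifnot(inherits(fit, "hctmc_fit"))
  if (fit$model_kind != "GAM")
    stop_invalid("time-varying curves require a GAM fit")
  basis <- fit$basis
  W <- basis$eval(clock_grid)                       # T x Q
  A <- if (is.null(individual)) fit$draws$mu else {
    B <- fit$draws$beta[, individual, , drop = FALSE]
    dim(B) <- c(dim(fit$draws$beta)[1L], length(fit$design_cols))
    colnames(B) <- fit$design_cols
    B
  }
  base <- fit$base_cols
  D <- nrow(A); TT <- length(clock_grid)
  curves <- array(0, dim = c(D, TT, length(base)),
                  dimnames = list(NULL, NULL, base))
  for (i in seq_along(base)) {
    qcols <- paste0(base[i], "|q", seq_len(basis$Q))
    curves[, , i] <- A[, qcols, drop = FALSE] %*% t(W)
  }
  out <- do.call(rbind, lapply(seq_along(base), function(i) {
    cm <- curves[, , i, drop = FALSE]
    dim(cm) <- c(D, TT)
    data.frame(covariate = base[i], clock = clock_grid,
               mean = colMeans(cm),
               lo95 = apply(cm, 2L, quantile, 0.025),
               hi95 = apply(cm, 2L, quantile, 0.975))
  }))
  rownames(out) <- NULL
  attr(out, "draws") <- curves
  out
}

#' Fit and score the four-model sex-split set
#'
#' Fits (1) a GLM to all individuals, (2) a GAM to all, (3) a GLM to the
#' first group plus a GAM to the second, and (4) the reverse, scoring each
#' on the held-out imputations; mixed-model scores are the sum over the two
#' group fits. Groups with zero individuals degrade the mixed models to the
#' remaining group's single-model score, with a warning.
#'
#' @param fit_table,score_table fit- and score-set `latent_table`s.
#' @param groups named character vector mapping individual id to group label
#'   (two labels, e.g. `"F"`, `"M"`).
#' @param Q GAM basis dimension.
#' @param priors,schedule,seed as in [fit_hctmc()].
#' @return list with `ranking` (data.frame sorted by score) and `reports`.
#' @export
compare_model_set <- function(fit_table, score_table, groups, Q = 6,
                              priors = hier_priors(),
                              schedule = mcmc_schedule(), seed = NULL) {
  ids <- unique(fit_table$individual_id)
  if (!all(ids %in% names(groups)))
    stop_invalid("every individual needs a group label")
  labs <- sort(unique(groups[ids]))
  if (length(labs) > 2L) stop_invalid("expected at most two group labels")
  sub <- function(tab, keep) {
    out <- tab[tab$individual_id %in% keep, , drop = FALSE]
    for (a in c("design_cols", "roles", "basis", "base_cols"))
      attr(out, a) <- attr(tab, a)
    class(out) <- class(tab)
    out
  }
  fit_score <- function(ft, st, model) {
    f <- fit_hctmc(ft, model = model, Q = Q, priors = priors,
                   schedule = schedule, seed = seed)
    posterior_predictive_score(f, st)$score
  }
  scores <- c("GLM-all" = fit_score(fit_table, score_table, "glm"),
              "GAM-all" = fit_score(fit_table, score_table, "gam"))
  mixed <- function(m1, m2, label) {
    if (length(labs) < 2L) {
      warning("only one group present; mixed model '", label,
              "' reduces to its single-group score", call. = FALSE)
      return(fit_score(fit_table, score_table, m1))
    }
    g1 <- ids[groups[ids] == labs[1L]]
    g2 <- ids[groups[ids] == labs[2L]]
    fit_score(sub(fit_table, g1), sub(score_table, g1), m1) +
      fit_score(sub(fit_table, g2), sub(score_table, g2), m2)
  }
  scores <- c(scores,
              structure(mixed("glm", "gam", "GLM+GAM"),
                        names = sprintf("GLM-%s+GAM-%s", labs[1L],
                                        labs[min(2L, length(labs))])),
              structure(mixed("gam", "glm", "GAM+GLM"),
                        names = sprintf("GAM-%s+GLM-%s", labs[1L],
                                        labs[min(2L, length(labs))])))
  ranking <- data.frame(model = names(scores), score = as.numeric(scores))
  ranking <- ranking[order(ranking$score), ]
  rownames(ranking) <- NULL
  list(ranking = ranking, scores = scores)
}
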