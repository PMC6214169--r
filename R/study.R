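#' Simulation study: recovery of a diel varying coefficient
#'
#' Simulates `J` individuals on a seeded synthetic landscape whose
#' directional response to the covariate follows a sinusoidal diel curve
#' (`amplitude * sin(2*pi*(t - 6)/24)`, zero-centered so it is commensurate
#' with the zero-mean regularization priors), discretizes the exact event
#' paths, fits the hierarchical GAM, and reports the pointwise coverage of
#' the true curve by the 95% credible bands.
#'
#' @param J individuals (default 6).
#' @param window_days window length (default 14).
#' @param amplitude diel amplitude of the directional coefficient
#'   (default 0.25).
#' @param Q basis dimension (default 6).
#' @param priors a [hier_priors()]; the default uses `sigma2_beta = 0.1`,
#'   reflecting that the simulated individuals share one curve.
#' @param schedule an [mcmc_schedule()] (reduced default).
#' @param seed integer seed.
#' @return list with `fit`, `curves`, `truth` (function of clock), and
#'   `coverage` (fraction of hourly grid points whose band covers the truth).
#' @export
curve_study <- function(J = 6, window_days = 14, amplitude = 0.25, Q = 6,
                        priors = hier_priors(0.1, 0.1),
                        schedule = mcmc_schedule(5000, 15000, 2000, 10),
                        seed = 1) {
  land <- make_landscape(1, c(80, 80), 5, seed = stage_seed(seed, 11L))
  roles <- ctmc_roles("cov1", "cov1", persistence = TRUE)
  truth <- function(t) amplitude * sin(2 * pi * (t - 6) / 24)
  bfun <- function(clock) c(log(0.25), 0.2, truth(clock), 0.15)
  seqs <- lapply(seq_len(J), function(j) {
    p <- simulate_ctmc_path(land, NULL, c(40, 40), window_days * 24, roles,
                            time_varying = bfun,
                            seed = stage_seed(seed, 20L + j),
                            individual_id = sprintf("i%02d", j))
    exact_sequence(p)
  })
  tab <- build_latent_table(do.call(rbind, seqs), land, roles)
  fit <- fit_hctmc(tab, "gam", Q = Q, priors = priors, schedule = schedule,
                   seed = stage_seed(seed, 40L))
  cur <- backtransform_curves(fit, clock_grid = seq(0, 24, by = 1))
  d <- cur[cur$covariate == "dir_cov1", ]
  tv <- truth(d$clock)
  list(fit = fit, curves = cur, truth = truth,
       coverage = mean(d$lo95 <= tv & tv <= d$hi95))
}

#' Exact cell-transition sequence of a simulated event path
#'
#' Converts an [simulate_ctmc_path()] result to the cell-sequence format of
#' [discretize_path()] without any imputation (known ground-truth path).
#'
#' @param p an `event_path`.
#' @param draw_index imputation index to label the rows with (default 1).
#' @param label optional fit/score label column.
#' @return a cell-sequence data.frame.
#' @export
exact_sequence <- function(p, draw_index = 1L, label = NULL) {
  n <- length(p$event_times)
  out <- data.frame(individual_id = p$individual_id, draw_index = draw_index,
                    segment_id = "s1", row = p$cells[, 1], col = p$cells[, 2],
                    tau_hours = c(diff(p$event_times),
                                  p$duration - p$event_times[n]),
                    entry_clock_hours = clock24(p$start_clock + p$event_times))
  if (!is.null(label)) out$label <- label
  out
}

#' Simulation study: sex-split model comparison on diel vs static movement
#'
#' Simulates a small population whose baseline movement rate either follows
#' a diel cycle (`log rate = log(0.25) + amplitude * sin(2*pi*(t - 4)/24)`,
#' per group as requested) or is static, runs the full stage-1 imputation
#' (GPS observation at 3 h, functional path model, `M` imputations split
#' into fit and score sets), and fits and scores the four-model set of
#' [compare_model_set()].
#'
#' @param J individuals, alternating group labels F, M (default 4).
#' @param window_days window length (default 6).
#' @param amplitude_f,amplitude_m diel amplitude of the baseline-rate curve
#'   for females / males (0 = static).
#' @param M,fit_count,score_count imputation counts (defaults 4, 2, 2).
#' @param Q GAM basis dimension (default 4).
#' @param priors,schedule as in [fit_hctmc()].
#' @param seed integer seed.
#' @return the [compare_model_set()] result (ranking and scores).
#' @export
compare_study <- function(J = 4, window_days = 6, amplitude_f = 0,
                          amplitude_m = 0, M = 4, fit_count = 2,
                          score_count = 2, Q = 4,
                          priors = hier_priors(1, 0.1),
                          schedule = mcmc_schedule(1500, 3000, 1000, 10),
                          seed = 1) {
  land <- make_landscape(1, c(80, 80), 5, seed = stage_seed(seed, 51L))
  roles <- ctmc_roles("cov1", "cov1", persistence = TRUE)
  geom <- raster_geometry(land[[1]])
  ids <- sprintf("i%02d", seq_len(J))
  groups <- structure(rep(c("F", "M"), length.out = J), names = ids)
  seqs <- list()
  for (j in seq_len(J)) {
    amp <- if (groups[j] == "F") amplitude_f else amplitude_m
    bfun <- local({
      a <- amp
      function(clock) c(log(0.25) + a * sin(2 * pi * (clock - 4) / 24),
                        0.2, 0.2, 0.15)
    })
    p <- simulate_ctmc_path(land, NULL, c(40, 40), window_days * 24, roles,
                            time_varying = bfun,
                            seed = stage_seed(seed, 60L + j),
                            individual_id = ids[j])
    tr <- observe_gps(p, geom, 3, 25, seed = stage_seed(seed, 90L + j))
    f <- fit_functional_path(tr, path_priors(sigma_obs = 25),
                             n_mcmc = 1200, burn = 300,
                             seed = stage_seed(seed, 120L + j))
    for (ip in draw_imputed_paths(f, M, fit_count, score_count))
      seqs[[length(seqs) + 1L]] <- discretize_path(ip, geom)
  }
  seqs <- do.call(rbind, seqs)
  tab <- build_latent_table(seqs, land, roles)
  lab <- seqs$label[match(paste(tab$individual_id, tab$draw_index),
                          paste(seqs$individual_id, seqs$draw_index))]
  fit_tab <- subset_table(tab, lab == "fit")
  score_tab <- subset_table(tab, lab == "score")
  compare_model_set(fit_tab, score_tab, groups, Q = Q, priors = priors,
                    schedule = schedule, seed = stage_seed(seed, 150L))
}
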