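#' @export
print.hctmc_fit <- function(x, ...) {
  cat(sprintf("Hierarchical CTMC movement model (%s)\n", x$model_kind))
  cat(sprintf("  individuals: %d   design width: %d   kept draws: %d\n",
              length(x$individuals), length(x$design_cols), x$n_kept))
  cat(sprintf("  sigma2_beta = %g, sigma2_mu = %g\n",
              x$priors$sigma2_beta, x$priors$sigma2_mu))
  if (!is.null(x$warnings)) cat("  note:", x$warnings, "\n")
  cat("\nPopulation-level posterior means (mu):\n")
  print(round(colMeans(x$draws$mu), 4))
  invisible(x)
}

#' Summarize a hierarchical CTMC fit
#'
#' @param object an `hctmc_fit`.
#' @param prob credible-interval mass (default 0.95).
#' @param ... unused.
#' @return a `summary.hctmc_fit`: population-level coefficient table (mean,
#'   sd, credible bounds), phi summaries and sampler diagnostics.
#' @export
summary.hctmc_fit <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  mu <- object$draws$mu
  pop <- data.frame(coef = colnames(mu), mean = colMeans(mu),
                    sd = apply(mu, 2L, sd),
                    lo = apply(mu, 2L, quantile, a),
                    hi = apply(mu, 2L, quantile, 1 - a))
  names(pop)[4:5] <- sprintf("q%g", c(a, 1 - a) * 100)
  rownames(pop) <- NULL
  phi <- colMeans(object$draws$phi)
  structure(list(model_kind = object$model_kind, population = pop, phi = phi,
                 accept = object$accept, n_clipped = object$n_clipped,
                 n_kept = object$n_kept, prob = prob),
            class = "summary.hctmc_fit")
}

#' @export
print.summary.hctmc_fit <- function(x, ...) {
  cat(sprintf("Hierarchical CTMC movement model (%s), %d posterior draws\n\n",
              x$model_kind, x$n_kept))
  cat(sprintf("Population-level effects (%g%% credible intervals):\n",
              x$prob * 100))
  print(x$population, digits = 4)
  cat("\nphi posterior means:\n")
  print(round(x$phi, 3))
  cat(sprintf("\nacceptance: beta blocks %.2f-%.2f, phi blocks %.2f-%.2f; %d clipped predictors\n",
              min(x$accept$beta), max(x$accept$beta),
              min(x$accept$phi[-1], Inf), max(x$accept$phi[-1], -Inf),
              x$n_clipped))
  invisible(x)
}

#' Extract coefficients from a hierarchical CTMC fit
#'
#' @param object an `hctmc_fit`.
#' @param level `"population"` (posterior mean of mu) or `"individual"`
#'   (J x P matrix of posterior means of beta_j).
#' @param ... unused.
#' @return named numeric vector or matrix of posterior means.
#' @export
coef.hctmc_fit <- function(object, level = c("population", "individual"),
                           ...) {
  level <- match.arg(level)
  if (level == "population") return(colMeans(object$draws$mu))
  apply(object$draws$beta, c(2L, 3L), mean)
}

#' Plot a hierarchical CTMC fit
#'
#' For a GLM fit: a caterpillar plot of population-level posterior means and
#' 95% credible intervals. For a GAM fit: the back-transformed time-varying
#' population coefficient curves with pointwise 95% bands.
#'
#' @param x an `hctmc_fit`.
#' @param ... passed to the underlying plotting calls.
#' @return `x`, invisibly.
#' @export
plot.hctmc_fit <- function(x, ...) {
  if (x$model_kind == "GAM") {
    cur <- backtransform_curves(x)
    covs <- unique(cur$covariate)
    old <- graphics::par(mfrow = grDevices::n2mfrow(length(covs)))
    on.exit(graphics::par(old))
    for (cv in covs) {
      d <- cur[cur$covariate == cv, ]
      plot(d$clock, d$mean, type = "l", ylim = range(d$lo95, d$hi95),
           xlab = "clock (h)", ylab = "coefficient", main = cv, ...)
      graphics::lines(d$clock, d$lo95, lty = 2)
      graphics::lines(d$clock, d$hi95, lty = 2)
      graphics::abline(h = 0, col = "gray")
    }
  } else {
    s <- summary(x)$population
    n <- nrow(s)
    plot(s$mean, seq_len(n), xlim = range(s[, 4], s[, 5]), yaxt = "n",
         xlab = "population-level effect", ylab = "", pch = 19, ...)
    graphics::segments(s[, 4], seq_len(n), s[, 5], seq_len(n))
    graphics::axis(2, at = seq_len(n), labels = s$coef, las = 1)
    graphics::abline(v = 0, col = "gray")
  }
  invisible(x)
}

#' Write posterior draws in long CSV format
#'
#' Columns: `draw`, `level` (`mu`, `phi` or individual id), `parameter`,
#' `value`.
#'
#' @param fit an `hctmc_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  D <- dim(fit$draws$mu)[1L]
  cols <- fit$design_cols
  pieces <- list(data.frame(draw = rep(seq_len(D), length(cols)),
                            level = "mu",
                            parameter = rep(cols, each = D),
                            value = as.numeric(fit$draws$mu)),
                 data.frame(draw = rep(seq_len(D), length(cols)),
                            level = "phi",
                            parameter = rep(cols, each = D),
                            value = as.numeric(fit$draws$phi)))
  for (id in fit$individuals) {
    B <- fit$draws$beta[, id, ]
    pieces[[length(pieces) + 1L]] <-
      data.frame(draw = rep(seq_len(D), length(cols)), level = id,
                 parameter = rep(cols, each = D), value = as.numeric(B))
  }
  write.csv(do.call(rbind, pieces), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
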