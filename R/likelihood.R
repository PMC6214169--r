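#' Latent-variable Poisson log-likelihood
#'
#' `sum over rows of z * log(lambda) - lambda` with
#' `lambda = tau * exp(x'beta)`; the `log z!` term vanishes because
#' `z` is 0/1. Linear predictors are clipped at +/-35 before exponentiation
#' as an overflow guard; the number of clipped rows is attached as an
#' attribute.
#'
#' @param table a `latent_table`.
#' @param coeffs numeric coefficient vector matching the design width.
#' @param clip clipping bound for the linear predictor.
#' @return the log-likelihood (scalar) with attribute `n_clipped`.
#' @export
poisson_loglik <- function(table, coeffs, clip = 35) {
  cols <- attr(table, "design_cols")
  if (length(coeffs) != length(cols))
    stop_invalid("coeffs has length ", length(coeffs),
                 ", design width is ", length(cols))
  if (!all(is.finite(coeffs))) stop_invalid("non-finite coefficients")
  if (!nrow(table)) return(structure(0, n_clipped = 0L))
  X <- as.matrix(table[, cols, drop = FALSE])
  res <- cpp_pois_loglik(X, table$z, table$tau, as.numeric(coeffs), clip)
  structure(res$loglik, n_clipped = res$n_clipped)
}

#' Direct CTMC log-likelihood of a cell sequence
#'
#' Computes, transition by transition, the continuous-time Markov chain
#' log-likelihood in the Poisson base measure:
#' `sum_i [log(tau_i * rate_chosen,i) - tau_i * sum_k rate_k,i]`. This is
#' identical to [poisson_loglik()] on the corresponding latent table for any
#' coefficient vector, and serves as its independent oracle. (The bare
#' exponential-holding-times-times-multinomial density differs only by the
#' path constant `sum_i log tau_i`.)
#'
#' @param seq a cell sequence (see [discretize_path()]).
#' @param rasters a `raster_stack`.
#' @param roles a `ctmc_roles`.
#' @param beta coefficient vector in [design_colnames()] order.
#' @return scalar log-likelihood.
#' @export
ctmc_loglik_direct <- function(seq, rasters, roles, beta) {
  arr <- design_arrays(rasters, roles)
  ll <- 0
  segs <- split(seq, list(seq$individual_id, seq$draw_index, seq$segment_id),
                drop = TRUE)
  for (s in segs) {
    n <- nrow(s)
    if (n < 2L) next
    prev_u <- c(0, 0)
    for (i in seq_len(n - 1L)) {
      X <- design_rows_at(arr, s$row[i], s$col[i], prev_u)
      rates <- exp(as.numeric(X %*% beta))
      if (any(rates <= 0)) stop_invalid("non-positive rate encountered")
      drow <- s$row[i + 1L] - s$row[i]; dcol <- s$col[i + 1L] - s$col[i]
      k <- which(NEIGHBOR_DROW == drow & NEIGHBOR_DCOL == dcol)
      if (length(k) != 1L) stop_invalid("sequence not rook-contiguous")
      tau <- s$tau_hours[i]
      ll <- ll + log(tau * rates[k]) - tau * sum(rates)
      prev_u <- c(NEIGHBOR_UX[k], NEIGHBOR_UY[k])
    }
  }
  ll
}
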