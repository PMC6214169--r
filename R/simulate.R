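#' Simulate an exact CTMC movement path on a raster landscape
#'
#' Event-time (Gillespie) simulation of the four-neighbor CTMC: residence
#' time in the current cell is exponential with rate equal to the sum of the
#' four neighbor rates, and the destination is drawn with probability
#' proportional to its rate. Rates use the same construction as the
#' likelihood (see [build_rates()]), so simulator and model share one
#' definition. With time-varying coefficients, the coefficient curve is
#' evaluated at the clock time of cell entry and held constant over the
#' residence (piecewise-constant approximation). Simulation requires a
#' 2-cell edge buffer and stops cleanly (truncation flag, not an error) if
#' the path would enter it.
#'
#' @param rasters a `raster_stack`.
#' @param beta coefficient vector in [design_colnames()] order.
#' @param start_cell length-2 `(row, col)`, 0-based, at least 2 cells from
#'   every edge.
#' @param duration_hours window length in hours.
#' @param roles a `ctmc_roles`.
#' @param start_clock clock time (hours in `[0, 24)`) at the window start.
#' @param time_varying optional `function(clock)` returning the full
#'   coefficient vector; overrides `beta`.
#' @param seed integer seed.
#' @param individual_id label carried through to observations.
#' @return an object of class `event_path`: list with `individual_id`,
#'   `event_times` (cell entry times, hours, starting at 0), `cells`
#'   (n x 2 matrix of 0-based row, col), `start_clock`, `duration`
#'   (realized end time), `truncated` flag, and the generating `roles`.
#' @export
simulate_ctmc_path <- function(rasters, beta, start_cell, duration_hours,
                               roles, start_clock = 0, time_varying = NULL,
                               seed = NULL, individual_id = "ind1") {
  arr <- design_arrays(rasters, roles)
  g <- arr$geom
  r0 <- as.integer(start_cell[1]); c0 <- as.integer(start_cell[2])
  if (r0 < 2L || c0 < 2L || r0 > g$nrow - 3L || c0 > g$ncol - 3L)
    stop_invalid("start_cell must be at least 2 cells from every raster edge")
  if (duration_hours <= 0) stop_invalid("duration_hours must be positive")
  bfun <- if (is.function(time_varying)) time_varying else NULL
  P <- 1L + length(arr$mot) + length(arr$gx) + as.integer(roles$persistence)
  if (is.null(bfun) && length(beta) != P)
    stop_invalid("beta has length ", length(beta), ", design width is ", P)
  with_seed(seed, {
    ## generous preallocation; grows if needed
    cap <- max(1024L, ceiling(duration_hours * 16))
    times <- numeric(cap); rows <- integer(cap); cols <- integer(cap)
    times[1L] <- 0; rows[1L] <- r0; cols[1L] <- c0
    n <- 1L; t <- 0; prev_u <- c(0, 0); truncated <- FALSE
    repeat {
      b <- if (is.null(bfun)) beta else bfun(clock24(start_clock + t))
      X <- design_rows_at(arr, rows[n], cols[n], prev_u)
      rates <- exp(as.numeric(X %*% b))
      lambda <- sum(rates)
      dt <- rexp(1L, rate = lambda)
      if (t + dt >= duration_hours) {
        t <- duration_hours
        break
      }
      t <- t + dt
      k <- sample.int(4L, 1L, prob = rates)
      nr <- rows[n] + NEIGHBOR_DROW[k]
      nc <- cols[n] + NEIGHBOR_DCOL[k]
      if (nr < 2L || nc < 2L || nr > g$nrow - 3L || nc > g$ncol - 3L) {
        truncated <- TRUE
        break
      }
      n <- n + 1L
      if (n > cap) {
        cap <- cap * 2L
        length(times) <- cap; length(rows) <- cap; length(cols) <- cap
      }
      times[n] <- t; rows[n] <- nr; cols[n] <- nc
      prev_u <- c(NEIGHBOR_UX[k], NEIGHBOR_UY[k])
    }
    structure(list(individual_id = individual_id,
                   event_times = times[seq_len(n)],
                   cells = cbind(row = rows[seq_len(n)], col = cols[seq_len(n)]),
                   start_clock = clock24(start_clock),
                   duration = t, truncated = truncated, roles = roles),
              class = "event_path")
  })
}

#' @export
print.event_path <- function(x, ...) {
  cat(sprintf("<event_path '%s': %d cell entries over %.2f h%s>\n",
              x$individual_id, length(x$event_times), x$duration,
              if (x$truncated) " (truncated at edge buffer)" else ""))
  invisible(x)
}

#' Observe a simulated path with a GPS fix schedule
#'
#' True position at each fix time is the center of the occupied cell (the
#' CTMC state is the cell); independent Gaussian noise with sd `sigma_obs`
#' (m) is added to each coordinate. Fix times beyond the realized path
#' duration are dropped.
#'
#' @param path an `event_path`.
#' @param geom a `covariate_raster` or geometry list (for cell centers).
#' @param fix_interval_hours fix spacing (default 3 h).
#' @param sigma_obs measurement-error sd in meters (>= 0).
#' @param seed integer seed.
#' @param window_id window label.
#' @return a `telemetry_track`: data.frame `individual_id`, `time_h`, `x_m`,
#'   `y_m`, `window_id`, `segment_id`, with `attr(, "start_clock")`.
#' @export
observe_gps <- function(path, geom, fix_interval_hours = 3, sigma_obs = 0,
                        seed = NULL, window_id = "w1") {
  stopifnot(inherits(path, "event_path"))
  if (fix_interval_hours <= 0) stop_invalid("fix_interval must be positive")
  if (sigma_obs < 0) stop_invalid("sigma_obs must be >= 0")
  ft <- seq(0, path$duration, by = fix_interval_hours)
  occ <- findInterval(ft, path$event_times)
  ctr <- cell_center(geom, path$cells[occ, 1L], path$cells[occ, 2L])
  with_seed(seed, {
    x <- ctr$x + rnorm(length(ft), sd = sigma_obs)
    y <- ctr$y + rnorm(length(ft), sd = sigma_obs)
    tr <- data.frame(individual_id = path$individual_id, time_h = ft,
                     x_m = x, y_m = y, window_id = window_id,
                     segment_id = "s1")
    attr(tr, "start_clock") <- path$start_clock
    class(tr) <- c("telemetry_track", "data.frame")
    tr
  })
}

#' Synthetic track with planted nocturnal revisit clusters
#'
#' Fixture generator for the kill-site detector: emits a track containing
#' `n_clusters` planted groups of >= 2 nocturnal fixes within `radius_m` and
#' within a 6-day span, plus background fixes that by construction cannot
#' satisfy the clustering rule (diurnal fixes, and isolated nocturnal fixes
#' spaced at least `3 * radius_m` from every other nocturnal fix). Planted
#' cluster centers are returned as ground truth in
#' `attr(, "cluster_centers")`.
#'
#' @param n_background number of background fixes.
#' @param n_clusters number of planted clusters.
#' @param radius_m within-cluster radius (> 0); planted fixes fall within
#'   `radius_m / 2` of their center.
#' @param night_window a [night_window()] defining nocturnal hours.
#' @param seed integer seed.
#' @param individual_id,window_id labels.
#' @return a `telemetry_track` with attribute `cluster_centers`.
#' @export
generate_revisit_track <- function(n_background, n_clusters, radius_m,
                                   night_window = NULL,
                                   seed = NULL, individual_id = "ind1",
                                   window_id = "w1") {
  if (radius_m <= 0) stop_invalid("radius_m must be positive")
  if (n_clusters < 0 || n_background < 0) stop_invalid("counts must be >= 0")
  if (is.null(night_window)) night_window <- hctmc_night_default()
  sep <- 3 * radius_m
  with_seed(seed, {
    mid_night <- clock24(night_window$night_start +
                         clock24(night_window$night_end - night_window$night_start) / 2)
    mid_day <- clock24(mid_night + 12)
    rowsl <- list()
    centers <- NULL
    if (n_clusters > 0) {
      ## cluster centers on a line, far apart and far from background
      cx <- sep * 4 * seq_len(n_clusters)
      cy <- rep(0, n_clusters)
      centers <- data.frame(x = cx, y = cy)
      for (i in seq_len(n_clusters)) {
        nfix <- 2L + (i %% 2L)   # alternate 2- and 3-fix clusters
        ang <- runif(nfix, 0, 2 * pi)
        rad <- runif(nfix, 0, radius_m / 2)
        ## whole-day offsets keep every fix at the (nocturnal) window middle;
        ## a few minutes of per-cluster shift avoids duplicate timestamps
        tt <- (i - 1 + seq_len(nfix) - 1) * 24 + mid_night + (i - 1) * 0.05
        rowsl[[length(rowsl) + 1L]] <- data.frame(
          time_h = tt, x_m = cx[i] + rad * cos(ang), y_m = cy[i] + rad * sin(ang),
          planted = i)
      }
    }
    if (n_background > 0) {
      n_noct <- floor(n_background / 2)
      n_diur <- n_background - n_noct
      if (n_diur > 0) {
        ## diurnal fixes can sit anywhere: never nocturnal, never clustered
        rowsl[[length(rowsl) + 1L]] <- data.frame(
          time_h = seq_len(n_diur) * 24 + mid_day,
          x_m = runif(n_diur, -sep * 10, -sep * 2),
          y_m = runif(n_diur, -sep * 5, sep * 5),
          planted = 0)
      }
      if (n_noct > 0) {
        ## isolated nocturnal fixes on a sparse grid south of everything
        gx <- ((seq_len(n_noct) - 1L) %% 25L) * sep
        gy <- -sep * 3 - (((seq_len(n_noct) - 1L) %/% 25L) * sep)
        rowsl[[length(rowsl) + 1L]] <- data.frame(
          time_h = seq_len(n_noct) * 24 + mid_night + 0.5,
          x_m = gx + runif(n_noct, -radius_m / 4, radius_m / 4),
          y_m = gy + runif(n_noct, -radius_m / 4, radius_m / 4),
          planted = 0)
      }
    }
    if (!length(rowsl))
      stop_invalid("nothing to generate: zero clusters and zero background")
    tr <- do.call(rbind, rowsl)
    tr <- tr[order(tr$time_h), ]
    out <- data.frame(individual_id = individual_id, time_h = tr$time_h,
                      x_m = tr$x_m, y_m = tr$y_m, window_id = window_id,
                      segment_id = "s1")
    attr(out, "start_clock") <- 0
    attr(out, "cluster_centers") <- centers
    attr(out, "planted") <- tr$planted
    class(out) <- c("telemetry_track", "data.frame")
    out
  })
}
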