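#' Nocturnal interval on the 24 h clock
#'
#' A fixed configured night window standing in for the average sunset-sunrise
#' interval of a two-week observation window. The interval may wrap midnight.
#'
#' @param night_start,night_end clock hours (e.g. 19.5 and 6.5).
#' @return an object of class `night_window`.
#' @export
night_window <- function(night_start, night_end) {
  ns <- clock24(night_start); ne <- clock24(night_end)
  if (ns == ne) stop_invalid("night window must be non-empty and not full-day")
  structure(list(night_start = ns, night_end = ne), class = "night_window")
}

hctmc_night_default <- function() night_window(19.5, 6.5)

#' Is a clock time nocturnal?
#'
#' @param clock hours (any real; reduced mod 24).
#' @param night a `night_window`.
#' @return logical vector. Membership is half-open: `[night_start, night_end)`
#'   with wrap-around handled.
#' @export
is_nocturnal <- function(clock, night) {
  t <- clock24(clock)
  if (night$night_start < night$night_end)
    t >= night$night_start & t < night$night_end
  else
    t >= night$night_start | t < night$night_end
}

#' Classify potential kill sites from a telemetry track
#'
#' A location is a potential kill site when two or more nocturnal GPS fixes
#' fall within `radius_m` of it within a `span_days` period. Candidates are
#' nocturnal fixes with at least `min_fixes - 1` other nocturnal fixes within
#' `radius_m` and within `span_days`; candidates are merged greedily in time
#' order (a candidate within `radius_m` of an already-accepted site joins
#' that site instead of founding a new one), and each site's location is the
#' centroid of its supporting fixes. Deterministic given the track.
#'
#' @param track a `telemetry_track` (sorted by time; it will be re-sorted).
#'   Clock time of a fix is `start_clock + time_h` mod 24, with
#'   `start_clock` taken from `attr(track, "start_clock")` (0 if absent).
#' @param night a `night_window` (default 19:30-06:30).
#' @param radius_m site radius in meters (default 200).
#' @param span_days maximum span between a founding fix and its supports
#'   (default 6).
#' @param min_fixes minimum fixes per site (default 2).
#' @return an object of class `kill_site_set`: list with `individual_id`,
#'   `window_id`, `sites` (data.frame `x`, `y`), and `supporting_fixes`
#'   (list of row indices into the time-sorted track).
#' @export
classify_kill_sites <- function(track, night = hctmc_night_default(),
                                radius_m = 200, span_days = 6, min_fixes = 2) {
  if (radius_m <= 0 || span_days <= 0 || min_fixes < 2)
    stop_invalid("radius_m and span_days must be positive, min_fixes >= 2")
  empty <- structure(list(individual_id = if (nrow(track)) track$individual_id[1] else NA,
                          window_id = if (nrow(track)) track$window_id[1] else NA,
                          sites = data.frame(x = numeric(), y = numeric()),
                          supporting_fixes = list()),
                     class = "kill_site_set")
  if (!nrow(track)) return(empty)
  track <- track[order(track$time_h), , drop = FALSE]
  sc <- attr(track, "start_clock"); if (is.null(sc)) sc <- 0
  noct <- which(is_nocturnal(sc + track$time_h, night))
  if (length(noct) < min_fixes) return(empty)
  nx <- track$x_m[noct]; ny <- track$y_m[noct]; nt <- track$time_h[noct]
  span_h <- span_days * 24
  site_x <- numeric(); site_y <- numeric(); members <- list()
  for (i in seq_along(noct)) {
    d2 <- (nx - nx[i])^2 + (ny - ny[i])^2
    near <- d2 <= radius_m^2 & abs(nt - nt[i]) <= span_h
    if (sum(near) < min_fixes) next       # includes the fix itself
    if (length(site_x)) {
      ds <- (site_x - nx[i])^2 + (site_y - ny[i])^2
      k <- which(ds <= radius_m^2)
      if (length(k)) {                    # absorb into the earliest such site
        k <- k[1L]
        if (!(noct[i] %in% members[[k]])) {
          members[[k]] <- c(members[[k]], noct[i])
          sup <- members[[k]]
          site_x[k] <- mean(track$x_m[sup]); site_y[k] <- mean(track$y_m[sup])
        }
        next
      }
    }
    sup <- noct[near]
    site_x <- c(site_x, mean(track$x_m[sup]))
    site_y <- c(site_y, mean(track$y_m[sup]))
    members[[length(members) + 1L]] <- sup
  }
  structure(list(individual_id = track$individual_id[1],
                 window_id = track$window_id[1],
                 sites = data.frame(x = site_x, y = site_y),
                 supporting_fixes = members),
            class = "kill_site_set")
}

#' @export
print.kill_site_set <- function(x, ...) {
  cat(sprintf("<kill_site_set '%s': %d potential kill site(s)>\n",
              x$individual_id, nrow(x$sites)))
  invisible(x)
}

#' Distance-to-nearest-kill-site covariate layer
#'
#' @param sites a `kill_site_set`.
#' @param geom a `covariate_raster` or geometry list.
#' @param name layer name (default `"killsite_dist"`).
#' @return a `covariate_raster` of Euclidean distances (m) from each cell
#'   center to the nearest site. With an empty site set, an all-`NA` layer
#'   flagged with `attr(, "empty") = TRUE` is returned so downstream code can
#'   drop the covariate.
#' @export
distance_to_killsites <- function(sites, geom, name = "killsite_dist") {
  g <- if (inherits(geom, "covariate_raster")) raster_geometry(geom) else geom
  if (!nrow(sites$sites)) {
    r <- covariate_raster(matrix(0, g$nrow, g$ncol), name = name,
                          cell_size = g$cell_size, origin = g$origin)
    r$values[] <- NA_real_
    attr(r, "empty") <- TRUE
    return(r)
  }
  r <- distance_layer(sites$sites, g, name = name)
  attr(r, "empty") <- FALSE
  r
}

#' Write a kill-site set as JSON
#' @param sites a `kill_site_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_kill_sites <- function(sites, path) {
  jsonlite::write_json(list(individual_id = sites$individual_id,
                            window_id = sites$window_id,
                            sites = sites$sites,
                            supporting_fixes = sites$supporting_fixes),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
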