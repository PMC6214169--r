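#' Generate smooth synthetic landscape layers
#'
#' Builds `n_layers` Gaussian-random-field-like surfaces by convolving seeded
#' white noise with a separable isotropic Gaussian kernel (length scale
#' `smoothness`, in cells; reflection padding at the edges), then standardizes
#' each layer to sample mean 0 and sd 1 over cells. Optionally adds one
#' "distance to attractor" layer: the Euclidean distance (m) from each cell
#' center to the nearest of `n_attractors` seeded planted points (emulating
#' structures or kill sites); the distance layer is not standardized.
#'
#' @param n_layers number of smooth layers.
#' @param dims length-2 integer, rows x cols (each >= 20).
#' @param smoothness Gaussian kernel length scale in cells (>= 1).
#' @param seed integer seed; the output is reproducible given the seed.
#' @param cell_size cell edge (m), default 100.
#' @param origin lower-left corner (m).
#' @param n_attractors if > 0, append a `dist_attractor` layer computed from
#'   this many planted points at seeded cell centers.
#' @param names layer names (default `cov1`, `cov2`, ...).
#' @return a `raster_stack`. If attractors were planted their coordinates are
#'   attached as `attr(, "attractors")`.
#' @export
make_landscape <- function(n_layers, dims, smoothness, seed = NULL,
                           cell_size = 100, origin = c(0, 0),
                           n_attractors = 0,
                           names = paste0("cov", seq_len(n_layers))) {
  dims <- as.integer(dims)
  if (length(dims) != 2L || any(dims < 20L))
    stop_invalid("dims must be two integers, each >= 20")
  if (!is.numeric(smoothness) || smoothness < 1)
    stop_invalid("smoothness must be >= 1")
  if (n_layers < 1L && n_attractors <= 0)
    stop_invalid("need at least one layer")
  with_seed(seed, {
    layers <- vector("list", n_layers)
    for (i in seq_len(n_layers)) {
      z <- matrix(rnorm(dims[1] * dims[2]), dims[1], dims[2])
      s <- gaussian_smooth(z, smoothness)
      s <- (s - mean(s)) / sd(s)
      layers[[i]] <- covariate_raster(s, name = names[i],
                                      cell_size = cell_size, origin = origin)
    }
    attractors <- NULL
    if (n_attractors > 0) {
      arow <- sample.int(dims[1], n_attractors, replace = FALSE) - 1L
      acol <- sample.int(dims[2], n_attractors, replace = FALSE) - 1L
      ctr <- cell_center(list(nrow = dims[1], ncol = dims[2],
                              cell_size = cell_size, origin = origin),
                         arow, acol)
      attractors <- data.frame(x = ctr$x, y = ctr$y)
      layers[[n_layers + 1L]] <- distance_layer(
        attractors, list(nrow = dims[1], ncol = dims[2],
                         cell_size = cell_size, origin = origin),
        name = "dist_attractor")
    }
    st <- raster_stack(layers)
    attr(st, "attractors") <- attractors
    st
  })
}

## Separable Gaussian blur with reflection padding; sigma in cells.
gaussian_smooth <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad_reflect <- function(v, h) c(rev(v[seq_len(h)]), v, rev(v)[seq_len(h)])
  conv1 <- function(v) {
    p <- pad_reflect(v, half)
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) out[i] <- sum(p[i:(i + 2L * half)] * k)
    out
  }
  m <- apply(m, 2L, conv1)            # smooth down columns
  t(apply(m, 1L, conv1))              # then along rows
}

#' Distance-to-points covariate layer
#'
#' Value at each cell is the Euclidean distance (m) from the cell center to
#' the nearest of the supplied points.
#'
#' @param points data.frame with `x`, `y` in meters (>= 1 row).
#' @param geom a `covariate_raster` or geometry list.
#' @param name layer name.
#' @return a `covariate_raster`.
#' @export
distance_layer <- function(points, geom, name = "dist") {
  g <- if (inherits(geom, "covariate_raster")) raster_geometry(geom) else geom
  if (!nrow(points)) stop_invalid("distance_layer needs at least one point")
  cx <- g$origin[1] + (seq_len(g$ncol) - 0.5) * g$cell_size
  cy <- g$origin[2] + (seq_len(g$nrow) - 0.5) * g$cell_size
  d2 <- matrix(Inf, g$nrow, g$ncol)
  for (i in seq_len(nrow(points))) {
    dd <- outer((cy - points$y[i])^2, (cx - points$x[i])^2, `+`)
    d2 <- pmin(d2, dd)
  }
  covariate_raster(sqrt(d2), name = name, cell_size = g$cell_size,
                   origin = g$origin)
}

#' Draw individual coefficient vectors from a population distribution
#'
#' Coefficients for `J` individuals are drawn independently from a normal
#' distribution with mean `mu` and per-coordinate standard deviation `sd`
#' (zero sd is allowed in the simulator and gives every individual exactly
#' `mu`).
#'
#' @param mu numeric population mean vector (length P, or P*Q for
#'   time-varying truth expressed in a basis).
#' @param sd non-negative sd vector, same length as `mu`.
#' @param J number of individuals (>= 1).
#' @param seed integer seed.
#' @return an object of class `population_truth`: list with `mu`, `sd`, `J`,
#'   `betas` (J x P matrix) and `seed`.
#' @export
draw_population <- function(mu, sd, J, seed = NULL) {
  if (length(mu) != length(sd))
    stop_invalid("mu and sd must have the same length")
  if (any(sd < 0)) stop_invalid("sd must be non-negative")
  if (J < 1) stop_invalid("J must be >= 1")
  betas <- with_seed(seed, {
    matrix(rnorm(J * length(mu), mean = rep(mu, each = J),
                 sd = rep(sd, each = J)), nrow = J)
  })
  colnames(betas) <- names(mu)
  structure(list(mu = mu, sd = sd, J = as.integer(J), betas = betas,
                 seed = seed),
            class = "population_truth")
}

#' @export
print.population_truth <- function(x, ...) {
  cat(sprintf("<population_truth: J = %d individuals, P = %d coefficients>\n",
              x$J, length(x$mu)))
  invisible(x)
}

#' Write / read population ground truth as JSON
#' @param truth a `population_truth`.
#' @param path file path.
#' @return `path` (write) or a `population_truth` (read).
#' @export
write_population <- function(truth, path) {
  jsonlite::write_json(list(mu = truth$mu, sd = truth$sd, J = truth$J,
                            betas = truth$betas, seed = truth$seed),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mu = x$mu, sd = x$sd, J = as.integer(x$J),
                 betas = matrix(unlist(x$betas), nrow = x$J),
                 seed = x$seed),
            class = "population_truth")
}
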