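#' Covariate roles for the CTMC design
#'
#' Declares how each landscape layer enters the movement model. Motility
#' drivers are the current cell's values and scale all four exit rates
#' equally (speed, not direction); directional drivers are the negated
#' projection of the layer's gradient onto each candidate cell displacement
#' (gradient times cell width, i.e. the covariate change incurred by that
#' cell crossing, keeping directional and motility coefficients on
#' commensurate covariate-unit scales), so a
#' positive coefficient biases movement toward decreasing covariate values
#' (e.g. toward a feature for a distance layer); the persistence term is the
#' dot product of the previous and candidate movement directions.
#'
#' @param motility character vector of layer names used as motility drivers.
#' @param directional character vector of layer names used as directional
#'   drivers (a layer may appear in both).
#' @param persistence logical, include the directional-persistence column.
#' @return an object of class `ctmc_roles`.
#' @export
ctmc_roles <- function(motility = character(), directional = character(),
                       persistence = TRUE) {
  structure(list(motility = as.character(motility),
                 directional = as.character(directional),
                 persistence = isTRUE(persistence)),
            class = "ctmc_roles")
}

#' Design column names implied by a role declaration
#'
#' Order is fixed: intercept, motility columns, directional columns,
#' persistence.
#' @param roles a `ctmc_roles`.
#' @return character vector of column names.
#' @export
design_colnames <- function(roles) {
  c("(Intercept)",
    if (length(roles$motility)) paste0("mot_", roles$motility),
    if (length(roles$directional)) paste0("dir_", roles$directional),
    if (roles$persistence) "persist")
}

## Precompute per-cell design ingredients for fast repeated rate evaluation.
## Returns matrices indexed [row+1, col+1] (0-based cells).
design_arrays <- function(rasters, roles) {
  stopifnot(inherits(rasters, "raster_stack"), inherits(roles, "ctmc_roles"))
  missing <- setdiff(union(roles$motility, roles$directional), names(rasters))
  if (length(missing))
    stop_invalid("layers not in stack: ", paste(missing, collapse = ", "))
  mot <- lapply(roles$motility, function(nm) rasters[[nm]]$values)
  grads <- lapply(roles$directional, function(nm) gradient_layers(rasters[[nm]]))
  dir_only <- setdiff(roles$directional, roles$motility)
  raw <- lapply(dir_only, function(nm) rasters[[nm]]$values)
  names(raw) <- dir_only
  list(mot = mot,
       gx = lapply(grads, function(g) g$dx$values),
       gy = lapply(grads, function(g) g$dy$values),
       raw = raw,
       geom = raster_geometry(rasters[[1L]]),
       roles = roles)
}

## Design vectors for the four neighbor slots of one interior cell.
## prev_u is the previous movement direction as c(ux, uy) (c(0, 0) for the
## first transition of a segment). Returns a 4 x P matrix (rows E, W, N, S).
design_rows_at <- function(arr, row, col, prev_u = c(0, 0)) {
  r1 <- row + 1L; c1 <- col + 1L
  g <- arr$geom
  if (row < 1L || col < 1L || row > g$nrow - 2L || col > g$ncol - 2L)
    stop_invalid(sprintf("cell (%d, %d) is on the raster edge", row, col))
  p_mot <- length(arr$mot); p_dir <- length(arr$gx)
  P <- 1L + p_mot + p_dir + as.integer(arr$roles$persistence)
  X <- matrix(0, 4L, P)
  X[, 1L] <- 1
  j <- 1L
  for (m in arr$mot) {
    j <- j + 1L
    X[, j] <- m[r1, c1]
  }
  for (k in seq_len(p_dir)) {
    j <- j + 1L
    gx <- arr$gx[[k]][r1, c1]; gy <- arr$gy[[k]][r1, c1]
    ## covariate change per cell crossing: gradient times the cell width
    X[, j] <- -(gx * NEIGHBOR_UX + gy * NEIGHBOR_UY) * g$cell_size
  }
  if (arr$roles$persistence) {
    j <- j + 1L
    X[, j] <- prev_u[1] * NEIGHBOR_UX + prev_u[2] * NEIGHBOR_UY
  }
  rownames(X) <- NEIGHBOR_SLOTS
  colnames(X) <- design_colnames(arr$roles)
  X
}

#' Movement rates toward the four rook neighbors of a cell
#'
#' Computes `rate_k = exp(x_k' beta)` for neighbor slots E, W, N, S, where
#' `x_k` stacks an intercept, the current cell's motility values, the
#' negated gradient projections for directional layers, and the persistence
#' term. With a time-varying coefficient function, `beta` is evaluated at
#' `clock`.
#'
#' @param cell length-2 integer `(row, col)`, 0-based, interior.
#' @param clock clock time (hours) at which time-varying coefficients are
#'   evaluated.
#' @param beta numeric coefficient vector in [design_colnames()] order, or a
#'   function `function(clock)` returning such a vector.
#' @param rasters a `raster_stack`.
#' @param roles a `ctmc_roles`.
#' @param prev_u previous movement direction `c(ux, uy)` (default none).
#' @return named numeric vector of four positive rates.
#' @export
build_rates <- function(cell, clock, beta, rasters, roles, prev_u = c(0, 0)) {
  arr <- design_arrays(rasters, roles)
  b <- if (is.function(beta)) beta(clock24(clock)) else beta
  X <- design_rows_at(arr, cell[1], cell[2], prev_u)
  if (length(b) != ncol(X))
    stop_invalid("beta has length ", length(b), ", design width is ", ncol(X))
  r <- exp(as.numeric(X %*% b))
  names(r) <- NEIGHBOR_SLOTS
  r
}

#' Latent-variable Poisson design table from a cell sequence
#'
#' Re-expresses a contiguous cell-transition sequence as the latent Poisson
#' design: each completed transition contributes four rows (neighbor slots
#' E, W, N, S) with indicator response `z` (1 for the cell entered), the
#' residence time `tau` of the departed cell as offset, the design vector
#' `x` of that cell, and the clock time of the transition (entry time of the
#' departed cell — the moment its rates took effect, matching the
#' simulator's piecewise-constant convention). The final, right-censored
#' residence of each segment
#' contributes no rows. Persistence is 0 on the first transition of a
#' segment.
#'
#' @param seq a cell sequence as returned by [discretize_path()]: data.frame
#'   with `individual_id`, `draw_index`, `segment_id`, `row`, `col`,
#'   `tau_hours`, `entry_clock_hours`.
#' @param rasters a `raster_stack` of covariates.
#' @param roles a `ctmc_roles`.
#' @return a `latent_table`: data.frame with identifier columns, `slot`,
#'   `z`, `tau`, `clock`, `cell_row`, `cell_col`, the design columns, and
#'   (for directional-only layers) raw-value columns `.val_<layer>` used by
#'   [center_scale()]. The design column names are in
#'   `attr(, "design_cols")`.
#' @export
build_latent_table <- function(seq, rasters, roles) {
  arr <- design_arrays(rasters, roles)
  segs <- split(seq, list(seq$individual_id, seq$draw_index, seq$segment_id),
                drop = TRUE)
  out <- lapply(segs, function(s) latent_table_segment(s, arr))
  out <- out[vapply(out, nrow, 0L) > 0L]
  tab <- if (length(out)) do.call(rbind, out) else empty_latent_table(arr)
  rownames(tab) <- NULL
  dir_only <- setdiff(arr$roles$directional, arr$roles$motility)
  structure(tab,
            design_cols = design_colnames(roles),
            raw_cols = if (length(dir_only)) paste0(".val_", dir_only) else character(),
            roles = roles,
            class = c("latent_table", "data.frame"))
}

empty_latent_table <- function(arr) {
  cols <- design_colnames(arr$roles)
  tab <- data.frame(individual_id = character(), draw_index = integer(),
                    segment_id = character(), trans = integer(),
                    slot = character(), z = numeric(), tau = numeric(),
                    clock = numeric(), cell_row = integer(),
                    cell_col = integer())
  for (cl in cols) tab[[cl]] <- numeric()
  dir_only <- setdiff(arr$roles$directional, arr$roles$motility)
  for (nm in dir_only) tab[[paste0(".val_", nm)]] <- numeric()
  tab
}

latent_table_segment <- function(s, arr) {
  n <- nrow(s)
  if (n < 2L) return(empty_latent_table(arr))
  g <- arr$geom
  from_r <- s$row[-n]; from_c <- s$col[-n]
  to_r <- s$row[-1L]; to_c <- s$col[-1L]
  if (any(from_r < 1L | from_c < 1L | from_r > g$nrow - 2L | from_c > g$ncol - 2L))
    stop_invalid("cell sequence touches the raster edge; design undefined there")
  drow <- to_r - from_r; dcol <- to_c - from_c
  if (any(abs(drow) + abs(dcol) != 1L))
    stop_invalid("cell sequence is not rook-contiguous")
  slot <- ifelse(dcol == 1L, "E", ifelse(dcol == -1L, "W",
                 ifelse(drow == 1L, "N", "S")))
  nt <- n - 1L
  ## previous direction for transition i is the direction of transition i-1
  pux <- c(0, NEIGHBOR_UX[slot[-nt]])
  puy <- c(0, NEIGHBOR_UY[slot[-nt]])
  idx <- from_r + 1L + g$nrow * from_c   # linear index into value matrices
  p_mot <- length(arr$mot); p_dir <- length(arr$gx)
  P <- 1L + p_mot + p_dir + as.integer(arr$roles$persistence)
  ## 4 rows per transition, slot-major within transition (E, W, N, S)
  X <- matrix(0, 4L * nt, P)
  X[, 1L] <- 1
  ux <- rep(NEIGHBOR_UX, nt); uy <- rep(NEIGHBOR_UY, nt)
  j <- 1L
  for (m in arr$mot) {
    j <- j + 1L
    X[, j] <- rep(m[idx], each = 4L)
  }
  for (k in seq_len(p_dir)) {
    j <- j + 1L
    X[, j] <- -(rep(arr$gx[[k]][idx], each = 4L) * ux +
                rep(arr$gy[[k]][idx], each = 4L) * uy) * g$cell_size
  }
  if (arr$roles$persistence) {
    j <- j + 1L
    X[, j] <- rep(pux, each = 4L) * ux + rep(puy, each = 4L) * uy
  }
  colnames(X) <- design_colnames(arr$roles)
  tab <- data.frame(individual_id = rep(s$individual_id[1L], 4L * nt),
                    draw_index = rep(s$draw_index[1L], 4L * nt),
                    segment_id = rep(s$segment_id[1L], 4L * nt),
                    trans = rep(seq_len(nt), each = 4L),
                    slot = rep(NEIGHBOR_SLOTS, nt),
                    z = as.numeric(rep(slot, each = 4L) ==
                                   rep(NEIGHBOR_SLOTS, nt)),
                    tau = rep(s$tau_hours[-n], each = 4L),
                    ## clock at which the rates governing transition i apply:
                    ## the entry time of the departed cell, matching the
                    ## piecewise-constant simulator exactly
                    clock = rep(s$entry_clock_hours[-n], each = 4L),
                    cell_row = rep(from_r, each = 4L),
                    cell_col = rep(from_c, each = 4L))
  tab <- cbind(tab, as.data.frame(X, check.names = FALSE))
  ## raw current-cell values of directional-only layers, kept (hidden) so
  ## center_scale can compute the individual's encountered mean/sd
  for (nm in names(arr$raw))
    tab[[paste0(".val_", nm)]] <- rep(arr$raw[[nm]][idx], each = 4L)
  tab
}

#' Per-individual centering and scaling of the latent design
#'
#' For each individual, every motility column is centered and scaled by the
#' mean and standard deviation of the covariate values that individual
#' encountered over all transitions in its fit-set tables (one value per
#' transition, pooled unweighted across fit imputations). Directional
#' columns for the same layer are divided by the same sd (the gradient of an
#' affinely rescaled layer). Intercept and persistence are untouched. A
#' layer with fewer than 2 distinct values for an individual is "dropped"
#' for that individual: its scaled columns are set to zero (with a warning)
#' so design widths stay equal across individuals.
#'
#' @param table a `latent_table` (fit-set rows, possibly many individuals and
#'   imputations).
#' @return list with `table` (scaled `latent_table`) and `report` (data.frame
#'   `individual_id`, `layer`, `mean`, `sd`, `dropped`) reusable on score-set
#'   tables via [apply_scaling()].
#' @export
center_scale <- function(table) {
  roles <- attr(table, "roles")
  layers <- union(roles$motility, roles$directional)
  report <- expand.grid(individual_id = unique(table$individual_id),
                        layer = layers, stringsAsFactors = FALSE)
  report$mean <- NA_real_; report$sd <- NA_real_; report$dropped <- FALSE
  for (i in seq_len(nrow(report))) {
    id <- report$individual_id[i]; nm <- report$layer[i]
    rows <- table$individual_id == id & table$slot == "E"
    mot_col <- paste0("mot_", nm)
    vals <- if (mot_col %in% names(table)) table[[mot_col]][rows]
            else raw_layer_values(table, nm)[rows]
    m <- mean(vals); s <- sd(vals)
    if (!is.finite(s) || s == 0 || length(unique(vals)) < 2L) {
      report$dropped[i] <- TRUE
      report$mean[i] <- m; report$sd[i] <- NA_real_
    } else {
      report$mean[i] <- m; report$sd[i] <- s
    }
  }
  list(table = apply_scaling(table, report), report = report)
}

## Current-cell values of a directional-only layer, reconstructed from the
## stored raw-value column.
raw_layer_values <- function(table, nm) {
  col <- paste0(".val_", nm)
  if (!col %in% names(table))
    stop_invalid("no values available to scale layer ", nm)
  table[[col]]
}

#' Apply a previously computed scaling report to a latent table
#'
#' Used to scale score-set tables with fit-set constants (no re-estimation).
#'
#' @param table a `latent_table`.
#' @param report the `report` from [center_scale()].
#' @return the scaled `latent_table`.
#' @export
apply_scaling <- function(table, report) {
  roles <- attr(table, "roles")
  for (i in seq_len(nrow(report))) {
    id <- report$individual_id[i]; nm <- report$layer[i]
    rows <- table$individual_id == id
    if (!any(rows)) next
    mot_col <- paste0("mot_", nm); dir_col <- paste0("dir_", nm)
    if (report$dropped[i]) {
      if (mot_col %in% names(table)) table[[mot_col]][rows] <- 0
      if (dir_col %in% names(table)) table[[dir_col]][rows] <- 0
      warning(sprintf("layer '%s' has no variation for individual '%s'; columns zeroed",
                      nm, id), call. = FALSE)
      next
    }
    if (mot_col %in% names(table))
      table[[mot_col]][rows] <- (table[[mot_col]][rows] - report$mean[i]) / report$sd[i]
    if (dir_col %in% names(table))
      table[[dir_col]][rows] <- table[[dir_col]][rows] / report$sd[i]
  }
  table
}

#' Cyclic cubic B-spline basis on the 24 h clock
#'
#' `Q` evenly spaced knots on `[0, 24)`; the basis is a partition of unity
#' (weights sum to 1 at every clock time) and is exactly periodic, so
#' `eval(0) == eval(24)`. `Q = 1` is the constant basis, under which the GAM
#' reduces to the GLM.
#'
#' @param Q basis dimension (>= 1; cyclic cubic splines need `Q >= 4`).
#' @param period cycle length in hours (default 24).
#' @return an object of class `cyclic_basis` with fields `Q`, `knots` and
#'   `eval(clock)` returning an `n x Q` weight matrix.
#' @export
cyclic_basis <- function(Q, period = 24) {
  Q <- as.integer(Q)
  if (Q < 1L) stop_invalid("Q must be >= 1")
  if (Q == 1L) {
    ev <- function(clock) matrix(1, length(clock), 1L)
    return(structure(list(Q = 1L, knots = c(0, period), eval = ev),
                     class = "cyclic_basis"))
  }
  if (Q < 4L) stop_invalid("cyclic cubic splines need Q >= 4 (or Q = 1)")
  knots <- seq(0, period, length.out = Q + 1L)
  ev <- function(clock) {
    W <- mgcv::cSplineDes(clock %% period, knots)
    dimnames(W) <- NULL
    W
  }
  structure(list(Q = Q, knots = knots, eval = ev), class = "cyclic_basis")
}

#' @export
print.cyclic_basis <- function(x, ...) {
  cat(sprintf("<cyclic_basis: Q = %d over [0, %g)>\n", x$Q, max(x$knots)))
  invisible(x)
}

#' Kronecker time-expansion of the latent design (GAM)
#'
#' Replaces each design column `x_p` with the `Q` products
#' `x_p * w_q(clock)` (covariate-major, basis-minor column order), giving the
#' varying-coefficient design `v = x (x) w(clock)` evaluated at the clock
#' time of each transition.
#'
#' @param table a `latent_table`.
#' @param basis a `cyclic_basis`.
#' @return the expanded `latent_table`; expanded design column names are
#'   `"<col>|q<k>"` and stored in `attr(, "design_cols")`; the basis rides
#'   along as `attr(, "basis")`.
#' @export
expand_gam <- function(table, basis) {
  stopifnot(inherits(basis, "cyclic_basis"))
  cols <- attr(table, "design_cols")
  W <- basis$eval(table$clock)
  newcols <- character(0)
  out <- table
  for (p in cols) {
    for (q in seq_len(basis$Q)) {
      nm <- paste0(p, "|q", q)
      out[[nm]] <- table[[p]] * W[, q]
      newcols <- c(newcols, nm)
    }
  }
  out <- out[, c(setdiff(names(out), c(cols, newcols)), newcols)]
  attr(out, "design_cols") <- newcols
  attr(out, "roles") <- attr(table, "roles")
  attr(out, "basis") <- basis
  attr(out, "base_cols") <- cols
  class(out) <- c("latent_table", "data.frame")
  out
}

#' Development-interaction columns
#'
#' Adds a developed-indicator motility column (the binary layer's value at
#' the current cell) and product columns `indicator x covariate` for each
#' named covariate's motility and directional forms, enabling contrasts of
#' movement rate and kill-site response between developed and undeveloped
#' areas.
#'
#' @param table a `latent_table` (un-expanded).
#' @param binary_layer a `covariate_raster` with values in `{0, 1}`.
#' @param interact_with character vector of layer names to interact.
#' @return the augmented `latent_table`; new columns are `mot_developed`,
#'   `mot_<layer>:dev` and/or `dir_<layer>:dev`.
#' @export
build_interaction <- function(table, binary_layer, interact_with = character()) {
  stopifnot(inherits(binary_layer, "covariate_raster"))
  v <- binary_layer$values
  if (!all(v %in% c(0, 1)))
    stop_invalid("interaction layer must be binary (0/1)")
  idx <- table$cell_row + 1L + nrow(v) * table$cell_col
  ind <- v[idx]
  cols <- attr(table, "design_cols")
  out <- table
  out[["mot_developed"]] <- ind
  added <- "mot_developed"
  for (nm in interact_with) {
    for (pref in c("mot_", "dir_")) {
      base <- paste0(pref, nm)
      if (base %in% cols) {
        newnm <- paste0(base, ":dev")
        out[[newnm]] <- out[[base]] * ind
        added <- c(added, newnm)
      }
    }
  }
  attr(out, "design_cols") <- c(cols, added)
  attr(out, "roles") <- attr(table, "roles")
  class(out) <- c("latent_table", "data.frame")
  out
}
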