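#' Gridded landscape covariate layer
#'
#' A named raster layer on a planar grid in meters. Values are stored as a
#' matrix with `values[r, c]` the cell in (0-based) row `r - 1`, column
#' `c - 1`; row 0 is the southernmost row (y increases with row index).
#' `origin` is the lower-left corner of the lower-left cell.
#'
#' @param values numeric matrix of cell values (rows x cols), all finite.
#' @param name label for the layer.
#' @param cell_size cell edge length in meters (default 100).
#' @param origin length-2 numeric, `(x0, y0)` in meters.
#' @return an object of class `covariate_raster`.
#' @export
covariate_raster <- function(values, name = "layer", cell_size = 100,
                             origin = c(0, 0)) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values)))
    stop_invalid("raster values must be finite numeric")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop_invalid("cell_size must be a positive scalar")
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop_invalid("origin must be two finite numbers")
  structure(list(values = values, name = as.character(name),
                 cell_size = cell_size, origin = as.numeric(origin)),
            class = "covariate_raster")
}

#' @export
print.covariate_raster <- function(x, ...) {
  cat(sprintf("<covariate_raster '%s': %d x %d cells of %g m, origin (%g, %g)>\n",
              x$name, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' Stack of covariate rasters sharing one geometry
#'
#' @param ... `covariate_raster` objects (or a single list of them).
#' @return a named list of layers with class `raster_stack`.
#' @export
raster_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1L]], "covariate_raster"))
    layers <- layers[[1L]]
  if (!length(layers)) stop_invalid("empty raster stack")
  for (l in layers)
    if (!inherits(l, "covariate_raster"))
      stop_invalid("all stack elements must be covariate_raster")
  g0 <- layers[[1L]]
  for (l in layers) {
    if (!identical(dim(l$values), dim(g0$values)) ||
        l$cell_size != g0$cell_size || !identical(l$origin, g0$origin))
      stop_invalid("all layers in a stack must share dims, cell_size and origin")
  }
  names(layers) <- vapply(layers, `[[`, "", "name")
  structure(layers, class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack of %d layers: %s>\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

raster_geometry <- function(r) {
  list(nrow = nrow(r$values), ncol = ncol(r$values),
       cell_size = r$cell_size, origin = r$origin)
}

#' Cell centers in meters
#'
#' @param geom a `covariate_raster` (or the geometry of one).
#' @param row,col 0-based cell indices (row 0 at the bottom).
#' @return list with numeric `x`, `y` of the cell centers.
#' @export
cell_center <- function(geom, row, col) {
  g <- if (inherits(geom, "covariate_raster")) raster_geometry(geom) else geom
  list(x = g$origin[1] + (col + 0.5) * g$cell_size,
       y = g$origin[2] + (row + 0.5) * g$cell_size)
}

#' Map planar coordinates to raster cells
#'
#' Cells are half-open, `[edge, edge + cell_size)` in both axes; points on
#' the top/right raster edge belong to the last row/column. Points outside
#' the raster raise an error.
#'
#' @param geom a `covariate_raster` or its geometry.
#' @param x,y coordinates in meters.
#' @return data.frame with 0-based `row`, `col`.
#' @export
locate_cell <- function(geom, x, y) {
  g <- if (inherits(geom, "covariate_raster")) raster_geometry(geom) else geom
  col <- floor((x - g$origin[1]) / g$cell_size)
  row <- floor((y - g$origin[2]) / g$cell_size)
  ## exact top/right edge folds into the last cell
  col[x == g$origin[1] + g$ncol * g$cell_size] <- g$ncol - 1L
  row[y == g$origin[2] + g$nrow * g$cell_size] <- g$nrow - 1L
  bad <- which(col < 0 | col >= g$ncol | row < 0 | row >= g$nrow)
  if (length(bad))
    stop_invalid(sprintf("point outside raster: (%g, %g)", x[bad[1]], y[bad[1]]))
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text single-band format (`ncols/nrows/xllcorner/yllcorner/cellsize`
#' header, rows written north to south).
#'
#' @param r a `covariate_raster`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  stopifnot(inherits(r, "covariate_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(r$values)),
               sprintf("nrows %d", nrow(r$values)),
               sprintf("xllcorner %.10g", r$origin[1]),
               sprintf("yllcorner %.10g", r$origin[2]),
               sprintf("cellsize %.10g", r$cell_size),
               "NODATA_value -9999"), con)
  ## ASCII grid rows run north->south; our matrix row 1 is the south row
  for (i in rev(seq_len(nrow(r$values))))
    writeLines(paste(sprintf("%.17g", r$values[i, ]), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#'
#' @param path file path.
#' @param name layer name (default: file stem).
#' @return a `covariate_raster`.
#' @export
read_ascii_grid <- function(path, name = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  vals <- lapply(lines[i:length(lines)],
                 function(s) as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1L]]))
  m <- do.call(rbind, vals)
  if (nrow(m) != hdr$nrows || ncol(m) != hdr$ncols)
    stop_invalid("ASCII grid dims do not match header")
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # back to south-row-first
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  covariate_raster(m, name = name, cell_size = hdr$cellsize,
                   origin = c(hdr$xllcorner, hdr$yllcorner))
}

#' Finite-difference gradient layers of a covariate
#'
#' Central differences over `2 * cell_size` in the interior, one-sided at the
#' edges; units are covariate units per meter. The x-gradient differentiates
#' along columns, the y-gradient along rows (row 0 at the bottom).
#'
#' @param cov a `covariate_raster` with at least 3 x 3 cells.
#' @return list with `covariate_raster`s `dx` and `dy`.
#' @export
gradient_layers <- function(cov) {
  stopifnot(inherits(cov, "covariate_raster"))
  v <- cov$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3L || nc < 3L) stop_invalid("gradient needs at least a 3x3 raster")
  h <- cov$cell_size
  dx <- matrix(0, nr, nc)
  dx[, 2:(nc - 1)] <- (v[, 3:nc] - v[, 1:(nc - 2)]) / (2 * h)
  dx[, 1] <- (v[, 2] - v[, 1]) / h
  dx[, nc] <- (v[, nc] - v[, nc - 1]) / h
  dy <- matrix(0, nr, nc)
  dy[2:(nr - 1), ] <- (v[3:nr, ] - v[1:(nr - 2), ]) / (2 * h)
  dy[1, ] <- (v[2, ] - v[1, ]) / h
  dy[nr, ] <- (v[nr, ] - v[nr - 1, ]) / h
  list(dx = covariate_raster(dx, name = paste0(cov$name, "_dx"),
                             cell_size = h, origin = cov$origin),
       dy = covariate_raster(dy, name = paste0(cov$name, "_dy"),
                             cell_size = h, origin = cov$origin))
}
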