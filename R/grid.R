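# Analysis grid: a regular latitude-longitude lattice of square cells,
# point-in-cell assignment with a half-open convention, sub-cell climate
# averaging and commune-rate pooling.

#' Build the analysis grid
#'
#' Constructs a regular lattice of square cells (default half a degree on
#' each side, roughly 30 km x 30 km at mid-latitudes).  Cell ids are
#' row-major starting at the origin corner; cell centres sit at
#' `origin + (index + 0.5) * cell_size` on each axis.
#'
#' @param origin_lon,origin_lat Lower-left corner of the grid, degrees.
#' @param cell_size Side of each square cell, degrees (> 0).
#' @param n_cols,n_rows Grid extent in cells (>= 1).
#' @param active_cells Optional subset of cell ids considered active.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- build_grid(0, 40, 0.5, n_cols = 2, n_rows = 2)
#' grid_cells(g)
#' @export
build_grid <- function(origin_lon, origin_lat, cell_size = 0.5,
                       n_cols, n_rows, active_cells = NULL) {
  if (!is.finite(cell_size) || cell_size <= 0) stop("`cell_size` must be > 0")
  n_cols <- as.integer(n_cols); n_rows <- as.integer(n_rows)
  if (n_cols < 1L || n_rows < 1L) stop("grid extent must be positive")
  row <- rep(seq_len(n_rows), each = n_cols)
  col <- rep(seq_len(n_cols), times = n_rows)
  cells <- data.frame(
    cell_id = sprintf("r%02dc%02d", row, col),
    row = row, col = col,
    center_lon = origin_lon + (col - 0.5) * cell_size,
    center_lat = origin_lat + (row - 0.5) * cell_size)
  if (!is.null(active_cells) && !all(active_cells %in% cells$cell_id))
    stop("`active_cells` contains ids outside the grid")
  structure(list(origin_lon = origin_lon, origin_lat = origin_lat,
                 cell_size = cell_size, n_cols = n_cols, n_rows = n_rows,
                 cells = cells,
                 active_cells = active_cells %||% cells$cell_id),
            class = "grid_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cell table of a grid
#' @param grid A [build_grid()] object.
#' @return `data.frame` with columns `cell_id`, `row`, `col`,
#'   `center_lon`, `center_lat`.
#' @export
grid_cells <- function(grid) grid$cells

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %.2f deg, origin (%.3f, %.3f)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat))
  invisible(x)
}

#' Assign points to grid cells
#'
#' Cell membership is half-open on both axes: a point belongs to the cell
#' whose extent is `[edge, edge + cell_size)`, so every interior point of
#' the grid maps to exactly one cell and the outer upper/right boundary
#' maps to none.
#'
#' @param lon,lat Coordinates, degrees (vectors allowed).
#' @param grid A [build_grid()] object.
#' @return Character vector of cell ids, `NA` for points outside the grid.
#' @export
assign_point <- function(lon, lat, grid) {
  if (anyNA(lon) || anyNA(lat) || any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("coordinates must be finite")
  col <- floor((lon - grid$origin_lon) / grid$cell_size) + 1
  row <- floor((lat - grid$origin_lat) / grid$cell_size) + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  out <- rep(NA_character_, length(lon))
  out[ok] <- sprintf("r%02dc%02d", row[ok], col[ok])
  out
}

#' Average four sub-cell daily series into one cell series
#'
#' The analysis cell aggregates four quarter-size source cells; its daily
#' value is the arithmetic mean of the four sub-cell values, missing
#' whenever any sub-cell value is missing.
#'
#' @param sub A numeric matrix with 4 columns (one per sub-cell) or a list
#'   of 4 `data.frame`s with columns `date` and `value`, all on identical
#'   dates.
#' @return Numeric vector of cell daily means.
#' @export
aggregate_subcells <- function(sub) {
  if (is.list(sub) && !is.data.frame(sub) && !is.matrix(sub)) {
    if (length(sub) != 4L) stop("exactly 4 sub-cell series required")
    dates <- lapply(sub, function(d) as.Date(d$date))
    if (!all(vapply(dates[-1], identical, logical(1), dates[[1]])))
      stop("sub-cell series have misaligned dates")
    sub <- do.call(cbind, lapply(sub, function(d) d$value))
  }
  sub <- as.matrix(sub)
  if (ncol(sub) != 4L) stop("exactly 4 sub-cell series required")
  rowMeans(sub)  # NA propagates: a day is missing if any sub-cell is
}

#' Pool commune-level rates to the cell level
#'
#' Rates are never averaged directly: the additive numerators and
#' denominators are summed over all communes whose centroid falls in the
#' cell and the pooled ratio is formed per cell.
#'
#' @param communes `data.frame` with columns `commune_id`, `lon`, `lat`,
#'   `numerator`, `denominator` (both non-negative).
#' @param grid A [build_grid()] object.
#' @return `data.frame` with columns `cell_id`, `numerator`,
#'   `denominator`, `rate` (`NA` where the pooled denominator is zero).
#' @export
aggregate_rates <- function(communes, grid) {
  if (any(communes$numerator < 0) || any(communes$denominator < 0))
    stop("numerators and denominators must be non-negative")
  cell <- assign_point(communes$lon, communes$lat, grid)
  keep <- !is.na(cell)
  num <- tapply(communes$numerator[keep], cell[keep], sum)
  den <- tapply(communes$denominator[keep], cell[keep], sum)
  out <- data.frame(cell_id = names(num), numerator = as.numeric(num),
                    denominator = as.numeric(den))
  out$rate <- ifelse(out$denominator > 0, out$numerator / out$denominator, NA_real_)
  rownames(out) <- NULL
  out
}
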