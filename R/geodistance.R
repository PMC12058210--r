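# Water-constrained least-cost distances on the conductance raster,
# Euclidean distances, and the combined (entrywise max) rule.

# cell (row from top, col) containing a point; NA if outside the grid
.cell_of <- function(grid, x, y) {
  col <- floor((x - grid$xll) / grid$cell_size) + 1L
  row_from_bottom <- floor((y - grid$yll) / grid$cell_size) + 1L
  row <- grid$nrows - row_from_bottom + 1L
  bad <- col < 1L | col > grid$ncols | row < 1L | row > grid$nrows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = row, col = col)
}

# center coordinates of cells
.cell_center <- function(grid, row, col) {
  cbind(x = grid$xll + (col - 0.5) * grid$cell_size,
        y = grid$yll + (grid$nrows - row + 0.5) * grid$cell_size)
}

#' Snap points to the nearest water cell
#'
#' Points already on water keep their containing cell; points on land or
#' outside the grid move to the Euclidean-nearest water cell center (ties
#' broken by row-major cell order).
#'
#' @param grid a `water_grid`.
#' @param x,y point coordinates.
#' @return data frame: `row`, `col`, `x`, `y` (snapped cell centers),
#'   `snapped` (logical).
#' @export
snap_to_water <- function(grid, x, y) {
  wat <- which(grid$conductance == 1, arr.ind = TRUE)  # row-major pairs
  if (!nrow(wat)) stop("grid contains no water cells")
  wat <- wat[order(wat[, 1], wat[, 2]), , drop = FALSE]
  ctr <- .cell_center(grid, wat[, 1], wat[, 2])
  cells <- .cell_of(grid, x, y)
  out <- data.frame(row = cells[, 1], col = cells[, 2], x = x, y = y,
                    snapped = FALSE)
  for (i in seq_along(x)) {
    on_water <- !is.na(cells[i, 1]) &&
      grid$conductance[cells[i, 1], cells[i, 2]] == 1
    if (on_water) next
    d2 <- (ctr[, 1] - x[i])^2 + (ctr[, 2] - y[i])^2
    j <- which.min(d2)   # first minimum = row-major tie-break
    out$row[i] <- wat[j, 1]; out$col[i] <- wat[j, 2]
    out$x[i] <- ctr[j, 1]; out$y[i] <- ctr[j, 2]
    out$snapped[i] <- TRUE
  }
  out
}

# 8-neighbour graph over water cells; orthogonal steps cost cell_size,
# diagonal steps cell_size * sqrt(2)
.water_graph <- function(grid) {
  m <- grid$conductance
  nr <- nrow(m); ncl <- ncol(m)
  id <- matrix(seq_len(nr * ncl), nr, ncl)   # column-major ids
  water <- m == 1
  edges <- list(); weights <- list()
  push <- function(from, to, w) {
    edges[[length(edges) + 1L]] <<- rbind(from, to)
    weights[[length(weights) + 1L]] <<- rep(w, length(from))
  }
  # right
  ok <- water[, -ncl, drop = FALSE] & water[, -1, drop = FALSE]
  push(id[, -ncl][ok], id[, -1][ok], grid$cell_size)
  # down
  ok <- water[-nr, , drop = FALSE] & water[-1, , drop = FALSE]
  push(id[-nr, ][ok], id[-1, ][ok], grid$cell_size)
  # down-right
  ok <- water[-nr, -ncl, drop = FALSE] & water[-1, -1, drop = FALSE]
  push(id[-nr, -ncl][ok], id[-1, -1][ok], grid$cell_size * sqrt(2))
  # down-left
  ok <- water[-nr, -1, drop = FALSE] & water[-1, -ncl, drop = FALSE]
  push(id[-nr, -1][ok], id[-1, -ncl][ok], grid$cell_size * sqrt(2))
  el <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = nr * ncl, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(el))
  igraph::E(g)$weight <- unlist(weights)
  g
}

#' Least-cost (through-water) distance matrix
#'
#' Dijkstra shortest paths on the 8-neighbour graph of water cells:
#' orthogonal steps cost one cell size, diagonal steps `cell_size * sqrt(2)`;
#' land is impassable. Distances are measured between the centers of the
#' cells containing (or snapped from) the points. Unreachable pairs are
#' `Inf`.
#'
#' @param grid a `water_grid`.
#' @param points data frame with columns `id`, `x`, `y`.
#' @param snap snap off-water points to the nearest water cell
#'   (default TRUE); with `snap = FALSE` a point on land is an error.
#' @return symmetric matrix of distances (m), `dimnames` from `points$id`.
#' @export
cost_distance <- function(grid, points, snap = TRUE) {
  cells <- .cell_of(grid, points$x, points$y)
  if (anyNA(cells)) {
    if (!snap) stop("point(s) outside the grid")
  }
  if (snap) {
    sn <- snap_to_water(grid, points$x, points$y)
    cells <- cbind(row = sn$row, col = sn$col)
  } else {
    on_land <- grid$conductance[cells] != 1
    if (any(on_land)) stop("point(s) on land; use snap = TRUE")
  }
  g <- .water_graph(grid)
  nodes <- (cells[, "col"] - 1L) * grid$nrows + cells[, "row"]  # column-major
  d <- igraph::distances(g, v = nodes, to = nodes,
                         algorithm = "dijkstra")
  dimnames(d) <- list(points$id, points$id)
  diag(d) <- 0
  d
}

#' Euclidean distance matrix between points
#'
#' @param points data frame with columns `id`, `x`, `y`.
#' @return symmetric matrix of planar distances (m).
#' @export
euclidean_distance <- function(points) {
  d <- as.matrix(stats::dist(cbind(points$x, points$y)))
  dimnames(d) <- list(points$id, points$id)
  d
}

#' Combined distance: entrywise maximum of Euclidean and cost
#'
#' Raster cost distances underestimate short direct paths (discretization),
#' Euclidean distances underestimate paths around shorelines; the larger of
#' the two is taken for every pair. Infinite cost entries (disconnected
#' water) propagate with a warning.
#'
#' @param euclid,cost distance matrices with identical ids.
#' @return combined matrix.
#' @export
combined_distance <- function(euclid, cost) {
  if (!identical(dimnames(euclid), dimnames(cost)))
    stop("entity ids of the two matrices differ")
  if (any(is.infinite(cost)))
    warning("infinite cost distances (disconnected water) propagated")
  pmax(euclid, cost)
}

#' Site centroids, snapped to water
#'
#' Mean of member-sample coordinates per site; centroids falling on land (or
#' outside the grid) are moved to the nearest water cell center.
#'
#' @param samples data frame with `site_id`, `x`, `y` (one row per sample).
#' @param grid optional `water_grid` for snapping.
#' @return data frame: `site_id`, `x`, `y`, `snapped`.
#' @export
site_centroids <- function(samples, grid = NULL) {
  agg <- stats::aggregate(cbind(x, y) ~ site_id, data = samples, FUN = mean)
  agg$snapped <- FALSE
  if (!is.null(grid)) {
    sn <- snap_to_water(grid, agg$x, agg$y)
    agg$x <- sn$x; agg$y <- sn$y; agg$snapped <- sn$snapped
  }
  agg
}
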