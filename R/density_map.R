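#' Fishnet counts of endpoints on a regular lat/lon grid
#'
#' Counts endpoints per cell of a regular grid ("fishnet") anchored at
#' `origin`, default cell size 0.5 degrees. Cell membership is half-open:
#' a point on a cell edge belongs to the higher-index cell. Counts are also
#' normalized to a probability per cell (per endpoint set).
#'
#' @param endpoints data.frame with `lat`, `lon`.
#' @param cell_size cell edge in degrees (default 0.5).
#' @param origin numeric `c(lat0, lon0)` grid anchor (cell lower-left edges
#'   are `origin + k * cell_size`).
#' @return object of class `density_grid`: data.frame
#'   `(row, col, cell_lat, cell_lon, count, prob)` over non-empty cells,
#'   where `cell_lat`/`cell_lon` are cell centroids; attributes `cell_size`,
#'   `origin`, `total`.
#' @export
fishnet_counts <- function(endpoints, cell_size = 0.5, origin = c(0, 0)) {
  if (cell_size <= 0) stop("cell_size must be > 0")
  n <- nrow(endpoints)
  if (n) {
    row <- floor((endpoints$lat - origin[1]) / cell_size)
    col <- floor((endpoints$lon - origin[2]) / cell_size)
    tab <- stats::aggregate(list(count = rep(1L, n)),
                            by = list(row = row, col = col), FUN = sum)
  } else {
    tab <- data.frame(row = integer(), col = integer(), count = integer())
  }
  tab <- tab[order(tab$row, tab$col), , drop = FALSE]
  tab$cell_lat <- origin[1] + (tab$row + 0.5) * cell_size
  tab$cell_lon <- origin[2] + (tab$col + 0.5) * cell_size
  total <- sum(tab$count)
  tab$prob <- if (total > 0) tab$count / total else numeric(nrow(tab))
  out <- tab[, c("row", "col", "cell_lat", "cell_lon", "count", "prob")]
  rownames(out) <- NULL
  structure(out, class = c("density_grid", "data.frame"),
            cell_size = cell_size, origin = origin, total = total)
}

# convex hull membership (boundary counts inside); pts: matrix [ , c(x, y)]
inside_hull <- function(px, py, x, y) {
  h <- grDevices::chull(x, y)
  sp::point.in.polygon(px, py, x[h], y[h]) > 0
}

#' Sibson natural-neighbor interpolation of a density grid
#'
#' Interpolates cell-centroid probabilities at query points by Sibson
#' area-stealing: the query is inserted into the Voronoi diagram of the
#' non-empty cell centroids, and each datum is weighted by the area its
#' Voronoi tile loses to the inserted point. Queries outside the convex hull
#' of the centroids return `NA` (no extrapolation); a query coinciding with
#' a centroid returns that cell's value exactly.
#'
#' @param grid a [fishnet_counts()] result (or any data.frame with
#'   `cell_lat`, `cell_lon`, `prob`).
#' @param query_lat,query_lon query coordinates, degrees.
#' @param values column of `grid` to interpolate (default `"prob"`).
#' @param method `"sibson"` (natural neighbor) or `"linear"` (barycentric
#'   interpolation on the Delaunay triangulation, via the interp package),
#'   a robustness fallback.
#' @return numeric vector of interpolated values (`NA` outside the hull).
#' @export
natural_neighbor_surface <- function(grid, query_lat, query_lon,
                                     values = "prob",
                                     method = c("sibson", "linear")) {
  method <- match.arg(method)
  x <- grid$cell_lon; y <- grid$cell_lat; v <- grid[[values]]
  keep <- !is.na(v)
  x <- x[keep]; y <- y[keep]; v <- v[keep]
  if (length(x) < 3) stop("need >= 3 non-empty cells for interpolation")
  # collinearity check via the rank of centered coordinates
  if (qr(cbind(x - mean(x), y - mean(y)))$rank < 2)
    stop("non-empty cell centroids are collinear; interpolation is degenerate")
  n <- max(length(query_lat), length(query_lon))
  qx <- rep_len(query_lon, n); qy <- rep_len(query_lat, n)

  if (method == "linear") {
    if (!requireNamespace("interp", quietly = TRUE))
      stop("method = 'linear' requires the interp package")
    return(interp::interpp(x, y, v, xo = qx, yo = qy)$z)
  }

  # bounding rectangle generously larger than data + queries so that every
  # tile of interest is finite and box-independent for in-hull queries
  pad <- 10 * max(diff(range(c(x, qx))), diff(range(c(y, qy))), 1)
  rw <- c(min(c(x, qx)) - pad, max(c(x, qx)) + pad,
          min(c(y, qy)) - pad, max(c(y, qy)) + pad)
  base <- deldir::deldir(x, y, rw = rw)
  base_area <- base$summary$dir.area

  ok <- inside_hull(qx, qy, x, y)
  out <- rep(NA_real_, n)
  for (i in which(ok)) {
    d2 <- (x - qx[i])^2 + (y - qy[i])^2
    j <- which.min(d2)
    if (d2[j] < 1e-18) { out[i] <- v[j]; next }
    aug <- deldir::deldir(c(x, qx[i]), c(y, qy[i]), rw = rw)
    stolen <- pmax(base_area - aug$summary$dir.area[seq_along(x)], 0)
    out[i] <- sum(stolen * v) / sum(stolen)
  }
  out
}

#' Write a density grid as CSV
#' @param grid a `density_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density_csv <- function(grid, path) {
  utils::write.csv(as.data.frame(grid)[, c("cell_lat", "cell_lon", "count", "prob")],
                   path, row.names = FALSE)
  invisible(path)
}
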