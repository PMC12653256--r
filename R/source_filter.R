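#' Construct a valid-source mask
#'
#' A source mask encodes the three valid-source criteria applied to trajectory
#' endpoints: (1) the endpoint lies at or south of a latitude cutoff (25
#' degrees N by default, because rice north of it is still at sowing/seedling
#' stage in May); (2) it falls inside a rice-cultivation polygon; (3) that
#' polygon has macropterous (long-winged, flight-capable) adults available as
#' an emigrant source.
#'
#' @param polygons list of polygons; each is a list with `lon`, `lat` numeric
#'   ring vertices (not necessarily closed), and logical `rice`, `macroptery`.
#' @param lat_cutoff degrees north; endpoints strictly north of it are
#'   excluded (the boundary latitude itself is retained).
#' @return object of class `source_mask`.
#' @export
source_mask <- function(polygons, lat_cutoff = 25) {
  if (!is.finite(lat_cutoff)) stop("lat_cutoff must be finite")
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    if (is.null(p$lon) || is.null(p$lat) || length(p$lon) != length(p$lat) ||
        length(p$lon) < 3)
      stop("polygon ", i, " must have matching lon/lat rings with >= 3 vertices")
    polygons[[i]]$rice <- isTRUE(p$rice)
    polygons[[i]]$macroptery <- isTRUE(p$macroptery)
  }
  structure(list(polygons = polygons, lat_cutoff = lat_cutoff),
            class = "source_mask")
}

#' Read a source mask from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features with boolean properties
#' `rice` and `macroptery`. Coordinates are treated as planar lon/lat (the
#' study domain is small enough that this is negligible at 0.5 degree
#' analysis resolution).
#'
#' @param path GeoJSON file path.
#' @param lat_cutoff see [source_mask()].
#' @return a [source_mask].
#' @export
read_source_mask <- function(path, lat_cutoff = 25) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features %||% list(gj)
  polys <- lapply(feats, function(f) {
    geom <- f$geometry %||% f
    if (!identical(geom$type, "Polygon"))
      stop("only Polygon features are supported, got ", geom$type)
    ring <- geom$coordinates[[1]]
    list(lon = vapply(ring, function(p) as.numeric(p[[1]]), numeric(1)),
         lat = vapply(ring, function(p) as.numeric(p[[2]]), numeric(1)),
         rice = isTRUE(f$properties$rice %||% TRUE),
         macroptery = isTRUE(f$properties$macroptery %||% TRUE))
  })
  source_mask(polys, lat_cutoff)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# planar point-in-polygon; boundary counts as inside
point_in_poly <- function(lat, lon, poly) {
  sp::point.in.polygon(lon, lat, poly$lon, poly$lat) > 0
}

#' Classify one endpoint against the valid-source criteria
#'
#' Criteria are evaluated in a fixed order — latitude cutoff, rice area,
#' macroptery — and the first failure is reported.
#'
#' @param endpoint one-row data.frame with `lat`, `lon` and `status`
#'   (must be `"complete"`).
#' @param mask a [source_mask].
#' @return list `(valid = logical, reason = one of "ok", "north_of_cutoff",
#'   "not_rice", "no_macroptery")`.
#' @export
is_valid_source <- function(endpoint, mask) {
  if (!identical(as.character(endpoint$status), "complete"))
    stop("endpoint must have complete status, got: ", endpoint$status)
  if (endpoint$lat > mask$lat_cutoff)
    return(list(valid = FALSE, reason = "north_of_cutoff"))
  hits <- vapply(mask$polygons, function(p)
    p$rice && point_in_poly(endpoint$lat, endpoint$lon, p), logical(1))
  if (!any(hits)) return(list(valid = FALSE, reason = "not_rice"))
  macro <- vapply(mask$polygons[hits], function(p) p$macroptery, logical(1))
  if (!any(macro)) return(list(valid = FALSE, reason = "no_macroptery"))
  list(valid = TRUE, reason = "ok")
}

#' Filter endpoints by the valid-source criteria
#'
#' @param endpoints data.frame from [takeoff_endpoints()].
#' @param mask a [source_mask].
#' @return list with `valid` (the passing subset) and `audit` (named integer
#'   counts per reason; the audit classes partition the input).
#' @export
filter_endpoints <- function(endpoints, mask) {
  reasons <- c("ok", "north_of_cutoff", "not_rice", "no_macroptery")
  if (!nrow(endpoints)) {
    audit <- stats::setNames(integer(length(reasons)), reasons)
    return(list(valid = endpoints, audit = audit))
  }
  res <- vapply(seq_len(nrow(endpoints)), function(i)
    is_valid_source(endpoints[i, , drop = FALSE], mask)$reason, character(1))
  audit <- table(factor(res, levels = reasons))
  list(valid = endpoints[res == "ok", , drop = FALSE],
       audit = stats::setNames(as.integer(audit), reasons))
}
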