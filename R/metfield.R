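# Beijing Time (UTC+8) is the single timezone used throughout; "Etc/GMT-8"
# is the POSIX name for a fixed UTC+8 offset (sign is inverted by convention).
BJT <- "Etc/GMT-8"

#' Parse timestamps as Beijing Time (UTC+8)
#'
#' All times in the pipeline are Beijing Time with no daylight saving; this
#' helper parses character timestamps (`"YYYY-mm-dd HH:MM"`) or coerces
#' POSIXct into that timezone.
#'
#' @param x character or POSIXct.
#' @return POSIXct in tz `"Etc/GMT-8"`.
#' @export
as_bjt <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- BJT
    return(x)
  }
  out <- as.POSIXct(x, tz = BJT)
  if (anyNA(out)) stop("unparseable timestamp(s): ", paste(x[is.na(out)], collapse = ", "))
  out
}

#' Construct a gridded wind/temperature field
#'
#' A `met_field` holds eastward wind `u`, northward wind `v` (m/s) and air
#' temperature `T` (degrees C) on a regular (time, lat, lon) grid at one
#' nominal flight level. It is the advection medium for backward trajectories.
#'
#' @param lats ascending latitudes, degrees north.
#' @param lons ascending longitudes, degrees east in \[-180, 180).
#' @param times ascending POSIXct timestamps (Beijing Time).
#' @param u,v,T numeric arrays with dim `c(length(times), length(lats), length(lons))`.
#' @param level_m nominal altitude of the fields in metres (metadata only).
#' @return object of class `met_field`.
#' @export
met_field <- function(lats, lons, times, u, v, T, level_m = 1000) {
  times <- as_bjt(times)
  axes <- list(lat = lats, lon = lons, time = as.numeric(times))
  for (nm in names(axes)) {
    ax <- axes[[nm]]
    if (length(ax) < 2 || any(diff(ax) <= 0))
      stop("axis ", nm, " is not strictly ascending with >= 2 values")
  }
  dims <- c(length(times), length(lats), length(lons))
  for (nm in c("u", "v", "T")) {
    arr <- get(nm)
    if (!is.array(arr) || !identical(dim(arr), as.integer(dims)))
      stop("variable ", nm, " must be an array with dim (time, lat, lon) = (",
           paste(dims, collapse = ", "), ")")
    if (anyNA(arr)) stop("variable ", nm, " contains missing values inside the declared domain")
  }
  if (!is.numeric(level_m) || level_m <= 0) stop("level_m must be > 0")
  structure(list(lats = lats, lons = lons, times = times,
                 u = u, v = v, T = T, level_m = level_m),
            class = "met_field")
}

#' @export
print.met_field <- function(x, ...) {
  cat(sprintf("met_field: %d times x %d lats x %d lons at %g m\n",
              length(x$times), length(x$lats), length(x$lons), x$level_m))
  cat(sprintf("  lat %.2f..%.2f  lon %.2f..%.2f\n",
              min(x$lats), max(x$lats), min(x$lons), max(x$lons)))
  cat(sprintf("  time %s .. %s (Beijing Time)\n",
              format(min(x$times)), format(max(x$times))))
  invisible(x)
}

#' Load a met field from NetCDF or long-format CSV
#'
#' The CSV dialect is long format with columns `time, lat, lon, u, v, T`
#' (one row per grid node, any row order); it is the hand-writable fixture
#' format. NetCDF input expects CF-style coordinate variables named
#' `lat`/`latitude`, `lon`/`longitude`, `time`, and data variables `u`, `v`,
#' `T` on (lon, lat, time) or (time, lat, lon) order; descending axes are
#' normalized to ascending with values reordered.
#'
#' @param path file path.
#' @param format `"csv_grid"` or `"netcdf"`.
#' @param level_m nominal altitude metadata, metres.
#' @param time_origin for NetCDF numeric time axes: origin timestamp
#'   (Beijing Time) to which the stored offsets (hours) are added.
#' @return a [met_field].
#' @export
load_metfield <- function(path, format = c("csv_grid", "netcdf"), level_m = 1000,
                          time_origin = "1970-01-01 00:00") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("met file not found: ", path)
  if (format == "csv_grid") load_metfield_csv(path, level_m) else
    load_metfield_nc(path, level_m, time_origin)
}

load_metfield_csv <- function(path, level_m) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "lat", "lon", "u", "v", "T")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variable ", paste(miss, collapse = ", "), " absent from ", path)
  times <- sort(unique(as_bjt(df$time)))
  lats <- sort(unique(df$lat))
  lons <- sort(unique(df$lon))
  nT <- length(times); nla <- length(lats); nlo <- length(lons)
  if (nrow(df) != nT * nla * nlo)
    stop("CSV grid is not complete: ", nrow(df), " rows for a ",
         nT, "x", nla, "x", nlo, " grid")
  it <- match(as.numeric(as_bjt(df$time)), as.numeric(times))
  ila <- match(df$lat, lats)
  ilo <- match(df$lon, lons)
  idx <- cbind(it, ila, ilo)
  mk <- function(col) { a <- array(NA_real_, c(nT, nla, nlo)); a[idx] <- col; a }
  met_field(lats, lons, times, mk(df$u), mk(df$v), mk(df$T), level_m)
}

load_metfield_nc <- function(path, level_m, time_origin) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("NetCDF input requires the ncdf4 package; use format = 'csv_grid' otherwise")
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  dimnames_nc <- names(nc$dim)
  pick <- function(cands, what) {
    hit <- intersect(cands, dimnames_nc)
    if (!length(hit)) stop("coordinate axis ", what, " absent from ", path)
    ncdf4::ncvar_get(nc, hit[1])
  }
  lats <- as.numeric(pick(c("lat", "latitude"), "lat"))
  lons <- as.numeric(pick(c("lon", "longitude"), "lon"))
  tval <- as.numeric(pick("time", "time"))
  times <- as_bjt(time_origin) + tval * 3600
  getv <- function(nm) {
    if (!nm %in% names(nc$var)) stop("variable ", nm, " absent from ", path)
    arr <- ncdf4::ncvar_get(nc, nm, collapse_degen = FALSE)
    # accept (lon, lat, time) — the common NetCDF layout — or (time, lat, lon)
    d <- dim(arr)
    target <- c(length(times), length(lats), length(lons))
    if (identical(as.integer(d), as.integer(target))) arr
    else if (identical(as.integer(d), as.integer(rev(target)))) aperm(arr, c(3, 2, 1))
    else stop("variable ", nm, " has dim (", paste(d, collapse = ","),
              "), expected a permutation of (time, lat, lon)")
  }
  u <- getv("u"); v <- getv("v"); Tv <- getv("T")
  # normalize descending axes
  if (length(lats) > 1 && lats[1] > lats[2]) {
    o <- order(lats); lats <- lats[o]
    u <- u[, o, , drop = FALSE]; v <- v[, o, , drop = FALSE]; Tv <- Tv[, o, , drop = FALSE]
  }
  if (length(lons) > 1 && lons[1] > lons[2]) {
    o <- order(lons); lons <- lons[o]
    u <- u[, , o, drop = FALSE]; v <- v[, , o, drop = FALSE]; Tv <- Tv[, , o, drop = FALSE]
  }
  if (length(times) > 1 && times[1] > times[2]) {
    o <- order(times); times <- times[o]
    u <- u[o, , , drop = FALSE]; v <- v[o, , , drop = FALSE]; Tv <- Tv[o, , , drop = FALSE]
  }
  met_field(lats, lons, times, u, v, Tv, level_m)
}

#' Sample a met field at arbitrary points
#'
#' Trilinear interpolation: bilinear in lat/lon, linear in time. Queries must
#' lie inside the grid's space-time domain.
#'
#' @param field a [met_field].
#' @param lat,lon query coordinates, degrees (vectorized).
#' @param t query timestamps (POSIXct or parseable character), recycled.
#' @param var one of `"u"`, `"v"`, `"T"`.
#' @return numeric vector of interpolated values in native units.
#' @export
sample_met <- function(field, lat, lon, t, var = c("u", "v", "T")) {
  var <- match.arg(var)
  t <- as.numeric(as_bjt(t))
  n <- max(length(lat), length(lon), length(t))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n); t <- rep_len(t, n)
  tax <- as.numeric(field$times)
  bad <- lat < min(field$lats) | lat > max(field$lats) |
    lon < min(field$lons) | lon > max(field$lons) |
    t < min(tax) | t > max(tax)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("query outside met domain: lat=%.4f lon=%.4f t=%s",
                 lat[i], lon[i], format(as.POSIXct(t[i], origin = "1970-01-01", tz = BJT))))
  }
  arr <- field[[var]]
  bracket <- function(x, ax) {
    i <- findInterval(x, ax, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(ax) - 1L)
    w <- (x - ax[i]) / (ax[i + 1L] - ax[i])
    list(i = i, w = w)
  }
  bt <- bracket(t, tax); bla <- bracket(lat, field$lats); blo <- bracket(lon, field$lons)
  val <- numeric(n)
  for (dt in 0:1) for (dla in 0:1) for (dlo in 0:1) {
    w <- (if (dt) bt$w else 1 - bt$w) *
      (if (dla) bla$w else 1 - bla$w) *
      (if (dlo) blo$w else 1 - blo$w)
    val <- val + w * arr[cbind(bt$i + dt, bla$i + dla, blo$i + dlo)]
  }
  val
}

#' Test whether points are inside a met field's spatial domain
#' @param field a [met_field].
#' @param lat,lon coordinates, degrees.
#' @return logical vector.
#' @export
in_met_domain <- function(field, lat, lon) {
  lat >= min(field$lats) & lat <= max(field$lats) &
    lon >= min(field$lons) & lon <= max(field$lons)
}

#' Write a met field as a long-format CSV grid
#' @param field a [met_field].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metfield_csv <- function(field, path) {
  grid <- expand.grid(time = field$times, lat = field$lats, lon = field$lons,
                      KEEP.OUT.ATTRS = FALSE)
  idx <- cbind(match(as.numeric(grid$time), as.numeric(field$times)),
               match(grid$lat, field$lats), match(grid$lon, field$lons))
  out <- data.frame(time = format(grid$time, "%Y-%m-%d %H:%M"),
                    lat = grid$lat, lon = grid$lon,
                    u = field$u[idx], v = field$v[idx], T = field$T[idx])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
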