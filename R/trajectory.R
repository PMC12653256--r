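# metres per degree of latitude on the spherical Earth used throughout
M_PER_DEG <- 111320

#' Flight behaviour configuration for backward trajectories
#'
#' Encodes the insect behavioural rules governing a migration flight:
#' planthoppers take off at dusk (19:00 Beijing Time), fly at a fixed
#' representative altitude, cannot fly below a temperature floor of 16.5
#' degrees C, and complete the journey within 24 h, so landings fall between
#' 20:00 on the departure day and 19:00 the next day.
#'
#' @param takeoff_hour local clock hour of dusk takeoff (default 19).
#' @param landing_window numeric length-2, earliest/latest landing in hours
#'   after takeoff (default `c(1, 24)`).
#' @param altitude_m flight level in metres (metadata; default 1000).
#' @param temp_floor_C minimum flight temperature, degrees C (default 16.5).
#' @param max_duration_h maximum flight duration, hours (default 24).
#' @param step_min integration step in minutes (default 6).
#' @param landing_hours integer clock hours at which backward trajectories
#'   start on the capture night. The default, 20:00–23:00 of the capture date
#'   plus 00:00–06:00 of the next morning, assumes nocturnal arrival at the
#'   trap (flight durations 1–11 h). `full_window = TRUE` extends to the
#'   whole physiological window (durations 1–24 h).
#' @param full_window enumerate landings through 19:00 the following day.
#' @return object of class `flight_config`.
#' @export
flight_config <- function(takeoff_hour = 19, landing_window = c(1, 24),
                          altitude_m = 1000, temp_floor_C = 16.5,
                          max_duration_h = 24, step_min = 6,
                          landing_hours = NULL, full_window = FALSE) {
  if (step_min <= 0 || step_min > 60) stop("step_min must be in (0, 60]")
  if (!is.finite(temp_floor_C)) stop("temp_floor_C must be finite")
  if (landing_window[1] <= 0 || landing_window[2] > max_duration_h)
    stop("landing_window must lie within (0, max_duration_h]")
  if (is.null(landing_hours))
    landing_hours <- if (full_window) c(20:23, 0:19) else c(20:23, 0:6)
  structure(list(takeoff_hour = takeoff_hour, landing_window = landing_window,
                 altitude_m = altitude_m, temp_floor_C = temp_floor_C,
                 max_duration_h = max_duration_h, step_min = step_min,
                 landing_hours = as.integer(landing_hours)),
            class = "flight_config")
}

#' Select migration events from light-trap records
#'
#' A migration event is a site-night whose light-trap catch reaches the event
#' threshold (>= 10 individuals per night by default); only such nights are
#' simulated.
#'
#' @param trap_records data.frame with columns `site_id, lat, lon, date, count`.
#' @param threshold minimum nightly count (inclusive).
#' @return data.frame of events (same columns), one row per qualifying
#'   site-date.
#' @export
select_events <- function(trap_records, threshold = 10) {
  need <- c("site_id", "lat", "lon", "date", "count")
  miss <- setdiff(need, names(trap_records))
  if (length(miss)) stop("trap records missing column(s): ", paste(miss, collapse = ", "))
  cnt <- trap_records$count
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != floor(cnt)))
    stop("counts must be non-negative integers")
  ev <- trap_records[cnt >= threshold, need, drop = FALSE]
  ev <- ev[!duplicated(ev[c("site_id", "date")]), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# most recent occurrence of `hour`:00 strictly before (or at) time t
last_clock_hour <- function(t, hour) {
  t <- as_bjt(t)
  day <- as.POSIXct(format(t, "%Y-%m-%d"), tz = BJT)
  cand <- day + hour * 3600
  cand[cand >= t] <- cand[cand >= t] - 86400
  cand
}

#' Integrate one backward trajectory to the dusk takeoff point
#'
#' Positions are integrated backward in time from the landing point using the
#' Petterssen predictor-corrector (iterated implicit midpoint) scheme at
#' `cfg$step_min` resolution, stopping at the most recent dusk takeoff hour
#' before landing. The flight temperature floor is enforced at every step:
#' the first position colder than `temp_floor_C` truncates the trajectory
#' (`status = "truncated_temp"`). Leaving the met field's spatial domain sets
#' `status = "exited_domain"`. Wind components are converted to angular rates
#' with dlat/dt = v / 111320 and dlon/dt = u / (111320 cos(lat)).
#'
#' @param field a [met_field].
#' @param start_lat,start_lon landing location, degrees.
#' @param landing_time landing timestamp (Beijing Time).
#' @param cfg a [flight_config].
#' @return object of class `trajectory`: data.frame `(time, lat, lon)` ordered
#'   landing -> takeoff (timestamps strictly decreasing), with attributes
#'   `status`, `landing_time`, `takeoff_time`.
#' @export
backward_trajectory <- function(field, start_lat, start_lon, landing_time,
                                cfg = flight_config()) {
  landing_time <- as_bjt(landing_time)
  takeoff_time <- last_clock_hour(landing_time, cfg$takeoff_hour)
  if (takeoff_time < min(field$times))
    stop("takeoff candidate ", format(takeoff_time),
         " precedes the met field time domain")
  if (landing_time > max(field$times))
    stop("landing_time outside met field time domain")
  if (!in_met_domain(field, start_lat, start_lon))
    stop("start location outside met field spatial domain")

  dt <- cfg$step_min * 60
  times <- seq(from = as.numeric(landing_time), to = as.numeric(takeoff_time), by = -dt)
  if (utils::tail(times, 1) > as.numeric(takeoff_time))
    times <- c(times, as.numeric(takeoff_time))

  lat <- numeric(length(times)); lon <- numeric(length(times))
  lat[1] <- start_lat; lon[1] <- start_lon
  status <- "complete"
  npts <- 1L

  vel <- function(la, lo, tt) {
    u <- sample_met(field, la, lo, tt, "u")
    v <- sample_met(field, la, lo, tt, "v")
    c(v / M_PER_DEG, u / (M_PER_DEG * cos(la * pi / 180)))  # (dlat, dlon)/s
  }
  t_at <- function(la, lo, tt) sample_met(field, la, lo, tt, "T")

  if (t_at(lat[1], lon[1], times[1]) < cfg$temp_floor_C) {
    status <- "truncated_temp"
  } else if (length(times) > 1) {
    for (k in seq_len(length(times) - 1L)) {
      h <- times[k + 1L] - times[k]  # negative: stepping backward
      v0 <- vel(lat[k], lon[k], times[k])
      la1 <- lat[k] + h * v0[1]
      lo1 <- lon[k] + h * v0[2]
      ok <- TRUE
      for (iter in 1:10) {
        if (!in_met_domain(field, la1, lo1)) { ok <- FALSE; break }
        v1 <- vel(la1, lo1, times[k + 1L])
        la2 <- lat[k] + h * (v0[1] + v1[1]) / 2
        lo2 <- lon[k] + h * (v0[2] + v1[2]) / 2
        conv <- max(abs(la2 - la1), abs(lo2 - lo1)) < 1e-10
        la1 <- la2; lo1 <- lo2
        if (conv) break
      }
      if (!ok || !in_met_domain(field, la1, lo1)) { status <- "exited_domain"; break }
      if (t_at(la1, lo1, times[k + 1L]) < cfg$temp_floor_C) { status <- "truncated_temp"; break }
      lat[k + 1L] <- la1; lon[k + 1L] <- lo1
      npts <- k + 1L
    }
  }

  pts <- data.frame(
    time = as.POSIXct(times[seq_len(npts)], origin = "1970-01-01", tz = BJT),
    lat = lat[seq_len(npts)], lon = lon[seq_len(npts)])
  structure(pts, class = c("trajectory", "data.frame"),
            status = status, landing_time = landing_time,
            takeoff_time = takeoff_time)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %s, %d points, landing %s -> takeoff %s\n",
              attr(x, "status"), nrow(x),
              format(attr(x, "landing_time")), format(attr(x, "takeoff_time"))))
  invisible(x)
}

#' Forward re-integration of a trajectory endpoint (verification tool)
#'
#' Integrates forward in time from a takeoff point to a landing time with the
#' same Petterssen scheme; used to check time-reversal consistency of the
#' backward integrator.
#'
#' @param field a [met_field].
#' @param lat,lon takeoff location, degrees.
#' @param takeoff_time,landing_time timestamps (Beijing Time).
#' @param step_min integration step, minutes.
#' @return list with final `lat`, `lon`.
#' @export
forward_position <- function(field, lat, lon, takeoff_time, landing_time,
                             step_min = 6) {
  t0 <- as.numeric(as_bjt(takeoff_time)); t1 <- as.numeric(as_bjt(landing_time))
  stopifnot(t1 > t0)
  times <- seq(t0, t1, by = step_min * 60)
  if (utils::tail(times, 1) < t1) times <- c(times, t1)
  vel <- function(la, lo, tt) {
    u <- sample_met(field, la, lo, tt, "u")
    v <- sample_met(field, la, lo, tt, "v")
    c(v / M_PER_DEG, u / (M_PER_DEG * cos(la * pi / 180)))
  }
  for (k in seq_len(length(times) - 1L)) {
    h <- times[k + 1L] - times[k]
    v0 <- vel(lat, lon, times[k])
    la1 <- lat + h * v0[1]; lo1 <- lon + h * v0[2]
    for (iter in 1:10) {
      v1 <- vel(la1, lo1, times[k + 1L])
      la2 <- lat + h * (v0[1] + v1[1]) / 2
      lo2 <- lon + h * (v0[2] + v1[2]) / 2
      conv <- max(abs(la2 - la1), abs(lo2 - lo1)) < 1e-10
      la1 <- la2; lo1 <- lo2
      if (conv) break
    }
    lat <- la1; lon <- lo1
  }
  list(lat = lat, lon = lon)
}

#' Backward trajectories for one migration event
#'
#' Launches one backward trajectory per landing hour of the capture night.
#' Hours >= 20 are interpreted as the evening of the capture date; hours
#' < 20 as the following morning, so default durations span 1–11 h back to
#' the 19:00 dusk takeoff. Failures of individual landing hours are recorded,
#' not fatal.
#'
#' @param field a [met_field].
#' @param event one-row data.frame from [select_events()].
#' @param cfg a [flight_config].
#' @return list of `trajectory` objects, named by landing hour; failed hours
#'   carry a `condition` attribute instead.
#' @export
trajectories_for_event <- function(field, event, cfg = flight_config()) {
  stopifnot(nrow(event) == 1)
  night0 <- as.POSIXct(as.character(event$date), tz = BJT)
  out <- list()
  for (h in cfg$landing_hours) {
    land <- night0 + (if (h >= 20) h else h + 24) * 3600
    dur_h <- as.numeric(land - last_clock_hour(land, cfg$takeoff_hour),
                        units = "hours")
    if (dur_h < cfg$landing_window[1] || dur_h > cfg$landing_window[2]) next
    tr <- tryCatch(
      backward_trajectory(field, event$lat, event$lon, land, cfg),
      error = function(e) structure(list(), class = "trajectory_error", condition = e))
    out[[sprintf("%02d", h)]] <- tr
  }
  out
}

#' Extract takeoff endpoints from trajectories
#'
#' Only trajectories with `status = "complete"` contribute an endpoint (the
#' takeoff-time terminus, a candidate emigration point); truncated or
#' domain-exited trajectories contribute none.
#'
#' @param trajectories list of `trajectory` objects (possibly nested per
#'   event), e.g. from [trajectories_for_event()].
#' @param event_id identifier attached to each endpoint (recycled).
#' @return data.frame `(event_id, landing_hour, status, lat, lon, takeoff_time)`
#'   with one row per complete trajectory.
#' @export
takeoff_endpoints <- function(trajectories, event_id = NA_character_) {
  rows <- list()
  for (nm in names2(trajectories)) {
    tr <- trajectories[[nm]]
    if (!inherits(tr, "trajectory")) next
    if (!identical(attr(tr, "status"), "complete")) next
    last <- tr[nrow(tr), ]
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = as.character(event_id), landing_hour = nm,
      status = "complete", lat = last$lat, lon = last$lon,
      takeoff_time = format(attr(tr, "takeoff_time"), "%Y-%m-%d %H:%M"),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(event_id = character(), landing_hour = character(),
                      status = character(), lat = numeric(), lon = numeric(),
                      takeoff_time = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

names2 <- function(x) {
  nm <- names(x)
  if (is.null(nm)) nm <- as.character(seq_along(x))
  nm
}

#' Endpoints for a whole event set
#'
#' Convenience wrapper: runs [trajectories_for_event()] for every event and
#' binds the complete-trajectory endpoints, with a per-status audit.
#'
#' @param field a [met_field].
#' @param events data.frame from [select_events()].
#' @param cfg a [flight_config].
#' @return list with `endpoints` (data.frame) and `status_counts` (named
#'   integer audit over all launched trajectories).
#' @export
endpoints_for_events <- function(field, events, cfg = flight_config()) {
  eps <- list(); statuses <- character()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, , drop = FALSE]
    trs <- trajectories_for_event(field, ev, cfg)
    statuses <- c(statuses, vapply(trs, function(tr)
      if (inherits(tr, "trajectory")) attr(tr, "status") else "error", character(1)))
    eps[[i]] <- takeoff_endpoints(trs, event_id = paste(ev$site_id, ev$date, sep = "_"))
  }
  endpoints <- if (length(eps)) do.call(rbind, eps) else takeoff_endpoints(list())
  rownames(endpoints) <- NULL
  list(endpoints = endpoints, status_counts = table(factor(
    statuses, levels = c("complete", "truncated_temp", "exited_domain", "error"))))
}
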