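#' Generate a synthetic wind/temperature field
#'
#' Parametric wind scenarios for testing the trajectory machinery without
#' real reanalysis data:
#' \describe{
#'   \item{uniform}{constant `u`, `v`, `T` everywhere.}
#'   \item{rotational}{solid-body rotation about `center` with angular rate
#'     `omega` (rad/s, positive counter-clockwise); zero wind at the center.}
#'   \item{southwesterly_jet}{a jet from the southwest (`u = v =
#'     speed/sqrt(2)` on the axis) whose speed decays as a Gaussian with the
#'     perpendicular distance from the axis line through `center` at 45
#'     degrees; `jet_halfwidth_deg` is the e-folding scale.}
#' }
#' Temperature is `T_base` plus `T_lapse_per_deglat * (lat - mean lat)`.
#'
#' @param kind scenario name.
#' @param lat_range,lon_range numeric length-2 domain bounds, degrees.
#' @param time_range POSIXct/character length-2 (Beijing Time).
#' @param res_deg spatial resolution, degrees (default 1, as in a 1-degree
#'   assimilation product).
#' @param time_step_h time resolution, hours (default 3).
#' @param u,v uniform wind components, m/s.
#' @param T_base,T_lapse_per_deglat temperature parameters, degrees C.
#' @param center `c(lat, lon)` for rotational/jet scenarios.
#' @param omega angular rate for `rotational`, rad/s.
#' @param speed jet axis speed, m/s.
#' @param jet_halfwidth_deg Gaussian half-width of the jet, degrees.
#' @return a [met_field].
#' @export
gen_windfield <- function(kind = c("uniform", "rotational", "southwesterly_jet"),
                          lat_range = c(18, 32), lon_range = c(100, 118),
                          time_range = c("2024-05-01 00:00", "2024-06-01 00:00"),
                          res_deg = 1, time_step_h = 3,
                          u = 0, v = 0, T_base = 20, T_lapse_per_deglat = 0,
                          center = c(mean(lat_range), mean(lon_range)),
                          omega = 1e-5, speed = 10, jet_halfwidth_deg = 3) {
  kind <- match.arg(kind)
  if (res_deg <= 0 || time_step_h <= 0) stop("resolution must be > 0")
  lats <- seq(lat_range[1], lat_range[2], by = res_deg)
  lons <- seq(lon_range[1], lon_range[2], by = res_deg)
  times <- seq(as_bjt(time_range[1]), as_bjt(time_range[2]), by = time_step_h * 3600)
  nT <- length(times); nla <- length(lats); nlo <- length(lons)
  la <- array(rep(lats, each = nT), c(nT, nla, nlo))
  lo <- array(rep(lons, each = nT * nla), c(nT, nla, nlo))
  if (kind == "uniform") {
    U <- array(u, c(nT, nla, nlo)); V <- array(v, c(nT, nla, nlo))
  } else if (kind == "rotational") {
    # displacement from center in metres (planar), solid-body rotation
    dy <- (la - center[1]) * M_PER_DEG
    dx <- (lo - center[2]) * M_PER_DEG * cos(center[1] * pi / 180)
    U <- -omega * dy
    V <- omega * dx
  } else {
    # axis through center with bearing 45 degrees (toward the northeast)
    dy <- la - center[1]
    dx <- lo - center[2]
    perp <- (dy - dx) / sqrt(2)  # signed distance to the 45-degree axis
    amp <- speed * exp(-(perp / jet_halfwidth_deg)^2)
    U <- amp / sqrt(2)
    V <- amp / sqrt(2)
  }
  TT <- T_base + T_lapse_per_deglat * (la - mean(lats))
  met_field(lats, lons, times, U, V, TT)
}

#' Generate a synthetic dose-mortality bioassay
#'
#' Draws binomial deaths from a probit dose-response with known truth:
#' `p(c) = c0 + (1 - c0) * Phi(slope * (log10 c - log10 lc50))` where `c0` is
#' the control mortality. The default design mirrors the reference assay
#' geometry: 5 log-spaced concentrations spanning LC10-LC90 and 80 insects
#' per concentration (4 replicates of 20, pooled).
#'
#' @param lc50 true LC50, mg/L.
#' @param slope true probit slope per log10 mg/L.
#' @param control_mortality natural mortality fraction (default 0).
#' @param conc concentrations, mg/L; default 5 log-spaced values covering
#'   LC10 to LC90 of the truth.
#' @param n_per_conc insects per concentration (default 80).
#' @param control_n control group size (default 80).
#' @param seed integer seed; every draw flows from it.
#' @param site_id,insecticide metadata passed through.
#' @return a [bioassay_table].
#' @export
gen_bioassay <- function(lc50, slope, control_mortality = 0,
                         conc = NULL, n_per_conc = 80, control_n = 80,
                         seed = 1, site_id = NA_character_,
                         insecticide = NA_character_) {
  stopifnot(lc50 > 0, slope > 0)
  if (is.null(conc)) {
    span <- stats::qnorm(0.90) / slope
    conc <- 10^seq(log10(lc50) - span, log10(lc50) + span, length.out = 5)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p <- control_mortality + (1 - control_mortality) *
    stats::pnorm(slope * (log10(conc) - log10(lc50)))
  dead <- stats::rbinom(length(conc), n_per_conc, p)
  cdead <- if (control_n > 0) stats::rbinom(1, control_n, control_mortality) else 0L
  bioassay_table(conc, rep(n_per_conc, length(conc)), dead,
                 control_n = control_n, control_dead = cdead,
                 site_id = site_id, insecticide = insecticide)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic light-trap capture series
#'
#' Nightly counts are Poisson with a low base rate; designated pulse nights
#' (immigration events) add an independent Poisson component with the pulse
#' magnitude as mean, so pulses of magnitude >= 30 exceed the 10-per-night
#' event threshold with high probability.
#'
#' @param sites data.frame `site_id, lat, lon`.
#' @param dates Date vector (or parseable character) of trap nights.
#' @param base_rate mean nightly background count.
#' @param pulses data.frame `site_id, date, magnitude` (may be empty).
#' @param seed integer seed.
#' @return data.frame `site_id, lat, lon, date, count`.
#' @export
gen_trap_series <- function(sites, dates, base_rate = 1,
                            pulses = NULL, seed = 1) {
  stopifnot(base_rate >= 0)
  dates <- as.Date(dates)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  grid <- expand.grid(i = seq_len(nrow(sites)), date = dates,
                      KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(site_id = sites$site_id[grid$i],
                    lat = sites$lat[grid$i], lon = sites$lon[grid$i],
                    date = as.character(grid$date),
                    count = stats::rpois(nrow(grid), base_rate),
                    stringsAsFactors = FALSE)
  if (!is.null(pulses) && nrow(pulses)) {
    if (any(pulses$magnitude < 0)) stop("pulse magnitudes must be >= 0")
    for (k in seq_len(nrow(pulses))) {
      hit <- out$site_id == pulses$site_id[k] &
        out$date == as.character(as.Date(pulses$date[k]))
      out$count[hit] <- out$count[hit] + stats::rpois(sum(hit), pulses$magnitude[k])
    }
  }
  out
}

#' Toy rectangular rice mask
#'
#' A single rectangular rice polygon, convenient for synthetic scenarios.
#'
#' @param lat_range,lon_range rectangle bounds, degrees.
#' @param rice,macroptery polygon attributes.
#' @param lat_cutoff see [source_mask()].
#' @return a [source_mask].
#' @export
gen_rice_mask <- function(lat_range = c(18, 25), lon_range = c(102, 112),
                          rice = TRUE, macroptery = TRUE, lat_cutoff = 25) {
  source_mask(list(list(
    lon = c(lon_range[1], lon_range[2], lon_range[2], lon_range[1]),
    lat = c(lat_range[1], lat_range[1], lat_range[2], lat_range[2]),
    rice = rice, macroptery = macroptery)), lat_cutoff = lat_cutoff)
}

#' Planted-source end-to-end scenario
#'
#' Builds a complete synthetic study in which the truth is known: a uniform
#' southwesterly flow carries migrants from a rice area in the southwest to
#' two destination trap sites; destination bioassays are generated from the
#' same probit truth as one candidate source ("true_source"), while a decoy
#' source is generated with `decoy_factor` times the LC50 for both
#' insecticides. A correct pipeline attributes the destination group to the
#' true source and rejects the decoy.
#'
#' @param seed integer seed driving every stochastic component.
#' @param dest_lc50 named numeric, destination truth per insecticide.
#' @param slope shared true probit slope per log10 mg/L.
#' @param decoy_factor LC50 multiplier for the decoy source (default 3).
#' @param wind_u,wind_v uniform wind components, m/s (default a
#'   southwesterly 8, 8).
#' @return list with `field`, `traps`, `mask`, `assays` (named list of
#'   [bioassay_table]s for dest sites, true source, decoy source), and
#'   `truth` (list of generating parameters).
#' @export
gen_planted_scenario <- function(seed = 1,
                                 dest_lc50 = c(pymetrozine = 30, nitenpyram = 1),
                                 slope = 3.4, decoy_factor = 3,
                                 wind_u = 8, wind_v = 8) {
  field <- gen_windfield("uniform", u = wind_u, v = wind_v, T_base = 20,
                         lat_range = c(16, 32), lon_range = c(98, 120),
                         time_range = c("2024-05-01 00:00", "2024-05-31 00:00"))
  sites <- data.frame(site_id = c("dest1", "dest2"),
                      lat = c(26.5, 26.9), lon = c(111.0, 111.5),
                      stringsAsFactors = FALSE)
  traps <- gen_trap_series(sites, seq(as.Date("2024-05-10"), as.Date("2024-05-20"), 1),
                           base_rate = 1,
                           pulses = data.frame(site_id = c("dest1", "dest2"),
                                               date = c("2024-05-14", "2024-05-15"),
                                               magnitude = 60),
                           seed = seed)
  mask <- gen_rice_mask(lat_range = c(18, 25), lon_range = c(100, 112))
  assays <- list()
  i <- 0L
  for (pop in c("dest1", "dest2", "true_source", "decoy_source")) {
    fac <- if (pop == "decoy_source") decoy_factor else 1
    for (k in names(dest_lc50)) {
      i <- i + 1L
      assays[[paste(pop, k, sep = ".")]] <- gen_bioassay(
        lc50 = fac * dest_lc50[[k]], slope = slope, seed = seed * 1000L + i,
        site_id = pop, insecticide = k)
    }
  }
  list(field = field, traps = traps, mask = mask, assays = assays,
       truth = list(dest_lc50 = dest_lc50, slope = slope,
                    decoy_factor = decoy_factor, seed = seed))
}
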