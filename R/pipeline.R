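stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full source-attribution pipeline
#'
#' Orchestrates the stages end-to-end: light-trap event selection, backward
#' trajectories to dusk takeoff endpoints, valid-source filtering, fishnet
#' density gridding, probit LC50 fits (or supplied intervals), destination
#' grouping by CI overlap, and source matching. Any stage error aborts with
#' the stage name.
#'
#' @param config list with components:
#' \describe{
#'   \item{met}{a [met_field], or a list `(path, format)` for [load_metfield()].}
#'   \item{traps}{trap-record data.frame (`site_id, lat, lon, date, count`) or CSV path.}
#'   \item{mask}{a [source_mask] or GeoJSON path.}
#'   \item{assays}{named list of [bioassay_table]s, or a bioassay CSV path;
#'     ignored when `intervals` is given.}
#'   \item{intervals}{data.frame `population, insecticide, lc50, lower, upper`
#'     (e.g. [load_toxicity_tables()]), bypassing the probit stage.}
#'   \item{dest_populations, source_populations}{character vectors splitting
#'     the interval populations into destinations and candidate sources.}
#'   \item{threshold}{event threshold, default 10.}
#'   \item{flight_cfg}{a [flight_config], default `flight_config()`.}
#'   \item{cell_size, origin}{fishnet parameters, defaults 0.5 and `c(0, 0)`.}
#'   \item{rule}{matching rule, default `"both_all"`.}
#'   \item{skip_trajectory}{run only the susceptibility half, default FALSE.}
#'   \item{out_dir}{optional directory for CSV/JSON stage outputs.}
#' }
#' @return list (class `hopper_report`): `events`, `endpoints`,
#'   `endpoint_audit`, `status_counts`, `density`, `intervals`, `groups`,
#'   `attribution`, `discrepancies`, `config_digest`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  flight <- cfg$flight_cfg %||% flight_config()
  threshold <- cfg$threshold %||% 10
  cell_size <- cfg$cell_size %||% 0.5
  origin <- cfg$origin %||% c(0, 0)
  rule <- cfg$rule %||% "both_all"
  skip_traj <- isTRUE(cfg$skip_trajectory)

  events <- endpoints <- audit <- status_counts <- grid <- NULL
  if (!skip_traj) {
    field <- stage("metfield", {
      if (inherits(cfg$met, "met_field")) cfg$met
      else load_metfield(cfg$met$path, cfg$met$format %||% "csv_grid")
    })
    traps <- stage("traps", {
      if (is.data.frame(cfg$traps)) cfg$traps
      else utils::read.csv(cfg$traps, stringsAsFactors = FALSE)
    })
    events <- stage("select_events", select_events(traps, threshold))
    res <- stage("trajectory", endpoints_for_events(field, events, flight))
    status_counts <- res$status_counts
    mask <- stage("mask", {
      if (inherits(cfg$mask, "source_mask")) cfg$mask else read_source_mask(cfg$mask)
    })
    filt <- stage("source_filter", filter_endpoints(res$endpoints, mask))
    endpoints <- filt$valid
    audit <- filt$audit
    grid <- stage("density_map",
                  if (nrow(endpoints)) fishnet_counts(endpoints, cell_size, origin)
                  else NULL)
  }

  intervals <- stage("bioassay_stats", {
    if (!is.null(cfg$intervals)) cfg$intervals
    else {
      assays <- if (is.character(cfg$assays)) read_bioassay_csv(cfg$assays) else cfg$assays
      do.call(rbind, lapply(assays, function(a) {
        f <- fit_probit(a)
        data.frame(population = f$site_id, insecticide = f$insecticide,
                   lc50 = f$lc50, lower = f$ci95[1], upper = f$ci95[2],
                   slope = f$beta, slope_se = f$se_beta, chi2 = f$chi2,
                   stringsAsFactors = FALSE)
      }))
    }
  })
  rownames(intervals) <- NULL

  dest <- intervals[intervals$population %in% cfg$dest_populations, , drop = FALSE]
  src <- intervals[intervals$population %in% cfg$source_populations, , drop = FALSE]
  if (!nrow(dest)) stop("pipeline stage 'attribution' failed: no destination intervals")

  groups <- stage("attribution", destination_groups(dest))
  attribution <- stage("attribution",
                       if (nrow(src)) match_sources(groups, dest, src, rule = rule)
                       else NULL)
  discrepancies <- stage("attribution", {
    if ("letter_printed" %in% names(intervals)) {
      dd <- lapply(unique(intervals$insecticide), function(k) {
        d <- cld_discrepancies(intervals[intervals$insecticide == k, , drop = FALSE])
        if (nrow(d)) cbind(insecticide = k, d) else NULL
      })
      dd <- dd[!vapply(dd, is.null, logical(1))]
      if (length(dd)) do.call(rbind, dd) else NULL
    } else NULL
  })

  report <- structure(list(
    events = events, endpoints = endpoints, endpoint_audit = audit,
    status_counts = status_counts, density = grid, intervals = intervals,
    groups = groups, attribution = attribution, discrepancies = discrepancies,
    config_digest = list(threshold = threshold, cell_size = cell_size,
                         rule = rule, skip_trajectory = skip_traj)),
    class = "hopper_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.hopper_report <- function(x, ...) {
  cat("hoppertrace run report\n")
  if (!is.null(x$events)) cat("  events:", nrow(x$events), "\n")
  if (!is.null(x$endpoint_audit)) {
    cat("  endpoint audit:",
        paste(names(x$endpoint_audit), x$endpoint_audit, sep = "=", collapse = " "), "\n")
  }
  cat("  groups:", paste(names(x$groups), vapply(x$groups, length, integer(1)),
                         sep = ":", collapse = " "), "\n")
  if (!is.null(x$attribution)) print(x$attribution)
  if (!is.null(x$discrepancies))
    cat("  letter/CI discrepant pairs:", nrow(x$discrepancies), "\n")
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) if (!is.null(df) && nrow(df))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wr(report$events, "events.csv")
  wr(report$endpoints, "endpoints_valid.csv")
  if (!is.null(report$density)) write_density_csv(report$density, file.path(out_dir, "density.csv"))
  wr(report$intervals, "intervals.csv")
  wr(report$discrepancies, "discrepancies.csv")
  js <- list(
    groups = report$groups,
    matches = if (!is.null(report$attribution)) report$attribution$matches,
    unmatched_sources = if (!is.null(report$attribution)) report$attribution$unmatched_sources,
    endpoint_audit = as.list(report$endpoint_audit %||% list()),
    config = report$config_digest)
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(out_dir)
}
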