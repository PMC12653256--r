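#' Do two LC50 confidence intervals overlap?
#'
#' Two populations are declared significantly different in susceptibility
#' (alpha = 0.05) when their 95\% CIs do not overlap; this predicate is the
#' currency of both the letter grouping and the source matching. Touching
#' intervals count as overlapping.
#'
#' @param a,b one-row data.frames (or lists) with `lower` and `upper`.
#' @return logical.
#' @export
ci_overlap <- function(a, b) {
  max(a$lower, b$lower) <= min(a$upper, b$upper)
}

overlap_matrix <- function(df) {
  n <- nrow(df)
  M <- matrix(TRUE, n, n, dimnames = list(df$population, df$population))
  for (i in seq_len(n)) for (j in seq_len(n))
    M[i, j] <- ci_overlap(df[i, ], df[j, ])
  M
}

#' Compact letter display from CI overlap
#'
#' Assigns lowercase letters to populations so that two populations share at
#' least one letter exactly when their 95\% CIs overlap (insertion-absorption
#' algorithm). Populations are processed in ascending LC50 order, so letter
#' naming is deterministic: letter "a" contains the most susceptible
#' populations.
#'
#' @param intervals data.frame with columns `population, lc50, lower, upper`
#'   (one row per population, a single insecticide).
#' @return object of class `group_assignment`: data.frame
#'   `(population, lc50, lower, upper, letters)` sorted by LC50, with
#'   attribute `rosters` (named list letter -> population vector).
#' @export
compact_letter_display <- function(intervals) {
  stopifnot(all(c("population", "lc50", "lower", "upper") %in% names(intervals)))
  if (anyDuplicated(intervals$population))
    stop("one interval per population required")
  df <- intervals[order(intervals$lc50), , drop = FALSE]
  rownames(df) <- NULL
  n <- nrow(df)
  M <- overlap_matrix(df)
  cols <- list(seq_len(n))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || M[i, j]) next
    hit <- vapply(cols, function(cl) i %in% cl && j %in% cl, logical(1))
    if (!any(hit)) next
    newcols <- list()
    for (k in seq_along(cols)) {
      if (!hit[k]) { newcols[[length(newcols) + 1L]] <- cols[[k]]; next }
      newcols[[length(newcols) + 1L]] <- setdiff(cols[[k]], i)
      newcols[[length(newcols) + 1L]] <- setdiff(cols[[k]], j)
    }
    # absorption: drop any column contained in another
    keep <- rep(TRUE, length(newcols))
    for (k in seq_along(newcols)) for (l in seq_along(newcols)) {
      if (k == l || !keep[k] || !keep[l]) next
      if (all(newcols[[k]] %in% newcols[[l]]) &&
          (length(newcols[[k]]) < length(newcols[[l]]) || k > l)) keep[k] <- FALSE
    }
    cols <- newcols[keep]
  }
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  letts <- letters[seq_along(cols)]
  df$letters <- vapply(seq_len(n), function(i)
    paste(letts[vapply(cols, function(cl) i %in% cl, logical(1))], collapse = ""),
    character(1))
  rosters <- stats::setNames(lapply(cols, function(cl) df$population[cl]), letts)
  structure(df, class = c("group_assignment", "data.frame"), rosters = rosters)
}

#' Discrepancies between printed letters and strict CI overlap
#'
#' Compares a published letter annotation with the pairwise CI-overlap
#' relation: a pair is discrepant when the printed letters imply a different
#' significance verdict than strict interval overlap. Discrepancies are
#' reported, never silently reconciled.
#'
#' @param intervals data.frame with `population, lower, upper,
#'   letter_printed` (single insecticide).
#' @return data.frame `(pop_a, pop_b, printed_share_letter, cis_overlap)`
#'   over discrepant pairs (zero rows if none).
#' @export
cld_discrepancies <- function(intervals) {
  stopifnot("letter_printed" %in% names(intervals))
  n <- nrow(intervals)
  out <- list()
  share <- function(a, b)
    length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ov <- ci_overlap(intervals[i, ], intervals[j, ])
    sh <- share(intervals$letter_printed[i], intervals$letter_printed[j])
    if (ov != sh)
      out[[length(out) + 1L]] <- data.frame(
        pop_a = intervals$population[i], pop_b = intervals$population[j],
        printed_share_letter = sh, cis_overlap = ov, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(pop_a = character(), pop_b = character(),
                      printed_share_letter = logical(), cis_overlap = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Pooled susceptibility interval of a population group
#'
#' The group-level interval is the envelope of its members' intervals:
#' (minimum lower bound, maximum upper bound).
#'
#' @param member_intervals data.frame with `lower`, `upper` (>= 1 row).
#' @return numeric `c(lower, upper)` mg/L.
#' @export
pooled_interval <- function(member_intervals) {
  if (!nrow(member_intervals)) stop("empty member list")
  c(lower = min(member_intervals$lower), upper = max(member_intervals$upper))
}

#' Destination population groups from susceptibility patterns
#'
#' Computes a compact letter display per insecticide and partitions the
#' destination sites by their joint letter signature. Groups are named
#' "A", "B", ... in ascending order of mean LC50 for the first insecticide,
#' so group A is the most susceptible.
#'
#' @param intervals data.frame with `population, insecticide, lc50, lower,
#'   upper` covering every destination site for each insecticide.
#' @return named list of population vectors (the group rosters), with the
#'   per-insecticide `group_assignment`s as attribute `cld`.
#' @export
destination_groups <- function(intervals) {
  ins <- unique(intervals$insecticide)
  clds <- lapply(ins, function(k)
    compact_letter_display(intervals[intervals$insecticide == k, , drop = FALSE]))
  names(clds) <- ins
  pops <- unique(intervals$population)
  sig <- vapply(pops, function(p) paste(vapply(clds, function(cl)
    cl$letters[cl$population == p], character(1)), collapse = "|"), character(1))
  if (any(grepl("[a-z]{2,}", sig)))
    warning("ambiguous (multi-letter) destination site(s): ",
            paste(pops[grepl("[a-z]{2,}", sig)], collapse = ", "))
  rosters <- split(pops, sig)
  mean_lc <- vapply(rosters, function(r) {
    sub <- intervals[intervals$population %in% r &
                       intervals$insecticide == ins[1], ]
    mean(sub$lc50)
  }, numeric(1))
  rosters <- rosters[order(mean_lc)]
  names(rosters) <- LETTERS[seq_along(rosters)]
  attr(rosters, "cld") <- clds
  rosters
}

#' Match candidate sources to destination groups by CI overlap
#'
#' The congruence test: a candidate source population matches a destination
#' group when its LC50 confidence intervals are statistically
#' indistinguishable from the group's. Under the default `both_all` rule the
#' source's CI must overlap the CI of every member site of the group for
#' both insecticides; `either_all` requires this for at least one
#' insecticide; `both_pooled` compares against the group's pooled interval
#' instead of every member.
#'
#' @param groups named list of member population vectors (e.g. from
#'   [destination_groups()]).
#' @param dest_intervals data.frame `population, insecticide, lc50, lower,
#'   upper` for the destination sites.
#' @param source_intervals same columns for the candidate sources; every
#'   source must carry both insecticides.
#' @param rule `"both_all"`, `"either_all"` or `"both_pooled"`.
#' @return object of class `attribution_result`: list with `matches` (named
#'   list group -> matched source vector), `unmatched_sources`, `rule`, and
#'   `decisions` (long data.frame of every pairwise test).
#' @export
match_sources <- function(groups, dest_intervals, source_intervals,
                          rule = c("both_all", "either_all", "both_pooled")) {
  rule <- match.arg(rule)
  ins <- sort(unique(dest_intervals$insecticide))
  srcs <- unique(source_intervals$population)
  for (s in srcs) {
    have <- sort(unique(source_intervals$insecticide[source_intervals$population == s]))
    if (!all(ins %in% have))
      stop("source ", s, " lacks interval(s) for: ",
           paste(setdiff(ins, have), collapse = ", "))
  }
  decisions <- list()
  matches <- stats::setNames(vector("list", length(groups)), names(groups))
  for (g in names(groups)) {
    members <- groups[[g]]
    for (s in srcs) {
      per_ins <- logical(length(ins)); names(per_ins) <- ins
      for (k in ins) {
        si <- source_intervals[source_intervals$population == s &
                                 source_intervals$insecticide == k, ]
        if (rule == "both_pooled") {
          mi <- dest_intervals[dest_intervals$population %in% members &
                                 dest_intervals$insecticide == k, ]
          pool <- pooled_interval(mi)
          ok <- ci_overlap(si, list(lower = pool["lower"], upper = pool["upper"]))
          decisions[[length(decisions) + 1L]] <- data.frame(
            group = g, source = s, insecticide = k, member = "(pooled)",
            overlap = ok, stringsAsFactors = FALSE)
          per_ins[k] <- ok
        } else {
          oks <- vapply(members, function(m) {
            mi <- dest_intervals[dest_intervals$population == m &
                                   dest_intervals$insecticide == k, ]
            ci_overlap(si, mi)
          }, logical(1))
          decisions[[length(decisions) + 1L]] <- data.frame(
            group = g, source = s, insecticide = k, member = members,
            overlap = unname(oks), stringsAsFactors = FALSE)
          per_ins[k] <- all(oks)
        }
      }
      hit <- if (rule == "either_all") any(per_ins) else all(per_ins)
      if (hit) matches[[g]] <- c(matches[[g]], s)
    }
  }
  matched_any <- unique(unlist(matches))
  structure(list(matches = lapply(matches, function(x) x %||% character()),
                 unmatched_sources = setdiff(srcs, matched_any),
                 rule = rule, decisions = do.call(rbind, decisions)),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat("source attribution (rule:", x$rule, ")\n")
  for (g in names(x$matches))
    cat(sprintf("  %s <- {%s}\n", g, paste(x$matches[[g]], collapse = ", ")))
  if (length(x$unmatched_sources))
    cat("  unmatched sources:", paste(x$unmatched_sources, collapse = ", "), "\n")
  invisible(x)
}

#' Load the packaged toxicity tables
#'
#' Returns the packaged site-level LC50 tables for pymetrozine and
#' nitenpyram across the 15 Hunan (destination) and 11 Guangxi (candidate
#' source) populations: LC50 with 95\% CI (mg/L), slope with SE (per log10
#' mg/L), chi-square, and the published letter annotation.
#'
#' @param insecticide `"pymetrozine"`, `"nitenpyram"`, or `"both"` (default).
#' @return data.frame `(population, province, insecticide, lc50, lower,
#'   upper, slope, slope_se, chi2, letter_printed)`.
#' @export
load_toxicity_tables <- function(insecticide = c("both", "pymetrozine", "nitenpyram")) {
  insecticide <- match.arg(insecticide)
  want <- if (insecticide == "both") c("pymetrozine", "nitenpyram") else insecticide
  out <- do.call(rbind, lapply(want, function(k) {
    path <- system.file("extdata", paste0("toxicity_", k, ".csv"),
                        package = "hoppertrace", mustWork = TRUE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df$insecticide <- k
    df
  }))
  rownames(out) <- NULL
  out
}
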