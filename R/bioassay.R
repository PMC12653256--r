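#' Construct a dose-mortality bioassay table
#'
#' Represents one site x insecticide rice-stem-dip assay: treated groups at
#' strictly positive concentrations plus an untreated (distilled-water)
#' control. Replicates at the same concentration are pooled before fitting,
#' matching the one-fit-per-site analysis.
#'
#' @param conc concentrations, mg/L (strictly positive; >= 2 distinct; the
#'   reference design uses 5).
#' @param n_exposed,n_dead integer counts per row (`0 <= n_dead <= n_exposed`).
#' @param control_n,control_dead pooled control counts.
#' @param site_id,insecticide metadata strings.
#' @param scoring_time_h mortality scoring time, hours (168 for pymetrozine,
#'   96 for nitenpyram by convention; metadata).
#' @return object of class `bioassay_table`.
#' @export
bioassay_table <- function(conc, n_exposed, n_dead,
                           control_n = 0, control_dead = 0,
                           site_id = NA_character_, insecticide = NA_character_,
                           scoring_time_h = NA_real_) {
  if (any(conc <= 0)) stop("concentrations must be strictly positive")
  if (length(unique(conc)) < 2) stop("need >= 2 distinct concentrations")
  if (any(n_dead < 0) || any(n_dead > n_exposed) || control_dead > control_n ||
      control_dead < 0)
    stop("counts must satisfy 0 <= n_dead <= n_exposed")
  # pool replicates per concentration
  agg <- stats::aggregate(cbind(n_exposed, n_dead) ~ conc,
                          data = data.frame(conc, n_exposed, n_dead), FUN = sum)
  agg <- agg[order(agg$conc), ]
  structure(list(doses = agg, control_n = control_n, control_dead = control_dead,
                 site_id = site_id, insecticide = insecticide,
                 scoring_time_h = scoring_time_h),
            class = "bioassay_table")
}

#' Validate an assay by its control mortality
#'
#' An assay is discarded when control mortality exceeds the threshold
#' (strictly greater than 10\% by default; exactly 10\% passes).
#'
#' @param table a [bioassay_table].
#' @param max_control_mortality fraction (default 0.10).
#' @return `TRUE` (pass) or `FALSE` (discard).
#' @export
validate_assay <- function(table, max_control_mortality = 0.10) {
  if (table$control_n == 0) return(TRUE)
  (table$control_dead / table$control_n) <= max_control_mortality
}

#' Abbott's control-mortality correction
#'
#' Rescales treated mortality by natural (control) mortality:
#' `(p_obs - p_control) / (1 - p_control)`, clipped to `[0, 1]`.
#'
#' @param p_obs observed treated mortality fraction(s).
#' @param p_control control mortality fraction, `0 <= p_control < 1`.
#' @return corrected fraction(s) in `[0, 1]`.
#' @export
abbott_correct <- function(p_obs, p_control) {
  if (any(p_control < 0) || any(p_control >= 1))
    stop("p_control must be in [0, 1)")
  pmin(pmax((p_obs - p_control) / (1 - p_control), 0), 1)
}

#' Maximum-likelihood probit fit of a dose-mortality table
#'
#' Fits mortality = Phi(alpha + beta * log10(concentration)) by weighted
#' binomial maximum likelihood (probit link). Control mortality, when
#' present and within the validity threshold, is removed with Abbott's
#' correction before fitting. Returns the LC50 (`10^(-alpha/beta)`), its 95\%
#' Fieller confidence interval, the slope (per log10 mg/L) with standard
#' error, and a Pearson chi-square goodness-of-fit with `k - 2` degrees of
#' freedom. When `chi2 / df > 1` the fit is heterogeneous and downstream
#' interval estimates inflate the variance by the heterogeneity factor
#' `h = chi2 / df` and use Student-t critical values.
#'
#' @param table a [bioassay_table] that passed [validate_assay()].
#' @param ci_method `"fieller"` (default) or `"delta"`, see [lc50_ci()].
#' @return object of class `probit_fit` with elements `alpha`, `beta`,
#'   `se_beta`, `vcov`, `lc50`, `ci95`, `chi2`, `df`, `heterogeneity`,
#'   `converged`, `doses`.
#' @export
fit_probit <- function(table, ci_method = c("fieller", "delta")) {
  ci_method <- match.arg(ci_method)
  if (!validate_assay(table))
    stop("assay discarded: control mortality exceeds the validity threshold")
  d <- table$doses
  p_ctrl <- if (table$control_n > 0) table$control_dead / table$control_n else 0
  p_obs <- d$n_dead / d$n_exposed
  p_corr <- abbott_correct(p_obs, p_ctrl)
  if (all(p_corr == 0) || all(p_corr == 1))
    stop("complete separation: corrected mortality is ",
         if (all(p_corr == 0)) "0%" else "100%", " at every dose")
  x <- log10(d$conc)
  fit <- suppressWarnings(stats::glm(p_corr ~ x, weights = d$n_exposed,
                                     family = stats::binomial(link = "probit"),
                                     control = stats::glm.control(
                                       epsilon = 1e-10, maxit = 100)))
  if (!fit$converged) stop("probit fit did not converge in 100 iterations")
  cf <- stats::coef(fit)
  alpha <- unname(cf[1]); beta <- unname(cf[2])
  V <- stats::vcov(fit)
  if (!is.finite(beta) || beta <= 0)
    stop("invalid fit: slope must be positive, got ", format(beta))
  # Pearson chi-square on corrected counts vs fitted expectations
  eta <- alpha + beta * x
  e <- d$n_exposed * stats::pnorm(eta)
  o <- p_corr * d$n_exposed
  chi2 <- sum((o - e)^2 / (e * (1 - e / d$n_exposed)))
  df <- nrow(d) - 2L
  h <- if (df > 0) max(1, chi2 / df) else 1
  out <- structure(list(alpha = alpha, beta = beta,
                        se_beta = sqrt(V[2, 2] * h),
                        vcov = V, lc50 = 10^(-alpha / beta),
                        chi2 = chi2, df = df, heterogeneity = h,
                        converged = fit$converged,
                        site_id = table$site_id, insecticide = table$insecticide,
                        doses = cbind(d, p_corr = p_corr)),
                   class = "probit_fit")
  # an unbounded/degenerate interval does not invalidate the point estimate;
  # lc50_ci() raises the condition when called directly
  out$ci95 <- tryCatch(lc50_ci(out, method = ci_method),
                       error = function(e) {
                         warning(conditionMessage(e), call. = FALSE)
                         c(NA_real_, NA_real_)
                       })
  out
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("probit fit%s: LC50 = %.4g mg/L (95%% CI %.4g-%.4g)\n",
              if (is.na(x$site_id)) "" else paste0(" [", x$site_id, "]"),
              x$lc50, x$ci95[1], x$ci95[2]))
  cat(sprintf("  slope %.3f +/- %.3f per log10 mg/L; chi2 = %.3f on %d df (h = %.2f)\n",
              x$beta, x$se_beta, x$chi2, x$df, x$heterogeneity))
  invisible(x)
}

#' LC50 confidence interval (Fieller or delta method)
#'
#' Interval for the log10 LC50 `m = -alpha/beta`, back-transformed to mg/L.
#' Fieller's theorem (default) solves the exact-ratio quadratic; the delta
#' method uses the first-order variance of the ratio. When the fit is
#' overdispersed (`chi2/df > 1`) the variance matrix is inflated by the
#' heterogeneity factor before the interval is formed.
#'
#' @param fit a `probit_fit`.
#' @param level confidence level (default 0.95).
#' @param method `"fieller"` or `"delta"`.
#' @return numeric `c(lower, upper)` in mg/L.
#' @export
lc50_ci <- function(fit, level = 0.95, method = c("fieller", "delta")) {
  method <- match.arg(method)
  if (!isTRUE(fit$converged)) stop("cannot form interval: fit did not converge")
  if (fit$beta <= 0) stop("cannot form interval: slope <= 0")
  h <- fit$heterogeneity
  V <- fit$vcov * h
  crit <- stats::qnorm(1 - (1 - level) / 2)
  a <- -fit$alpha; b <- fit$beta
  va <- V[1, 1]; vb <- V[2, 2]; cab <- -V[1, 2]  # cov(-alpha, beta)
  m <- a / b
  if (method == "delta") {
    # var(m) = (va - 2 m cab + m^2 vb) / b^2
    se <- sqrt((va - 2 * m * cab + m^2 * vb)) / b
    return(10^(m + c(-1, 1) * crit * se))
  }
  g <- crit^2 * vb / b^2
  if (g >= 1)
    stop("Fieller interval unbounded: slope not distinguishable from zero (g = ",
         format(g), ")")
  # roots of (b^2 - t^2 vb) m^2 - 2 (ab - t^2 cab) m + (a^2 - t^2 va) = 0
  A <- b^2 - crit^2 * vb
  B <- -2 * (a * b - crit^2 * cab)
  C <- a^2 - crit^2 * va
  disc <- B^2 - 4 * A * C
  if (disc < 0) stop("Fieller interval empty (negative discriminant)")
  roots <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  10^roots
}

#' Read bioassay tables from CSV
#'
#' Expects columns `site_id, insecticide, conc_mg_L, n_exposed, n_dead,
#' is_control` (control rows have `is_control = TRUE` / 1 and their
#' `conc_mg_L` is ignored). Returns one [bioassay_table] per site x
#' insecticide.
#'
#' @param path CSV file path.
#' @return named list of `bioassay_table` objects (`site_id.insecticide`).
#' @export
read_bioassay_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "insecticide", "conc_mg_L", "n_exposed", "n_dead", "is_control")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("bioassay CSV missing column(s): ", paste(miss, collapse = ", "))
  df$is_control <- as.logical(df$is_control)
  out <- list()
  for (key in unique(paste(df$site_id, df$insecticide, sep = "."))) {
    sub <- df[paste(df$site_id, df$insecticide, sep = ".") == key, ]
    trt <- sub[!sub$is_control, ]; ctl <- sub[sub$is_control, ]
    out[[key]] <- bioassay_table(trt$conc_mg_L, trt$n_exposed, trt$n_dead,
                                 control_n = sum(ctl$n_exposed),
                                 control_dead = sum(ctl$n_dead),
                                 site_id = sub$site_id[1],
                                 insecticide = sub$insecticide[1])
  }
  out
}
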