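# independent oracle: maximize the binomial probit likelihood by grid search
# over (log10 LC50, slope), refining twice; no IRLS involved
grid_probit <- function(conc, n, dead) {
  x <- log10(conc)
  ll <- function(m, b) sum(dbinom(dead, n, pnorm(b * (x - m)), log = TRUE))
  m_rng <- range(x); b_rng <- c(0.1, 20)
  for (pass in 1:3) {
    ms <- seq(m_rng[1], m_rng[2], length.out = 60)
    bs <- seq(b_rng[1], b_rng[2], length.out = 60)
    sc <- outer(ms, bs, Vectorize(ll))
    ij <- which(sc == max(sc), arr.ind = TRUE)[1, ]
    m0 <- ms[ij[1]]; b0 <- bs[ij[2]]
    dm <- diff(m_rng) / 10; db <- diff(b_rng) / 10
    m_rng <- c(m0 - dm, m0 + dm); b_rng <- c(max(b0 - db, 1e-3), b0 + db)
  }
  list(lc50 = 10^m0, slope = b0)
}

test_that("assay validation discards only control mortality above 10%", {
  tb <- function(cd) bioassay_table(c(1, 3, 10, 30, 100), rep(80, 5),
                                    c(5, 20, 40, 60, 75),
                                    control_n = 80, control_dead = cd)
  expect_true(validate_assay(tb(8)))    # exactly 10%: not exceeded
  expect_false(validate_assay(tb(12)))  # 15%
  expect_true(validate_assay(tb(0)))
  expect_error(fit_probit(tb(12)), "discarded")
})

test_that("Abbott correction matches its closed form and clips", {
  expect_equal(abbott_correct(0.5, 0), 0.5)
  expect_equal(abbott_correct(0.55, 0.10), 0.50)
  expect_equal(abbott_correct(0.05, 0.10), 0)
  expect_equal(abbott_correct(1, 0.2), 1)
  expect_error(abbott_correct(0.5, 1), "p_control")
})

test_that("probit fit recovers data constructed exactly on the probit line", {
  # deaths at Phi(log10 c - 1): LC50 = 10, slope = 1 per log10
  tb <- bioassay_table(c(1, 10, 100), rep(10000, 3), c(1587, 5000, 8413))
  ft <- fit_probit(tb)
  expect_true(ft$converged)
  expect_equal(ft$beta, 1, tolerance = 1e-3)
  expect_equal(ft$lc50, 10, tolerance = 1e-3)
  expect_lt(ft$chi2, 0.01)
  expect_true(ft$ci95[1] < 10 && 10 < ft$ci95[2])
  # agreement with the independent grid-search oracle
  or <- grid_probit(c(1, 10, 100), rep(10000, 3), c(1587, 5000, 8413))
  expect_equal(ft$lc50, or$lc50, tolerance = 0.01)
  expect_equal(ft$beta, or$slope, tolerance = 0.02)
})

test_that("grid-search oracle and ML fit agree on noisy simulated assays", {
  for (s in 1:3) {
    g <- gen_bioassay(29.208, 3.090, seed = s)
    ft <- fit_probit(g)
    or <- grid_probit(g$doses$conc, g$doses$n_exposed, g$doses$n_dead)
    expect_equal(ft$lc50, or$lc50, tolerance = 0.02)
    expect_equal(ft$beta, or$slope, tolerance = 0.05)
  }
})

test_that("LC50 sits at a symmetric middle dose with 50% mortality", {
  tb <- bioassay_table(c(1, 10, 100), rep(1000, 3), c(100, 500, 900))
  expect_equal(fit_probit(tb)$lc50, 10, tolerance = 1e-6)
})

test_that("complete separation and missing variation are errors", {
  expect_error(fit_probit(bioassay_table(c(1, 10), c(80, 80), c(80, 80))),
               "separation")
  expect_error(fit_probit(bioassay_table(c(1, 10), c(80, 80), c(0, 0))),
               "separation")
})

test_that("LC50 is equivariant under concentration rescaling", {
  g <- gen_bioassay(29.208, 3.090, seed = 4)
  mg <- fit_probit(g)
  g_ug <- bioassay_table(g$doses$conc / 1000, g$doses$n_exposed, g$doses$n_dead)
  ug <- fit_probit(g_ug)
  expect_equal(ug$lc50 * 1000, mg$lc50, tolerance = 1e-8)
  expect_equal(ug$beta, mg$beta, tolerance = 1e-8)
})

test_that("Fieller and delta intervals agree when the slope is precise", {
  tb <- bioassay_table(c(1, 10, 100), rep(10000, 3), c(1587, 5000, 8413))
  ft <- fit_probit(tb)
  fe <- lc50_ci(ft, method = "fieller")
  de <- lc50_ci(ft, method = "delta")
  expect_equal(fe, de, tolerance = 5e-4)  # 3 significant figures
  # delta cross-check against MASS::dose.p on the same weighted glm
  skip_if_not_installed("MASS")
  x <- log10(ft$doses$conc)
  p <- ft$doses$p_corr
  gl <- suppressWarnings(glm(p ~ x, weights = ft$doses$n_exposed,
                             family = binomial(link = "probit")))
  dp <- MASS::dose.p(gl, p = 0.5)
  se_log <- as.numeric(attr(dp, "SE"))
  expect_equal(de, 10^(as.numeric(dp) + c(-1, 1) * qnorm(0.975) * se_log),
               tolerance = 1e-6)
})

test_that("a hopeless slope yields an unbounded Fieller interval error", {
  # tiny n and near-flat response: slope indistinguishable from zero
  tb <- bioassay_table(c(1, 10, 100), rep(6, 3), c(2, 3, 4))
  expect_warning(ft <- fit_probit(tb), "unbounded")
  expect_true(all(is.na(ft$ci95)))
  expect_error(lc50_ci(ft, method = "fieller"), "unbounded")
})

test_that("heterogeneity factor inflates intervals only when chi2/df > 1", {
  g <- gen_bioassay(29.208, 3.090, seed = 12)
  ft <- fit_probit(g)
  expect_gte(ft$heterogeneity, 1)
  expect_equal(ft$df, 3)
  if (ft$heterogeneity > 1) {
    plain <- ft; plain$heterogeneity <- 1
    expect_gt(diff(log(lc50_ci(ft))), diff(log(lc50_ci(plain))))
  }
})

test_that("chi-square is near zero when data are generated from the fitted model", {
  # large-n expectation-valued data
  x <- log10(c(2, 6, 18, 54, 162))
  p <- pnorm(2.5 * (x - log10(18)))
  tb <- bioassay_table(10^x, rep(1e5, 5), round(1e5 * p))
  expect_lt(fit_probit(tb)$chi2, 0.01)
})

test_that("bioassay CSV reader pools replicates and controls per site", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(site_id = "s1", insecticide = "pymetrozine",
                   conc_mg_L = c(rep(c(10, 30), each = 2), 0, 0),
                   n_exposed = 20, n_dead = c(4, 6, 14, 12, 1, 0),
                   is_control = c(rep(FALSE, 4), TRUE, TRUE))
  write.csv(df, path, row.names = FALSE)
  tabs <- read_bioassay_csv(path)
  expect_length(tabs, 1)
  tb <- tabs[[1]]
  expect_equal(tb$doses$n_exposed, c(40, 40))
  expect_equal(tb$doses$n_dead, c(10, 26))
  expect_equal(tb$control_n, 40)
  expect_equal(tb$control_dead, 1)
})
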