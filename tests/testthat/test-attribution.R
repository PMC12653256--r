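test_that("CI overlap matches the printed pairwise examples and is symmetric", {
  hj <- list(lower = 26.377, upper = 32.467)   # Hongjiang pymetrozine
  lz <- list(lower = 25.568, upper = 30.751)   # Longzhou
  lj <- list(lower = 38.525, upper = 46.867)   # Liujiang
  expect_true(ci_overlap(hj, lz))
  expect_false(ci_overlap(hj, lj))
  expect_true(ci_overlap(hj, hj))
  # touching intervals overlap
  expect_true(ci_overlap(list(lower = 1, upper = 2), list(lower = 2, upper = 3)))
  # symmetry on random intervals
  set.seed(21)
  for (i in 1:50) {
    a <- sort(runif(2)); b <- sort(runif(2))
    A <- list(lower = a[1], upper = a[2]); B <- list(lower = b[1], upper = b[2])
    expect_identical(ci_overlap(A, B), ci_overlap(B, A))
  }
})

test_that("letters are sound: shared letter iff overlapping CIs, any input", {
  set.seed(31)
  share <- function(a, b) length(intersect(strsplit(a, "")[[1]],
                                           strsplit(b, "")[[1]])) > 0
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    lo <- runif(n, 0, 10); hi <- lo + runif(n, 0.1, 4)
    iv <- mk_intervals(paste0("p", 1:n), (lo + hi) / 2, lo, hi)
    cl <- compact_letter_display(iv)
    for (i in 1:n) for (j in 1:n) {
      if (i >= j) next
      ov <- ci_overlap(cl[i, ], cl[j, ])
      expect_identical(share(cl$letters[i], cl$letters[j]), ov,
                       info = sprintf("rep %d pair %d-%d", rep, i, j))
    }
  }
})

test_that("degenerate letterings: all-disjoint and all-overlapping", {
  iv <- mk_intervals(c("x", "y", "z"), c(1, 5, 9), c(0.5, 4.5, 8.5), c(1.5, 5.5, 9.5))
  cl <- compact_letter_display(iv)
  expect_equal(cl$letters, c("a", "b", "c"))
  iv2 <- mk_intervals(c("x", "y", "z"), c(1, 1.2, 1.4), c(0.5, 0.6, 0.7), c(2, 2, 2))
  expect_equal(unique(compact_letter_display(iv2)$letters), "a")
})

test_that("the 15 destination sites split into exactly the three groups", {
  tabs <- hn_gx_tables()
  rosters_expect <- list(
    a = c("Hongjiang", "Linli", "Longshan", "Hanshou", "Zhijiang"),
    b = c("Dongan", "Shuangfeng", "Ningxiang", "Linxiang", "Xiangyin", "Qidong"),
    c = c("Daoxian", "Youxian", "Guiyang", "Yizhang"))
  for (k in c("pymetrozine", "nitenpyram")) {
    cl <- compact_letter_display(tabs$hn[tabs$hn$insecticide == k, ])
    ros <- attr(cl, "rosters")
    expect_length(ros, 3)
    for (l in names(rosters_expect))
      expect_setequal(ros[[l]], rosters_expect[[l]])
    # computed letters agree with the printed annotation for these sites
    expect_equal(cl$letters, cl$letter_printed)
  }
  groups <- destination_groups(tabs$hn)
  expect_equal(names(groups), c("A", "B", "C"))
  expect_setequal(groups$A, rosters_expect$a)
  expect_setequal(groups$B, rosters_expect$b)
  expect_setequal(groups$C, rosters_expect$c)
})

test_that("pooled group intervals reproduce the printed ranges", {
  tabs <- hn_gx_tables()
  groups <- destination_groups(tabs$hn)
  expect_pool <- function(g, k, lo, hi) {
    sub <- tabs$hn[tabs$hn$population %in% groups[[g]] & tabs$hn$insecticide == k, ]
    expect_equal(unname(pooled_interval(sub)), c(lo, hi))
  }
  expect_pool("A", "pymetrozine", 24.437, 35.801)
  expect_pool("B", "pymetrozine", 36.703, 48.100)
  expect_pool("C", "pymetrozine", 51.502, 58.522)
  expect_pool("A", "nitenpyram", 0.729, 1.181)
  expect_pool("B", "nitenpyram", 1.948, 3.056)
  expect_pool("C", "nitenpyram", 3.236, 4.613)
  # single member: its own interval
  one <- mk_intervals("x", 2, 1, 3)
  expect_equal(unname(pooled_interval(one)), c(1, 3))
  expect_error(pooled_interval(one[0, ]), "empty")
})

test_that("source matching under both_all reproduces the published attribution", {
  tabs <- hn_gx_tables()
  groups <- destination_groups(tabs$hn)
  m <- match_sources(groups, tabs$hn, tabs$gx, rule = "both_all")
  expect_setequal(m$matches$A, c("Longzhou", "Jinchengjiang"))
  expect_setequal(m$matches$B, c("Liujiang", "Xingbin", "Fangchenggang", "Hepu", "Bobai"))
  expect_setequal(m$matches$C, c("Zhaoping", "Babu", "Fangchenggang", "Hepu", "Bobai"))
  expect_setequal(m$unmatched_sources, c("Quanzhou", "Yongfu"))
  # the decision matrix records every pairwise test
  expect_equal(sort(unique(m$decisions$group)), c("A", "B", "C"))
  expect_true(all(table(m$decisions$source, m$decisions$group) > 0))
})

test_that("matching rules behave as documented on constructed cases", {
  dest <- rbind(mk_intervals(c("d1", "d2"), c(1, 1.2), c(0.8, 1.0), c(1.2, 1.4)),
                mk_intervals(c("d1", "d2"), c(10, 12), c(8, 10), c(12, 14),
                             insecticide = "nitenpyram"))
  groups <- list(A = c("d1", "d2"))
  # source overlapping on one insecticide only
  src <- rbind(mk_intervals("s", 1.1, 0.9, 1.3),
               mk_intervals("s", 30, 25, 35, insecticide = "nitenpyram"))
  expect_length(match_sources(groups, dest, src, "both_all")$matches$A, 0)
  expect_equal(match_sources(groups, dest, src, "either_all")$matches$A, "s")
  # pooled rule can match where the member-wise rule fails
  dest2 <- rbind(mk_intervals(c("d1", "d2"), c(1, 3), c(0.8, 2.8), c(1.2, 3.2)),
                 mk_intervals(c("d1", "d2"), c(10, 12), c(8, 10), c(12, 14),
                              insecticide = "nitenpyram"))
  src2 <- rbind(mk_intervals("s", 2, 1.5, 2.5),
                mk_intervals("s", 11, 9, 13, insecticide = "nitenpyram"))
  expect_length(match_sources(groups, dest2, src2, "both_all")$matches$A, 0)
  expect_equal(match_sources(groups, dest2, src2, "both_pooled")$matches$A, "s")
  # a source lacking one insecticide is a data error
  expect_error(match_sources(groups, dest, src[1, ], "both_all"), "lacks interval")
})

test_that("printed-letter vs strict-overlap discrepancies are surfaced, not hidden", {
  tabs <- hn_gx_tables()
  nit <- tabs$all[tabs$all$insecticide == "nitenpyram", ]
  d <- cld_discrepancies(nit)
  key <- paste(pmin(d$pop_a, d$pop_b), pmax(d$pop_a, d$pop_b))
  expect_true("Xingbin Youxian" %in% key)
  expect_true("Babu Xingbin" %in% key)
  # the discrepancy does not alter the match result (checked above); and a
  # fully consistent table reports none
  clean <- mk_intervals(c("x", "y"), c(1, 5), c(0.5, 4.5), c(1.5, 5.5))
  clean$letter_printed <- c("a", "b")
  expect_equal(nrow(cld_discrepancies(clean)), 0)
})
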