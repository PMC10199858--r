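test_that("group summaries follow the stated conventions", {
  s <- summarizeGroup(c(1, 2, 3, 4, 5), "nonparametric")
  expect_equal(c(s$central, s$spread_lo, s$spread_hi), c(3, 2, 4))
  s0 <- summarizeGroup(c(0, 0, 0), "parametric")
  expect_equal(c(s0$central, s0$spread_hi - s0$central), c(0, 0))
  expect_error(summarizeGroup(numeric(0)), "empty")
  ## published per-patient means: the lowest patient sits at 0.83
  ratios <- referenceCohortSummaries()$patient_mean_t2p_138h
  expect_equal(min(ratios), 0.83)
})

test_that("one-way ANOVA matches the textbook sums-of-squares oracle", {
  groups <- list(A = c(1, 2, 3), B = c(2, 3, 4), C = c(10, 11, 12))
  res <- compareParametric(groups)
  ## hand-computed mean squares
  gm <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(res$global_stat, f_oracle, tolerance = 1e-9)
  expect_equal(unname(res$df), c(2, 6))
  ## Tukey: the far group separates, the near pair does not
  pw <- res$pairwise
  expect_lt(pw$p_adjusted[pw$pair == "A vs C"], 0.05)
  expect_lt(pw$p_adjusted[pw$pair == "B vs C"], 0.05)
  expect_gt(pw$p_adjusted[pw$pair == "A vs B"], 0.05)

  ## two identical groups: F = 0
  expect_equal(compareParametric(list(A = c(1, 2, 3),
                                      B = c(1, 2, 3)))$global_stat, 0)
  expect_error(compareParametric(list(A = c(2, 2), B = c(2, 2))), "identical")
})

test_that("rank-sum p-values agree with full enumeration for small groups", {
  res <- compareNonparametric(list(A = c(1, 2, 3), B = c(4, 5, 6)))
  expect_equal(res$pairwise$p_raw, 0.1)  # 2/20 extreme orderings, doubled
  expect_equal(res$pairwise$p_raw, enumRankSumP(c(1, 2, 3), c(4, 5, 6)))

  set.seed(77)
  for (i in 1:15) {
    nx <- sample(2:7, 1); ny <- sample(2:7, 1)
    x <- round(rnorm(nx), 6); y <- round(rnorm(ny, 0.5), 6)
    res <- compareNonparametric(list(a = x, b = y))
    expect_equal(res$pairwise$p_raw, enumRankSumP(x, y), tolerance = 1e-12)
  }
})

test_that("identical groups give H ~ 0 and capped Bonferroni p-values", {
  g <- list(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4), C = c(1, 2, 3, 4))
  res <- compareNonparametric(g)
  expect_lt(res$global_stat, 1e-9)
  expect_true(all(res$pairwise$p_adjusted == 1))
  ## Bonferroni multiplier equals the number of pairs (3 here)
  g2 <- list(A = c(1, 2, 3), B = c(4, 5, 6), C = c(2, 3, 5))
  res2 <- compareNonparametric(g2)
  expect_equal(res2$pairwise$p_adjusted,
               pmin(1, 3 * res2$pairwise$p_raw))
  expect_true(all(res2$pairwise$p_adjusted >= res2$pairwise$p_raw))
  expect_error(compareNonparametric(list(A = numeric(0), B = 1:3)),
               "non-empty")
})

test_that("saturation fractions and classifications are correct", {
  rep <- saturationReport(c(`4` = 30.06, `44` = 2.91, `604` = 0.67),
                          "4", "604")
  expect_equal(rep$fraction_blocked[rep$dose == "4"], 0)
  expect_equal(rep$fraction_blocked[rep$dose == "604"], 1)
  expect_equal(rep$classification[rep$dose == "604"], "full")
  ## hand arithmetic: 1 - (2.91 - 0.67)/(30.06 - 0.67)
  expect_equal(rep$fraction_blocked[rep$dose == "44"],
               1 - (2.91 - 0.67) / (30.06 - 0.67), tolerance = 1e-12)
  expect_equal(round(rep$fraction_blocked[rep$dose == "44"], 3), 0.924)
  expect_equal(rep$classification[rep$dose == "44"], "partial")
  expect_error(saturationReport(c(`4` = 1, `604` = 2), "4", "604"), "exceed")
})

test_that("dose comparison on a cohort orders the arms as expected", {
  up <- uptakeTable(noiseFreeCohort())
  cmp <- compareDoseGroups(up, time_h = 138)
  meds <- vapply(cmp$groups, median, 0)
  expect_true(meds[["4"]] > meds[["44"]])
  expect_true(meds[["4"]] > meds[["604"]])
  ## patient-clustered sensitivity mode aggregates to <= 6 values per arm
  cmp2 <- compareDoseGroups(up, time_h = 138, cluster = "patient")
  expect_true(all(lengths(cmp2$groups) <= 6))
})
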