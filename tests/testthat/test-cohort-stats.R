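test_that("score histogram counts totals per group", {
  sp <- specimen_table(
    c("a", "b", "c"), "g",
    ck13 = c("A", "C", "C"), ck17 = c("A", "C", "C"),
    ki67 = c("A", "C", "C"), ln5g2 = c("A1", "D", "D")
  )
  sc <- score_specimens(sp)
  h <- score_histogram(sc)
  expect_identical(h$n, 3L)
  expect_identical(unname(h$counts[c("0", "11")]), c(1L, 2L))
  expect_identical(sum(h$counts), h$n)

  # empty cohort: all-zero histogram with n = 0, not an error
  h0 <- score_histogram(sc[0, ])
  expect_identical(h0$n, 0L)
  expect_true(all(h0$counts == 0L))
})

test_that("proportion_at_or_above counts the cutoff tail", {
  one <- score_specimens(spt1("C", "C", "C", "D"))
  p <- proportion_at_or_above(one, 9)
  expect_identical(p$count, 1L)
  expect_identical(p$fraction, 1)
  expect_identical(p$percent, 100L)
  expect_error(proportion_at_or_above(one[0, ], 9), "empty")

  # non-increasing in the cutoff
  sc <- score_specimens(build_discovery_fixture())
  fracs <- vapply(0:11, function(ct) proportion_at_or_above(sc, ct)$fraction, numeric(1))
  expect_true(all(diff(fracs) <= 0))
  expect_identical(fracs[1], 1)
})

test_that("pattern prevalence tabulates calls with display percents", {
  fx <- build_discovery_fixture()
  prev <- pattern_prevalence(fx, "LN5G2", group = "OVC")
  expect_identical(prev$n, 33L)
  expect_identical(
    unname(prev$counts[c("A1", "A2", "B", "C", "D")]),
    c(1L, 0L, 15L, 12L, 5L)
  )
  expect_identical(unname(prev$percent[c("B", "C", "D")]), c(45L, 36L, 15L))

  prev2 <- pattern_prevalence(fx, "CK17", group = "OSCC")
  expect_identical(unname(prev2$counts), c(0L, 8L, 13L))
  expect_identical(unname(prev2$percent[c("B", "C")]), c(38L, 62L))

  expect_error(pattern_prevalence(fx, "CK13", group = "nonexistent"), "no specimens")
  gap <- specimen_table("s", "g", "A", "A", NA, "A1")
  expect_error(pattern_prevalence(gap, "KI67"), "missing KI67.*s")
})

test_that("collapse_to_indicator dichotomizes and conserves counts", {
  fx <- build_discovery_fixture()
  prev <- pattern_prevalence(fx, "LN5G2", group = "OVC")
  d <- collapse_to_indicator(prev, "D")
  expect_identical(d$in_count, 5L)
  expect_identical(d$out_count, 28L)
  pos <- collapse_to_indicator(prev, c("B", "C", "D"))
  expect_identical(pos$in_count, 32L)
  expect_identical(pos$percent, 97L)
  full <- collapse_to_indicator(prev, pattern_levels("LN5G2"))
  expect_identical(full$in_count, prev$n)
  expect_identical(full$out_count, 0L)

  # conservation over every subset of labels
  labels <- pattern_levels("LN5G2")
  for (k in 1:5) {
    combos <- utils::combn(labels, k, simplify = FALSE)
    for (set in combos) {
      ind <- collapse_to_indicator(prev, set)
      expect_identical(ind$in_count + ind$out_count, prev$n)
    }
  }
})

test_that("2x2 comparison is an uncorrected Pearson chi-square", {
  fx <- build_discovery_fixture()
  ovc <- pattern_prevalence(fx, "LN5G2", group = "OVC")
  oscc <- pattern_prevalence(fx, "LN5G2", group = "OSCC")
  res <- compare_pattern_proportions(ovc, oscc, "D")
  # shortcut formula N(ad-bc)^2 / (row1 row2 col1 col2) on [[5,28],[12,9]]
  expect_equal(res$chi_square, 54 * (5 * 9 - 28 * 12)^2 / (33 * 21 * 17 * 37),
    tolerance = 1e-12
  )
  expect_equal(res$p_value, 0.0012, tolerance = 0.05)
  expect_identical(res$df, 1L)

  # identical proportions give a null statistic
  pa <- pb <- ovc
  expect_equal(compare_pattern_proportions(pa, pb, "D")$chi_square, 0)
  expect_equal(compare_pattern_proportions(pa, pb, "D")$p_value, 1)

  # degenerate margins error
  allpos <- pattern_prevalence(fx, "LN5G2", group = "OSCC")
  expect_error(
    compare_pattern_proportions(allpos, allpos, pattern_levels("LN5G2")),
    "degenerate"
  )
  expect_error(compare_pattern_proportions(ovc, pattern_prevalence(fx, "CK13", group = "OVC"), "C"),
    "different markers"
  )
})

test_that("chi-square agrees with brute-force expected counts on random tables", {
  set.seed(20260920)
  for (i in 1:1000) {
    tab <- matrix(sample(1:40, 4, replace = TRUE), 2, 2)
    res <- oralscore:::contingency_2x2(tab)
    expect_equal(res$chi_square, oracle_chisq(tab), tolerance = 1e-9)
    expect_equal(res$p_value, pchisq(oracle_chisq(tab), df = 1, lower.tail = FALSE),
      tolerance = 1e-12
    )
  }
})

test_that("Yates correction shrinks the statistic when requested", {
  fx <- build_discovery_fixture()
  ovc <- pattern_prevalence(fx, "KI67", group = "OVC")
  oscc <- pattern_prevalence(fx, "KI67", group = "OSCC")
  plain <- compare_pattern_proportions(ovc, oscc, "C")
  yates <- compare_pattern_proportions(ovc, oscc, "C", correct = TRUE)
  expect_lt(yates$chi_square, plain$chi_square)
  expect_gt(yates$p_value, plain$p_value)
})

test_that("r x 2 chi-square over full distributions matches chisq.test", {
  fx <- build_discovery_fixture()
  ovc <- pattern_prevalence(fx, "CK17", group = "OVC")
  oscc <- pattern_prevalence(fx, "CK17", group = "OSCC")
  res <- compare_pattern_distributions(ovc, oscc)
  expect_identical(res$df, 2L)
  expect_equal(res$chi_square, oracle_chisq(res$table), tolerance = 1e-9)
})

test_that("select_cutoff returns the largest cutoff meeting coverage", {
  sc <- score_specimens(build_discovery_fixture())
  h <- score_histogram(sc)
  expect_identical(select_cutoff(h, 0.95), 9L)

  # degenerate histogram all at 11
  all11 <- score_histogram(score_specimens(specimen_table(
    c("x", "y"), "g", c("C", "C"), c("C", "C"), c("C", "C"), c("D", "D")
  )))
  expect_identical(select_cutoff(all11, 0.95), 11L)

  # full coverage keeps every specimen: the fixture's minimum total is 5
  expect_identical(select_cutoff(h, 1.0), min(sc$total_score))

  # non-increasing in min_coverage
  cuts <- vapply(
    c(0.05, 0.25, 0.5, 0.75, 0.9, 0.95, 0.99, 1),
    function(mc) select_cutoff(h, mc), integer(1)
  )
  expect_true(all(diff(cuts) <= 0))
  expect_error(select_cutoff(score_histogram(sc[0, ])), "empty")
})
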