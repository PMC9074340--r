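test_that("prevalence specs validate their probabilities", {
  good <- prevalence_spec("toy", list(
    CK13 = c(B = 0.4, C = 0.6), CK17 = c(C = 1),
    KI67 = c(B = 0.5, C = 0.5), LN5G2 = c(B = 0.3, C = 0.3, D = 0.4)
  ))
  expect_s3_class(good, "prevalence_spec")
  expect_equal(unname(good$per_marker$CK17), c(0, 0, 1))
  expect_error(
    prevalence_spec("bad", list(
      CK13 = c(B = 0.4, C = 0.7), CK17 = c(C = 1),
      KI67 = c(B = 1), LN5G2 = c(D = 1)
    )),
    "sum to 1"
  )
  expect_error(
    prevalence_spec("bad", list(CK13 = c(C = 1))),
    "lacks marker"
  )
})

test_that("generated cohorts are seeded, reproducible and follow the spec", {
  spec <- default_prevalence("OSCC")
  expect_identical(nrow(generate_pattern_cohort(spec, 0, seed = 1)), 0L)

  a <- generate_pattern_cohort(spec, 50, seed = 1)
  b <- generate_pattern_cohort(spec, 50, seed = 1)
  c <- generate_pattern_cohort(spec, 50, seed = 2)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))

  # degenerate multinomial: all mass on one label
  deg <- prevalence_spec("deg", list(
    CK13 = c(C = 1), CK17 = c(C = 1), KI67 = c(C = 1), LN5G2 = c(D = 1)
  ))
  d <- generate_pattern_cohort(deg, 25, seed = 3)
  expect_true(all(d$ck13 == "C" & d$ln5g2 == "D"))

  # law of large numbers: empirical frequencies near the spec at n = 10000
  big <- generate_pattern_cohort(spec, 10000, seed = 4)
  for (m in markers()) {
    prev <- pattern_prevalence(big, m)
    emp <- prev$counts / prev$n
    expect_true(all(abs(emp - spec$per_marker[[m]]) < 0.02), info = m)
  }
})

test_that("generated marginals pass a goodness-of-fit test against the spec", {
  spec <- default_prevalence("OVC")
  big <- generate_pattern_cohort(spec, 10000, seed = 5)
  for (m in markers()) {
    p <- spec$per_marker[[m]]
    keep <- p > 0
    counts <- pattern_prevalence(big, m)$counts[keep]
    gof <- suppressWarnings(chisq.test(counts, p = p[keep] / sum(p[keep])))
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("the discovery fixture reproduces every published marginal count", {
  fx <- build_discovery_fixture()
  expect_identical(nrow(fx), 54L)
  expect_identical(sum(fx$group == "OVC"), 33L)
  expect_identical(sum(fx$group == "OSCC"), 21L)
  expected <- oralscore:::discovery_marginals()
  for (g in c("OVC", "OSCC")) {
    for (m in markers()) {
      prev <- pattern_prevalence(fx, m, group = g)
      expect_identical(
        as.numeric(prev$counts), unname(expected[[g]][[m]]),
        info = paste(g, m)
      )
    }
  }
})

test_that("the discovery fixture satisfies the documented joint constraints", {
  sc <- score_specimens(build_discovery_fixture())
  expect_identical(sum(sc$total_score >= 9), 52L)
  low <- sc[sc$total_score < 9, ]
  expect_true(all(low$group == "OVC"))
  # one sub-9 specimen is the single Ln5g2-negative one, the other the
  # CK13-B/CK17-A/Ln5g2-positive one
  expect_identical(sort(low$score_ln5g2), c(0L, 4L))
  pos_low <- low[low$score_ln5g2 == 4L, ]
  expect_identical(pos_low$ck13, "B")
  expect_identical(pos_low$ck17, "A")
  # every OSCC necessarily scores >= 9
  expect_true(all(sc$total_score[sc$group == "OSCC"] >= 9))
})

test_that("fixtures are deterministic across calls", {
  expect_identical(
    as.data.frame(build_discovery_fixture()),
    as.data.frame(build_discovery_fixture())
  )
  expect_identical(
    as.data.frame(build_validation_fixture()),
    as.data.frame(build_validation_fixture())
  )
  expect_identical(
    as.data.frame(build_cohort2_fixture()),
    as.data.frame(build_cohort2_fixture())
  )
})

test_that("the validation fixture realizes the 31/34 split with complete records", {
  fx <- build_validation_fixture()
  expect_identical(nrow(fx), 34L)
  expect_false(anyNA(as.data.frame(fx)[, c("ck13", "ck17", "ki67", "ln5g2")]))
  sc <- score_specimens(fx)
  expect_identical(sum(sc$total_score >= 9), 31L)
  expect_identical(sum(sc$total_score < 9), 3L)
})

test_that("the benign/malignant fixture separates cleanly at the cutoff", {
  fx <- build_cohort2_fixture()
  sc <- score_specimens(fx)
  malignant <- sc$group %in% c("OVC", "OSCC")
  expect_identical(sum(malignant), 11L)
  expect_identical(sum(!malignant), 11L)
  expect_true(all(sc$total_score[malignant] >= 9))
  expect_true(all(sc$total_score[!malignant] < 9))
  expect_identical(sum(sc$group == "OVC"), 2L)
  expect_identical(sum(sc$group == "OSCC"), 9L)
  expect_identical(sum(sc$group == "papilloma"), 5L)
  expect_identical(sum(sc$group == "fibroma_polyp"), 4L)
  expect_identical(sum(sc$group == "fordyce"), 1L)
})

test_that("rater-pair generation flips calls at the requested rate", {
  fx <- build_discovery_fixture()
  # rate 0: identical raters
  rp0 <- generate_rater_pairs(fx, 0, seed = 1)
  for (m in markers()) {
    expect_identical(cohens_kappa(rp0, m)$kappa, 1)
  }
  # rate 1: every call flipped, observed agreement 0
  rp1 <- generate_rater_pairs(fx, 1, seed = 1)
  for (m in markers()) {
    expect_identical(cohens_kappa(rp1, m)$observed_agreement, 0)
  }
  # rate 0.1 at n = 5000: empirical flip fraction within 1 point of 10%
  big <- generate_pattern_cohort(default_prevalence("OVC"), 5000, seed = 6)
  rp <- generate_rater_pairs(big, 0.1, seed = 7)
  flips <- mean(c(
    rp$ck13_a != rp$ck13_b, rp$ck17_a != rp$ck17_b,
    rp$ki67_a != rp$ki67_b, rp$ln5g2_a != rp$ln5g2_b
  ))
  expect_lt(abs(flips - 0.1), 0.01)
  # reproducible per seed
  expect_identical(
    as.data.frame(generate_rater_pairs(fx, 0.3, seed = 9)),
    as.data.frame(generate_rater_pairs(fx, 0.3, seed = 9))
  )
})

test_that("expression-pair generation is seeded and respects its parameters", {
  fc <- c(KRT13 = 0.5, KRT17 = 2)
  a <- generate_expression_pairs(fc, 40, 0.25, seed = 8)
  b <- generate_expression_pairs(fc, 40, 0.25, seed = 8)
  expect_identical(a, b)
  expect_identical(nrow(a), 80L)
  expect_true(all(a$normal > 0 & a$tumor > 0))

  expect_error(generate_expression_pairs(c(G = -1), 10, 0.2, 1), "positive")
  expect_error(generate_expression_pairs(c(G = 1), 1, 0.2, 1), "at least 2")
  expect_error(generate_expression_pairs(c(1, 2), 10, 0.2, 1), "named")

  # a null fold change gives near-flat results at large n
  null <- generate_expression_pairs(c(G = 1), 2000, 0.25, seed = 10)
  res <- paired_log_t_test(null$normal, null$tumor)
  expect_lt(abs(res$mean_log_diff), 0.05)

  # reciprocal fold changes differ by exactly log2(2) - log2(0.5) = 2
  # under shared seed (identical baseline and noise draws)
  up <- generate_expression_pairs(c(G = 2), 40, 0.25, seed = 11)
  down <- generate_expression_pairs(c(G = 0.5), 40, 0.25, seed = 11)
  r_up <- paired_log_t_test(up$normal, up$tumor)
  r_down <- paired_log_t_test(down$normal, down$tumor)
  expect_equal(r_up$mean_log_diff - r_down$mean_log_diff, 2, tolerance = 1e-9)
})
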