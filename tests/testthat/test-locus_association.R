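test_that("odds ratio is the cross-product ratio with NA for zero products", {
  expect_equal(odds_ratio(contingency_2x2(13.00, 83.86, 2.00, 94.00)),
               7.286, tolerance = 0.01 / 7.286)
  expect_equal(odds_ratio(contingency_2x2(10, 10, 10, 10)), 1.0)
  expect_true(is.na(odds_ratio(contingency_2x2(15.41, 81.45, 0, 96))))
  expect_true(is.na(odds_ratio(contingency_2x2(0, 10, 0, 10))))
})

test_that("odds ratios of group-swapped tables are reciprocal", {
  set.seed(11)
  for (i in 1:25) {
    t <- contingency_2x2(sample(1:50, 1), sample(1:50, 1),
                         sample(1:50, 1), sample(1:50, 1))
    sw <- contingency_2x2(t[["n3"]], t[["n4"]], t[["n1"]], t[["n2"]])
    expect_equal(odds_ratio(t) * odds_ratio(sw), 1)
  }
})

test_that("Woolf interval reproduces published and hand-derived bounds", {
  ci <- woolf_ci(contingency_2x2(13.00, 83.86, 2.00, 94.00))
  expect_equal(unname(ci), c(1.597, 33.234), tolerance = 0.05 / 1.597)
  ci2 <- woolf_ci(contingency_2x2(10, 10, 10, 10))
  expect_equal(unname(ci2), c(exp(-1.96 * sqrt(0.4)), exp(1.96 * sqrt(0.4))),
               tolerance = 1e-9)
  expect_equal(unname(ci2), c(0.2895, 3.4541), tolerance = 1e-3)
  expect_true(all(is.na(woolf_ci(contingency_2x2(0, 5, 5, 5)))))
})

test_that("uncorrected chi-square matches the closed form and published value", {
  expect_equal(chi2_2x2(contingency_2x2(45.53, 51.33, 93.00, 3.00)),
               59.251, tolerance = 0.15 / 59.251)
  expect_equal(chi2_2x2(contingency_2x2(10, 20, 5, 10)), 0)
  expect_equal(chi2_2x2(contingency_2x2(10, 20, 20, 10)), 20 / 3,
               tolerance = 1e-9)
  expect_error(chi2_2x2(contingency_2x2(0, 0, 5, 5)), "degenerate margin")
})

test_that("chi-square is invariant under simultaneous row and column swaps", {
  set.seed(12)
  for (i in 1:20) {
    v <- sample(1:40, 4, replace = TRUE)
    t <- contingency_2x2(v[1], v[2], v[3], v[4])
    swapped <- contingency_2x2(v[4], v[3], v[2], v[1])
    expect_equal(chi2_2x2(t), chi2_2x2(swapped))
  }
})

test_that("1-df chi-square p-values match published and textbook values", {
  expect_equal(chi2_pvalue_df1(7.182), 0.0074, tolerance = 0.0002 / 0.0074)
  expect_equal(chi2_pvalue_df1(0), 1.0)
  expect_equal(chi2_pvalue_df1(3.841), 0.0500, tolerance = 0.0005 / 0.05)
})

test_that("Fisher exact test matches enumeration on frozen examples", {
  expect_equal(fisher_exact_2x2(contingency_2x2(5, 5, 5, 5)), 1.0)
  expect_equal(fisher_exact_2x2(contingency_2x2(0, 10, 10, 0)),
               2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(contingency_2x2(3, 7, 7, 3)), 0.17889,
               tolerance = 1e-5 / 0.17889)
  expect_error(fisher_exact_2x2(contingency_2x2(1.5, 2, 3, 4)),
               "round_half_even")
})

test_that("Fisher exact test agrees with the choose() oracle and stats::fisher.test", {
  set.seed(13)
  for (i in 1:100) {
    repeat {
      v <- as.integer(stats::rmultinom(1, sample(4:40, 1), rep(1, 4)))
      if (sum(v) > 0) break
    }
    p <- fisher_exact_2x2(contingency_2x2(v[1], v[2], v[3], v[4]))
    expect_equal(p, fisher_oracle(v[1], v[2], v[3], v[4]), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(matrix(v, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("half-even rounding produces integer tables", {
  r <- round_half_even_2x2(contingency_2x2(0.5, 1.5, 2.49, 3.51))
  expect_equal(unname(unclass(r)), c(0, 2, 2, 4))
})

test_that("carrier contingency pools het and hom_alt against hom_ref", {
  codes <- matrix(c(rep(1L, 3), rep(0L, 7), rep(1L, 1), rep(0L, 9)), ncol = 1)
  gt <- gt_from_codes(codes, c(rep("tolerant", 10), rep("intolerant", 10)))
  t <- carrier_contingency(gt, "L1")
  expect_equal(unname(unclass(t)), c(3, 7, 1, 9))
  # hom_alt counts as carrier; missing excluded from all cells
  codes2 <- matrix(c(2L, 1L, 0L, NA, 0L, 0L), ncol = 1)
  gt2 <- gt_from_codes(codes2, c(rep("tolerant", 3), rep("intolerant", 3)))
  expect_equal(unname(unclass(carrier_contingency(gt2, "L1"))), c(2, 1, 0, 2))
  # all hom_ref
  gt3 <- gt_from_codes(matrix(0L, 8, 1),
                       rep(c("tolerant", "intolerant"), each = 4))
  expect_equal(unname(unclass(carrier_contingency(gt3, "L1"))), c(0, 4, 0, 4))
  # a group with no typed sample errors
  gt4 <- gt_from_codes(matrix(c(1L, NA), ncol = 1),
                       c("tolerant", "intolerant"))
  expect_error(carrier_contingency(gt4, "L1"), "typed sample")
  # per-genotype coding gives the 3-row count table
  m <- carrier_contingency(gt2, "L1", coding = "genotype")
  expect_equal(unname(m[, "tolerant"]), c(1, 1, 1))
  expect_equal(unname(m[, "intolerant"]), c(2, 0, 0))
})

test_that("logistic slope equals ln(OR) and its SE the Woolf SE", {
  lg <- logistic_from_table(contingency_2x2(30, 20, 10, 40))
  expect_equal(lg$log_or, log(6), tolerance = 1e-6)
  lg0 <- logistic_from_table(contingency_2x2(10, 10, 20, 20))
  expect_equal(lg0$log_or, 0, tolerance = 1e-6)
  lg1 <- logistic_from_table(contingency_2x2(10, 10, 10, 10))
  expect_equal(lg1$se, sqrt(0.4), tolerance = 1e-6)
  sep <- logistic_from_table(contingency_2x2(0, 10, 5, 5))
  expect_identical(sep$flag, "separation")
  expect_true(is.na(sep$log_or))
  # identity holds across random nondegenerate tables
  set.seed(14)
  for (i in 1:50) {
    v <- sample(1:60, 4, replace = TRUE)
    t <- contingency_2x2(v[1], v[2], v[3], v[4])
    lg <- logistic_from_table(t)
    expect_equal(lg$log_or, log(odds_ratio(t)), tolerance = 1e-6)
    expect_equal(lg$se, sqrt(sum(1 / t)), tolerance = 1e-6)
  }
})

test_that("the per-locus association table wires all statistics together", {
  cfg <- sim_config(n_tolerant = 40, n_intolerant = 40, seed = 9,
                    missing_rate = 0)
  gt <- simulate_population(cfg)
  tab <- association_table(gt)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$p_pearson >= 0 & tab$p_pearson <= 1, na.rm = TRUE))
  expect_true(all(tab$p_fisher >= 0 & tab$p_fisher <= 1))
  # log_or agrees with ln(odds_ratio) wherever both are defined
  ok <- !is.na(tab$log_or) & !is.na(tab$odds_ratio)
  expect_equal(tab$log_or[ok], log(tab$odds_ratio[ok]), tolerance = 1e-6)
  # the tolerant group is enriched for mutant carriers under the generator
  expect_true(all(tab$odds_ratio > 1, na.rm = TRUE))
})
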