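two_loci <- snp_loci(c("A", "B"), c("G", "G"), c("T", "T"))

test_that("phase enumeration yields max(1, 2^(h-1)) consistent pairs", {
  loci4 <- default_loci()
  # all homozygous: one pair, the homozygous haplotype twice
  cfg0 <- enumerate_phase_configurations(c(0L, 0L, 2L, 0L), loci4)
  expect_length(cfg0, 1)
  expect_identical(cfg0[[1]], c("GGTG", "GGTG"))
  # one het: one pair
  cfg1 <- enumerate_phase_configurations(c(1L, 0L, 0L, 0L), loci4)
  expect_length(cfg1, 1)
  expect_setequal(cfg1[[1]], c("GGGG", "TGGG"))
  # two het: cis and trans
  cfg2 <- enumerate_phase_configurations(c(1L, 1L, 0L, 0L), loci4)
  expect_length(cfg2, 2)
  pairs <- lapply(cfg2, sort)
  expect_true(any(vapply(pairs, identical, TRUE, y = c("GGGG", "TCGG"))))
  expect_true(any(vapply(pairs, identical, TRUE, y = c("GCGG", "TGGG"))))
  # h het loci: 2^(h-1) distinct pairs, all consistent with the genotype
  for (h in 1:4) {
    codes <- c(rep(1L, h), rep(0L, 4 - h))
    cfg <- enumerate_phase_configurations(codes, loci4)
    expect_length(cfg, max(1, 2^(h - 1)))
    expect_equal(anyDuplicated(vapply(cfg, function(p)
      paste(sort(p), collapse = "|"), "")), 0)
    for (p in cfg) {
      a1 <- strsplit(p[1], "")[[1]]; a2 <- strsplit(p[2], "")[[1]]
      recoded <- (a1 == loci4$alt) + (a2 == loci4$alt)
      expect_equal(as.integer(recoded), codes)
    }
  }
})

test_that("single-locus EM reduces to allele counting", {
  codes <- matrix(c(rep(0L, 20), rep(1L, 20), rep(2L, 10)), ncol = 1)
  gt <- gt_from_codes(codes, rep("tolerant", 50))
  em <- em_haplotype_frequencies(gt)
  expect_equal(unname(em$frequencies[c("G", "T")]), c(0.6, 0.4),
               tolerance = 1e-9)
})

test_that("EM solves the classic double-heterozygote phase problem", {
  # 30 hom GG/GG, 10 hom TT/TT, 10 double het at two loci
  codes <- rbind(matrix(0L, 30, 2), matrix(2L, 10, 2), matrix(1L, 10, 2))
  gt <- gt_from_codes(codes, rep("tolerant", 50), loci = two_loci)
  em <- em_haplotype_frequencies(gt)
  expect_equal(unname(em$frequencies["GG"]), 0.70, tolerance = 1e-4 / 0.7)
  expect_equal(unname(em$frequencies["TT"]), 0.30, tolerance = 1e-4 / 0.3)
  expect_lt(sum(em$frequencies[c("GT", "TG")]), 1e-4)
  # independent oracle: grid search of the multinomial likelihood over the
  # symmetric slice of the simplex (f_GT = f_TG by exchangeability)
  grid <- seq(0, 1, by = 0.005)
  best <- c(ll = -Inf, g = NA, u = NA)
  for (g in grid) for (u in grid[grid <= 1 - g + 1e-12]) {
    t2 <- (1 - g - u) / 2
    ll <- 60 * log(g) + 20 * log(u) + 10 * log(2 * g * u + 2 * t2 * t2)
    if (is.finite(ll) && ll > best["ll"]) best <- c(ll = ll, g = g, u = u)
  }
  expect_equal(unname(em$frequencies["GG"]), unname(best["g"]),
               tolerance = 0.005 / 0.7)
  expect_equal(unname(em$frequencies["TT"]), unname(best["u"]),
               tolerance = 0.005 / 0.3)
})

test_that("without double heterozygotes EM equals direct gene counting", {
  codes <- rbind(matrix(c(1L, 0L), 10, 2, byrow = TRUE),
                 matrix(c(0L, 1L), 6, 2, byrow = TRUE),
                 matrix(0L, 14, 2))
  gt <- gt_from_codes(codes, rep("tolerant", 30), loci = two_loci)
  em <- em_haplotype_frequencies(gt)
  direct <- c(GG = (10 + 6 + 2 * 14) / 60, TG = 10 / 60, GT = 6 / 60)
  expect_equal(unname(em$frequencies[names(direct)]), unname(direct),
               tolerance = 1e-8)
})

test_that("EM log-likelihood is nondecreasing and stays on the simplex", {
  for (seed in c(2, 31, 77)) {
    cfg <- sim_config(n_tolerant = 60, n_intolerant = 60, seed = seed)
    gt <- simulate_population(cfg)
    for (grp in c("tolerant", "intolerant")) {
      em <- em_haplotype_frequencies(gt, grp)
      expect_true(all(diff(em$loglik_trace) >= -1e-9))
      expect_lt(abs(sum(em$frequencies) - 1), 1e-9)
      expect_true(all(em$frequencies >= 0))
      expect_lt(abs(sum(em$expected_counts) - 2 * em$n_used), 1e-6)
    }
  }
})

test_that("EM excludes individuals with missing calls and reports counts", {
  cfg <- sim_config(n_tolerant = 40, n_intolerant = 40, seed = 6,
                    missing_rate = 0.1)
  gt <- simulate_population(cfg)
  em <- em_haplotype_frequencies(gt, "tolerant")
  n_complete <- sum(!apply(
    is.na(gt$calls[gt$phenotype == "tolerant", ]), 1, any))
  expect_equal(em$n_used, n_complete)
  expect_equal(em$n_excluded, 40 - n_complete)
})

test_that("EM estimates are invariant to individual ordering", {
  cfg <- sim_config(n_tolerant = 50, n_intolerant = 50, seed = 8,
                    missing_rate = 0)
  gt <- simulate_population(cfg)
  em1 <- em_haplotype_frequencies(gt, "tolerant")
  set.seed(99)
  perm <- sample(length(gt$samples))
  gt2 <- genotype_table(gt$calls[perm, ], gt$loci, gt$phenotype[perm])
  em2 <- em_haplotype_frequencies(gt2, "tolerant")
  expect_equal(em1$frequencies, em2$frequencies, tolerance = 1e-10)
})

test_that("haplotype_distribution wraps published counts faithfully", {
  d <- table3_distributions()
  expect_lt(abs(sum(d$tol$frequencies) - 1), 1e-9)
  expect_equal(sum(d$tol$expected_counts), 98)
  expect_equal(sum(d$intol$expected_counts), 96)
  expect_equal(unname(d$tol$frequencies["GGGG"]), 45.53 / 98,
               tolerance = 1e-9)
})
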