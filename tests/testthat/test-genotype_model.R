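test_that("peak-ratio calling applies the het/noise thresholds", {
  expect_equal(call_genotype_from_peaks(1000, 500), "het")     # ratio 0.50
  expect_equal(call_genotype_from_peaks(1000, 100), "hom")     # ratio 0.10
  expect_equal(call_genotype_from_peaks(1000, 250), "missing") # 0.20-0.30 band
  expect_equal(call_genotype_from_peaks(1000, 300), "het")     # boundary >=
  expect_equal(call_genotype_from_peaks(1000, 199.9), "hom")   # just below
  # vectorised
  expect_equal(call_genotype_from_peaks(c(1000, 1000), c(500, 100)),
               c("het", "hom"))
  expect_warning(res <- call_genotype_from_peaks(0, 0), "no signal")
  expect_equal(res, "missing")
  expect_error(call_genotype_from_peaks(100, 200), "exceed")
  expect_error(call_genotype_from_peaks(100, 50, het_ratio = 0.2,
                                        noise_ratio = 0.3), "noise_ratio")
})

test_that("calling is monotone in the secondary peak height", {
  sec <- seq(0, 1000, by = 5)
  calls <- call_genotype_from_peaks(rep(1000, length(sec)), sec)
  rank <- c(hom = 1, missing = 2, het = 3)
  expect_true(all(diff(rank[calls]) >= 0))
})

test_that("allele frequencies count alt copies over typed genotypes", {
  gt <- gt_from_codes(matrix(1L, 10, 1))
  af <- allele_frequencies(gt, "L1")
  expect_equal(unname(af$freq), c(0.5, 0.5))
  # 32 samples, 4 alt alleles of 64 (4 hets)
  gt2 <- gt_from_codes(matrix(c(rep(1L, 4), rep(0L, 28)), ncol = 1))
  af2 <- allele_frequencies(gt2, "L1")
  expect_equal(af2$maf, 0.0625)
  expect_equal(af2$n_typed, 32)
  # missing excluded from the denominator
  gt3 <- gt_from_codes(matrix(c(rep(0L, 5), rep(NA_integer_, 5)), ncol = 1))
  af3 <- allele_frequencies(gt3, "L1")
  expect_equal(unname(af3$freq[2]), 0)
  expect_equal(af3$n_typed, 5)
  expect_error(allele_frequencies(
    gt_from_codes(matrix(NA_integer_, 3, 1)), "L1"), "no typed")
})

test_that("allele frequencies sum to 1 and ignore sample order", {
  set.seed(42)
  for (rep in 1:20) {
    codes <- matrix(sample(c(0:2, NA), 30, replace = TRUE), ncol = 1)
    if (all(is.na(codes))) next
    gt <- gt_from_codes(codes)
    af <- allele_frequencies(gt, "L1")
    expect_lt(abs(sum(af$freq) - 1), 1e-12)
    perm <- sample(nrow(codes))
    af_p <- allele_frequencies(gt_from_codes(codes[perm, , drop = FALSE]),
                               "L1")
    expect_identical(af$freq, af_p$freq)
  }
})

test_that("MAF filter keeps >= threshold on exact counts and is idempotent", {
  # locus A: 3/64 minor alleles (dropped), locus B: 4/64 (kept), C: monomorphic
  codes <- cbind(c(rep(1L, 3), rep(0L, 29)),
                 c(rep(1L, 4), rep(0L, 28)),
                 rep(0L, 32))
  gt <- gt_from_codes(codes)
  f <- filter_loci_by_maf(gt, 0.05)
  expect_identical(f$loci$id, "L2")
  expect_identical(f$samples, gt$samples)
  f2 <- filter_loci_by_maf(f, 0.05)
  expect_identical(f2$calls, f$calls)
  # threshold exactly at the observed MAF is kept (1/20 at 0.05)
  gt4 <- gt_from_codes(matrix(c(1L, rep(0L, 9)), ncol = 1))
  expect_equal(nrow(filter_loci_by_maf(gt4, 0.05)$loci), 1)
})

test_that("genotype tables round-trip through delimited text", {
  loci <- default_loci()
  cfg <- sim_config(n_tolerant = 15, n_intolerant = 15, seed = 3,
                    missing_rate = 0.1)
  gt <- simulate_population(cfg)
  path <- tempfile(fileext = ".tsv")
  write_genotype_table(gt, path)
  back <- read_genotype_table(path, loci = loci)
  expect_identical(unname(back$calls), unname(gt$calls))
  expect_identical(back$phenotype, gt$phenotype)
  expect_identical(back$samples, gt$samples)
})

test_that("ingestion rejects a third allele, naming sample and locus", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tphenotype\tL1",
               "s1\ttolerant\tG/T",
               "s2\tintolerant\tG/A"), path)
  expect_error(read_genotype_table(path), "3 alleles|alleles")
  # with a declared locus panel the error names the sample and locus
  expect_error(
    read_genotype_table(path, loci = snp_loci("L1", "G", "T")),
    "s2.*L1")
})

test_that("peak tables round-trip to the generating genotypes", {
  cfg <- sim_config(n_tolerant = 20, n_intolerant = 20, seed = 5,
                    missing_rate = 0, ambiguous_rate = 0)
  gt <- simulate_population(cfg)
  peaks <- simulate_peak_table(cfg, gt)
  called <- call_genotypes_from_peak_table(
    peaks, cfg$loci,
    phenotype = stats::setNames(gt$phenotype, gt$samples))
  expect_identical(called$calls[gt$samples, ], gt$calls)
  expect_identical(called$phenotype[match(gt$samples, called$samples)],
                   gt$phenotype)
})

test_that("minimal VCF ingestion maps unphased GT codes", {
  skip_if_not_installed("vcfR")
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "chr1\t100\tsnpA\tG\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\tsnpB\tG\tC\t.\tPASS\t.\tGT\t0/1\t./.\t0/0"), path)
  gt <- read_vcf_genotypes(path)
  expect_identical(gt$loci$id, c("snpA", "snpB"))
  expect_identical(unname(gt$calls[, "snpA"]), c(0L, 1L, 2L))
  expect_identical(unname(gt$calls[, "snpB"]), c(1L, NA_integer_, 0L))
})
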