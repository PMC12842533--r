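# Shared fixtures and independent oracles, built in code.

# genotype_table from an integer code matrix (0/1/2/NA)
gt_from_codes <- function(codes, phenotype = NULL, loci = NULL) {
  codes <- as.matrix(codes)
  if (is.null(loci))
    loci <- snp_loci(paste0("L", seq_len(ncol(codes))),
                     rep("G", ncol(codes)), rep("T", ncol(codes)))
  colnames(codes) <- loci$id
  genotype_table(codes, loci, phenotype)
}

# published per-group haplotype expected counts (four-SNP panel)
table3_counts <- function() {
  list(tolerant = c(GGGG = 45.53, GGTT = 9.49, TGGG = 13.00, GGTG = 5.98,
                    TCGG = 15.41, TCGT = 1.06, TCTG = 0.08, TCTT = 7.45),
       intolerant = c(GGGG = 93, GGTT = 1, TGGG = 2))
}

table3_distributions <- function() {
  cnt <- table3_counts()
  loci <- default_loci()$id
  list(tol = haplotype_distribution(cnt$tolerant, loci),
       intol = haplotype_distribution(cnt$intolerant, loci))
}

# independent Fisher oracle: hypergeometric probabilities from choose()
fisher_oracle <- function(n1, n2, n3, n4) {
  r1 <- n1 + n2; c1 <- n1 + n3; n <- n1 + n2 + n3 + n4
  a <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  po <- choose(c1, n1) * choose(n - c1, r1 - n1) / choose(n, r1)
  min(1, sum(pr[pr <= po * (1 + 1e-12)]))
}
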