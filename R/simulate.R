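#' Default locus panel for simulation
#'
#' Four biallelic SNPs in a candidate osmoregulation gene: one nonsense,
#' one intronic and two missense variants, all G-reference.
#'
#' @return Locus table from [snp_loci()].
#' @export
default_loci <- function() {
  snp_loci(id = c("g.72037G>T", "g.72122G>C", "g.74293G>T", "g.74433G>T"),
           ref = c("G", "G", "G", "G"),
           alt = c("T", "C", "T", "T"),
           region = c("exon", "intron", "exon", "exon"),
           effect = c("nonsense", "intronic", "missense", "missense"))
}

#' Default group-specific haplotype frequencies
#'
#' The generating model for the synthetic cohorts: haplotype distributions
#' over the four default loci, one per phenotype group, renormalized from
#' the published relative frequencies of the tolerant and intolerant
#' case-control groups. Drawing whole haplotypes (rather than independent
#' per-locus alleles) makes linkage disequilibrium between the loci
#' implicit in the simulation.
#'
#' @return List with numeric vectors `tolerant` and `intolerant`, each
#'   named by haplotype and summing to 1.
#' @export
default_haplotype_freqs <- function() {
  tol <- c(GGGG = 0.465, GGTT = 0.097, TGGG = 0.133, GGTG = 0.061,
           TCGG = 0.157, TCGT = 0.011, TCTG = 0.001, TCTT = 0.076)
  int <- c(GGGG = 0.969, GGTT = 0.010, TGGG = 0.021)
  list(tolerant = tol / sum(tol), intolerant = int / sum(int))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with defaults
#' matching the genotyped study cohorts: 50 individuals per phenotype
#' group, group-specific haplotype frequency distributions, 2% missing
#' calls, three strongly correlated growth traits (inter-trait correlation
#' 0.95) with a positive size shift for mutant-allele carriers, and
#' genotype-dependent expression shifts on the Ct scale.
#'
#' @param n_tolerant,n_intolerant Group sizes (defaults 50, 50).
#' @param haplotype_freqs_tol,haplotype_freqs_intol Named frequency vectors
#'   over haplotype strings (defaults from [default_haplotype_freqs()]).
#' @param loci Locus table (default [default_loci()]).
#' @param missing_rate Per-call missing probability (default 0.02).
#' @param growth_mean,growth_sd Length-3 trait means/SDs for carapace
#'   length (mm), carapace width (mm), body weight (g).
#' @param growth_cor Common inter-trait correlation (default 0.95).
#' @param carrier_shift Size-factor shift (in SD units) for carriers of at
#'   least one mutant allele (default 0.8).
#' @param ct_reference_mean,ct_reference_sd Reference-gene Ct distribution.
#' @param baseline_dct Baseline target-minus-reference Ct difference.
#' @param genotype_shift Named vector of downward Ct shifts (higher
#'   expression) for het and hom_alt genotypes, in cycles.
#' @param ct_noise_sd Technical noise SD on the Ct scale (default 0.1).
#' @param ambiguous_rate Fraction of peak observations pushed into the
#'   ambiguous ratio band (default 0).
#' @param seed Integer seed; every generator is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tolerant = 50, n_intolerant = 50,
                       haplotype_freqs_tol = default_haplotype_freqs()$tolerant,
                       haplotype_freqs_intol = default_haplotype_freqs()$intolerant,
                       loci = default_loci(),
                       missing_rate = 0.02,
                       growth_mean = c(20, 28, 5),
                       growth_sd = c(3, 4, 1.2),
                       growth_cor = 0.95,
                       carrier_shift = 0.8,
                       ct_reference_mean = 12, ct_reference_sd = 0.15,
                       baseline_dct = 8,
                       genotype_shift = c(het = 0.5, hom_alt = 1.0),
                       ct_noise_sd = 0.1,
                       ambiguous_rate = 0,
                       seed = 1) {
  check_simplex <- function(f, what) {
    if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
      stop(what, " frequencies must be nonnegative and sum to 1")
    if (any(nchar(names(f)) != nrow(loci)))
      stop(what, " haplotype strings must have one allele per locus")
  }
  check_simplex(haplotype_freqs_tol, "tolerant")
  check_simplex(haplotype_freqs_intol, "intolerant")
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            ambiguous_rate >= 0, ambiguous_rate <= 1,
            growth_cor > -0.5, growth_cor <= 1,
            length(growth_mean) == 3, length(growth_sd) == 3)
  structure(list(n_tolerant = n_tolerant, n_intolerant = n_intolerant,
                 haplotype_freqs_tol = haplotype_freqs_tol,
                 haplotype_freqs_intol = haplotype_freqs_intol,
                 loci = loci, missing_rate = missing_rate,
                 growth_mean = growth_mean, growth_sd = growth_sd,
                 growth_cor = growth_cor, carrier_shift = carrier_shift,
                 ct_reference_mean = ct_reference_mean,
                 ct_reference_sd = ct_reference_sd,
                 baseline_dct = baseline_dct,
                 genotype_shift = genotype_shift,
                 ct_noise_sd = ct_noise_sd,
                 ambiguous_rate = ambiguous_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

hap_to_codes <- function(h1, h2, loci) {
  a1 <- strsplit(h1, "")[[1]]; a2 <- strsplit(h2, "")[[1]]
  as.integer((a1 == loci$alt) + (a2 == loci$alt))
}

#' Simulate a genotyped case-control population
#'
#' Each individual draws two haplotypes independently from its phenotype
#' group's haplotype distribution; the unphased per-locus genotype is the
#' count of alternate alleles. Missing calls are injected uniformly at
#' `missing_rate`. Fully reproducible under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A labelled [genotype_table()].
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  draw_group <- function(n, freqs, prefix) {
    if (length(freqs) == 1 && freqs[1] <= 0) stop("degenerate frequencies")
    haps <- names(freqs)
    h1 <- sample(haps, n, replace = TRUE, prob = freqs)
    h2 <- sample(haps, n, replace = TRUE, prob = freqs)
    calls <- t(vapply(seq_len(n),
                      function(i) hap_to_codes(h1[i], h2[i], cfg$loci),
                      integer(nrow(cfg$loci))))
    rownames(calls) <- sprintf("%s%03d", prefix, seq_len(n))
    calls
  }
  ct <- draw_group(cfg$n_tolerant, cfg$haplotype_freqs_tol, "T")
  ci <- draw_group(cfg$n_intolerant, cfg$haplotype_freqs_intol, "I")
  calls <- rbind(ct, ci)
  colnames(calls) <- cfg$loci$id
  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(length(calls)) < cfg$missing_rate,
                   nrow(calls))
    calls[drop] <- NA_integer_
  }
  genotype_table(calls, cfg$loci,
                 c(rep("tolerant", cfg$n_tolerant),
                   rep("intolerant", cfg$n_intolerant)))
}

#' Simulate correlated growth traits for the tolerant group
#'
#' Traits follow a one-factor model: a common standard-normal size factor
#' (shifted upward by `carrier_shift` SD for mutant-allele carriers) plus
#' independent trait-specific noise, calibrated so every trait pair has
#' correlation `growth_cor`. Values are truncated to stay positive.
#'
#' @param cfg A [sim_config()].
#' @param gt Genotype table from [simulate_population()]; growth records
#'   are generated for its tolerant samples.
#' @return A `data.frame`: `sample_id`, `carapace_length`,
#'   `carapace_width`, `body_weight`.
#' @export
simulate_growth <- function(cfg, gt) {
  stopifnot(inherits(cfg, "sim_config"), inherits(gt, "genotype_table"))
  set.seed(cfg$seed + 1L)
  keep <- gt$phenotype == "tolerant"
  ids <- gt$samples[keep]
  n <- length(ids)
  carrier <- apply(gt$calls[keep, , drop = FALSE] >= 1L, 1,
                   function(r) any(r, na.rm = TRUE))
  rho <- cfg$growth_cor
  if (rho < 0) stop("one-factor model needs a nonnegative correlation")
  u <- stats::rnorm(n) + cfg$carrier_shift * carrier
  z <- sapply(1:3, function(j)
    sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(n))
  x <- sweep(sweep(z, 2, cfg$growth_sd, "*"), 2, cfg$growth_mean, "+")
  x <- pmax(x, 0.1)
  data.frame(sample_id = ids,
             carapace_length = x[, 1], carapace_width = x[, 2],
             body_weight = x[, 3], stringsAsFactors = FALSE)
}

#' Simulate qPCR expression records per genotype class
#'
#' For each locus and each genotype class observed there, draws
#' `n_individuals` individuals, each with `n_replicates` technical
#' replicates: reference Ct from the configured normal, target Ct =
#' reference + baseline dCt - genotype shift + technical noise. A genotype
#' shift of one cycle therefore doubles expected expression.
#'
#' @param cfg A [sim_config()].
#' @param gt Genotype table supplying the genotype classes per locus.
#' @param n_individuals,n_replicates Biological / technical replication
#'   (defaults 3 and 3).
#' @return A `data.frame` of expression records (see
#'   [relative_expression()]).
#' @export
simulate_expression <- function(cfg, gt, n_individuals = 3,
                                n_replicates = 3) {
  stopifnot(inherits(cfg, "sim_config"), inherits(gt, "genotype_table"))
  set.seed(cfg$seed + 2L)
  codes <- c("hom_ref", "het", "hom_alt")
  shift_of <- function(code)
    switch(code, hom_ref = 0,
           het = unname(cfg$genotype_shift["het"]),
           hom_alt = unname(cfg$genotype_shift["hom_alt"]))
  rows <- list()
  for (j in seq_len(nrow(gt$loci))) {
    g <- gt$calls[, j]
    for (code_i in 0:2) {
      pool <- which(!is.na(g) & g == code_i)
      if (length(pool) == 0) next
      pick <- pool[seq_len(min(n_individuals, length(pool)))]
      for (s in pick) {
        ref_ct <- stats::rnorm(1, cfg$ct_reference_mean, cfg$ct_reference_sd)
        for (r in seq_len(n_replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = gt$samples[s], locus = gt$loci$id[j],
            genotype = codes[code_i + 1L], replicate = r,
            ct_target = ref_ct + cfg$baseline_dct -
              shift_of(codes[code_i + 1L]) +
              stats::rnorm(1, 0, cfg$ct_noise_sd),
            ct_reference = ref_ct + stats::rnorm(1, 0, cfg$ct_noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a chromatogram peak-height table
#'
#' Emits one peak observation per non-missing call: heterozygotes with
#' secondary/primary ratios uniform on 0.35-0.9, homozygotes on 0-0.15, and
#' a configurable fraction (`cfg$ambiguous_rate`) pushed into the ambiguous
#' 0.20-0.30 band, which the caller maps back to missing.
#'
#' @param cfg A [sim_config()].
#' @param gt Genotype table to emit peaks for.
#' @return A peak table `data.frame` (see [read_peak_table()]).
#' @export
simulate_peak_table <- function(cfg, gt) {
  stopifnot(inherits(cfg, "sim_config"), inherits(gt, "genotype_table"))
  set.seed(cfg$seed + 3L)
  rows <- list()
  for (j in seq_len(nrow(gt$loci))) {
    ref <- gt$loci$ref[j]; alt <- gt$loci$alt[j]
    for (i in seq_along(gt$samples)) {
      code <- gt$calls[i, j]
      if (is.na(code)) next
      primary_height <- stats::runif(1, 800, 1200)
      ambiguous <- stats::runif(1) < cfg$ambiguous_rate
      ratio <- if (ambiguous) stats::runif(1, 0.20, 0.2999)
      else if (code == 1L) stats::runif(1, 0.35, 0.9)
      else stats::runif(1, 0, 0.15)
      if (code == 0L) { pb <- ref; sb <- alt }
      else if (code == 2L) { pb <- alt; sb <- ref }
      else { pb <- ref; sb <- alt }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = gt$samples[i], locus = gt$loci$id[j],
        primary_base = pb, primary_height = primary_height,
        secondary_base = sb,
        secondary_height = ratio * primary_height,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
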