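#' Diversity statistics from allele frequencies
#'
#' Plug-in estimators: expected heterozygosity (gene diversity)
#' `He = 1 - sum(p^2)`, effective allele number `Ne = 1 / sum(p^2)`, and
#' polymorphic information content
#' `PIC = 1 - sum(p^2) - sum_{i<j} 2 p_i^2 p_j^2`. No small-sample
#' correction is applied, so the identity `He = 1 - 1/Ne` holds exactly.
#'
#' @param p Numeric vector of allele frequencies summing to 1.
#' @return Named numeric `c(he, ne, pic)`.
#' @examples
#' diversity_from_frequencies(c(0.62, 0.38))
#' @export
diversity_from_frequencies <- function(p) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-9)
  p <- unname(p)
  sp2 <- sum(p^2)
  cross <- 0
  k <- length(p)
  if (k >= 2)
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      cross <- cross + 2 * p[i]^2 * p[j]^2
  c(he = 1 - sp2, ne = 1 / sp2, pic = 1 - sp2 - cross)
}

#' Per-group, per-locus diversity summary
#'
#' Observed heterozygosity is the fraction of heterozygous individuals among
#' typed genotypes; He, Ne and PIC come from the allele frequencies in the
#' same set via [diversity_from_frequencies()]. A monomorphic locus yields
#' `(Ho, He, Ne, PIC) = (0, 0, 1, 0)`.
#'
#' @param gt A [genotype_table()].
#' @param locus Locus id.
#' @param group Phenotype group (`"tolerant"` or `"intolerant"`).
#' @return Named numeric `c(ho, he, ne, pic)` with attribute `n_typed`.
#' @export
diversity_summary <- function(gt, locus, group) {
  af <- allele_frequencies(gt, locus, group = group)
  sub <- group_samples(gt, group)
  g <- sub$calls[, locus_index(sub, locus)]
  g <- g[!is.na(g)]
  ho <- mean(g == 1L)
  d <- diversity_from_frequencies(af$freq)
  structure(c(ho = ho, d), n_typed = af$n_typed)
}

#' Diversity table across groups and loci
#'
#' One row per group x locus combination, shaped like the standard
#' PowerMarker-style summary (Ho, He, Ne, PIC).
#'
#' @param gt A [genotype_table()].
#' @param groups Phenotype groups to summarise (default both).
#' @return A `data.frame` with columns group, locus, ho, he, ne, pic.
#' @export
diversity_table <- function(gt, groups = c("tolerant", "intolerant")) {
  stopifnot(inherits(gt, "genotype_table"))
  rows <- list()
  for (grp in groups) for (lc in gt$loci$id) {
    d <- diversity_summary(gt, lc, grp)
    rows[[length(rows) + 1L]] <-
      data.frame(group = grp, locus = lc, ho = d[["ho"]], he = d[["he"]],
                 ne = d[["ne"]], pic = d[["pic"]], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
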