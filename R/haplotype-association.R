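#' Case-control haplotype association table
#'
#' For each haplotype present in either group, forms the 2x2 table "this
#' haplotype vs all others" on EM expected counts and computes the
#' uncorrected chi-square with its p-value, a Fisher exact p on the
#' half-even-rounded table (approximate, since the cells are fractional
#' expected counts), and the odds ratio with Woolf interval.
#'
#' Group totals include only haplotypes whose relative frequency reaches
#' `rare_threshold` in at least one group; rarer haplotypes have their
#' counts reported but all statistics left undefined (`NA`, rendered `"-"`),
#' the convention under which published haplotype tables of this kind are
#' reproducible. Rows are ordered by descending count in the first
#' (tolerant) distribution.
#'
#' @param tol,intol `haplotype_distribution` objects for the tolerant and
#'   intolerant groups, over the same loci.
#' @param rare_threshold Minimum relative frequency for a haplotype to enter
#'   the group totals (default 0.03).
#' @return A `data.frame` with one row per haplotype: `haplotype`,
#'   `count_tol`, `freq_tol`, `count_intol`, `freq_intol`, `chi2`,
#'   `p_pearson`, `p_fisher`, `odds_ratio`, `ci_low`, `ci_high`, `included`.
#' @export
build_haplotype_table <- function(tol, intol, rare_threshold = 0.03) {
  stopifnot(inherits(tol, "haplotype_distribution"),
            inherits(intol, "haplotype_distribution"))
  if (length(tol$loci) != length(intol$loci) ||
      !all(tol$loci == intol$loci))
    stop("the two distributions must be over the same loci")
  haps <- union(names(tol$frequencies)[tol$expected_counts > 0],
                names(intol$frequencies)[intol$expected_counts > 0])
  cnt_t <- vapply(haps, function(h) {
    v <- tol$expected_counts[h]; if (is.na(v)) 0 else unname(v)
  }, 0)
  cnt_i <- vapply(haps, function(h) {
    v <- intol$expected_counts[h]; if (is.na(v)) 0 else unname(v)
  }, 0)
  frq_t <- cnt_t / sum(tol$expected_counts)
  frq_i <- cnt_i / sum(intol$expected_counts)
  included <- frq_t >= rare_threshold | frq_i >= rare_threshold
  tot_t <- sum(cnt_t[included])
  tot_i <- sum(cnt_i[included])
  rows <- lapply(seq_along(haps), function(k) {
    out <- data.frame(haplotype = haps[k],
                      count_tol = cnt_t[k], freq_tol = frq_t[k],
                      count_intol = cnt_i[k], freq_intol = frq_i[k],
                      chi2 = NA_real_, p_pearson = NA_real_,
                      p_fisher = NA_real_, odds_ratio = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      included = included[k], stringsAsFactors = FALSE)
    if (!included[k]) return(out)
    t2 <- contingency_2x2(cnt_t[k], tot_t - cnt_t[k],
                          cnt_i[k], tot_i - cnt_i[k])
    out$chi2 <- tryCatch(chi2_2x2(t2), error = function(e) NA_real_)
    if (!is.na(out$chi2)) out$p_pearson <- chi2_pvalue_df1(out$chi2)
    out$p_fisher <- tryCatch(fisher_exact_2x2(round_half_even_2x2(t2)),
                             error = function(e) NA_real_)
    out$odds_ratio <- odds_ratio(t2)
    ci <- woolf_ci(t2)
    out$ci_low <- ci[["ci_low"]]; out$ci_high <- ci[["ci_high"]]
    out
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$count_tol, res$haplotype), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "group_totals") <- c(tolerant = tot_t, intolerant = tot_i)
  attr(res, "rare_threshold") <- rare_threshold
  res
}
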