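#' Run the full candidate-gene association analysis
#'
#' Orchestrates every stage on a genotype table (plus optional growth and
#' expression inputs): MAF filtering, per-locus case-control association,
#' per-group diversity summaries, EM haplotype inference with the
#' case-control haplotype table, the multi-locus genotype-frequency
#' classifier with its accuracy curve, growth PCA with fast/slow grouping
#' and the genotype-by-growth-group table, and per-genotype relative
#' expression. Each output is written as a TSV in `output_dir` (with `"-"`
#' for undefined statistics) and also returned invisibly; every threshold
#' actually used is echoed into `run_summary.tsv`.
#'
#' @param gt A labelled [genotype_table()], or a path readable by
#'   [read_genotype_table()].
#' @param growth Optional growth data frame (`sample_id`,
#'   `carapace_length`, `carapace_width`, `body_weight`) or file path.
#' @param expression Optional expression records data frame or file path
#'   (see [relative_expression()]).
#' @param output_dir Output directory (created if absent).
#' @param maf_threshold,rare_threshold,smoothing,alpha Analysis thresholds.
#' @param locus_order Locus order for the accuracy curve (default filtered
#'   table order).
#' @param n_per_group Fast/slow growth group size (default 25).
#' @param eval_mode Classifier evaluation, `"resubstitution"` or `"loo"`.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a named list of all result tables.
#' @export
run_full_analysis <- function(gt, growth = NULL, expression = NULL,
                              output_dir = ".",
                              maf_threshold = 0.05, rare_threshold = 0.03,
                              smoothing = 0.005, alpha = 0.05,
                              locus_order = NULL, n_per_group = 25,
                              eval_mode = "resubstitution",
                              quiet = FALSE) {
  say <- function(...) if (!quiet) message("[salsnp] ", ...)
  if (is.character(gt)) gt <- read_genotype_table(gt)
  stopifnot(inherits(gt, "genotype_table"))
  if (is.character(growth))
    growth <- utils::read.table(growth, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  if (is.character(expression))
    expression <- utils::read.table(expression, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  say("MAF filter (threshold ", maf_threshold, ")")
  gt_f <- filter_loci_by_maf(gt, maf_threshold)
  say(nrow(gt_f$loci), "/", nrow(gt$loci), " loci retained")
  if (is.null(locus_order)) locus_order <- gt_f$loci$id

  say("per-locus association")
  out$association <- association_table(gt_f)
  write_dash_tsv(out$association, file.path(output_dir, "association.tsv"))

  say("diversity summaries")
  out$diversity <- diversity_table(gt_f)
  write_dash_tsv(out$diversity, file.path(output_dir, "diversity.tsv"))

  say("EM haplotype inference")
  em_tol <- em_haplotype_frequencies(gt_f, "tolerant")
  em_int <- em_haplotype_frequencies(gt_f, "intolerant")
  out$haplotypes <- build_haplotype_table(em_tol, em_int, rare_threshold)
  out$em <- list(tolerant = em_tol, intolerant = em_int)
  write_dash_tsv(out$haplotypes, file.path(output_dir, "haplotypes.tsv"))

  say("multi-locus classifier (", eval_mode, ")")
  model <- fit_frequency_model(gt_f, locus_order, smoothing)
  out$predictions <- classify(model, gt_f)
  write_dash_tsv(out$predictions,
                 file.path(output_dir, "classifier_predictions.tsv"))
  out$accuracy_curve <- cumulative_accuracy_curve(gt_f, locus_order,
                                                  mode = eval_mode,
                                                  smoothing = smoothing)
  write_dash_tsv(out$accuracy_curve,
                 file.path(output_dir, "accuracy_curve.tsv"))

  if (!is.null(growth)) {
    say("growth PCA and fast/slow grouping")
    pca <- correlation_pca(growth)
    out$pca <- pca
    pca_tab <- data.frame(component = colnames(pca$loadings),
                          eigenvalue = pca$eigenvalues,
                          variance_explained = pca$variance_explained,
                          cumulative_variance =
                            cumsum(pca$variance_explained))
    pca_tab <- cbind(pca_tab, t(pca$loadings))
    write_dash_tsv(pca_tab, file.path(output_dir, "pca_summary.tsv"))
    grp <- assign_growth_groups(pca, n_per_group)
    out$growth_groups <- grp
    out$growth_genotypes <- growth_group_genotype_table(gt_f, grp$fast,
                                                        grp$slow)
    write_dash_tsv(out$growth_genotypes,
                   file.path(output_dir, "growth_genotypes.tsv"))
  }

  if (!is.null(expression)) {
    say("relative expression (2^-ddCt) with ANOVA")
    out$expression <- expression_summary(expression, alpha = alpha)
    write_dash_tsv(out$expression, file.path(output_dir, "expression.tsv"))
  }

  cfg <- data.frame(
    parameter = c("maf_threshold", "rare_threshold", "smoothing", "alpha",
                  "n_per_group", "eval_mode", "locus_order"),
    value = c(maf_threshold, rare_threshold, smoothing, alpha, n_per_group,
              eval_mode, paste(locus_order, collapse = ",")),
    stringsAsFactors = FALSE)
  utils::write.table(cfg, file.path(output_dir, "run_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("done; outputs in ", normalizePath(output_dir))
  invisible(out)
}
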