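#' Fit the per-locus genotype-frequency model
#'
#' Estimates, separately in the tolerant and intolerant training groups, the
#' relative frequency of each genotype code (hom_ref / het / hom_alt) at
#' each locus over typed samples. Genotype codes unseen in a group receive
#' the `smoothing` pseudo-frequency instead of 0, so a single unobserved
#' genotype does not annihilate a multi-locus product; `smoothing = 0`
#' restores the strict literal rule.
#'
#' @param gt A labelled [genotype_table()] with both groups non-empty.
#' @param loci Locus ids to use (default all, in table order).
#' @param smoothing Pseudo-frequency for unseen genotypes (default 0.005,
#'   about half of 1/(2n) at the typical group size of 50).
#' @return An object of class `classifier_model`.
#' @export
fit_frequency_model <- function(gt, loci = NULL, smoothing = 0.005) {
  stopifnot(inherits(gt, "genotype_table"), smoothing >= 0)
  if (is.null(loci)) loci <- gt$loci$id
  for (lc in loci) locus_index(gt, lc)
  freq_for <- function(group) {
    sub <- group_samples(gt, group)
    fl <- lapply(loci, function(lc) {
      g <- sub$calls[, locus_index(sub, lc)]
      g <- g[!is.na(g)]
      if (length(g) == 0) stop("no typed genotypes in ", group, " at ", lc)
      f <- tabulate(g + 1L, 3L) / length(g)
      names(f) <- c("hom_ref", "het", "hom_alt")
      f
    })
    names(fl) <- loci
    fl
  }
  structure(list(loci = loci,
                 freq_tol = freq_for("tolerant"),
                 freq_intol = freq_for("intolerant"),
                 smoothing = smoothing),
            class = "classifier_model")
}

#' Classify samples by genotype-frequency products
#'
#' For each sample, the composite score for a group is the product over the
#' model's loci of that group's frequency of the sample's genotype; the
#' higher score determines the predicted phenotype. Equal scores are
#' classified intolerant (the conservative choice for a tolerance-selection
#' marker). Samples with a missing call at any model locus are excluded and
#' counted in `n_excluded`.
#'
#' @param model A `classifier_model` from [fit_frequency_model()].
#' @param gt A [genotype_table()] whose loci include the model's.
#' @param tie `"intolerant"` (default) or `"tolerant"`: label given on exact
#'   score ties.
#' @return A `data.frame` with columns `sample_id`, `score_tol`,
#'   `score_intol`, `predicted`, `truth`; attribute `n_excluded`.
#' @export
classify <- function(model, gt, tie = c("intolerant", "tolerant")) {
  stopifnot(inherits(model, "classifier_model"),
            inherits(gt, "genotype_table"))
  tie <- match.arg(tie)
  jj <- vapply(model$loci, locus_index, 0L, gt = gt)
  sub <- gt$calls[, jj, drop = FALSE]
  complete <- !apply(is.na(sub), 1, any)
  n_excluded <- sum(!complete)
  idx <- which(complete)
  score <- function(freqs, i) {
    s <- 1
    for (k in seq_along(model$loci)) {
      f <- freqs[[model$loci[k]]][sub[i, k] + 1L]
      if (f == 0) f <- model$smoothing
      s <- s * f
    }
    s
  }
  st <- vapply(idx, function(i) score(model$freq_tol, i), 0)
  si <- vapply(idx, function(i) score(model$freq_intol, i), 0)
  pred <- ifelse(st > si, "tolerant",
                 ifelse(st < si, "intolerant", tie))
  out <- data.frame(sample_id = gt$samples[idx],
                    score_tol = st, score_intol = si,
                    predicted = pred, truth = gt$phenotype[idx],
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Validation accuracy of a classification
#'
#' `R = 100 * n_correct / n_all` over the classified (non-excluded)
#' samples.
#'
#' @param result Data frame from [classify()] (or any with `predicted`).
#' @param truth True labels; defaults to the `truth` column of `result`.
#' @return List with `accuracy_r` (percent), `n_correct`, `n_all`.
#' @export
accuracy_r <- function(result, truth = result$truth) {
  stopifnot(length(truth) == nrow(result))
  if (nrow(result) == 0) stop("no classified samples (n_all = 0)")
  n_correct <- sum(result$predicted == truth)
  list(accuracy_r = 100 * n_correct / nrow(result),
       n_correct = n_correct, n_all = nrow(result))
}

#' Single-locus and cumulative multi-locus validation accuracy
#'
#' Computes, for each locus in `locus_order`, the accuracy of the
#' single-locus classifier, and for each prefix of `locus_order` the
#' accuracy of the multi-locus product classifier. Evaluation is
#' resubstitution by default (fit and evaluate on the same labelled
#' samples); leave-one-out refits the genotype-frequency model without the
#' evaluated sample, guarding against resubstitution optimism.
#'
#' @param gt A labelled [genotype_table()].
#' @param locus_order Locus ids in the order loci are accumulated (default
#'   table order).
#' @param mode `"resubstitution"` (default) or `"loo"`.
#' @param smoothing,tie Passed to [fit_frequency_model()] / [classify()].
#' @return A `data.frame` with columns `k`, `loci`, `type`
#'   (`"single"`/`"cumulative"`), `n_all`, `n_correct`, `accuracy_r`.
#' @export
cumulative_accuracy_curve <- function(gt, locus_order = NULL,
                                      mode = c("resubstitution", "loo"),
                                      smoothing = 0.005,
                                      tie = "intolerant") {
  stopifnot(inherits(gt, "genotype_table"))
  mode <- match.arg(mode)
  if (is.null(locus_order)) locus_order <- gt$loci$id
  if (length(locus_order) < 1) stop("need at least one locus")
  eval_set <- function(loci) {
    if (mode == "resubstitution") {
      model <- fit_frequency_model(gt, loci, smoothing)
      res <- classify(model, gt, tie)
    } else {
      labelled <- which(gt$phenotype %in% c("tolerant", "intolerant"))
      rows <- lapply(labelled, function(i) {
        train <- genotype_table(gt$calls[-i, , drop = FALSE], gt$loci,
                                gt$phenotype[-i])
        test <- genotype_table(gt$calls[i, , drop = FALSE], gt$loci,
                               gt$phenotype[i])
        model <- fit_frequency_model(train, loci, smoothing)
        classify(model, test, tie)
      })
      res <- do.call(rbind, rows)
    }
    acc <- accuracy_r(res)
    data.frame(loci = paste(loci, collapse = "+"),
               n_all = acc$n_all, n_correct = acc$n_correct,
               accuracy_r = acc$accuracy_r, stringsAsFactors = FALSE)
  }
  singles <- do.call(rbind, lapply(locus_order, function(lc) {
    cbind(k = 1L, eval_set(lc), type = "single")
  }))
  cums <- do.call(rbind, lapply(seq_along(locus_order), function(k) {
    cbind(k = k, eval_set(locus_order[seq_len(k)]), type = "cumulative")
  }))
  out <- rbind(singles, cums)
  out[, c("k", "loci", "type", "n_all", "n_correct", "accuracy_r")]
}
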