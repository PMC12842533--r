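#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are first averaged on the Ct scale per sample, then
#' `dCt = ct_target - ct_reference`, `ddCt = dCt - mean(dCt of the
#' calibrator genotype)`, and the fold change is `2^-ddCt`, all within each
#' locus. The calibrator defaults to the homozygous wild-type class
#' (`"hom_ref"`). Records lacking either Ct value are dropped with a
#' warning.
#'
#' @param records Data frame with columns `sample_id`, `locus`, `genotype`
#'   (one of `hom_ref`, `het`, `hom_alt`), `replicate`, `ct_target`,
#'   `ct_reference`.
#' @param calibrator Calibrator genotype code (default `"hom_ref"`).
#' @return A `data.frame` per sample x locus: `sample_id`, `locus`,
#'   `genotype`, `delta_ct`, `fold`.
#' @export
relative_expression <- function(records, calibrator = "hom_ref") {
  need <- c("sample_id", "locus", "genotype", "ct_target", "ct_reference")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  bad <- is.na(records$ct_target) | is.na(records$ct_reference)
  if (any(bad)) {
    warning(sum(bad), " record(s) missing a Ct value; excluded")
    records <- records[!bad, , drop = FALSE]
  }
  if (any(records$ct_target <= 0 | records$ct_target >= 45 |
          records$ct_reference <= 0 | records$ct_reference >= 45))
    stop("Ct values must lie in (0, 45)")
  agg <- stats::aggregate(cbind(ct_target, ct_reference) ~
                            sample_id + locus + genotype,
                          data = records, FUN = mean)
  agg$delta_ct <- agg$ct_target - agg$ct_reference
  out <- lapply(split(agg, agg$locus), function(d) {
    cal <- d$delta_ct[d$genotype == calibrator]
    if (length(cal) == 0)
      stop("no calibrator ('", calibrator, "') samples at locus ",
           d$locus[1])
    d$fold <- 2^(-(d$delta_ct - mean(cal)))
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$locus, out$genotype, out$sample_id),
      c("sample_id", "locus", "genotype", "delta_ct", "fold")]
}

#' One-way ANOVA with post-hoc grouping letters
#'
#' Standard one-way ANOVA across genotype groups followed by pairwise
#' multiple comparisons (Tukey HSD by default, Duncan's multiple range test
#' optionally) and a compact letter display: groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param values Numeric response (e.g. fold changes).
#' @param groups Group labels, coercible to factor; at least two groups with
#'   at least two observations each.
#' @param alpha Significance level (default 0.05).
#' @param method `"tukey"` (default) or `"duncan"`.
#' @return List with `f`, `p`, `df`, `pairwise` (matrix of logical
#'   "significantly different" flags), `letters` (named character vector),
#'   `means`, `se`.
#' @export
anova_posthoc <- function(values, groups, alpha = 0.05,
                          method = c("tukey", "duncan")) {
  method <- match.arg(method)
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 observations")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  mse <- an["Residuals", "Mean Sq"]
  tot <- stats::var(values)
  if (tot == 0 || mse <= 1e-12 * tot)
    stop("degenerate ANOVA: zero within-group variance")
  f <- an[1, "F value"]; p <- an[1, "Pr(>F)"]
  lev <- levels(groups)
  k <- nlevels(groups)
  ns <- as.numeric(table(groups))
  mns <- tapply(values, groups, mean)
  dfe <- an["Residuals", "Df"]
  sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  if (method == "tukey") {
    th <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
    for (r in rownames(th)) {
      pair <- strsplit(r, "-", fixed = TRUE)[[1]]
      s <- th[r, "p adj"] < alpha
      sig[pair[1], pair[2]] <- s; sig[pair[2], pair[1]] <- s
    }
  } else {
    # Duncan's multiple range test: means ranked; two means p ranks apart
    # are compared against the studentized range at the protection level
    # 1 - (1 - alpha)^(p - 1), with the harmonic mean of group sizes.
    ord <- order(mns, decreasing = TRUE)
    nh <- k / sum(1 / ns)
    sem <- sqrt(mse / nh)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      span <- j - i + 1
      crit <- stats::qtukey(1 - (1 - alpha)^(span - 1), span, dfe) * sem
      a <- lev[ord[i]]; b <- lev[ord[j]]
      s <- abs(mns[ord[i]] - mns[ord[j]]) > crit
      sig[a, b] <- s; sig[b, a] <- s
    }
  }
  list(f = f, p = p, df = c(an[1, "Df"], dfe), pairwise = sig,
       letters = compact_letters(mns, sig),
       means = mns,
       se = tapply(values, groups, function(v) stats::sd(v) / sqrt(length(v))))
}

#' Compact letter display from a pairwise significance matrix
#'
#' The insert-and-absorb algorithm: start with one letter covering all
#' groups; for each significantly different pair covered by a common
#' letter, split that letter into two (each excluding one member of the
#' pair) and absorb any letter whose group set is contained in another's.
#' Letters are assigned in order of decreasing group mean.
#'
#' @param means Named numeric vector of group means.
#' @param sig Square logical matrix: `TRUE` where two groups differ
#'   significantly; dimnames matching `names(means)`.
#' @return Named character vector of letter strings.
#' @export
compact_letters <- function(means, sig) {
  lev <- names(means)
  stopifnot(identical(rownames(sig), lev), identical(colnames(sig), lev))
  k <- length(lev)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    split_any <- TRUE
    while (split_any) {
      split_any <- FALSE
      for (c in seq_along(cols)) {
        if (cols[[c]][i] && cols[[c]][j]) {
          a <- cols[[c]]; a[j] <- FALSE
          b <- cols[[c]]; b[i] <- FALSE
          cols[[c]] <- a
          cols[[length(cols) + 1L]] <- b
          split_any <- TRUE
          break
        }
      }
      # absorb duplicated / contained columns
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) for (b in seq_along(cols)) {
        if (a == b || !keep[a] || !keep[b]) next
        if (all(cols[[a]] <= cols[[b]]) &&
            (any(cols[[a]] < cols[[b]]) || a > b)) keep[a] <- FALSE
      }
      cols <- cols[keep]
    }
  }
  # order letters by the best (highest) mean they cover
  best <- vapply(cols, function(cl) max(means[cl]), 0)
  cols <- cols[order(-best)]
  out <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, function(cl) cl[g], TRUE))],
          collapse = "")
  }, "")
  stats::setNames(out, lev)
}

#' Per-genotype expression summary with letters
#'
#' Convenience wrapper: runs [relative_expression()] then, per locus,
#' [anova_posthoc()] on the fold changes, returning a summary table of
#' mean fold +/- SE with grouping letters.
#'
#' @param records Expression records (see [relative_expression()]).
#' @param calibrator,alpha,method Passed through.
#' @return A `data.frame`: `locus`, `genotype`, `n`, `mean_fold`, `se`,
#'   `letter`, `f`, `p`.
#' @export
expression_summary <- function(records, calibrator = "hom_ref",
                               alpha = 0.05, method = "tukey") {
  folds <- relative_expression(records, calibrator)
  out <- lapply(split(folds, folds$locus), function(d) {
    if (length(unique(d$genotype)) < 2) return(NULL)
    a <- anova_posthoc(d$fold, d$genotype, alpha, method)
    data.frame(locus = d$locus[1], genotype = names(a$means),
               n = as.numeric(table(factor(d$genotype,
                                           names(a$means)))),
               mean_fold = as.numeric(a$means), se = as.numeric(a$se),
               letter = unname(a$letters), f = a$f, p = a$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
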