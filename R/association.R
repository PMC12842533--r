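#' Carrier-vs-wild-type contingency table for a locus
#'
#' Builds the 2x2 table behind the case-control odds ratio: carriers of the
#' mutant allele (heterozygous or homozygous alternate) versus homozygous
#' wild type, split by phenotype group. Cell names follow the convention
#' n1 = carriers in the tolerant group, n2 = wild type in the tolerant group,
#' n3 = carriers in the intolerant group, n4 = wild type in the intolerant
#' group. Missing genotypes are excluded from all four cells.
#'
#' @param gt A [genotype_table()] with both phenotype groups present.
#' @param locus Locus id.
#' @param coding `"carrier"` (default; het + hom_alt pooled against hom_ref)
#'   or `"genotype"` for a per-genotype 3-row count table instead.
#' @return For `coding = "carrier"`, a named numeric vector
#'   `c(n1, n2, n3, n4)` of class `contingency_2x2`. For
#'   `coding = "genotype"`, a 3x2 count matrix (genotype x group).
#' @export
carrier_contingency <- function(gt, locus, coding = c("carrier", "genotype")) {
  stopifnot(inherits(gt, "genotype_table"))
  coding <- match.arg(coding)
  j <- locus_index(gt, locus)
  g <- gt$calls[, j]
  tol <- g[gt$phenotype == "tolerant"]
  int <- g[gt$phenotype == "intolerant"]
  if (sum(!is.na(tol)) == 0 || sum(!is.na(int)) == 0)
    stop("each phenotype group needs at least one typed sample at ", locus)
  if (coding == "genotype") {
    m <- cbind(tolerant  = tabulate(tol + 1L, 3L),
               intolerant = tabulate(int + 1L, 3L))
    rownames(m) <- c("hom_ref", "het", "hom_alt")
    return(m)
  }
  contingency_2x2(n1 = sum(tol >= 1L, na.rm = TRUE),
                  n2 = sum(tol == 0L, na.rm = TRUE),
                  n3 = sum(int >= 1L, na.rm = TRUE),
                  n4 = sum(int == 0L, na.rm = TRUE))
}

#' Construct a 2x2 contingency table
#'
#' Entries may be nonnegative reals: haplotype association works on
#' fractional expected counts from the EM step.
#'
#' @param n1,n2,n3,n4 Cell counts: carrier/wild-type in the tolerant group
#'   (n1, n2) and in the intolerant group (n3, n4).
#' @return Named numeric vector of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(n1, n2, n3, n4) {
  t <- c(unname(n1), unname(n2), unname(n3), unname(n4))
  if (any(!is.finite(t)) || any(t < 0)) stop("cells must be nonnegative")
  if (all(t == 0)) stop("at least one cell must be positive")
  structure(as.numeric(t), names = c("n1", "n2", "n3", "n4"),
            class = "contingency_2x2")
}

#' Odds ratio of a 2x2 table
#'
#' The cross-product ratio `n1 * n4 / (n2 * n3)`. Returns `NA` (rendered
#' `"-"` in output tables) when either product is zero, i.e. when the ratio
#' is zero, infinite, or 0/0.
#'
#' @param t A [contingency_2x2()].
#' @return Positive numeric, or `NA_real_` when undefined.
#' @export
odds_ratio <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  num <- t[["n1"]] * t[["n4"]]
  den <- t[["n2"]] * t[["n3"]]
  if (num == 0 || den == 0) return(NA_real_)
  num / den
}

#' Woolf confidence interval for an odds ratio
#'
#' Log-normal interval `exp(log(OR) +/- z * SE)` with the Woolf standard
#' error `sqrt(1/n1 + 1/n2 + 1/n3 + 1/n4)`. Undefined (NA) when any cell is
#' zero.
#'
#' @param t A [contingency_2x2()].
#' @param z Normal quantile (default 1.96 for a 95% interval).
#' @return Named numeric `c(ci_low, ci_high)`, or both `NA` when undefined.
#' @export
woolf_ci <- function(t, z = 1.96) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (any(t == 0)) return(c(ci_low = NA_real_, ci_high = NA_real_))
  or <- odds_ratio(t)
  se <- sqrt(sum(1 / t))
  ci <- exp(log(or) + c(-1, 1) * z * se)
  c(ci_low = ci[1], ci_high = ci[2])
}

#' Pearson chi-square statistic of a 2x2 table
#'
#' Uncorrected (no continuity correction):
#' `N * (n1*n4 - n2*n3)^2 / ((n1+n2)(n3+n4)(n1+n3)(n2+n4))`.
#'
#' @param t A [contingency_2x2()].
#' @return Nonnegative chi-square statistic (1 df).
#' @export
chi2_2x2 <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  n1 <- t[["n1"]]; n2 <- t[["n2"]]; n3 <- t[["n3"]]; n4 <- t[["n4"]]
  margins <- c(n1 + n2, n3 + n4, n1 + n3, n2 + n4)
  if (any(margins == 0)) stop("degenerate margin: a row or column sums to 0")
  n <- sum(t)
  n * (n1 * n4 - n2 * n3)^2 / prod(margins)
}

#' Upper-tail p-value of a 1-df chi-square statistic
#'
#' @param x Nonnegative statistic (vectorised).
#' @return Upper-tail probability under the chi-square distribution, 1 df.
#' @export
chi2_pvalue_df1 <- function(x) {
  stopifnot(all(x >= 0))
  stats::pchisq(x, df = 1, lower.tail = FALSE)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums, over all tables with the observed margins, the hypergeometric
#' probabilities not exceeding that of the observed table (with a small
#' relative slack so ties at the observed probability are included).
#' Requires integer cells; fractional EM expected counts must be rounded
#' first with [round_half_even_2x2()].
#'
#' @param t A [contingency_2x2()] with integer cells.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (any(abs(t - round(t)) > 1e-9))
    stop("Fisher's exact test needs integer cells; round fractional ",
         "expected counts first (see round_half_even_2x2)")
  n1 <- round(t[["n1"]]); n2 <- round(t[["n2"]])
  n3 <- round(t[["n3"]]); n4 <- round(t[["n4"]])
  r1 <- n1 + n2; c1 <- n1 + n3; n <- n1 + n2 + n3 + n4
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(n1, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  min(1, p)
}

#' Round a fractional 2x2 table half-to-even
#'
#' Banker's rounding per cell, used before the exact test on EM expected
#' counts; the resulting p-value is labelled approximate in reports.
#'
#' @param t A [contingency_2x2()].
#' @return A [contingency_2x2()] with integer cells.
#' @export
round_half_even_2x2 <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  r <- round(t)  # base round() is half-to-even
  contingency_2x2(r[[1]], r[[2]], r[[3]], r[[4]])
}

#' Single-locus logistic regression effect size
#'
#' Fits `tolerant ~ carrier` by maximum likelihood (IRLS via `glm`). For a
#' single binary predictor the fitted slope is algebraically the log odds
#' ratio of the 2x2 table and its standard error is the Woolf standard
#' error; both identities are exposed so the effect-size display and the
#' contingency statistics cannot drift apart. A zero cell (complete or
#' quasi-complete separation) yields `NA` estimates with flag
#' `"separation"`.
#'
#' @param gt A [genotype_table()].
#' @param locus Locus id.
#' @return List with `log_or`, `se`, `p` (Wald), and `flag`
#'   (`"ok"` or `"separation"`).
#' @export
logistic_single_locus <- function(gt, locus) {
  t <- carrier_contingency(gt, locus)
  logistic_from_table(t)
}

#' @rdname logistic_single_locus
#' @param t A [contingency_2x2()].
#' @export
logistic_from_table <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (any(t == 0))
    return(list(log_or = NA_real_, se = NA_real_, p = NA_real_,
                flag = "separation"))
  # aggregated binomial: rows = carrier yes/no, successes = tolerant counts
  carrier <- c(1, 0)
  y_tol <- c(t[["n1"]], t[["n2"]])
  y_int <- c(t[["n3"]], t[["n4"]])
  fit <- stats::glm(cbind(y_tol, y_int) ~ carrier, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100))
  sm <- summary(fit)$coefficients
  list(log_or = unname(sm["carrier", "Estimate"]),
       se = unname(sm["carrier", "Std. Error"]),
       p = unname(sm["carrier", "Pr(>|z|)"]),
       flag = "ok")
}

#' Per-locus association table
#'
#' One row per locus: contingency cells, odds ratio with Woolf interval,
#' uncorrected chi-square with its p-value, Fisher exact p, and the logistic
#' log-OR effect size with standard error. No multiple-testing correction is
#' applied; p-values are raw.
#'
#' @param gt A [genotype_table()] with both phenotype groups.
#' @return A `data.frame`, one row per locus; undefined statistics are `NA`
#'   (written as `"-"` by [write_dash_tsv()]).
#' @export
association_table <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  rows <- lapply(gt$loci$id, function(lc) {
    t <- carrier_contingency(gt, lc)
    or <- odds_ratio(t)
    ci <- woolf_ci(t)
    chi <- tryCatch(chi2_2x2(t), error = function(e) NA_real_)
    lg <- logistic_from_table(t)
    data.frame(locus = lc,
               n1 = t[["n1"]], n2 = t[["n2"]], n3 = t[["n3"]], n4 = t[["n4"]],
               odds_ratio = or, ci_low = ci[["ci_low"]],
               ci_high = ci[["ci_high"]], chi2 = chi,
               p_pearson = if (is.na(chi)) NA_real_ else chi2_pvalue_df1(chi),
               p_fisher = fisher_exact_2x2(t),
               log_or = lg$log_or, log_or_se = lg$se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
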