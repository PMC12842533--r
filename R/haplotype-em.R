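#' Enumerate phase configurations of an unphased multi-locus genotype
#'
#' For an individual heterozygous at `h` loci there are `max(1, 2^(h-1))`
#' distinct unordered haplotype pairs consistent with the genotype. The
#' first heterozygous locus is anchored to the reference allele on the first
#' haplotype so each unordered pair is produced exactly once.
#'
#' @param codes Integer vector of genotype codes (0/1/2, no missing).
#' @param loci Locus table from [snp_loci()] (supplies the allele letters).
#' @return List of length-2 character vectors, each an unordered haplotype
#'   pair written as allele strings in locus order.
#' @export
enumerate_phase_configurations <- function(codes, loci) {
  stopifnot(length(codes) == nrow(loci), !anyNA(codes))
  het <- which(codes == 1L)
  if (length(het) > 20L) stop("phase explosion: more than 20 heterozygous loci")
  base1 <- ifelse(codes == 2L, loci$alt, loci$ref)
  base2 <- ifelse(codes >= 1L, loci$alt, loci$ref)
  if (length(het) == 0L)
    return(list(c(paste(base1, collapse = ""), paste(base2, collapse = ""))))
  free <- het[-1]  # first het locus anchored: hap1 = ref there
  n_cfg <- 2L^length(free)
  out <- vector("list", n_cfg)
  for (k in seq_len(n_cfg) - 1L) {
    h1 <- base1; h2 <- base2
    h1[het[1]] <- loci$ref[het[1]]; h2[het[1]] <- loci$alt[het[1]]
    if (length(free)) {
      flip <- as.logical(bitwAnd(k, 2L^(seq_along(free) - 1L)))
      sw <- free[flip]
      tmp <- h1[sw]; h1[sw] <- h2[sw]; h2[sw] <- tmp
    }
    out[[k + 1L]] <- c(paste(h1, collapse = ""), paste(h2, collapse = ""))
  }
  out
}

#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Multinomial expectation-maximization under Hardy-Weinberg random pairing.
#' The E-step distributes each individual over its compatible phase
#' configurations with weights proportional to `f(h1) * f(h2) * (2 - [h1 ==
#' h2])`; the M-step sets each haplotype frequency to its expected copy
#' count divided by `2n`. Individuals with any missing call at the requested
#' loci are excluded. Initialization is the deterministic
#' linkage-equilibrium start (product of single-locus allele frequencies);
#' seeded Dirichlet random restarts guard against flat starts in
#' pathological configurations, and the run with the best final
#' log-likelihood is kept.
#'
#' @param gt A [genotype_table()].
#' @param group Optional phenotype group to restrict to.
#' @param loci Locus ids to phase (default all, in table order).
#' @param tol Convergence tolerance on the maximum absolute frequency change
#'   (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @param n_restarts Number of seeded random restarts in addition to the
#'   linkage-equilibrium start (default 3).
#' @param seed Seed for the restarts (default 1; ignored when
#'   `n_restarts = 0`).
#' @return An object of class `haplotype_distribution`: `loci`,
#'   `frequencies` (named, summing to 1), `expected_counts` (summing to
#'   `2 * n_used`), `log_likelihood`, `loglik_trace`, `n_iterations`,
#'   `converged`, `n_used`, `n_excluded`.
#' @export
em_haplotype_frequencies <- function(gt, group = NULL, loci = NULL,
                                     tol = 1e-8, max_iter = 1000,
                                     n_restarts = 3, seed = 1) {
  stopifnot(inherits(gt, "genotype_table"))
  if (!is.null(group)) gt <- group_samples(gt, group)
  if (is.null(loci)) loci <- gt$loci$id
  jj <- vapply(loci, locus_index, 0L, gt = gt)
  ltab <- gt$loci[jj, , drop = FALSE]
  calls <- gt$calls[, jj, drop = FALSE]
  complete <- !apply(is.na(calls), 1, any)
  n_excluded <- sum(!complete)
  calls <- calls[complete, , drop = FALSE]
  n <- nrow(calls)
  if (n == 0) stop("no fully typed individuals at the requested loci")

  # collapse to unique multi-locus genotypes with multiplicities
  sig <- apply(calls, 1, paste, collapse = "")
  counts <- table(sig)
  uniq <- do.call(rbind, strsplit(names(counts), ""))
  storage.mode(uniq) <- "integer"
  cfgs <- lapply(seq_len(nrow(uniq)),
                 function(i) enumerate_phase_configurations(uniq[i, ], ltab))
  haps <- sort(unique(unlist(cfgs)))
  h1_idx <- lapply(cfgs, function(cf) match(vapply(cf, `[`, "", 1), haps))
  h2_idx <- lapply(cfgs, function(cf) match(vapply(cf, `[`, "", 2), haps))
  w_mult <- lapply(cfgs, function(cf)
    ifelse(vapply(cf, function(p) p[1] == p[2], TRUE), 1, 2))
  n_g <- as.numeric(counts)

  run_em <- function(f) {
    trace <- numeric(0)
    converged <- FALSE
    it <- 0L
    repeat {
      it <- it + 1L
      # E-step: posterior weight of each configuration
      new_counts <- numeric(length(haps))
      ll <- 0
      for (i in seq_along(cfgs)) {
        pr <- f[h1_idx[[i]]] * f[h2_idx[[i]]] * w_mult[[i]]
        tot <- sum(pr)
        if (tot <= 0) {  # all mass lost; spread evenly over configurations
          pr <- rep(1 / length(pr), length(pr))
          tot <- .Machine$double.xmin
        } else pr <- pr / tot
        ll <- ll + n_g[i] * log(tot)
        inc <- n_g[i] * pr
        for (k in seq_along(inc)) {
          new_counts[h1_idx[[i]][k]] <- new_counts[h1_idx[[i]][k]] + inc[k]
          new_counts[h2_idx[[i]][k]] <- new_counts[h2_idx[[i]][k]] + inc[k]
        }
      }
      trace <- c(trace, ll)
      f_new <- new_counts / (2 * n)
      delta <- max(abs(f_new - f))
      f <- f_new
      if (delta < tol) { converged <- TRUE; break }
      if (it >= max_iter) break
    }
    list(f = f, trace = trace, iter = it, converged = converged)
  }

  # linkage-equilibrium start: product of single-locus allele frequencies
  p_alt <- colMeans(calls) / 2
  hap_mat <- do.call(rbind, strsplit(haps, ""))
  f0 <- rep(1, length(haps))
  for (j in seq_len(ncol(hap_mat))) {
    is_alt <- hap_mat[, j] == ltab$alt[j]
    f0 <- f0 * ifelse(is_alt, p_alt[j], 1 - p_alt[j])
  }
  if (sum(f0) <= 0) f0 <- rep(1, length(haps))
  starts <- list(f0 / sum(f0))
  if (n_restarts > 0) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    for (r in seq_len(n_restarts)) {
      g <- stats::rgamma(length(haps), 1)
      starts[[length(starts) + 1L]] <- g / sum(g)
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  best <- NULL
  for (s in starts) {
    res <- run_em(s)
    if (is.null(best) || res$trace[length(res$trace)] >
        best$trace[length(best$trace)]) best <- res
  }
  f <- best$f
  # frequencies driven to machine noise are true zeros of the MLE;
  # flooring them keeps downstream zero-count conventions exact
  f[f < 1e-10] <- 0
  f <- f / sum(f)
  names(f) <- haps
  structure(list(loci = ltab$id,
                 frequencies = f,
                 expected_counts = 2 * n * f,
                 log_likelihood = best$trace[length(best$trace)],
                 loglik_trace = best$trace,
                 n_iterations = best$iter,
                 converged = best$converged,
                 n_used = n,
                 n_excluded = n_excluded),
            class = "haplotype_distribution")
}

#' Construct a haplotype distribution from known counts
#'
#' Wraps externally given expected haplotype counts (for example a published
#' per-group haplotype table) in the same container returned by
#' [em_haplotype_frequencies()], so downstream association analysis treats
#' published and freshly estimated distributions identically.
#'
#' @param counts Named nonnegative numeric vector of expected haplotype copy
#'   counts; names are haplotype strings in locus order.
#' @param loci Character vector of locus ids (default inferred positions).
#' @return A `haplotype_distribution`.
#' @export
haplotype_distribution <- function(counts, loci = NULL) {
  stopifnot(is.numeric(counts), !is.null(names(counts)), all(counts >= 0),
            sum(counts) > 0)
  nch <- unique(nchar(names(counts)))
  if (length(nch) != 1) stop("haplotype strings must have equal length")
  if (is.null(loci)) loci <- paste0("locus", seq_len(nch))
  structure(list(loci = loci,
                 frequencies = counts / sum(counts),
                 expected_counts = stats::setNames(as.numeric(counts),
                                                   names(counts)),
                 log_likelihood = NA_real_,
                 loglik_trace = numeric(0),
                 n_iterations = 0L,
                 converged = NA,
                 n_used = sum(counts) / 2,
                 n_excluded = 0L),
            class = "haplotype_distribution")
}

#' @export
print.haplotype_distribution <- function(x, ...) {
  cat("haplotype_distribution over loci:",
      paste(x$loci, collapse = ", "), "\n")
  ord <- order(-x$expected_counts)
  df <- data.frame(haplotype = names(x$frequencies)[ord],
                   expected_count = round(x$expected_counts[ord], 2),
                   frequency = round(x$frequencies[ord], 3))
  rownames(df) <- NULL
  print(df)
  if (!is.na(x$converged))
    cat(sprintf("n = %d individuals (%d excluded), %d iterations, %s\n",
                x$n_used, x$n_excluded, x$n_iterations,
                if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}
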