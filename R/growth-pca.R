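#' Correlation-matrix PCA of growth traits
#'
#' Standardizes each trait to zero mean and unit variance, eigendecomposes
#' the correlation matrix, and reports loadings scaled as
#' `eigenvector * sqrt(eigenvalue)` (so a loading is the correlation of the
#' trait with the component). Eigenvector signs are fixed so each column's
#' loading sum is nonnegative; for morphometric data this orients PC1 as an
#' overall size axis with positive loadings.
#'
#' @param records Data frame with `sample_id` and numeric trait columns
#'   (default `carapace_length`, `carapace_width`, `body_weight`).
#' @param traits Trait column names.
#' @return Object of class `pca_result`: `loadings` (trait x component),
#'   `eigenvalues`, `variance_explained` (percent, summing to 100),
#'   `scores` (sample x component), `sample_id`.
#' @export
correlation_pca <- function(records,
                            traits = c("carapace_length", "carapace_width",
                                       "body_weight")) {
  stopifnot(is.data.frame(records), all(traits %in% names(records)),
            nrow(records) >= 3)
  x <- as.matrix(records[, traits])
  if (anyNA(x)) stop("missing trait values are not supported")
  if (any(x <= 0)) stop("trait measurements must be positive")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance trait: ", traits[which(sds == 0)[1]])
  z <- scale(x)
  r <- stats::cor(x)
  e <- eigen(r, symmetric = TRUE)
  vec <- e$vectors
  val <- pmax(e$values, 0)
  for (j in seq_len(ncol(vec)))
    if (sum(vec[, j]) < 0) vec[, j] <- -vec[, j]
  loadings <- vec %*% diag(sqrt(val), length(val))
  dimnames(loadings) <- list(traits, paste0("PC", seq_along(val)))
  scores <- z %*% vec
  colnames(scores) <- colnames(loadings)
  structure(list(loadings = loadings,
                 eigenvalues = stats::setNames(val, colnames(loadings)),
                 variance_explained = 100 * val / sum(val),
                 scores = scores,
                 sample_id = if ("sample_id" %in% names(records))
                   as.character(records$sample_id)
                 else as.character(seq_len(nrow(records)))),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("correlation-matrix PCA of", nrow(x$loadings), "traits,",
      nrow(x$scores), "samples\n")
  tab <- rbind(round(x$loadings, 3),
               Eigenvalue = round(x$eigenvalues, 3),
               `Variance explained (%)` = round(x$variance_explained, 3),
               `Cumulative variance (%)` =
                 round(cumsum(x$variance_explained), 3))
  print(tab)
  invisible(x)
}

#' Assign fast- and slow-growing groups by PC1 score
#'
#' The `n_per_group` samples with the highest PC1 scores form the
#' fast-growing group, the lowest the slow-growing group; samples in the
#' middle remain unassigned. PC1 is oriented so that a larger overall body
#' size gives a larger score (positive correlation with the last trait
#' column, body weight, flipping the score sign if needed). Boundary ties
#' are broken by input order.
#'
#' @param pca A `pca_result` from [correlation_pca()].
#' @param n_per_group Group size (default 25).
#' @return List with character vectors `fast`, `slow`, `unassigned`.
#' @export
assign_growth_groups <- function(pca, n_per_group = 25) {
  stopifnot(inherits(pca, "pca_result"))
  n <- nrow(pca$scores)
  if (n < 2 * n_per_group)
    stop("need at least ", 2 * n_per_group, " samples, have ", n)
  s <- pca$scores[, 1]
  # orient: bigger body weight (last loading row) => bigger score
  if (pca$loadings[nrow(pca$loadings), 1] < 0) s <- -s
  ord <- order(-s, seq_along(s))
  list(fast = pca$sample_id[ord[seq_len(n_per_group)]],
       slow = pca$sample_id[rev(ord)[seq_len(n_per_group)]],
       unassigned = pca$sample_id[setdiff(seq_len(n),
                                          c(ord[seq_len(n_per_group)],
                                            rev(ord)[seq_len(n_per_group)]))])
}

#' Mutant-carrier counts and frequencies by growth group
#'
#' Per locus: the number of mutant-allele carriers (het or hom_alt) in the
#' fast- and slow-growing groups, with frequencies defined as each group's
#' carrier count over the total carriers across both groups. When neither
#' group has a carrier the frequencies are undefined (`NA`, rendered
#' `"-"`).
#'
#' @param gt A [genotype_table()].
#' @param fast,slow Disjoint character vectors of sample ids.
#' @return A `data.frame`: `locus`, `n_fast`, `freq_fast`, `n_slow`,
#'   `freq_slow`.
#' @export
growth_group_genotype_table <- function(gt, fast, slow) {
  stopifnot(inherits(gt, "genotype_table"))
  if (length(intersect(fast, slow)) > 0)
    stop("fast and slow groups must be disjoint")
  fi <- match(fast, gt$samples); si <- match(slow, gt$samples)
  if (anyNA(fi) || anyNA(si)) stop("unknown sample id in growth groups")
  rows <- lapply(seq_len(nrow(gt$loci)), function(j) {
    g <- gt$calls[, j]
    nf <- sum(g[fi] >= 1L, na.rm = TRUE)
    ns <- sum(g[si] >= 1L, na.rm = TRUE)
    tot <- nf + ns
    data.frame(locus = gt$loci$id[j], n_fast = nf,
               freq_fast = if (tot > 0) nf / tot else NA_real_,
               n_slow = ns,
               freq_slow = if (tot > 0) ns / tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
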