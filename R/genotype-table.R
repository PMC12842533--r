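#' SNP locus definitions
#'
#' Build a locus table describing biallelic SNPs. Every locus carries exactly
#' two alleles (the model is strictly biallelic); a third allele observed at
#' ingestion is an error, not a silent recode.
#'
#' @param id Character vector of locus labels (e.g. `"g.72037G>T"`).
#' @param ref,alt Single-nucleotide reference and alternate alleles.
#' @param region Optional region annotation, `"exon"` or `"intron"`.
#' @param effect Optional consequence annotation (`"missense"`, `"nonsense"`,
#'   `"intronic"`, `"synonymous"`, `"unknown"`).
#' @return A `data.frame` with one row per locus.
#' @examples
#' snp_loci("g.72037G>T", "G", "T", region = "exon", effect = "nonsense")
#' @export
snp_loci <- function(id, ref, alt, region = "unknown", effect = "unknown") {
  stopifnot(length(id) == length(ref), length(ref) == length(alt))
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(ref == alt)) stop("ref and alt alleles must differ at every locus")
  bad <- !grepl("^[ACGT]$", ref) | !(grepl("^[ACGT]$", alt) | is.na(alt))
  if (any(bad)) stop("alleles must be single nucleotides (A/C/G/T)")
  data.frame(id = as.character(id), ref = ref, alt = alt,
             region = rep_len(as.character(region), length(id)),
             effect = rep_len(as.character(effect), length(id)),
             stringsAsFactors = FALSE)
}

#' Construct a genotype table
#'
#' The central container: an unphased sample-by-locus genotype matrix with a
#' binary phenotype label per sample. Calls are coded as copies of the
#' alternate allele: 0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, `NA` = missing.
#'
#' @param calls Integer matrix (samples x loci) with values in `{0, 1, 2, NA}`.
#'   Row names are sample identifiers; column names must match `loci$id`.
#' @param loci Locus table from [snp_loci()].
#' @param phenotype Per-sample label, one of `"tolerant"`, `"intolerant"`,
#'   `"unlabelled"`.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(calls, loci, phenotype = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- loci$id
  if (ncol(calls) != nrow(loci))
    stop("calls has ", ncol(calls), " columns but loci describes ", nrow(loci))
  if (!identical(colnames(calls), loci$id))
    stop("column names of calls must match loci$id in order")
  ok <- is.na(calls) | (calls >= 0L & calls <= 2L)
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(phenotype)) phenotype <- rep("unlabelled", nrow(calls))
  phenotype <- as.character(phenotype)
  if (length(phenotype) != nrow(calls))
    stop("phenotype length must equal the number of samples")
  if (!all(phenotype %in% c("tolerant", "intolerant", "unlabelled")))
    stop("phenotype labels must be 'tolerant', 'intolerant' or 'unlabelled'")
  structure(list(samples = rownames(calls), loci = loci, calls = calls,
                 phenotype = phenotype),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table: ", length(x$samples), " samples x ", nrow(x$loci),
      " loci\n", sep = "")
  tab <- table(factor(x$phenotype, c("tolerant", "intolerant", "unlabelled")))
  cat("phenotype: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  miss <- mean(is.na(x$calls))
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

#' Subset a genotype table to the samples of one phenotype group
#'
#' @param gt A [genotype_table()].
#' @param group `"tolerant"` or `"intolerant"` (or `"unlabelled"`).
#' @return A `genotype_table` with only that group's samples.
#' @export
group_samples <- function(gt, group) {
  stopifnot(inherits(gt, "genotype_table"))
  keep <- gt$phenotype == group
  if (!any(keep)) stop("no samples with phenotype '", group, "'")
  genotype_table(gt$calls[keep, , drop = FALSE], gt$loci, gt$phenotype[keep])
}

locus_index <- function(gt, locus) {
  i <- match(locus, gt$loci$id)
  if (is.na(i)) stop("locus '", locus, "' not present in table")
  i
}

#' Read a genotype table from delimited text
#'
#' Expected layout: a header row, then one row per sample with columns
#' `sample_id`, `phenotype`, and one column per locus containing allele pairs
#' such as `"G/T"`, with `"./."` for missing. When `loci` is not supplied the
#' reference allele at each locus is taken as the more frequent observed
#' allele (ties broken alphabetically). Any third allele at a locus is an
#' ingestion error naming the offending sample and locus.
#'
#' @param path File path.
#' @param loci Optional locus table from [snp_loci()]; locus ids must match
#'   the file's locus column names.
#' @param sep Field separator (default tab).
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path, loci = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3 || !identical(tolower(names(df)[1:2]),
                                 c("sample_id", "phenotype")))
    stop("expected columns: sample_id, phenotype, then one column per locus")
  locus_ids <- names(df)[-(1:2)]
  parsed <- lapply(locus_ids, function(lc) {
    g <- df[[lc]]
    miss <- g %in% c("./.", ".", "", "NA")
    parts <- strsplit(ifelse(miss, "N/N", g), "/", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad))
      stop("malformed genotype '", g[which(bad)[1]], "' for sample ",
           df$sample_id[which(bad)[1]], " at locus ", lc)
    a1 <- toupper(vapply(parts, `[`, "", 1))
    a2 <- toupper(vapply(parts, `[`, "", 2))
    a1[miss] <- NA; a2[miss] <- NA
    list(a1 = a1, a2 = a2)
  })
  names(parsed) <- locus_ids
  if (is.null(loci)) {
    loci <- do.call(rbind, lapply(locus_ids, function(lc) {
      al <- c(parsed[[lc]]$a1, parsed[[lc]]$a2)
      cnt <- sort(table(al[!is.na(al)]), decreasing = TRUE)
      if (length(cnt) > 2)
        stop("locus ", lc, " shows ", length(cnt),
             " alleles; only biallelic loci are supported")
      if (length(cnt) == 0) stop("locus ", lc, " has no typed genotypes")
      ref <- names(cnt)[1]
      alt <- if (length(cnt) == 2) names(cnt)[2] else NA_character_
      if (length(cnt) == 2 && cnt[1] == cnt[2]) {
        ref <- min(names(cnt)); alt <- max(names(cnt))
      }
      data.frame(id = lc, ref = ref, alt = alt, region = "unknown",
                 effect = "unknown", stringsAsFactors = FALSE)
    }))
  } else {
    if (!setequal(loci$id, locus_ids))
      stop("locus table ids do not match the file's locus columns")
    loci <- loci[match(locus_ids, loci$id), , drop = FALSE]
  }
  calls <- matrix(NA_integer_, nrow(df), length(locus_ids),
                  dimnames = list(df$sample_id, locus_ids))
  for (j in seq_along(locus_ids)) {
    lc <- locus_ids[j]
    ref <- loci$ref[j]; alt <- loci$alt[j]
    a1 <- parsed[[lc]]$a1; a2 <- parsed[[lc]]$a2
    known <- c(ref, alt[!is.na(alt)])
    bad <- (!is.na(a1) & !(a1 %in% known)) | (!is.na(a2) & !(a2 %in% known))
    if (any(bad))
      stop("allele outside {", paste(known, collapse = ","), "} for sample ",
           df$sample_id[which(bad)[1]], " at locus ", lc)
    calls[, j] <- (a1 == alt) + (a2 == alt)
  }
  genotype_table(calls, loci, df$phenotype)
}

#' Write a genotype table as delimited text
#'
#' Inverse of [read_genotype_table()]: allele-pair encoding with `"./."` for
#' missing calls. Heterozygotes are written ref-first.
#'
#' @param gt A [genotype_table()].
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_genotype_table <- function(gt, path, sep = "\t") {
  stopifnot(inherits(gt, "genotype_table"))
  enc <- vapply(seq_len(nrow(gt$loci)), function(j) {
    ref <- gt$loci$ref[j]; alt <- gt$loci$alt[j]
    code <- gt$calls[, j]
    out <- c(paste0(ref, "/", ref), paste0(ref, "/", alt),
             paste0(alt, "/", alt))[code + 1L]
    out[is.na(code)] <- "./."
    out
  }, character(length(gt$samples)))
  enc <- matrix(enc, nrow = length(gt$samples),
                dimnames = list(NULL, gt$loci$id))
  df <- data.frame(sample_id = gt$samples, phenotype = gt$phenotype,
                   enc, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read unphased genotypes from a minimal VCF
#'
#' A thin wrapper around the vcfR reader extracting only the GT field
#' (unphased `0/1`-style codes), one record per biallelic locus. Phenotype
#' labels are attached afterwards from a named vector.
#'
#' @param path VCF path (uncompressed or bgzipped).
#' @param phenotype Optional named character vector, names = sample ids.
#' @return A [genotype_table()].
#' @export
read_vcf_genotypes <- function(path, phenotype = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required for VCF input")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  anon <- is.na(ids) | ids == "."
  ids[anon] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[anon]
  if (any(nchar(fix[, "REF"]) != 1 | nchar(fix[, "ALT"]) != 1 |
          grepl(",", fix[, "ALT"])))
    stop("only biallelic SNP records are supported")
  loci <- snp_loci(ids, fix[, "REF"], fix[, "ALT"])
  gtf <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out
  }
  calls <- t(matrix(code(gtf), nrow = nrow(gtf)))  # samples x loci
  dimnames(calls) <- list(colnames(gtf), ids)
  ph <- if (is.null(phenotype)) NULL else unname(phenotype[rownames(calls)])
  genotype_table(calls, loci, ph)
}

#' Call a genotype from chromatogram peak heights
#'
#' Direct-sequencing heterozygote detection from the ratio of the secondary
#' to the primary peak at a SNP position. A secondary peak at `>= het_ratio`
#' of the primary is a heterozygote; below `noise_ratio` it is noise and the
#' call is homozygous for the primary base. Ratios falling between the two
#' thresholds are ambiguous and returned as missing rather than forced,
#' mirroring how equivocal traces are set aside for re-checking.
#'
#' @param primary_height,secondary_height Nonnegative peak intensities,
#'   vectorised; `secondary_height <= primary_height` elementwise.
#' @param het_ratio Minimum secondary/primary ratio for a heterozygote call
#'   (default 0.30).
#' @param noise_ratio Ratio below which the secondary peak is treated as
#'   noise (default 0.20). Must satisfy `0 <= noise_ratio < het_ratio <= 1`.
#' @return Character vector with values `"het"`, `"hom"` (for the primary
#'   base) or `"missing"`.
#' @examples
#' call_genotype_from_peaks(1000, 500)  # "het"
#' call_genotype_from_peaks(1000, 100)  # "hom"
#' call_genotype_from_peaks(1000, 250)  # "missing" (ambiguous band)
#' @export
call_genotype_from_peaks <- function(primary_height, secondary_height,
                                     het_ratio = 0.30, noise_ratio = 0.20) {
  if (!(noise_ratio >= 0 && noise_ratio < het_ratio && het_ratio <= 1))
    stop("need 0 <= noise_ratio < het_ratio <= 1")
  if (any(secondary_height < 0) || any(primary_height < 0))
    stop("peak heights must be nonnegative")
  if (any(secondary_height > primary_height))
    stop("secondary peak cannot exceed the primary peak")
  n <- max(length(primary_height), length(secondary_height))
  primary_height <- rep_len(primary_height, n)
  secondary_height <- rep_len(secondary_height, n)
  out <- rep("missing", n)
  zero <- primary_height == 0
  if (any(zero)) warning("no signal (primary peak height 0); call set missing")
  ratio <- ifelse(zero, NA_real_, secondary_height / primary_height)
  out[!zero & ratio >= het_ratio] <- "het"
  out[!zero & ratio < noise_ratio] <- "hom"
  out
}

#' Read a peak-height table
#'
#' Columns: `sample_id`, `locus`, `primary_base`, `primary_height`,
#' `secondary_base`, `secondary_height`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A `data.frame` of peak observations.
#' @export
read_peak_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "locus", "primary_base", "primary_height",
            "secondary_base", "secondary_height")
  if (!all(need %in% names(df)))
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Call a genotype table from a peak-height table
#'
#' Applies [call_genotype_from_peaks()] to every row and maps the called
#' bases onto the locus's reference/alternate alleles.
#'
#' @param peaks Peak table as returned by [read_peak_table()].
#' @param loci Locus table from [snp_loci()].
#' @param phenotype Optional named character vector keyed by sample id.
#' @param het_ratio,noise_ratio Passed to [call_genotype_from_peaks()].
#' @return A [genotype_table()].
#' @export
call_genotypes_from_peak_table <- function(peaks, loci, phenotype = NULL,
                                           het_ratio = 0.30,
                                           noise_ratio = 0.20) {
  stopifnot(all(peaks$locus %in% loci$id))
  samples <- unique(peaks$sample_id)
  calls <- matrix(NA_integer_, length(samples), nrow(loci),
                  dimnames = list(samples, loci$id))
  verdict <- call_genotype_from_peaks(peaks$primary_height,
                                      peaks$secondary_height,
                                      het_ratio, noise_ratio)
  for (k in seq_len(nrow(peaks))) {
    j <- match(peaks$locus[k], loci$id)
    ref <- loci$ref[j]; alt <- loci$alt[j]
    code <- NA_integer_
    if (verdict[k] == "hom") {
      pb <- toupper(peaks$primary_base[k])
      if (pb == ref) code <- 0L
      else if (!is.na(alt) && pb == alt) code <- 2L
      else stop("primary base ", pb, " not an allele of locus ", loci$id[j])
    } else if (verdict[k] == "het") {
      bases <- toupper(c(peaks$primary_base[k], peaks$secondary_base[k]))
      if (!setequal(bases, c(ref, alt)))
        stop("heterozygous bases {", paste(bases, collapse = ","),
             "} do not match alleles of locus ", loci$id[j])
      code <- 1L
    }
    calls[peaks$sample_id[k], j] <- code
  }
  ph <- if (is.null(phenotype)) NULL else unname(phenotype[samples])
  genotype_table(calls, loci, ph)
}

#' Allele frequencies at a locus
#'
#' Frequencies over typed (non-missing) genotypes only; the alternate allele
#' frequency is `(2 * hom_alt + het) / (2 * n_typed)`.
#'
#' @param gt A [genotype_table()].
#' @param locus Locus id.
#' @param group Optional phenotype group to restrict to.
#' @return List with `freq` (named vector over ref/alt summing to 1),
#'   `n_typed`, `maf`, and integer allele `counts`.
#' @export
allele_frequencies <- function(gt, locus, group = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  if (!is.null(group)) gt <- group_samples(gt, group)
  j <- locus_index(gt, locus)
  g <- gt$calls[, j]
  g <- g[!is.na(g)]
  if (length(g) == 0) stop("no typed genotypes at locus ", locus)
  n_alt <- sum(g)
  n2 <- 2L * length(g)
  freq <- c(1 - n_alt / n2, n_alt / n2)
  names(freq) <- c(gt$loci$ref[j],
                   if (is.na(gt$loci$alt[j])) "." else gt$loci$alt[j])
  list(freq = freq, n_typed = length(g), maf = min(freq),
       counts = c(n2 - n_alt, n_alt))
}

#' Filter loci by minor allele frequency
#'
#' Retains loci whose MAF is at least `threshold`. The comparison is done on
#' allele counts (minor count vs `threshold * 2n`) so that boundary cases
#' such as 4 minor alleles out of 64 at a 5% threshold are kept exactly,
#' free of floating-point artefacts.
#'
#' @param gt A [genotype_table()].
#' @param threshold MAF threshold (default 0.05).
#' @return A `genotype_table` with the retained loci; sample set unchanged.
#' @export
filter_loci_by_maf <- function(gt, threshold = 0.05) {
  stopifnot(inherits(gt, "genotype_table"), threshold >= 0, threshold <= 0.5)
  keep <- vapply(gt$loci$id, function(lc) {
    af <- allele_frequencies(gt, lc)
    m <- min(af$counts)
    # m / 2n >= threshold, compared on counts with a guard against the
    # binary representation of thresholds like 0.05
    m >= threshold * sum(af$counts) - 1e-9
  }, logical(1))
  genotype_table(gt$calls[, keep, drop = FALSE],
                 gt$loci[keep, , drop = FALSE], gt$phenotype)
}
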