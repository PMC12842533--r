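#' Write a table as TSV with "-" for undefined statistics
#'
#' Numeric columns are rounded to `digits` decimal places; `NA` values are
#' rendered as `"-"`, matching the convention of published association
#' tables.
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @param digits Decimal places for numeric columns (default 4).
#' @export
write_dash_tsv <- function(df, path, digits = 4) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(round(out[[j]], digits), format = "f",
                          digits = digits)
    out[[j]] <- as.character(out[[j]])
    out[[j]][is.na(df[[j]]) | out[[j]] %in% c("NA", "NaN")] <- "-"
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
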