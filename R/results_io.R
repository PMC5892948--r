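#' Write a result table as TSV
#'
#' Tab-separated, header row, deterministic column order (as given), floating
#' point values rendered with a fixed number of significant digits.
#'
#' @param table a data frame.
#' @param path output path.
#' @param digits significant digits for non-integer numeric columns.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path, digits = 6L) {
  out <- as.data.frame(table, stringsAsFactors = FALSE)
  for (j in seq_along(out)) {
    x <- out[[j]]
    if (is.numeric(x) && !is.integer(x)) {
      out[[j]] <- ifelse(is.na(x), "NA", formatC(x, digits = digits,
                                                 format = "g"))
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_results()]
#' @param path file path.
#' @return A data frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
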