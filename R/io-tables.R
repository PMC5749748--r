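#' Read a domain-annotation TSV
#'
#' Ingests precomputed domain annotations (e.g. exported from WDSP or
#' InterPro runs) as a 4-column tab-separated file with header:
#' `protein_id`, `domain_name`, `start`, `end`.  Coordinates are 0-based
#' half-open.  Annotations referring to unknown proteins are accepted here
#' and resolved at join time.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `protein_id`, `domain_name`, `start`,
#'   `end` (integer, 0-based half-open).
#' @export
read_domain_tsv <- function(path) {
  if (!file.exists(path)) stop("domain TSV not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "integer", "integer"))
  need <- c("protein_id", "domain_name", "start", "end")
  if (!all(need %in% names(df)))
    stop("domain TSV must have header columns ",
         paste(need, collapse = ", "), call. = FALSE)
  df <- df[, need]
  for (k in seq_len(nrow(df))) {
    if (is.na(df$start[k]) || is.na(df$end[k]) || df$start[k] < 0L ||
        df$start[k] >= df$end[k])
      stop("invalid domain interval at row ", k, " of ", path,
           " (need 0 <= start < end)", call. = FALSE)
  }
  df
}

#' Write a data frame as TSV
#'
#' Plain tab-separated output with header, no quoting, no row names, and a
#' fixed `"\n"` end-of-line so that identical inputs give byte-identical
#' files on every platform.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

empty_domains <- function() {
  data.frame(protein_id = character(), domain_name = character(),
             start = integer(), end = integer(), stringsAsFactors = FALSE)
}
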