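#' Read a protein FASTA file into a proteome table
#'
#' Parses a (multi-)FASTA file of amino-acid sequences into a data frame of
#' protein records.  The species tag for each record is taken from the header:
#' by default the token after the first `"|"`, falling back to the whole
#' header (first whitespace-delimited word) when no `"|"` is present.  A
#' single file may therefore carry a multi-species pool, which the
#' cross-species phylogeny stage requires.
#'
#' Sequences are upper-cased and restricted to the 20 amino-acid letters plus
#' `X` (unknown residue).  Record ids must be unique within a file.
#'
#' @param path Path to a FASTA file.
#' @param species Optional single species tag overriding header parsing for
#'   every record.
#' @return A data frame with columns `id`, `species` and `sequence`, one row
#'   per record, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1|At", "MIVAA"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, species = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^>", lines)
  if (!length(hdr_idx)) {
    if (all(!nzchar(trimws(lines)))) {
      warning("empty FASTA file: ", path, call. = FALSE)
      return(empty_proteome())
    }
    stop("not a FASTA file (no '>' header found): ", path, call. = FALSE)
  }
  first_content <- which(nzchar(trimws(lines)))[1L]
  if (first_content < hdr_idx[1L])
    stop("sequence data before first FASTA header at line ", first_content,
         call. = FALSE)

  n <- length(hdr_idx)
  ids <- character(n); sps <- character(n); seqs <- character(n)
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (k in seq_len(n)) {
    header <- sub("^>", "", lines[hdr_idx[k]])
    word <- strsplit(trimws(header), "[ \t]")[[1L]][1L]
    toks <- strsplit(word, "|", fixed = TRUE)[[1L]]
    ids[k] <- toks[1L]
    sps[k] <- if (!is.null(species)) species
              else if (length(toks) >= 2L && nzchar(toks[2L])) toks[2L]
              else word
    body_lines <- lines[seq(hdr_idx[k] + 1L, bounds[k + 1L] - 1L)]
    body_lines <- body_lines[nzchar(trimws(body_lines))]
    body <- toupper(gsub("[ \t]", "", paste(body_lines, collapse = "")))
    # report the first offending line number for illegal characters
    for (ln in seq_along(body_lines)) {
      chars <- unique(seq_chars(toupper(gsub("[ \t]", "", body_lines[ln]))))
      bad <- setdiff(chars, AA21)
      if (length(bad))
        stop("illegal residue character(s) ", paste(bad, collapse = ", "),
             " at line ", hdr_idx[k] + ln, " of ", path, call. = FALSE)
    }
    if (!nzchar(body))
      stop("record '", ids[k], "' has an empty sequence (line ",
           hdr_idx[k], ")", call. = FALSE)
    seqs[k] <- body
  }
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  data.frame(id = ids, species = sps, sequence = seqs,
             stringsAsFactors = FALSE)
}

empty_proteome <- function() {
  data.frame(id = character(), species = character(),
             sequence = character(), stringsAsFactors = FALSE)
}

#' Write a proteome table to FASTA
#'
#' Headers are written as `>id|species`; sequences are wrapped at 60
#' columns.  `read_fasta()` of the written file reproduces the input table.
#'
#' @param proteome Data frame with columns `id`, `species`, `sequence`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  stopifnot(all(c("id", "species", "sequence") %in% names(proteome)))
  con <- file(path, open = "wb")  # fixed "\n" EOL for byte-identical output
  on.exit(close(con))
  for (k in seq_len(nrow(proteome))) {
    writeLines(paste0(">", proteome$id[k], "|", proteome$species[k]), con)
    s <- proteome$sequence[k]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}
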