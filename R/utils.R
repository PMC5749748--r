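# Shared constants and small internal helpers.

# The 20 proteinogenic amino acids; X marks an unknown residue.  X is legal
# in input sequences but never matches any motif position class.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA21 <- c(AA20, "X")

#' @keywords internal
seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1L]]

# Fast byte-code view of a sequence (ASCII codes), used by the scanner.
seq_codes <- function(sequence) as.integer(charToRaw(sequence))

# logical lookup table over raw byte codes for a residue class
class_table <- function(residues) {
  tbl <- logical(256L)
  tbl[vapply(residues, utf8ToInt, integer(1L))] <- TRUE
  tbl
}

assert_valid_sequence <- function(sequence, id = "<sequence>") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence for '", id, "' must be a single string", call. = FALSE)
  if (nchar(sequence) < 1L)
    stop("sequence for '", id, "' is empty", call. = FALSE)
  bad <- setdiff(unique(seq_chars(sequence)), AA21)
  if (length(bad))
    stop("sequence for '", id, "' contains illegal residue characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# 0-based half-open interval -> 1-based inclusive, for report boundaries only
to_1based <- function(start0) start0 + 1L

`%||%` <- function(a, b) if (is.null(a)) b else a
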