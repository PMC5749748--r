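#' The 16-residue DWD motif pattern
#'
#' The DWD (WDxR) motif is the signature by which a WD40 protein binds the
#' DDB1 adaptor of CUL4-RING E3 ubiquitin ligases.  It is a hard
#' position-class consensus over 16 residues:
#'
#' ```
#' [IFVL]-[IFVL]-[AGST]-[AGST]-[AGST]-x-[DE]-x-x-[IFVL]-x-[IFVL]-[WY]-[DE]-[IFVL]-[RK]
#' ```
#'
#' Hydrophobic residues (Ile/Phe/Val/Leu) occupy positions 1, 2, 10, 12 and
#' 15; small residues (Ala/Gly/Ser/Thr) positions 3-5; acidic Asp/Glu
#' positions 7 and 14; Trp/Tyr position 13; and the functionally critical
#' Arg/Lys position 16 (mutations there weaken DDB1 binding).  `x`
#' positions accept any of the 20 amino acids.  The unknown residue `X`
#' matches no position, including `x` positions (conservative detection).
#'
#' @return An object of class `"dwd_motif_pattern"`: a list of 16 character
#'   vectors, each the allowed residue set at that position.
#' @export
dwd_motif_pattern <- function() {
  hyd <- c("I", "F", "V", "L")
  sml <- c("A", "G", "S", "T")
  acid <- c("D", "E")
  pat <- list(hyd, hyd, sml, sml, sml, AA20, acid, AA20, AA20, hyd,
              AA20, hyd, c("W", "Y"), acid, hyd, c("R", "K"))
  structure(pat, class = "dwd_motif_pattern")
}

#' @export
print.dwd_motif_pattern <- function(x, ...) {
  cat("DWD motif pattern (16 positions):\n")
  cat(paste(vapply(x, function(cls) {
    if (length(cls) == 20L) "x" else paste0("[", paste(cls, collapse = ""), "]")
  }, character(1L)), collapse = "-"), "\n")
  invisible(x)
}

#' Scan a sequence for DWD motif occurrences
#'
#' Reports every 16-residue window whose residues all fall in their motif
#' position classes.  Overlapping hits are all reported.  Hits are returned
#' in ascending start order with ordinals `D1`, `D2`, `D3`, ... — the
#' field's labels for the first, second, third motif occurrence N- to
#' C-terminal within one protein.
#'
#' @param sequence Amino-acid string (upper case, 20 letters plus `X`).
#' @param pattern A motif pattern from [dwd_motif_pattern()].
#' @param region Optional 0-based half-open interval `c(start, end)`;
#'   when given, only windows lying fully inside it are scanned.
#' @return Data frame with columns `start` (0-based), `motif_seq` (16-mer)
#'   and `ordinal`; zero rows when the sequence is shorter than 16 or no
#'   window matches.
#' @examples
#' scan_motifs("IIAAAADAAIAIWDIR")
#' @export
scan_motifs <- function(sequence, pattern = dwd_motif_pattern(),
                        region = NULL) {
  stopifnot(inherits(pattern, "dwd_motif_pattern"), length(pattern) == 16L)
  n <- nchar(sequence)
  if (n < 16L) return(empty_hits())
  codes <- seq_codes(sequence)
  nw <- n - 15L
  ok <- rep(TRUE, nw)
  for (p in seq_len(16L)) {
    tbl <- class_table(pattern[[p]])
    ok <- ok & tbl[codes[p:(p + nw - 1L)]]
  }
  starts0 <- which(ok) - 1L
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1L] <= region[2L])
    starts0 <- starts0[starts0 >= region[1L] & starts0 + 16L <= region[2L]]
  }
  if (!length(starts0)) return(empty_hits())
  data.frame(start = starts0,
             motif_seq = substring(sequence, starts0 + 1L, starts0 + 16L),
             ordinal = paste0("D", seq_along(starts0)),
             stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(start = integer(), motif_seq = character(),
             ordinal = character(), stringsAsFactors = FALSE)
}
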