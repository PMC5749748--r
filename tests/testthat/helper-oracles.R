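# Independent oracles and small random-fixture builders.  These
# deliberately re-derive results by brute force (per-window checks,
# exhaustive enumeration) and never call the code paths they verify.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa_string <- function(n) paste(sample(AA, n, replace = TRUE),
                                      collapse = "")

# --- motif scanning -------------------------------------------------------

# character-by-character check of one 16-mer against the position classes
brute_match_window <- function(window, pattern) {
  ch <- strsplit(window, "", fixed = TRUE)[[1L]]
  length(ch) == 16L &&
    all(vapply(seq_len(16L), function(p) ch[p] %in% pattern[[p]],
               logical(1L)))
}

# all matching 0-based window starts of a sequence, by per-window loop
brute_scan <- function(sequence, pattern) {
  n <- nchar(sequence)
  if (n < 16L) return(integer(0))
  starts <- integer(0)
  for (s in 0:(n - 16L)) {
    if (brute_match_window(substr(sequence, s + 1L, s + 16L), pattern))
      starts <- c(starts, s)
  }
  starts
}

# mutate one constrained position of a motif out of its class
break_motif <- function(motif, pattern) {
  constrained <- which(vapply(pattern, length, integer(1L)) < 20L)
  p <- sample(constrained, 1L)
  ch <- strsplit(motif, "", fixed = TRUE)[[1L]]
  ch[p] <- sample(setdiff(AA, pattern[[p]]), 1L)
  paste(ch, collapse = "")
}

# --- WD40 chain detection -------------------------------------------------

# maximum-size anchor chain by exhaustive subset enumeration (<= 12 anchors);
# consecutive end spacings must lie in [min_len, max_len]; ties resolved by
# leftmost first anchor.  Returns the chain of 0-based anchor ends.
brute_best_chain <- function(ends, min_len, max_len) {
  na <- length(ends)
  stopifnot(na <= 12L)
  best <- integer(0)
  for (mask in seq_len(2^na) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(na) - 1L)) > 0L)
    if (!length(sel)) next
    e <- ends[sel]
    if (length(e) > 1L) {
      gaps <- diff(e)
      if (any(gaps < min_len | gaps > max_len)) next
    }
    if (length(e) > length(best) ||
        (length(e) == length(best) && length(best) && e[1L] < best[1L]))
      best <- e
  }
  best
}

# --- alignment ------------------------------------------------------------

# exhaustive enumeration of all global alignments under affine gap costs
# (a gap of length k costs open + k * ext); returns a matrix with one row
# per alignment: score, identities, alignment length
enum_alignments <- function(a, b, mat, open = 11, ext = 1) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(ca); m <- length(cb)
  out <- list()
  rec <- function(i, j, state, score, ident, len) {
    if (i > n && j > m) {
      out[[length(out) + 1L]] <<- c(score, ident, len)
      return(invisible())
    }
    if (i <= n && j <= m)
      rec(i + 1L, j + 1L, "M", score + mat[ca[i], cb[j]],
          ident + (ca[i] == cb[j]), len + 1L)
    if (i <= n)
      rec(i + 1L, j, "X",
          score - ext - if (state == "X") 0 else open, ident, len + 1L)
    if (j <= m)
      rec(i, j + 1L, "Y",
          score - ext - if (state == "Y") 0 else open, ident, len + 1L)
  }
  rec(1L, 1L, "S", 0, 0L, 0L)
  do.call(rbind, out)
}

blosum62_test <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# --- misc -----------------------------------------------------------------

# random unrooted-compatible phylo tree with positive branch lengths
random_additive_tree <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, rooted = FALSE,
                   tip.label = sprintf("t%02d", seq_len(ntaxa)))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  tr
}

scan_proteome_hits <- function(proteins, pattern = dwd_motif_pattern()) {
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    h <- scan_motifs(proteins$sequence[i], pattern)
    if (nrow(h)) cbind(protein_id = proteins$id[i], h) else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(), start = integer(),
                      motif_seq = character(), ordinal = character())
  out
}
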