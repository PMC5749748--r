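#' Read a reference DWD database
#'
#' A reference database is a FASTA of reference proteins plus a two-column
#' TSV (`id`, `group`) assigning every reference record to a group label
#' (e.g. `G1`...`G15`, the phylogenetic groups of the reference organism's
#' DWD repertoire).
#'
#' @param fasta_path Reference FASTA.
#' @param group_tsv_path TSV with header columns `id` and `group`.
#' @return A list of class `"reference_db"` with elements `records`
#'   (proteome data frame) and `group_of` (named character vector).
#' @export
read_reference_db <- function(fasta_path, group_tsv_path) {
  records <- read_fasta(fasta_path)
  g <- utils::read.delim(group_tsv_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("id", "group") %in% names(g)))
    stop("group TSV must have columns 'id' and 'group'", call. = FALSE)
  missing <- setdiff(records$id, g$id)
  if (length(missing))
    stop("reference record(s) without group label: ",
         paste(missing, collapse = ", "), call. = FALSE)
  reference_db(records, stats::setNames(g$group, g$id))
}

#' Construct a reference database in memory
#'
#' @param records Proteome data frame (`id`, `species`, `sequence`).
#' @param group_of Named character vector mapping every record id to a
#'   group label.
#' @return A `"reference_db"` object.
#' @export
reference_db <- function(records, group_of) {
  missing <- setdiff(records$id, names(group_of))
  if (length(missing))
    stop("reference record(s) without group label: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(records = records,
                 group_of = group_of[records$id]),
            class = "reference_db")
}

#' Pairwise global alignment with percent identity and similarity
#'
#' Affine-gap global (Needleman-Wunsch) alignment under BLOSUM62 with
#' BLAST's default gap costs (a gap of length k costs
#' `gap_open + k * gap_extend` = 11 + k).  Percent identity is
#' `100 * identities / alignment_length` and percent similarity is
#' `100 * (identities + positive-scoring substitutions) / alignment_length`
#' — the "positives" convention — where `alignment_length` counts gap
#' columns.  A local-alignment mode is available for comparison with
#' HSP-style similarity.
#'
#' @param a,b Amino-acid strings (non-empty).
#' @param gap_open,gap_extend Affine gap parameters.
#' @param type `"global"` (default) or `"local"`.
#' @return A list with `identity`, `similarity` (percent), `score`,
#'   `alignment_length`, `aligned_cols` (columns with residues on both
#'   rows) and `coverage` (aligned columns / shorter sequence length).
#' @examples
#' global_align_percent("ACDEFG", "ACDEFG")$identity
#' @export
global_align_percent <- function(a, b, gap_open = 11, gap_extend = 1,
                                 type = c("global", "local")) {
  type <- match.arg(type)
  if (!nzchar(a) || !nzchar(b))
    stop("cannot align an empty sequence", call. = FALSE)
  # canonical argument order: when several alignments are optimal the DP
  # traceback is orientation-dependent, so align the lexicographically
  # smaller sequence as pattern to make identity/similarity symmetric
  swapped <- a > b
  if (swapped) { tmp <- a; a <- b; b <- tmp }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(), gapOpening = gap_open,
    gapExtension = gap_extend, type = type)
  pa <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  pb <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  len <- length(pa)
  both <- pa != "-" & pb != "-"
  ident <- sum(both & pa == pb)
  mat <- blosum62()
  pos <- sum(mat[cbind(pa[both], pb[both])] > 0)
  list(identity = 100 * ident / len,
       similarity = 100 * pos / len,
       score = Biostrings::score(al),
       alignment_length = len,
       aligned_cols = sum(both),
       coverage = sum(both) / min(nchar(a), nchar(b)))
}

# cache the BLOSUM62 matrix from Biostrings' data set
blosum62 <- local({
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

#' Build the query-by-reference percent-similarity matrix
#'
#' Aligns every query against every reference record and records percent
#' similarity (the heat-matrix quantity), percent identity and coverage.
#' When `ref_order` is supplied (e.g. the phylogenetic ordering of the
#' reference proteins), columns follow it.  Duplicate ids across the query
#' and reference namespaces are disambiguated by prefixing the query id
#' with `"q:"`.
#'
#' @param queries Proteome data frame of query proteins.
#' @param refdb A `"reference_db"`.
#' @param ref_order Optional character vector ordering the reference ids.
#' @param type Alignment type, see [global_align_percent()].
#' @return A list of class `"similarity_matrix"` with numeric matrices
#'   `similarity`, `identity`, `coverage` (rows = queries, cols =
#'   references).
#' @export
build_similarity_matrix <- function(queries, refdb, ref_order = NULL,
                                    type = "global") {
  stopifnot(inherits(refdb, "reference_db"), nrow(queries) > 0L,
            nrow(refdb$records) > 0L)
  ref_ids <- refdb$records$id
  if (!is.null(ref_order)) {
    stopifnot(setequal(ref_order, ref_ids))
    ref_ids <- ref_order
  }
  q_ids <- queries$id
  if (any(q_ids %in% ref_ids)) q_ids <- paste0("q:", q_ids)
  ref_seq <- stats::setNames(refdb$records$sequence, refdb$records$id)
  dims <- list(q_ids, ref_ids)
  sim <- matrix(NA_real_, nrow(queries), length(ref_ids), dimnames = dims)
  idn <- sim; cov <- sim
  for (i in seq_len(nrow(queries))) {
    for (j in seq_along(ref_ids)) {
      r <- global_align_percent(queries$sequence[i], ref_seq[[ref_ids[j]]],
                                type = type)
      sim[i, j] <- r$similarity
      idn[i, j] <- r$identity
      cov[i, j] <- r$coverage
    }
  }
  structure(list(similarity = sim, identity = idn, coverage = cov,
                 query_id = stats::setNames(queries$id, q_ids)),
            class = "similarity_matrix")
}

#' Assign queries to reference groups
#'
#' Each query is assigned the group of its best-hit reference (highest
#' percent similarity) provided the hit clears `min_similarity` and the
#' aligned-column coverage of the shorter sequence clears `min_coverage`;
#' ties are broken by higher percent identity, then lexicographically
#' smaller reference id.  Queries clearing neither are `unassigned` (`NA`
#' group).
#'
#' @param simmat A `"similarity_matrix"` from [build_similarity_matrix()].
#' @param refdb The matching `"reference_db"`.
#' @param min_similarity Minimum percent similarity (default 40: the
#'   positives fraction of globally aligned unrelated random proteins
#'   concentrates near 28 percent, so the cutoff must clear that null).
#' @param min_coverage Minimum coverage of the shorter sequence (default
#'   0.5).
#' @return Data frame with columns `query_id`, `best_ref`, `similarity`,
#'   `identity`, `coverage`, `group` (`NA` when unassigned).
#' @export
assign_groups <- function(simmat, refdb, min_similarity = 40,
                          min_coverage = 0.5) {
  stopifnot(inherits(simmat, "similarity_matrix"),
            inherits(refdb, "reference_db"))
  rows <- rownames(simmat$similarity)
  out <- lapply(seq_along(rows), function(i) {
    s <- simmat$similarity[i, ]
    best <- which(s == max(s))
    if (length(best) > 1L) {   # tie: higher identity, then lexicographic id
      idn <- simmat$identity[i, best]
      best <- best[idn == max(idn)]
      best <- best[order(colnames(simmat$similarity)[best])]
    }
    j <- best[1L]
    ref <- colnames(simmat$similarity)[j]
    ok <- s[j] >= min_similarity && simmat$coverage[i, j] >= min_coverage
    data.frame(query_id = unname(simmat$query_id[rows[i]]),
               best_ref = ref,
               similarity = unname(s[j]),
               identity = unname(simmat$identity[i, j]),
               coverage = unname(simmat$coverage[i, j]),
               group = if (ok) unname(refdb$group_of[ref]) else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-group orthology fraction
#'
#' For each reference group, the percentage of its members that have at
#' least one assigned query homolog (i.e. are the best hit of some
#' assigned query): `100 * covered_members / group_size`.
#'
#' @param refdb A `"reference_db"`.
#' @param assignments Data frame from [assign_groups()].
#' @return Data frame with columns `group`, `n_members`, `n_with_homolog`,
#'   `percent` (full precision; reports round to one decimal).
#' @export
group_orthology_fraction <- function(refdb, assignments) {
  stopifnot(inherits(refdb, "reference_db"))
  covered <- unique(assignments$best_ref[!is.na(assignments$group)])
  groups <- split(names(refdb$group_of), unname(refdb$group_of))
  empty <- vapply(groups, length, integer(1L)) == 0L
  if (any(empty)) {
    warning("excluding empty group(s): ",
            paste(names(groups)[empty], collapse = ", "), call. = FALSE)
    groups <- groups[!empty]
  }
  out <- data.frame(
    group = names(groups),
    n_members = vapply(groups, length, integer(1L)),
    n_with_homolog = vapply(groups, function(m) sum(m %in% covered),
                            integer(1L)),
    stringsAsFactors = FALSE)
  out$percent <- 100 * out$n_with_homolog / out$n_members
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}
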