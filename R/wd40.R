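#' Naive WD40 repeat detection by WD-anchor chaining
#'
#' WD40 proteins are built from several copies of 40-60 residue repeats
#' typically ending in the Trp-Asp (WD) dipeptide.  This detector is a
#' deliberately simple sequence-level heuristic (profile-based homology
#' search is out of scope; precomputed annotations can be supplied instead
#' via [resolve_wd40()]): it anchors on every `WD` dipeptide and chains
#' anchors whose end-to-end spacing lies in `[min_len, max_len]`.  The
#' longest such chain is found by dynamic programming over anchors (ties
#' broken by leftmost region start) and reported when it has at least
#' `min_repeats` units.
#'
#' The first unit of a chain is the `min_len` residues ending at its anchor
#' (clipped at sequence start); each subsequent unit spans from the previous
#' anchor end to the current one, so every unit ends with `WD`.
#'
#' @param protein A protein record: a list or one-row data frame with at
#'   least `id` and `sequence`.
#' @param min_len,max_len Allowed repeat-unit length range (residues).
#' @param min_repeats Minimum number of chained units for a call.  The
#'   default 4 (not 7, the canonical blade count) tolerates partially
#'   annotated repeats.
#' @return An object of class `"wd40_region"` — a list with `protein_id`,
#'   `units` (data frame of 0-based half-open `start`,`end`) and `span`
#'   (hull interval) — or `NULL` when no qualifying chain exists.
#' @export
detect_wd40_naive <- function(protein, min_len = 40L, max_len = 60L,
                              min_repeats = 4L) {
  sequence <- protein$sequence
  id <- protein$id %||% NA_character_
  stopifnot(min_len >= 1L, max_len >= min_len, min_repeats >= 1L)
  m <- gregexpr("WD", sequence, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) return(NULL)
  ends0 <- as.integer(m) + 1L  # 0-based half-open end of each WD anchor
  na <- length(ends0)

  # longest chain ending at each anchor; S = leftmost achievable first-anchor
  len <- rep(1L, na); pred <- rep(NA_integer_, na); first_end <- ends0
  for (j in seq_len(na)) {
    if (j == 1L) next
    for (i in seq_len(j - 1L)) {
      gap <- ends0[j] - ends0[i]
      if (gap < min_len || gap > max_len) next
      cand_len <- len[i] + 1L
      better <- cand_len > len[j] ||
        (cand_len == len[j] && first_end[i] < first_end[j])
      if (better) {
        len[j] <- cand_len; pred[j] <- i; first_end[j] <- first_end[i]
      }
    }
  }
  best_len <- max(len)
  if (best_len < min_repeats) return(NULL)
  cand <- which(len == best_len)
  j <- cand[which.min(first_end[cand])]
  chain <- integer(0)
  while (!is.na(j)) { chain <- c(j, chain); j <- pred[j] }
  e <- ends0[chain]
  starts <- c(max(0L, e[1L] - min_len),
              if (best_len > 1L) e[-best_len])
  units <- data.frame(start = starts, end = e)
  structure(list(protein_id = id, units = units,
                 span = c(units$start[1L], units$end[nrow(units)])),
            class = "wd40_region")
}

#' Resolve a protein's WD40 repeat region
#'
#' Dispatches between the naive detector and precomputed domain
#' annotations.  In annotation modes, annotation rows whose `domain_name`
#' is in `wd40_names` (case-insensitive) for this protein become repeat
#' units verbatim, regardless of sequence content — this is the hook for
#' substituting real WDSP/InterPro calls.
#'
#' @param protein Protein record (list or one-row data frame with `id`,
#'   `sequence`).
#' @param annotations Data frame as returned by [read_domain_tsv()], or
#'   `NULL`.
#' @param mode One of `"naive"`, `"annotation"`, `"annotation_else_naive"`.
#' @param wd40_names Character vector of domain names treated as WD40
#'   repeat annotations.
#' @param ... Passed to [detect_wd40_naive()].
#' @return A `"wd40_region"` or `NULL`.
#' @export
resolve_wd40 <- function(protein, annotations = NULL,
                         mode = c("naive", "annotation",
                                  "annotation_else_naive"),
                         wd40_names = "WD40", ...) {
  mode <- match.arg(mode)
  if (mode == "naive") return(detect_wd40_naive(protein, ...))
  rows <- if (is.null(annotations)) empty_domains() else
    annotations[annotations$protein_id == protein$id &
                  tolower(annotations$domain_name) %in% tolower(wd40_names), ,
                drop = FALSE]
  if (nrow(rows)) {
    plen <- nchar(protein$sequence)
    if (any(rows$start < 0L | rows$start >= rows$end | rows$end > plen))
      stop("malformed WD40 annotation interval(s) for protein '",
           protein$id, "'", call. = FALSE)
    rows <- rows[order(rows$start, rows$end), , drop = FALSE]
    units <- data.frame(start = as.integer(rows$start),
                        end = as.integer(rows$end))
    return(structure(list(protein_id = protein$id, units = units,
                          span = c(min(units$start), max(units$end))),
                     class = "wd40_region"))
  }
  if (mode == "annotation_else_naive")
    detect_wd40_naive(protein, ...)
  else
    NULL
}

#' Assemble a DWD record from a WD40 protein and its motif hits
#'
#' DWD proteins are the subset of WD40 proteins carrying at least one DWD
#' motif; a WD40 protein with zero hits is not a DWD and yields `NULL`.
#' Motif ordinals are recomputed in ascending start order, and other-domain
#' annotations are filtered to this protein's non-WD40 domains.
#'
#' @param protein Protein record with `id`, `species`, `sequence`.
#' @param region The protein's `"wd40_region"` (must be non-`NULL`:
#'   DWD is only sought within confirmed WD40 proteins).
#' @param hits Motif-hit data frame from [scan_motifs()]; may carry a
#'   `protein_id` column, which must match.
#' @param other_domains Optional domain-annotation data frame.
#' @param wd40_names Domain names excluded as WD40 annotations.
#' @return An object of class `"dwd_record"` (list with `protein_id`,
#'   `species`, `length`, `hits`, `region`, `other_domains`, `dwd_type`) or
#'   `NULL` when `hits` is empty.
#' @export
assemble_dwd <- function(protein, region, hits, other_domains = NULL,
                         wd40_names = "WD40") {
  if (is.null(region) || !inherits(region, "wd40_region"))
    stop("assemble_dwd() requires a wd40_region: DWDs are a subset of ",
         "WD40 proteins", call. = FALSE)
  if (!is.null(hits$protein_id) &&
      any(hits$protein_id != protein$id, na.rm = TRUE))
    stop("motif hits refer to a different protein than '", protein$id, "'",
         call. = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  hits <- hits[order(hits$start), , drop = FALSE]
  hits$ordinal <- paste0("D", seq_len(nrow(hits)))
  rownames(hits) <- NULL
  od <- if (is.null(other_domains)) empty_domains() else
    other_domains[other_domains$protein_id == protein$id &
                    !(tolower(other_domains$domain_name) %in%
                        tolower(wd40_names)), , drop = FALSE]
  rownames(od) <- NULL
  structure(list(protein_id = protein$id,
                 species = protein$species %||% NA_character_,
                 length = nchar(protein$sequence),
                 hits = hits[, c("start", "motif_seq", "ordinal")],
                 region = region,
                 other_domains = od,
                 dwd_type = NA_character_),
            class = "dwd_record")
}
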