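#' Default DWD type-classification rules
#'
#' The generic DWD classification (Types A-K, plus PP for partial
#' proteins) is driven by three criteria: position of the DWD motif,
#' number of DWD motifs, and presence/absence/topology of other domains.
#' The exact bin boundaries are not fixed by the criteria alone, so this
#' rule table is an explicit, documented reconstruction and every knob is
#' overridable (see [load_type_rules()]):
#'
#' * `PP` — protein flagged partial (caller-supplied predicate).
#' * Other domains present:
#'   * `K` — other domains present AND >= `multi_motif_min` motifs
#'     (checked before F-J);
#'   * `H` — other domains on both N- and C-terminal sides of the repeat
#'     region hull;
#'   * `J` — >= 2 distinct other-domain names on one side;
#'   * `I` — other domain nested inside the hull (or straddling it);
#'   * `F` — a single other domain N-terminal of the hull;
#'   * `G` — a single other domain C-terminal.
#' * Else `E` — >= `multi_motif_min` (default 2) motifs.
#' * Else `A`/`B`/`C`/`D` by quartile of relative motif position
#'   (motif start / protein length): breaks at 0.25, 0.5, 0.75.
#'
#' @param quartile_breaks Increasing numeric vector of 3 cut points in
#'   (0,1) separating types A/B/C/D.
#' @param multi_motif_min Motif count from which a record is multi-motif
#'   (types E/K).
#' @return An object of class `"dwd_type_rules"`.
#' @export
default_type_rules <- function(quartile_breaks = c(0.25, 0.5, 0.75),
                               multi_motif_min = 2L) {
  stopifnot(length(quartile_breaks) == 3L, !is.unsorted(quartile_breaks),
            all(quartile_breaks > 0 & quartile_breaks < 1),
            multi_motif_min >= 2L)
  structure(list(quartile_breaks = quartile_breaks,
                 multi_motif_min = as.integer(multi_motif_min)),
            class = "dwd_type_rules")
}

#' Load type rules from a JSON config
#'
#' Reads a JSON object with optional keys `quartile_breaks` and
#' `multi_motif_min`; unknown keys are rejected.  This is the hook for
#' matching an externally specified rule table exactly.
#'
#' @param path Path to a JSON file.
#' @return A `"dwd_type_rules"` object.
#' @export
load_type_rules <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("quartile_breaks", "multi_motif_min")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown type-rule key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  default_type_rules(
    quartile_breaks = cfg$quartile_breaks %||% c(0.25, 0.5, 0.75),
    multi_motif_min = cfg$multi_motif_min %||% 2L)
}

#' Classify a DWD record into a generic type
#'
#' Applies the rule precedence documented in [default_type_rules()].
#' Every record receives exactly one label; classification is a pure
#' function of the record (plus the `partial` flag), so it is invariant to
#' input order and re-running.
#'
#' @param record A `"dwd_record"` from [assemble_dwd()].
#' @param rules A `"dwd_type_rules"` object.
#' @param partial Logical: is this a partial protein?  The criterion (e.g.
#'   missing initial Met, annotated fragment) is supplied by the caller
#'   via [is_partial_protein()] or a custom predicate.
#' @return A single label in `A`-`K` or `"PP"`.
#' @export
classify_dwd <- function(record, rules = default_type_rules(),
                         partial = FALSE) {
  stopifnot(inherits(record, "dwd_record"), inherits(rules, "dwd_type_rules"))
  if (isTRUE(partial)) return("PP")
  od <- record$other_domains
  n_motifs <- nrow(record$hits)
  if (!is.null(od) && nrow(od) > 0L) {
    if (n_motifs >= rules$multi_motif_min) return("K")
    hull <- record$region$span
    side <- ifelse(od$end <= hull[1L], "N",
                   ifelse(od$start >= hull[2L], "C", "nested"))
    n_names <- unique(od$domain_name[side == "N"])
    c_names <- unique(od$domain_name[side == "C"])
    nested <- any(side == "nested")
    if (length(n_names) > 0L && length(c_names) > 0L) return("H")
    if (length(n_names) >= 2L || length(c_names) >= 2L) return("J")
    if (nested) return("I")
    if (length(n_names) == 1L) return("F")
    return("G")
  }
  if (n_motifs >= rules$multi_motif_min) return("E")
  rel <- record$hits$start[1L] / record$length
  br <- rules$quartile_breaks
  if (rel < br[1L]) "A" else if (rel < br[2L]) "B"
  else if (rel < br[3L]) "C" else "D"
}

#' Default partial-protein predicate
#'
#' A protein is flagged partial when its sequence does not begin with
#' methionine (no start Met suggests a truncated gene model).  Users with
#' curated fragment annotations should supply their own flags instead.
#'
#' @param sequence Amino-acid string.
#' @return Logical.
#' @export
is_partial_protein <- function(sequence) {
  substr(sequence, 1L, 1L) != "M"
}

#' Type distribution over a set of classified DWD records
#'
#' Counts each label and reports fractions over the non-PP labels; PP
#' (partial proteins, no architecture call) is counted but excluded from
#' the fraction denominator.
#'
#' @param labels Character vector of labels from [classify_dwd()] (or a
#'   list of classified `"dwd_record"`s, in which case their `dwd_type`
#'   fields are used).
#' @return Data frame with columns `label`, `count`, `fraction`
#'   (`fraction` is `NA` for PP); zero rows for empty input.
#' @export
type_distribution <- function(labels) {
  if (is.list(labels))
    labels <- vapply(labels, function(r) r$dwd_type, character(1L))
  if (!length(labels))
    return(data.frame(label = character(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  tab <- table(labels)
  out <- data.frame(label = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  n_eff <- sum(out$count[out$label != "PP"])
  out$fraction <- ifelse(out$label == "PP", NA_real_,
                         if (n_eff > 0L) out$count / n_eff else NA_real_)
  out[order(out$label), , drop = FALSE]
}
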