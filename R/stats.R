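#' Per-species WD40/DWD summary statistics
#'
#' Computes, for each species, the WD40 count, DWD count, DWD/WD40 ratio
#' (percent), and the distribution of motif counts per DWD (fractions of
#' DWDs carrying exactly 1, 2, or 3-or-more motifs — proteins with more
#' than three motifs are binned as `3+`).
#'
#' @param wd40_table Data frame with one row per detected WD40 protein,
#'   columns `protein_id`, `species`.
#' @param dwd_table Data frame with one row per DWD record, columns
#'   `protein_id`, `species`, `n_motifs`, and optionally `dwd_type`.
#' @param species Optional character vector of species to report on
#'   (default: every species occurring in either table); species without
#'   rows get zero counts and missing ratios.
#' @return Data frame with one row per species: `species`, `n_wd40`,
#'   `n_dwd`, `dwd_ratio_pct` (`NA` when `n_wd40` is 0), `frac_1`,
#'   `frac_2`, `frac_3plus` (`NA` when `n_dwd` is 0).
#' @export
compute_species_stats <- function(wd40_table, dwd_table, species = NULL) {
  stopifnot(all(c("protein_id", "species") %in% names(wd40_table)))
  if (is.null(species))
    species <- unique(c(wd40_table$species, dwd_table$species))
  species <- sort(species)
  rows <- lapply(species, function(sp) {
    n_wd40 <- sum(wd40_table$species == sp)
    dw <- dwd_table[dwd_table$species == sp, , drop = FALSE]
    n_dwd <- nrow(dw)
    if (n_dwd > n_wd40)
      stop("species '", sp, "' has more DWDs than WD40s: inconsistent ",
           "input tables", call. = FALSE)
    ratio <- if (n_wd40 > 0L) 100 * n_dwd / n_wd40 else NA_real_
    if (n_dwd > 0L) {
      f1 <- mean(dw$n_motifs == 1L)
      f2 <- mean(dw$n_motifs == 2L)
      f3 <- mean(dw$n_motifs >= 3L)
    } else f1 <- f2 <- f3 <- NA_real_
    data.frame(species = sp, n_wd40 = n_wd40, n_dwd = n_dwd,
               dwd_ratio_pct = ratio, frac_1 = f1, frac_2 = f2,
               frac_3plus = f3, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write per-species and pooled summary reports
#'
#' Emits the species-statistics table as TSV (percentages rendered to one
#' decimal) and JSON (full precision), appending a pooled row recomputed
#' from summed counts (so with equal per-species sizes the pooled ratio is
#' the mean of the per-species ratios).
#'
#' @param stats_df Data frame from [compute_species_stats()].
#' @param dwd_table The DWD table used to build `stats_df` (needed to
#'   recompute pooled motif-count fractions).
#' @param outdir Output directory.
#' @return Invisibly, the full table including the pooled row.
#' @export
aggregate_report <- function(stats_df, dwd_table, outdir) {
  stopifnot(nrow(stats_df) >= 1L)
  n_wd40 <- sum(stats_df$n_wd40)
  n_dwd <- sum(stats_df$n_dwd)
  pooled <- data.frame(
    species = "pooled", n_wd40 = n_wd40, n_dwd = n_dwd,
    dwd_ratio_pct = if (n_wd40 > 0L) 100 * n_dwd / n_wd40 else NA_real_,
    frac_1 = if (n_dwd > 0L) mean(dwd_table$n_motifs == 1L) else NA_real_,
    frac_2 = if (n_dwd > 0L) mean(dwd_table$n_motifs == 2L) else NA_real_,
    frac_3plus = if (n_dwd > 0L) mean(dwd_table$n_motifs >= 3L) else NA_real_,
    stringsAsFactors = FALSE)
  full <- rbind(stats_df, pooled)

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  disp <- full
  disp$dwd_ratio_pct <- sprintf("%.1f", disp$dwd_ratio_pct)
  for (cl in c("frac_1", "frac_2", "frac_3plus"))
    disp[[cl]] <- sprintf("%.1f", 100 * full[[cl]])
  disp$dwd_ratio_pct[is.na(full$dwd_ratio_pct)] <- ""
  for (cl in c("frac_1", "frac_2", "frac_3plus"))
    disp[[cl]][is.na(full[[cl]])] <- ""
  names(disp)[names(disp) == "frac_1"] <- "pct_1_motif"
  names(disp)[names(disp) == "frac_2"] <- "pct_2_motifs"
  names(disp)[names(disp) == "frac_3plus"] <- "pct_3plus_motifs"
  write_tsv(disp, file.path(outdir, "species_stats.tsv"))
  jsonlite::write_json(full, file.path(outdir, "species_stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(full)
}
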