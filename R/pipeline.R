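#' Build or load a pipeline run configuration
#'
#' A single configuration object drives the whole pipeline.  It can be
#' written to / read from JSON; unknown keys in a JSON file are rejected
#' so typos fail loudly rather than silently falling back to defaults.
#'
#' @param input_fastas Character vector of input proteome FASTA paths.
#' @param outdir Output directory.
#' @param annotations Optional domain-annotation TSV path.
#' @param refdb_fasta,refdb_groups Optional reference-database paths
#'   (FASTA + group TSV); both or neither.
#' @param detector_mode WD40 resolution mode, see [resolve_wd40()].
#' @param min_len,max_len,min_repeats Naive-detector thresholds.
#' @param region_only Logical; restrict the motif scan to the repeat
#'   region hull instead of the full sequence (default scans the whole
#'   protein of WD40-confirmed records).
#' @param min_similarity,min_coverage Homolog-call thresholds.
#' @param n_boot Bootstrap replicates for the motif tree (1000 mirrors
#'   the usual published setting; 0 skips bootstrapping).
#' @param k_groups Number of groups to cut the motif tree into.
#' @param tree_motif Which motif represents a multi-motif protein in
#'   trees (default `"D1"`).
#' @param flag_partial Logical; classify proteins without an initial Met
#'   as PP (partial).
#' @param seed Integer seed funnelling all run randomness.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(input_fastas = character(), outdir = "dwd_out",
                       annotations = NULL, refdb_fasta = NULL,
                       refdb_groups = NULL,
                       detector_mode = "naive", min_len = 40L,
                       max_len = 60L, min_repeats = 4L,
                       region_only = FALSE, min_similarity = 40,
                       min_coverage = 0.5, n_boot = 1000L,
                       k_groups = 15L, tree_motif = "D1",
                       flag_partial = FALSE, seed = 1L) {
  if (xor(is.null(refdb_fasta), is.null(refdb_groups)))
    stop("refdb_fasta and refdb_groups must be given together",
         call. = FALSE)
  structure(list(input_fastas = input_fastas, outdir = outdir,
                 annotations = annotations, refdb_fasta = refdb_fasta,
                 refdb_groups = refdb_groups,
                 detector_mode = detector_mode,
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 min_repeats = as.integer(min_repeats),
                 region_only = isTRUE(region_only),
                 min_similarity = min_similarity,
                 min_coverage = min_coverage,
                 n_boot = as.integer(n_boot),
                 k_groups = as.integer(k_groups),
                 tree_motif = tree_motif,
                 flag_partial = isTRUE(flag_partial),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file with `run_config` fields.
#' @export
load_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- lapply(cfg, function(x) if (is.list(x) && !length(x)) NULL else x)
  known <- names(formals(run_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown run_config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  do.call(run_config, cfg)
}

#' Simulate a dataset (pipeline subcommand)
#'
#' Thin orchestration wrapper over [generate_dataset()]: validates the
#' simulation config, writes the dataset and logs file paths.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, the [generate_dataset()] result.
#' @export
cmd_simulate <- function(config, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) && !force)
    stop("output directory ", outdir,
         " is not empty (use force = TRUE to overwrite)", call. = FALSE)
  res <- generate_dataset(config, outdir)
  message("simulate: wrote ", nrow(res$proteins), " proteins for ",
          length(unique(res$proteins$species)), " species to ", outdir)
  invisible(res)
}

#' Run the full DWD discovery pipeline
#'
#' Executes the stages in order: WD40 detection, DWD motif scan, type
#' classification, (optional) homology characterization against a
#' reference database, motif phylogeny with tree cutting, and per-species
#' summary statistics.  Every intermediate is written to `outdir` as
#' TSV/Newick/JSON; per-stage record counts are logged via `message()`.
#' Motif start positions in the hit TSV are printed 1-based inclusive
#' (the biologists' convention); all in-memory coordinates stay 0-based
#' half-open.
#'
#' @param config A [run_config()].
#' @param force Overwrite an existing non-empty output directory.
#' @return Invisibly, a list with the main result tables (`proteome`,
#'   `wd40`, `hits`, `dwd`, `types`, `assignments`, `orthology`, `tree`,
#'   `groups`, `stats`).
#' @export
cmd_run_all <- function(config, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(config$outdir) && length(list.files(config$outdir)) &&
      !force)
    stop("output directory ", config$outdir,
         " is not empty (use force = TRUE to overwrite)", call. = FALSE)
  set.seed(config$seed)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  missing <- config$input_fastas[!file.exists(config$input_fastas)]
  if (length(missing))
    stop("input FASTA(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  proteome <- do.call(rbind, lapply(config$input_fastas, read_fasta))
  if (anyDuplicated(proteome$id))
    stop("duplicate protein ids across input FASTAs", call. = FALSE)
  message("inputs: ", nrow(proteome), " proteins, ",
          length(unique(proteome$species)), " species")
  ann <- if (!is.null(config$annotations))
    read_domain_tsv(config$annotations) else NULL

  # --- detect ---
  regions <- vector("list", nrow(proteome))
  for (i in seq_len(nrow(proteome))) {
    regions[[i]] <- resolve_wd40(
      as.list(proteome[i, ]), annotations = ann,
      mode = config$detector_mode, min_len = config$min_len,
      max_len = config$max_len, min_repeats = config$min_repeats)
  }
  is_wd40 <- !vapply(regions, is.null, logical(1L))
  wd40_units <- do.call(rbind, lapply(regions[is_wd40], function(r)
    data.frame(protein_id = r$protein_id, unit_start = r$units$start,
               unit_end = r$units$end, stringsAsFactors = FALSE)))
  if (is.null(wd40_units))
    wd40_units <- data.frame(protein_id = character(),
                             unit_start = integer(), unit_end = integer())
  write_tsv(wd40_units, file.path(config$outdir, "wd40_regions.tsv"))
  wd40_table <- proteome[is_wd40, c("id", "species"), drop = FALSE]
  names(wd40_table)[1L] <- "protein_id"
  message("detect: ", nrow(wd40_table), " WD40 proteins")

  # --- scan + assemble ---
  pattern <- dwd_motif_pattern()
  dwd <- list()
  for (i in which(is_wd40)) {
    reg <- regions[[i]]
    hits <- scan_motifs(proteome$sequence[i], pattern,
                        region = if (config$region_only) reg$span else NULL)
    rec <- assemble_dwd(as.list(proteome[i, ]), reg, hits,
                        other_domains = ann)
    if (!is.null(rec)) dwd[[length(dwd) + 1L]] <- rec
  }
  hit_rows <- do.call(rbind, lapply(dwd, function(r)
    data.frame(protein_id = r$protein_id, species = r$species,
               ordinal = r$hits$ordinal,
               start_1based = to_1based(r$hits$start),
               motif_seq = r$hits$motif_seq, stringsAsFactors = FALSE)))
  if (is.null(hit_rows))
    hit_rows <- data.frame(protein_id = character(), species = character(),
                           ordinal = character(), start_1based = integer(),
                           motif_seq = character())
  write_tsv(hit_rows, file.path(config$outdir, "motif_hits.tsv"))
  message("scan: ", length(dwd), " DWD proteins, ", nrow(hit_rows),
          " motif hits")

  # --- classify ---
  seq_of <- stats::setNames(proteome$sequence, proteome$id)
  for (i in seq_along(dwd)) {
    partial <- config$flag_partial &&
      is_partial_protein(seq_of[[dwd[[i]]$protein_id]])
    dwd[[i]]$dwd_type <- classify_dwd(dwd[[i]], partial = partial)
  }
  dwd_table <- do.call(rbind, lapply(dwd, function(r)
    data.frame(protein_id = r$protein_id, species = r$species,
               n_motifs = nrow(r$hits), dwd_type = r$dwd_type,
               stringsAsFactors = FALSE)))
  if (is.null(dwd_table))
    dwd_table <- data.frame(protein_id = character(), species = character(),
                            n_motifs = integer(), dwd_type = character())
  write_tsv(dwd_table, file.path(config$outdir, "dwd_types.tsv"))
  tdist <- type_distribution(dwd_table$dwd_type)
  write_tsv(tdist, file.path(config$outdir, "type_distribution.tsv"))
  message("classify: ", nrow(dwd_table), " records, ",
          nrow(tdist), " types")

  # --- characterize (optional) ---
  assignments <- NULL; orthology <- NULL
  if (!is.null(config$refdb_fasta)) {
    refdb <- read_reference_db(config$refdb_fasta, config$refdb_groups)
    queries <- proteome[proteome$id %in% dwd_table$protein_id, ,
                        drop = FALSE]
    if (nrow(queries)) {
      simmat <- build_similarity_matrix(queries, refdb)
      write_tsv(cbind(query_id = rownames(simmat$similarity),
                      as.data.frame(simmat$similarity)),
                file.path(config$outdir, "similarity_matrix.tsv"))
      assignments <- assign_groups(simmat, refdb,
                                   min_similarity = config$min_similarity,
                                   min_coverage = config$min_coverage)
      write_tsv(assignments, file.path(config$outdir, "assignments.tsv"))
      orthology <- group_orthology_fraction(refdb, assignments)
      write_tsv(orthology, file.path(config$outdir, "group_orthology.tsv"))
      message("characterize: ", sum(!is.na(assignments$group)), "/",
              nrow(assignments), " queries assigned")
    }
  }

  # --- phylogeny ---
  tree <- NULL; groups <- NULL
  rep_hits <- dwd_table$protein_id
  if (length(dwd) >= 4L) {
    motifs <- vapply(dwd, function(r) {
      m <- r$hits$motif_seq[r$hits$ordinal == config$tree_motif]
      if (length(m)) m[1L] else NA_character_
    }, character(1L))
    names(motifs) <- vapply(dwd, function(r) r$protein_id, character(1L))
    motifs <- motifs[!is.na(motifs)]
    if (length(motifs) >= 4L) {
      if (config$n_boot > 0L) {
        tree <- bootstrap_support(motifs, n_reps = config$n_boot,
                                  seed = config$seed)
      } else {
        tree <- neighbor_joining(p_distance_matrix(motifs))
      }
      write_newick(tree, file.path(config$outdir, "motif_tree.nwk"))
      k <- min(config$k_groups, length(motifs))
      groups <- cut_tree_groups(tree, k)
      write_tsv(data.frame(protein_id = names(groups),
                           group = unname(groups),
                           stringsAsFactors = FALSE),
                file.path(config$outdir, "tree_groups.tsv"))
      message("phylo: ", length(motifs), " motif leaves, ", k, " groups")
    }
  }

  # --- stats ---
  stats_df <- compute_species_stats(wd40_table, dwd_table)
  full_stats <- aggregate_report(stats_df, dwd_table, config$outdir)
  message("stats: ", nrow(stats_df), " species")

  invisible(list(proteome = proteome, wd40 = wd40_table, hits = hit_rows,
                 dwd = dwd, types = dwd_table, assignments = assignments,
                 orthology = orthology, tree = tree, groups = groups,
                 stats = full_stats))
}
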