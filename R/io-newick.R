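#' Write a phylogenetic tree to Newick
#'
#' Serializes an [ape::ape] `"phylo"` tree with branch lengths printed to
#' exactly six decimals and integer bootstrap supports (from `node.label`)
#' as internal-node labels.  Leaf names containing Newick metacharacters
#' (`( ) , : ; '` or whitespace) are single-quoted.  Re-parsing with
#' [read_newick()] yields an isomorphic tree.
#'
#' @param tree A `"phylo"` object (rooted or unrooted; branch lengths
#'   optional — absent lengths are omitted, not zero-filled).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  txt <- newick_string(tree)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con)
  invisible(path)
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] returning a `"phylo"` object.
#'
#' @param path Path to a Newick file.
#' @return A `"phylo"` object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path, call. = FALSE)
  # ape keeps single quotes around quoted labels; strip and unescape them
  unquote <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]))
    x
  }
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  tr
}

# Newick text for a phylo object, 6-decimal branch lengths, node labels kept.
newick_string <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt_label <- function(lab) {
    if (grepl("[(),:;'[:space:]]", lab))
      paste0("'", gsub("'", "''", lab), "'")
    else lab
  }
  node_txt <- function(node) {
    if (node <= ntip) return(fmt_label(tree$tip.label[node]))
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(e) {
      child <- tree$edge[e, 2L]
      txt <- node_txt(child)
      if (!is.null(tree$edge.length))
        txt <- paste0(txt, sprintf(":%.6f", tree$edge.length[e]))
      txt
    }, character(1L))
    lab <- ""
    if (!is.null(tree$node.label)) {
      lab <- tree$node.label[node - ntip]
      if (is.na(lab)) lab <- ""
    }
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  paste0(node_txt(root), ";")
}
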