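#' p-distance between two aligned sequences
#'
#' The proportion of differing sites between two equal-length aligned
#' sequences (amino-acid differences per site).  Sites where either
#' residue is `X` (unknown) are excluded from both numerator and
#' denominator.
#'
#' @param a,b Equal-length aligned strings.
#' @return A proportion in `[0, 1]`.
#' @examples
#' p_distance("AAAA", "AAAT")  # 0.25
#' @export
p_distance <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (length(ca) != length(cb))
    stop("p_distance() requires equal-length sequences", call. = FALSE)
  keep <- ca != "X" & cb != "X"
  if (!any(keep))
    stop("no comparable sites (all positions carry X)", call. = FALSE)
  mean(ca[keep] != cb[keep])
}

#' p-distance matrix over a motif alignment
#'
#' A motif alignment is a named character vector of equal-length sequences
#' (for DWD motifs, fixed 16-mers aligned positionally — no gaps exist, so
#' the alignment is the identity mapping of columns).
#'
#' @param alignment Named character vector; names unique, sequences of one
#'   common length.
#' @return Symmetric numeric matrix with zero diagonal and dimnames from
#'   the alignment names.
#' @export
p_distance_matrix <- function(alignment) {
  stopifnot(length(alignment) >= 2L, !is.null(names(alignment)),
            !anyDuplicated(names(alignment)))
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L)
    stop("alignment rows must share one length", call. = FALSE)
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  pdist_from_char_matrix(mat, names(alignment))
}

# rows = taxa, cols = sites; X-masked proportion of differing sites
pdist_from_char_matrix <- function(mat, labels) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  notx <- mat != "X"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      keep <- notx[i, ] & notx[j, ]
      if (!any(keep))
        stop("no comparable sites between '", labels[i], "' and '",
             labels[j], "'", call. = FALSE)
      d[i, j] <- d[j, i] <- mean(mat[i, keep] != mat[j, keep])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair `(i, j)`
#' minimizing `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is
#' joined, with branch lengths from the standard NJ formulas and the final
#' three nodes resolved in closed form (`a = (dAB + dAC - dBC)/2`, etc.).
#' Ties in `Q` are broken by the lexicographically smallest label pair
#' (each internal node is represented by the smallest leaf label beneath
#' it), making the output independent of input row order.  Negative branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' branch, preserving the pair's summed length.
#'
#' NJ is consistent on additive matrices: the returned tree's path-length
#' matrix then reproduces the input exactly.
#'
#' @param d Symmetric numeric matrix with zero diagonal, non-negative
#'   entries and unique dimnames; at least 3 taxa.
#' @return An unrooted `"phylo"` tree (trifurcating at the root node).
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (is.null(rownames(d))) stop("distance matrix needs labels", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(d < 0))
    stop("distance matrix must be non-negative", call. = FALSE)

  frag <- quote_newick_labels(rownames(d))   # newick fragment per node
  rep_lab <- rownames(d)                     # smallest leaf label beneath
  D <- unname(d)
  active <- seq_len(n)

  while (length(active) > 3L) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    if (nrow(cand) > 1L) {   # lexicographic label-pair tie-break
      keys <- apply(cand, 1L, function(ij) {
        labs <- sort(rep_lab[active[ij]])
        paste(labs, collapse = "\r")
      })
      cand <- cand[order(keys), , drop = FALSE]
    }
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    dij <- Dm[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    ai <- active[i]; aj <- active[j]
    new_frag <- sprintf("(%s:%.15g,%s:%.15g)", frag[ai], li, frag[aj], lj)
    new_d <- (D[ai, active] + D[aj, active] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    k <- nrow(D)
    D[k, active] <- new_d; D[active, k] <- new_d; D[k, k] <- 0
    frag <- c(frag, new_frag)
    rep_lab <- c(rep_lab, min(rep_lab[ai], rep_lab[aj]))
    active <- c(setdiff(active, c(ai, aj)), k)
  }

  a1 <- active[1L]; a2 <- active[2L]; a3 <- active[3L]
  d12 <- D[a1, a2]; d13 <- D[a1, a3]; d23 <- D[a2, a3]
  l1 <- max(0, (d12 + d13 - d23) / 2)
  l2 <- max(0, (d12 + d23 - d13) / 2)
  l3 <- max(0, (d13 + d23 - d12) / 2)
  txt <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[a1], l1, frag[a2], l2, frag[a3], l3)
  ape::read.tree(text = txt)
}

quote_newick_labels <- function(labs) {
  vapply(labs, function(lab) {
    if (grepl("[(),:;'[:space:]]", lab))
      paste0("'", gsub("'", "''", lab), "'")
    else lab
  }, character(1L))
}

# --- bipartitions ---------------------------------------------------------

# For every internal (non-root) node of an ape tree, the canonical key of
# the bipartition induced by the edge above it, plus that edge's length.
# Canonical form: the side NOT containing the alphabetically first leaf,
# sorted and collapsed.  Returns a data frame (node, key, length).
internal_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  if (nnode < 2L)
    return(data.frame(node = integer(), key = character(),
                      length = numeric(), stringsAsFactors = FALSE))
  root <- ntip + 1L
  below <- clade_leaves(tree)
  anchor <- min(tree$tip.label)
  all_leaves <- tree$tip.label
  nodes <- setdiff((ntip + 1L):(ntip + nnode), root)
  keys <- character(length(nodes)); lens <- numeric(length(nodes))
  for (k in seq_along(nodes)) {
    nd <- nodes[k]
    side <- below[[nd]]
    if (anchor %in% side) side <- setdiff(all_leaves, side)
    keys[k] <- paste(sort(side), collapse = "\r")
    e <- which(tree$edge[, 2L] == nd)
    lens[k] <- if (!is.null(tree$edge.length)) tree$edge.length[e] else NA_real_
  }
  data.frame(node = nodes, key = keys, length = lens,
             stringsAsFactors = FALSE)
}

# leaf labels below every node (index by node id)
clade_leaves <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  below <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  # edges in ape "cladewise" order: children appear after parents; walk
  # reversed so children are resolved before their parent is assembled
  ord <- rev(seq_len(nrow(tree$edge)))
  for (e in ord) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the reference NJ tree from the full fixed-length alignment, then
#' resamples alignment columns with replacement `n_reps` times,
#' recomputing p-distances and the NJ tree each time.  The support of each
#' internal edge of the reference tree is the percentage of replicates
#' containing the same bipartition, stored as integer node labels
#' (`node.label`) on the child node of each internal edge; the root label
#' is empty.
#'
#' A bipartition only counts as present in a replicate when its internal
#' edge has positive length (`> 1e-12`): a zero-length edge carries no
#' signal, so fully degenerate alignments (all rows identical) yield
#' support 0 everywhere rather than spuriously perfect support for an
#' arbitrary resolution.
#'
#' @param alignment Named character vector of equal-length sequences
#'   (>= 4).
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed; fixed seed gives identical supports.
#' @return The reference `"phylo"` tree with `node.label` supports.
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = NULL) {
  stopifnot(length(alignment) >= 4L, n_reps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  labels <- names(alignment)
  nsites <- ncol(mat)
  ref <- neighbor_joining(pdist_from_char_matrix(mat, labels))
  bip <- internal_bipartitions(ref)
  counts <- stats::setNames(rep(0L, nrow(bip)), bip$key)
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(nsites, nsites, replace = TRUE)
    dm <- pdist_from_char_matrix(mat[, cols, drop = FALSE], labels)
    tr <- neighbor_joining(dm)
    bp <- internal_bipartitions(tr)
    seen <- unique(bp$key[bp$length > 1e-12])
    hit <- intersect(seen, names(counts))
    counts[hit] <- counts[hit] + 1L
  }
  support <- as.integer(round(100 * counts / n_reps))
  ntip <- length(ref$tip.label)
  ref$node.label <- rep("", ref$Nnode)
  ref$node.label[bip$node - ntip] <- as.character(support)
  ref
}

#' Cut a tree into k leaf groups
#'
#' Splits a tree into `k` groups of leaves by severing its longest edges:
#' candidate edges are ranked by branch length (descending), then by
#' bootstrap support (higher first; edges without support rank last), then
#' by the lexicographically smallest leaf below the edge.  Edges are
#' removed in rank order, but only when the removal splits a
#' leaf-containing component into two leaf-containing components, until
#' `k` groups exist.  Groups are labelled `G1`...`Gk` by the order of
#' their smallest leaf label.
#'
#' @param tree A `"phylo"` tree with branch lengths.
#' @param k Number of groups, `1 <= k <=` number of leaves.
#' @return Named character vector mapping each leaf label to its group.
#' @export
cut_tree_groups <- function(tree, k) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (k > ntip) stop("k exceeds the number of leaves", call. = FALSE)
  if (k < 1L) stop("k must be positive", call. = FALSE)
  ne <- nrow(tree$edge)
  below <- clade_leaves(tree)
  lens <- tree$edge.length %||% rep(0, ne)
  supp <- rep(-Inf, ne)
  if (!is.null(tree$node.label)) {
    for (e in seq_len(ne)) {
      ch <- tree$edge[e, 2L]
      if (ch > ntip) {
        s <- suppressWarnings(as.numeric(tree$node.label[ch - ntip]))
        if (!is.na(s)) supp[e] <- s
      }
    }
  }
  min_leaf <- vapply(tree$edge[, 2L], function(ch) min(below[[ch]]),
                     character(1L))
  ord <- order(-lens, -supp, min_leaf)

  removed <- logical(ne)
  comp_of <- function() {      # component id per node, over kept edges
    nn <- ntip + tree$Nnode
    comp <- seq_len(nn)
    find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
    for (e in which(!removed)) {
      a <- find(tree$edge[e, 1L]); b <- find(tree$edge[e, 2L])
      if (a != b) comp[a] <- b
    }
    vapply(seq_len(nn), find, integer(1L))
  }
  n_groups <- 1L
  for (e in ord) {
    if (n_groups >= k) break
    removed[e] <- TRUE
    comp <- comp_of()
    leaf_comps <- unique(comp[seq_len(ntip)])
    if (length(leaf_comps) == n_groups + 1L) {
      n_groups <- n_groups + 1L
    } else {
      removed[e] <- FALSE      # split stranded no new leaf group
    }
  }
  if (n_groups < k)
    stop("could not separate ", k, " leaf groups", call. = FALSE)
  comp <- comp_of()
  leaf_comp <- comp[seq_len(ntip)]
  groups <- split(tree$tip.label, leaf_comp)
  groups <- groups[order(vapply(groups, min, character(1L)))]
  out <- character(ntip)
  names(out) <- tree$tip.label
  for (g in seq_along(groups)) out[groups[[g]]] <- paste0("G", g)
  out
}
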