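#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q-criterion
#' Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k). Taxa are first put
#' in sorted label order, so the result is independent of input order; at
#' each step the pair minimizing Q is joined, with ties broken by the
#' smallest label pair.
#' Negative branch lengths are clamped to zero with the deficit
#' transferred to the sister branch (the sum of the two sibling branch
#' lengths is preserved), keeping path lengths approximately additive.
#'
#' On an exactly additive matrix the tree reproduces all leaf-to-leaf
#' path lengths.
#'
#' @param dm A [dist_matrix()] with at least 3 labels.
#' @return An unrooted `ape` `"phylo"` tree (trifurcating root node) with
#'   the matrix labels as tips.
#' @export
neighbor_joining <- function(dm) {
  labels <- dm$labels
  n <- length(labels)
  if (n < 3) stopf("neighbor joining requires at least 3 taxa",
                   class = "too_few_taxa_error")
  if (anyNA(dm$values)) stopf("distance matrix contains NaN", class = "data_error")
  ord <- order(labels)
  labels <- labels[ord]
  d <- dm$values[ord, ord, drop = FALSE]
  frag <- labels                    # newick fragment per active node
  act <- seq_len(n)                 # active node indices in original order
  while (length(act) > 3) {
    m <- length(act)
    dd <- d[act, act, drop = FALSE]
    r <- rowSums(dd)
    q <- (m - 2) * dd - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]      # positions within act
    dij <- dd[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    ai <- act[i]; aj <- act[j]
    frag[ai] <- sprintf("(%s:%.12g,%s:%.12g)", frag[ai], bi, frag[aj], bj)
    newd <- (d[ai, act] + d[aj, act] - dij) / 2
    d[ai, act] <- newd
    d[act, ai] <- newd
    d[ai, ai] <- 0
    act <- act[-j]                  # merged node keeps position of i
  }
  a1 <- act[1]; a2 <- act[2]; a3 <- act[3]
  b1 <- max((d[a1, a2] + d[a1, a3] - d[a2, a3]) / 2, 0)
  b2 <- max((d[a1, a2] + d[a2, a3] - d[a1, a3]) / 2, 0)
  b3 <- max((d[a1, a3] + d[a2, a3] - d[a1, a2]) / 2, 0)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[a1], b1, frag[a2], b2, frag[a3], b3)
  ape::read.tree(text = nwk)
}

# canonical string for each non-trivial split of an unrooted tree, relative
# to a fixed reference label ordering: the side NOT containing ref_labels[1]
tree_splits <- function(tree, ref_labels) {
  parts <- ape::prop.part(tree)
  tips <- attr(parts, "labels")
  n <- length(tips)
  out <- character(0)
  for (p in parts) {
    side <- tips[p]
    if (length(side) <= 1 || length(side) >= n - 1) next
    if (ref_labels[1] %in% side) side <- setdiff(ref_labels, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

# split string for each internal node of a tree (NA for trivial splits)
node_split_strings <- function(tree, ref_labels) {
  parts <- ape::prop.part(tree)
  tips <- attr(parts, "labels")
  n <- length(tips)
  vapply(parts, function(p) {
    side <- tips[p]
    if (length(side) <= 1 || length(side) >= n - 1) return(NA_character_)
    if (ref_labels[1] %in% side) side <- setdiff(ref_labels, side)
    paste(sort(side), collapse = "|")
  }, character(1))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the distance
#' matrix and NJ tree per replicate, and counts how often each internal
#' bipartition of the reference tree (built from the full alignment) is
#' recovered. Supports are round(100 x frequency) over the replicates that
#' completed; replicates failing with an incomparable pair are skipped and
#' tallied in `attr(tree, "skipped_replicates")`.
#'
#' @param aln An [alignment()].
#' @param model Distance model (default `"p_distance"`).
#' @param n_replicates Bootstrap replicates (>= 1).
#' @param seed Integer RNG seed.
#' @return The reference NJ tree with integer supports in `node.label`
#'   (empty for the root / trivial splits) and attributes
#'   `n_replicates_used` and `skipped_replicates`.
#' @export
bootstrap_support <- function(aln, model = "p_distance", n_replicates = 100,
                              seed = 1) {
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  L <- alignment_length(aln)
  if (L < 1) stopf("alignment must have at least 1 column")
  ref_tree <- neighbor_joining(distance_matrix(aln, model = model))
  ref_labels <- sort(aln$ids)
  ref_node_splits <- node_split_strings(ref_tree, ref_labels)
  tally <- stats::setNames(integer(sum(!is.na(ref_node_splits))),
                           ref_node_splits[!is.na(ref_node_splits)])
  set.seed(seed)
  used <- 0L; skipped <- 0L
  seqm <- seq_matrix(aln)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    boot_aln <- alignment(aln$ids, aln$libraries,
                          apply(seqm[, cols, drop = FALSE], 1, paste, collapse = ""),
                          aln$alphabet)
    tr <- tryCatch(neighbor_joining(distance_matrix(boot_aln, model = model)),
                   methanodiv_error = function(e) NULL)
    if (is.null(tr)) { skipped <- skipped + 1L; next }
    used <- used + 1L
    hits <- intersect(tree_splits(tr, ref_labels), names(tally))
    tally[hits] <- tally[hits] + 1L
  }
  if (used == 0L) stopf("all bootstrap replicates failed")
  supports <- ifelse(is.na(ref_node_splits), "",
                     as.character(round(100 * tally[ref_node_splits] / used)))
  ref_tree$node.label <- unname(supports)
  attr(ref_tree, "n_replicates_used") <- used
  attr(ref_tree, "skipped_replicates") <- skipped
  ref_tree
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge, so
#' leaf-to-leaf path lengths are unchanged.
#'
#' @param tree An `ape` `"phylo"` tree.
#' @param outgroup_label A tip label of `tree`.
#' @return A rooted `"phylo"` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_label) {
  if (!outgroup_label %in% tree$tip.label)
    stopf("outgroup '%s' is not a leaf of the tree", outgroup_label,
          class = "unknown_outgroup_error")
  rooted <- ape::root(tree, outgroup = outgroup_label, resolve.root = TRUE)
  root_node <- length(rooted$tip.label) + 1L
  child_edges <- which(rooted$edge[, 1] == root_node)
  total <- sum(rooted$edge.length[child_edges])
  rooted$edge.length[child_edges] <- total / 2
  rooted
}
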