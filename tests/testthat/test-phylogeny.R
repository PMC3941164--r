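path_lengths <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d))]
}

test_that("3-taxon branch lengths follow the closed form", {
  v <- matrix(c(0, 0.2, 0.3,
                0.2, 0, 0.4,
                0.3, 0.4, 0), 3, byrow = TRUE)
  tree <- neighbor_joining(dist_matrix(c("A", "B", "C"), v))
  bl <- setNames(tree$edge.length,
                 tree$tip.label[tree$edge[, 2]])
  expect_equal(bl[["A"]], 0.05)
  expect_equal(bl[["B"]], 0.15)
  expect_equal(bl[["C"]], 0.25)
  expect_error(neighbor_joining(dist_matrix("A", matrix(0, 1, 1))),
               class = "too_few_taxa_error")
})

test_that("NJ recovers topology and path lengths from additive matrices", {
  set.seed(15)
  for (rep in 1:30) {
    n <- sample(4:10, 1)
    true_tree <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
    dmat <- ape::cophenetic.phylo(true_tree)
    labs <- rownames(dmat)
    tree <- neighbor_joining(dist_matrix(labs, dmat))
    expect_equal(path_lengths(tree), path_lengths(true_tree),
                 tolerance = 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(true_tree), tree), 0,
                 ignore_attr = TRUE)
    # fully resolved unrooted tree: 2n - 3 edges
    expect_equal(nrow(tree$edge), 2 * n - 3)
  }
})

test_that("NJ agrees with the reference implementation on random matrices", {
  set.seed(33)
  for (rep in 1:10) {
    true_tree <- ape::rtree(8, br = function(k) runif(k, 0.05, 0.5))
    dmat <- ape::cophenetic.phylo(true_tree)
    ours <- neighbor_joining(dist_matrix(rownames(dmat), dmat))
    theirs <- ape::nj(as.dist(dmat))
    expect_equal(ape::dist.topo(ours, theirs), 0, ignore_attr = TRUE)
  }
})

test_that("equidistant taxa resolve by the documented tie-break", {
  v <- matrix(0.3, 4, 4); diag(v) <- 0
  tree <- neighbor_joining(dist_matrix(c("A", "B", "C", "D"), v))
  # first join must be the first label pair
  splits <- lapply(ape::prop.part(tree), function(p)
    sort(attr(ape::prop.part(tree), "labels")[p]))
  expect_true(any(vapply(splits, identical, logical(1), y = c("A", "B"))))
})

test_that("bootstrap supports are 100 for congruent divergent blocks", {
  # every column supports the same split: two blocks of identical sequences
  blockA <- paste(rep("A", 120), collapse = "")
  blockC <- paste(rep("C", 120), collapse = "")
  near_A <- paste(c("G", rep("A", 119)), collapse = "")
  near_C <- paste(c("G", rep("C", 119)), collapse = "")
  aln <- alignment(paste0("l_", c("a1", "a2", "b1", "b2")), rep("l", 4),
                   c(blockA, near_A, blockC, near_C), "dna")
  tree <- bootstrap_support(aln, n_replicates = 30, seed = 2)
  sup <- suppressWarnings(as.integer(tree$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  one <- bootstrap_support(aln, n_replicates = 1, seed = 3)
  s1 <- suppressWarnings(as.integer(one$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0L, 100L)))
})

test_that("bootstrap supports are invariant to leaf input order", {
  spec <- community_spec(S_true = 5, sequence_length = 200, seed = 21)
  lib <- generate_library(spec, n_clones = 10, library_name = "l")
  aln <- lib$alignment
  perm <- sample(length(aln$ids))
  aln2 <- alignment(aln$ids[perm], aln$libraries[perm], aln$sequences[perm],
                    "dna")
  t1 <- bootstrap_support(aln, n_replicates = 50, seed = 7)
  t2 <- bootstrap_support(aln2, n_replicates = 50, seed = 7)
  sup <- function(tr) {
    s <- suppressWarnings(as.integer(tr$node.label))
    sort(s[!is.na(s)])
  }
  expect_equal(sup(t1), sup(t2))
})

test_that("outgroup rooting bisects the pendant edge and conserves paths", {
  v <- matrix(c(0, 0.2, 0.3,
                0.2, 0, 0.4,
                0.3, 0.4, 0), 3, byrow = TRUE)
  tree <- neighbor_joining(dist_matrix(c("A", "B", "C"), v))
  rooted <- root_with_outgroup(tree, "C")
  expect_true(ape::is.rooted(rooted))
  # bipartition {A,B} | {C} at the root
  kids <- rooted$edge[rooted$edge[, 1] == length(rooted$tip.label) + 1L, 2]
  expect_true(any(kids == which(rooted$tip.label == "C")))
  expect_equal(path_lengths(rooted), path_lengths(tree), tolerance = 1e-12)

  set.seed(64)
  rt <- ape::rtree(7)
  rooted2 <- root_with_outgroup(ape::unroot(rt), rt$tip.label[1])
  expect_equal(path_lengths(rooted2), path_lengths(ape::unroot(rt)),
               tolerance = 1e-9)
  # unrooting again restores the original bipartition set
  expect_equal(ape::dist.topo(ape::unroot(rooted2), ape::unroot(rt)), 0,
               ignore_attr = TRUE)

  expect_error(root_with_outgroup(tree, "Z"), class = "unknown_outgroup_error")
})
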