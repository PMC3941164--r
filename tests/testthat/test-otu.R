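block_matrix <- function(sizes, intra, inter) {
  n <- sum(sizes)
  blk <- rep(seq_along(sizes), sizes)
  v <- matrix(inter, n, n)
  v[outer(blk, blk, `==`)] <- intra
  diag(v) <- 0
  dist_matrix(sprintf("l_s%02d", seq_len(n)), v)
}

test_that("degenerate cutoffs give one OTU or all singletons", {
  dm <- dist_matrix(paste0("l_s", 1:4), matrix(0, 4, 4))
  cl <- cluster_furthest_neighbor(dm, 0.02)
  expect_equal(unname(cl$otu_of), rep(1L, 4))

  set.seed(2)
  dm2 <- random_dist_matrix(6, scale = 1)
  dm2$values[dm2$values > 0] <- dm2$values[dm2$values > 0] + 0.5
  cl2 <- cluster_furthest_neighbor(dist_matrix(dm2$labels, dm2$values), 0.02)
  expect_equal(sort(unname(cl2$otu_of)), 1:6)

  # cutoff at/above the max distance collapses everything
  cl3 <- cluster_furthest_neighbor(dm2, max(dm2$values))
  expect_equal(unname(cl3$otu_of), rep(1L, 6))

  empty <- dist_matrix(character(0), matrix(numeric(0), 0, 0))
  expect_length(cluster_furthest_neighbor(empty, 0.02)$otu_of, 0)
})

test_that("planted blocks are recovered and are the minimal feasible partition", {
  dm <- block_matrix(c(3, 3, 3), intra = 0.01, inter = 0.20)
  cl <- cluster_furthest_neighbor(dm, 0.02)
  expect_equal(max(cl$otu_of), 3)
  expect_equal(unname(cl$otu_of), rep(1:3, each = 3))
  expect_equal(oracle_min_feasible_blocks(dm$values, 0.02), 3)
})

test_that("furthest-neighbor partition matches complete-linkage cutree", {
  set.seed(14)
  for (rep in 1:25) {
    dm <- random_dist_matrix(12)
    cutoff <- runif(1, 0.1, 0.9)
    cl <- cluster_furthest_neighbor(dm, cutoff)
    hc <- stats::hclust(stats::as.dist(dm$values), method = "complete")
    ct <- stats::cutree(hc, h = cutoff)
    # same partition up to OTU relabeling
    expect_equal(max(cl$otu_of), max(ct))
    expect_true(all(tapply(ct, cl$otu_of[dm$labels],
                           function(g) length(unique(g))) == 1))
  }
})

test_that("cluster diameters never exceed the cutoff and OTUs shrink with cutoff", {
  set.seed(31)
  for (rep in 1:20) {
    dm <- random_dist_matrix(15)
    cutoffs <- sort(runif(3, 0, 1))
    n_otus <- integer(0)
    for (cutoff in cutoffs) {
      cl <- cluster_furthest_neighbor(dm, cutoff)
      for (k in unique(cl$otu_of)) {
        idx <- which(cl$otu_of == k)
        if (length(idx) > 1)
          expect_lte(max(dm$values[idx, idx]), cutoff)
      }
      n_otus <- c(n_otus, max(cl$otu_of))
    }
    expect_true(all(diff(n_otus) <= 0))
  }
})

test_that("cutoff zero groups exactly the duplicate sequences", {
  seqs <- c(a = "ACGT", b = "ACGT", c = "ACGA", d = "ACGA", e = "TTTT")
  aln <- alignment(paste0("l_", names(seqs)), rep("l", 5), unname(seqs), "dna")
  cl <- cluster_furthest_neighbor(distance_matrix(aln), 0)
  expect_equal(unname(cl$otu_of), c(1L, 1L, 2L, 2L, 3L))
})

test_that("equal-distance merges follow the lexicographic tie rule", {
  # all off-diagonal distances equal: first merge must be the (a, b) pair
  dm <- dist_matrix(c("l_c", "l_a", "l_b"),
                    matrix(0.01, 3, 3) - diag(0.01, 3))
  cl <- cluster_furthest_neighbor(dm, 0.05)
  expect_equal(cl$merge_trace$cluster_a[1], "l_a")
  expect_equal(cl$merge_trace$cluster_b[1], "l_b")
})

test_that("OTU tables count clones per library, largest OTU first", {
  aln_ids <- c(paste0("horse_c", 1:50), paste0("pony_c", 1:50))
  otu_of <- setNames(rep(1L, 100), aln_ids)
  aln <- alignment(aln_ids, sub("_.*", "", aln_ids),
                   rep("ACGT", 100), "dna")
  assignment <- structure(list(cutoff = 0.02, otu_of = otu_of),
                          class = "otu_clustering")
  tab <- otu_table(assignment, aln)
  expect_equal(dim(unclass(tab)), c(1L, 2L))
  expect_equal(unclass(tab)[1, ], c(horse = 50L, pony = 50L))
})

test_that("synthetic planted counts are recovered through clustering", {
  spec <- community_spec(S_true = 6, abundance_model = "explicit",
                         counts = c(29, 10, 6, 2, 2, 1),
                         sequence_length = 300, seed = 77)
  lib <- generate_library(spec, n_clones = 50, library_name = "horse")
  dm <- distance_matrix(lib$alignment)
  cl <- cluster_furthest_neighbor(dm, 0.02)
  tab <- otu_table(cl, lib$alignment)
  expect_equal(sort(unclass(tab)[, "horse"], decreasing = TRUE),
               sort(as.integer(spec$counts), decreasing = TRUE),
               ignore_attr = TRUE)
  # recovered partition equals the planted one
  expect_true(all(tapply(lib$truth, cl$otu_of[names(lib$truth)],
                         function(g) length(unique(g))) == 1))
  expect_equal(max(cl$otu_of), 6)
})

test_that("nearest_reference reports the row argmin with first-tie order", {
  refs <- alignment(c("R1", "R2", "R3"), rep("ref", 3),
                    c("AAAAAAAAAA", "AAAAAAACCC", "CCCCCCCCCC"), "dna")
  q <- alignment("q_1", "q", "AAAAAAAAAA", "dna")
  hit <- nearest_reference(q, refs)
  expect_equal(hit$reference, "R1")
  expect_equal(hit$percent_similarity, 100)

  # 0.07 away from the nearest reference -> 93% similarity
  q2 <- alignment("q_2", "q", paste(c(rep("C", 7), rep("A", 93)), collapse = ""),
                  "dna")
  refs2 <- alignment("R1", "ref", paste(rep("A", 100), collapse = ""), "dna")
  expect_equal(nearest_reference(q2, refs2)$percent_similarity, 93)

  set.seed(8)
  queries <- alignment(paste0("q_", 1:6), rep("q", 6), random_dna(6, 40), "dna")
  refs3 <- alignment(paste0("R", 1:5), rep("ref", 5), random_dna(5, 40), "dna")
  hits <- nearest_reference(queries, refs3)
  for (i in 1:6) {
    d <- vapply(seq_len(5), function(j)
      oracle_pdist(queries$sequences[i], refs3$sequences[j]), numeric(1))
    expect_equal(hits$reference[i], refs3$ids[which.min(d)])
    expect_equal(hits$percent_similarity[i], (1 - min(d)) * 100)
  }
})
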