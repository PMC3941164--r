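test_that("explicit abundances replay verbatim and validate their sum", {
  spec <- community_spec(S_true = 8, abundance_model = "explicit",
                         counts = c(29, 10, 6, 1, 1, 1, 1, 1))
  expect_equal(unname(sample_abundances(spec, 50)),
               c(29L, 10L, 6L, 1L, 1L, 1L, 1L, 1L))
  expect_error(sample_abundances(spec, 49), class = "spec_error")
})

test_that("geometric abundances concentrate on OTU1 as theta grows", {
  spec <- community_spec(S_true = 1, theta = 0.99, seed = 1)
  expect_equal(unname(sample_abundances(spec, 50)), 50L)

  # mean dominant share matches the normalized-geometric expectation
  theta <- 0.6; S <- 8; n <- 50
  expected <- theta / (1 - (1 - theta)^S)
  set.seed(123)
  spec2 <- community_spec(S_true = S, theta = theta)
  shares <- vapply(1:2000, function(i) sample_abundances(spec2, n)[1] / n,
                   numeric(1))
  se <- sd(shares) / sqrt(length(shares))
  expect_lt(abs(mean(shares) - expected), 3 * se)
})

test_that("generated libraries respect the planted divergence bounds", {
  spec <- community_spec(S_true = 3, intra_otu_divergence = 0.005,
                         inter_otu_divergence = 0.20,
                         sequence_length = 1254, seed = 99)
  lib <- generate_library(spec, n_clones = 50, library_name = "horse")
  expect_length(lib$truth, 50)
  dm <- distance_matrix(lib$alignment)
  same <- outer(lib$truth, lib$truth, `==`)
  up <- upper.tri(dm$values)
  expect_lte(max(dm$values[up & same]), 0.005)
  expect_gte(min(dm$values[up & !same]), 0.15)

  cl <- cluster_furthest_neighbor(dm, 0.02)
  expect_equal(max(cl$otu_of), length(unique(lib$truth)))
  expect_true(all(tapply(lib$truth, cl$otu_of[names(lib$truth)],
                         function(g) length(unique(g))) == 1))
})

test_that("zero intra-OTU divergence yields identical clones", {
  spec <- community_spec(S_true = 1, intra_otu_divergence = 0,
                         sequence_length = 100, seed = 5)
  lib <- generate_library(spec, n_clones = 10)
  expect_length(unique(lib$alignment$sequences), 1)
})

test_that("generation is byte-deterministic given spec and seed", {
  spec <- community_spec(S_true = 4, sequence_length = 150, seed = 31)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  write_synthetic_library(generate_library(spec, 20, "d"), f1, t1)
  write_synthetic_library(generate_library(spec, 20, "d"), f2, t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
})

test_that("paired-marker generation plants an exact or recoverable slope", {
  noiseless <- generate_paired_markers(23, 2.1944, noise_sd = 0, seed = 8)
  expect_length(noiseless$x, 253)
  expect_equal(through_origin_regression(noiseless)$slope, 2.1944)

  unit <- generate_paired_markers(10, 1, noise_sd = 0, seed = 9)
  fit <- through_origin_regression(unit)
  expect_equal(map_cutoff(fit$slope, 0.02)$similarity_criterion_pct, 98L)
})

test_that("library pairs share or separate their ancestor pools as requested", {
  spec <- community_spec(S_true = 4, sequence_length = 300)
  shared <- generate_library_pair(spec, n_each = 30, shared = TRUE, seed = 13)
  aln <- pool_libraries(shared)
  dm <- distance_matrix(aln)
  cl <- cluster_furthest_neighbor(dm, 0.02)
  # pooled truth: clones of the same planted OTU cluster together across
  # libraries, so some OTU holds members of both
  truth_pool <- c(shared[[1]]$truth, shared[[2]]$truth)
  lib_of <- setNames(aln$libraries, aln$ids)
  both <- vapply(split(names(cl$otu_of), cl$otu_of),
                 function(ids) length(unique(lib_of[ids])) == 2, logical(1))
  expect_true(any(both))
  expect_true(all(tapply(truth_pool[names(cl$otu_of)], cl$otu_of,
                         function(g) length(unique(g))) == 1))

  disjoint <- generate_library_pair(spec, n_each = 30, shared = FALSE, seed = 13)
  alnd <- pool_libraries(disjoint)
  dmd <- distance_matrix(alnd)
  cld <- cluster_furthest_neighbor(dmd, 0.02)
  lib_ofd <- setNames(alnd$libraries, alnd$ids)
  bothd <- vapply(split(names(cld$otu_of), cld$otu_of),
                  function(ids) length(unique(lib_ofd[ids])) == 2, logical(1))
  expect_false(any(bothd))
})
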