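test_that("Shannon index matches published per-library values and edge cases", {
  expect_equal(round(shannon(c(29, 10, 6, 1, 1, 1, 1, 1)), 2), 1.28)
  expect_equal(round(shannon(c(33, 13, 2, 1, 1)), 2), 0.91)
  expect_equal(shannon(50), 0)
  expect_equal(shannon(c(1, 1, 1, 1)), log(4))
})

test_that("evenness supports both H_max conventions", {
  horse <- c(29, 10, 6, 1, 1, 1, 1, 1)
  expect_equal(round(evenness(horse, "printed"), 2), 0.33)
  expect_equal(round(evenness(c(33, 13, 2, 1, 1), "printed"), 2), 0.23)
  expect_equal(evenness(c(1, 1, 1, 1), "formula"), 1.0)
  expect_equal(evenness(horse, "formula"), shannon(horse) / log(8))
  expect_error(evenness(50, "formula"), class = "undefined_evenness_error")
})

test_that("coverage supports both denominators", {
  horse_mcra <- c(29, 10, 6, 1, 1, 1, 1, 1)
  expect_equal(good_coverage(horse_mcra, "clones"), 90.0)
  expect_equal(good_coverage(horse_mcra, "otus"), 37.5)
  horse_16s <- c(32, 4, 1, 6, 2, 1, 2, 2)
  expect_equal(good_coverage(horse_16s, "otus"), 75.0)
  expect_equal(good_coverage(c(5, 4, 3), "otus"), 100)
  expect_equal(good_coverage(c(5, 4, 3), "clones"), 100)
})

test_that("Chao-1 uses the F2 = 0 fallback and never drops below S_obs", {
  expect_equal(chao1(c(29, 10, 6, 1, 1, 1, 1, 1)), 18)
  expect_equal(chao1(c(33, 13, 2, 1, 1)), 7)
  expect_equal(chao1(c(5, 4, 3)), 3)
  set.seed(4)
  for (rep in 1:50) {
    v <- sample(1:10, sample(2:12, 1), replace = TRUE)
    est <- chao1(v)
    f1 <- sum(v == 1); f2 <- sum(v == 2)
    expect_gte(est, length(v))
    # equality holds when no singletons, or one singleton under the
    # F2 = 0 fallback term F1 (F1 - 1) / 2
    expect_equal(est == length(v), f1 == 0 || (f1 == 1 && f2 == 0))
  }
})

test_that("Shannon is permutation-invariant, maximal iff uniform, and merge-monotone", {
  set.seed(12)
  for (rep in 1:30) {
    v <- sample(1:20, sample(3:9, 1), replace = TRUE)
    expect_equal(shannon(v), shannon(rev(sample(v))))
    expect_lte(shannon(v), log(length(v)) + 1e-12)
    if (length(unique(v)) > 1) expect_lt(shannon(v), log(length(v)))
    # merging two OTUs never increases H'
    merged <- c(v[1] + v[2], v[-(1:2)])
    expect_lte(shannon(merged), shannon(v) + 1e-12)
  }
})

test_that("diversity statistics match independent recomputation and vegan", {
  skip_if_not_installed("vegan")
  set.seed(77)
  for (rep in 1:30) {
    v <- sample(1:30, sample(2:10, 1), replace = TRUE)
    expect_equal(shannon(v), oracle_shannon(v))
    expect_equal(shannon(v), unname(vegan::diversity(v, index = "shannon")))
    expect_equal(chao1(v), oracle_chao1(v))
  }
})

test_that("diversity_report computes every statistic per library column", {
  tab <- otu_table_from_counts(horse = table3_horse_mcra,
                               pony = table3_pony_mcra)
  rep <- diversity_report(tab)
  expect_equal(rep$S_obs, c(8, 5))
  expect_equal(rep$N, c(50, 50))
  horse <- table3_horse_mcra[table3_horse_mcra > 0]
  expect_equal(rep$H_prime[1], shannon(horse))
  expect_equal(rep$evenness_printed[1], evenness(horse, "printed"))
  expect_equal(rep$coverage_otus_pct[1], good_coverage(horse, "otus"))
  expect_equal(rep$chao1[1], chao1(horse))

  single <- diversity_report(otu_table_from_counts(only = 50L))
  expect_equal(single$H_prime, 0)
  expect_equal(single$chao1, 1)
  expect_equal(single$coverage_clones_pct, 100)

  expect_warning(
    out <- diversity_report(otu_table_from_counts(a = c(2L, 1L), b = c(0L, 0L))),
    "zero clones")
  expect_equal(out$library, "a")

  set.seed(19)
  counts <- matrix(rpois(12, 4), 4)
  colnames(counts) <- c("l1", "l2", "l3")
  tab2 <- otu_table_from_counts(l1 = counts[, 1], l2 = counts[, 2],
                                l3 = counts[, 3])
  rep2 <- diversity_report(tab2)
  for (i in seq_len(nrow(rep2))) {
    v <- counts[, rep2$library[i]]
    v <- v[v > 0]
    expect_equal(rep2$H_prime[i], oracle_shannon(v))
    expect_equal(rep2$chao1[i], oracle_chao1(v))
    expect_equal(rep2$F1[i], sum(v == 1))
  }
})

test_that("invalid abundance vectors are rejected", {
  expect_error(shannon(numeric(0)), class = "undefined_statistic_error")
  expect_error(shannon(c(3, 0, 1)))
  expect_error(chao1(c(1.5, 2)))
})
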