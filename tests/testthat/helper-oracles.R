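# Independent brute-force oracles. These deliberately use naive per-site /
# per-pair loops, not the package's vectorized paths.

oracle_pdist <- function(a, b, amb = "N") {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  mm <- 0L; comp <- 0L
  for (i in seq_along(a)) {
    if (a[i] %in% c("-", amb) || b[i] %in% c("-", amb)) next
    comp <- comp + 1L
    if (a[i] != b[i]) mm <- mm + 1L
  }
  mm / comp
}

oracle_shannon <- function(counts) {
  n <- sum(counts)
  h <- 0
  for (c in counts) h <- h - (c / n) * log(c / n)
  h
}

oracle_chao1 <- function(counts) {
  f <- tabulate(counts)
  f1 <- if (length(f) >= 1) f[1] else 0
  f2 <- if (length(f) >= 2) f[2] else 0
  if (f2 > 0) length(counts) + f1 * f1 / (2 * f2)
  else length(counts) + f1 * (f1 - 1) / 2
}

# coverage-curve statistic by direct per-sequence, per-grid-point scanning
oracle_delta_c <- function(values, ix, iy, step, d_max) {
  grid <- seq(0, d_max + step, by = step)
  cov_at <- function(from, to, d) {
    covered <- vapply(from, function(i) {
      others <- setdiff(to, i)
      any(values[i, others] <= d)
    }, logical(1))
    mean(covered)
  }
  one <- function(ia, ib) {
    tot <- 0
    for (d in grid)
      tot <- tot + max(cov_at(ia, ia, d) - cov_at(ia, ib, d), 0)^2
    tot * step
  }
  c(xy = one(ix, iy), yx = one(iy, ix))
}

# dense grid search for the through-origin least-squares slope, refined
# around the running minimum until the grid step is ~1e-10
oracle_slope_grid <- function(x, y, lo = 0, hi = 6) {
  b <- seq(lo, hi, length.out = 6001)
  for (iter in 1:4) {
    rss <- vapply(b, function(bb) sum((y - bb * x)^2), numeric(1))
    i <- which.min(rss)
    b <- seq(b[max(1, i - 1)], b[min(length(b), i + 1)], length.out = 6001)
  }
  rss <- vapply(b, function(bb) sum((y - bb * x)^2), numeric(1))
  b[which.min(rss)]
}

# all set partitions of 1..n (Bell-number enumeration, small n only)
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (k in seq_along(p)) {
      q <- p; q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

# smallest number of blocks over partitions whose every block has
# diameter <= cutoff
oracle_min_feasible_blocks <- function(values, cutoff) {
  n <- nrow(values)
  best <- n
  for (p in all_partitions(n)) {
    ok <- all(vapply(p, function(blk) {
      length(blk) == 1 || max(values[blk, blk]) <= cutoff
    }, logical(1)))
    if (ok) best <- min(best, length(p))
  }
  best
}

random_dna <- function(n, len) {
  vapply(seq_len(n),
         function(i) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                           collapse = ""),
         character(1))
}

random_dist_matrix <- function(n, scale = 1) {
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- runif(n * (n - 1) / 2) * scale
  v <- v + t(v)
  dist_matrix(paste0("s", seq_len(n)), v)
}

table3_horse_mcra <- c(29, 10, 6, 1, 0, 1, 1, 1, 1)
table3_pony_mcra  <- c(33, 13, 0, 1, 2, 0, 1, 0, 0)
table4_horse_16s  <- c(32, 4, 0, 1, 6, 2, 0, 1, 2, 2)
table4_pony_16s   <- c(37, 1, 1, 5, 0, 2, 1, 3, 0, 0)
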