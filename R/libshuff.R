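# min distance from each row sequence to any column sequence; exclude_diag
# for homologous use where the matrix is the same library on both axes
row_min_dist <- function(m, exclude_diag = FALSE) {
  if (exclude_diag) diag(m) <- Inf
  apply(m, 1, min)
}

#' Homologous coverage of a library at distance D
#'
#' C_X(D) = fraction of sequences in X having at least one *other*
#' X-sequence within distance D. The LIBSHUFF homologous coverage curve is
#' this quantity as a function of D.
#'
#' @param dm_x A [dist_matrix()] (or plain square matrix) over library X.
#' @param D Distance threshold(s), >= 0.
#' @return Coverage value(s) in `[0, 1]`.
#' @export
homologous_coverage <- function(dm_x, D) {
  m <- if (inherits(dm_x, "dist_matrix")) dm_x$values else as.matrix(dm_x)
  if (nrow(m) == 0) stopf("empty library", class = "empty_library_error")
  mins <- row_min_dist(m, exclude_diag = TRUE)
  vapply(D, function(d) mean(mins <= d), numeric(1))
}

#' Heterologous coverage at distance D
#'
#' C_XY(D) = fraction of X-sequences having at least one Y-sequence within
#' distance D.
#'
#' @param dm_xy |X| x |Y| cross-library distance matrix (rows X, columns Y).
#' @param D Distance threshold(s), >= 0.
#' @return Coverage value(s) in `[0, 1]`.
#' @export
heterologous_coverage <- function(dm_xy, D) {
  m <- as.matrix(dm_xy)
  if (nrow(m) == 0 || ncol(m) == 0)
    stopf("empty library", class = "empty_library_error")
  mins <- row_min_dist(m)
  vapply(D, function(d) mean(mins <= d), numeric(1))
}

# core Cramer-von-Mises-type statistic from precomputed nearest-neighbour
# distances: sum over the grid of the squared coverage SHORTFALL
# max(C_X - C_XY, 0)^2 times step. The one-sided form measures how much
# worse the other library covers X than X covers itself, and is exactly 0
# whenever the heterologous curve dominates -- in particular for
# sequence-identical libraries, where every X sequence has a zero-distance
# heterologous neighbour. The coverage curve at D is the ECDF of
# nearest-neighbour distances, so one findInterval over the sorted minima
# evaluates the whole grid.
delta_c_from_mins <- function(hom_mins, het_mins, grid, step) {
  cx <- findInterval(grid, sort(hom_mins)) / length(hom_mins)
  cxy <- findInterval(grid, sort(het_mins)) / length(het_mins)
  sum(pmax(cx - cxy, 0)^2) * step
}

libshuff_grid <- function(d_max, step) seq(0, d_max + step, by = step)

#' LIBSHUFF delta-C statistics for two libraries
#'
#' The squared area by which the homologous coverage curve exceeds the
#' heterologous one, discretized on a regular distance grid:
#' Delta C_XY = sum_D max(C_X(D) - C_XY(D), 0)^2 * step, and symmetrically
#' Delta C_YX. The one-sided (shortfall) form is used so that a library
#' fully covered by the other contributes nothing; in particular both
#' statistics are exactly zero when the two libraries are identical
#' multisets of sequences. The convention is recorded in the result.
#'
#' @param dm_pooled [dist_matrix()] over the pooled libraries.
#' @param labels_x,labels_y Ids belonging to library X and Y; together they
#'   must partition the pooled labels.
#' @param step Grid step (default 0.01).
#' @param d_max Upper end of the grid (default: max pooled distance).
#' @return List with `delta_c_xy`, `delta_c_yx`, `step`, `d_max`,
#'   `integral = "one-sided squared shortfall x step"`.
#' @export
delta_c <- function(dm_pooled, labels_x, labels_y, step = 0.01, d_max = NULL) {
  if (step <= 0) stopf("step must be positive")
  all_labels <- dm_pooled$labels
  if (!setequal(c(labels_x, labels_y), all_labels) ||
      length(intersect(labels_x, labels_y)))
    stopf("labels_x and labels_y must partition the pooled matrix labels")
  if (length(labels_x) < 2 || length(labels_y) < 2)
    stopf("each library needs at least 2 sequences",
          class = "insufficient_data_error")
  v <- dm_pooled$values
  d_max <- d_max %||% max(v)
  grid <- libshuff_grid(d_max, step)
  ix <- match(labels_x, all_labels); iy <- match(labels_y, all_labels)
  hx <- row_min_dist(v[ix, ix, drop = FALSE], exclude_diag = TRUE)
  hy <- row_min_dist(v[iy, iy, drop = FALSE], exclude_diag = TRUE)
  xy <- row_min_dist(v[ix, iy, drop = FALSE])
  yx <- row_min_dist(v[iy, ix, drop = FALSE])
  list(delta_c_xy = delta_c_from_mins(hx, xy, grid, step),
       delta_c_yx = delta_c_from_mins(hy, yx, grid, step),
       step = step, d_max = d_max,
       integral = "one-sided squared shortfall x step")
}

#' LIBSHUFF permutation test for two clone libraries
#'
#' Compares two sequence libraries by the reciprocal delta-C statistics
#' with significance from library-label permutations over the pooled
#' sequence set (library sizes fixed). P-values use the add-one estimator
#' p = (1 + #permuted >= observed) / (1 + n_permutations). Because the two
#' reciprocal comparisons are reported together, the per-comparison
#' threshold is the experiment-wise correction
#' 1 - (1 - alpha)^(1/2).
#'
#' @param dm_pooled [dist_matrix()] over both libraries.
#' @param labels Named character vector id -> library name (exactly two
#'   distinct library names).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer RNG seed; recorded in the result.
#' @param alpha Experiment-wise significance level (default 0.05).
#' @param step Coverage-curve grid step (default 0.01).
#' @return An object of class `"libshuff_result"`: `delta_c_xy`,
#'   `delta_c_yx`, `p_xy`, `p_yx`, `n_permutations`, `seed`,
#'   `pairwise_alpha`, `significant`, `libraries`, `step`, `d_max`,
#'   `integral`.
#' @export
libshuff_test <- function(dm_pooled, labels, n_permutations = 999, seed = 1,
                          alpha = 0.05, step = 0.01) {
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  ids <- dm_pooled$labels
  if (!all(ids %in% names(labels)))
    stopf("labels must cover every pooled id")
  lib <- labels[ids]
  lib_names <- unique(lib)
  if (length(lib_names) != 2)
    stopf("libshuff_test compares exactly 2 libraries, found %d",
          length(lib_names))
  ix <- which(lib == lib_names[1]); iy <- which(lib == lib_names[2])
  if (length(ix) < 2 || length(iy) < 2)
    stopf("each library needs at least 2 sequences",
          class = "insufficient_data_error")
  v <- dm_pooled$values
  d_max <- max(v)
  grid <- libshuff_grid(d_max, step)
  stat <- function(ia, ib) {
    hom <- row_min_dist(v[ia, ia, drop = FALSE], exclude_diag = TRUE)
    het <- row_min_dist(v[ia, ib, drop = FALSE])
    delta_c_from_mins(hom, het, grid, step)
  }
  obs_xy <- stat(ix, iy)
  obs_yx <- stat(iy, ix)
  set.seed(seed)
  n <- length(ids); nx <- length(ix)
  ge_xy <- 0L; ge_yx <- 0L
  for (b in seq_len(n_permutations)) {
    px <- sample.int(n, nx)
    py <- setdiff(seq_len(n), px)
    if (stat(px, py) >= obs_xy) ge_xy <- ge_xy + 1L
    if (stat(py, px) >= obs_yx) ge_yx <- ge_yx + 1L
  }
  p_xy <- (1 + ge_xy) / (1 + n_permutations)
  p_yx <- (1 + ge_yx) / (1 + n_permutations)
  pairwise_alpha <- 1 - (1 - alpha)^(1 / 2)
  structure(list(delta_c_xy = obs_xy, delta_c_yx = obs_yx,
                 p_xy = p_xy, p_yx = p_yx,
                 n_permutations = n_permutations, seed = seed,
                 alpha = alpha, pairwise_alpha = pairwise_alpha,
                 significant = min(p_xy, p_yx) < pairwise_alpha,
                 libraries = lib_names, step = step, d_max = d_max,
                 integral = "one-sided squared shortfall x step"),
            class = "libshuff_result")
}

#' @export
print.libshuff_result <- function(x, ...) {
  cat(sprintf("LIBSHUFF %s vs %s: dCxy=%.4g (p=%.4f), dCyx=%.4g (p=%.4f)\n",
              x$libraries[1], x$libraries[2],
              x$delta_c_xy, x$p_xy, x$delta_c_yx, x$p_yx))
  cat(sprintf("  %d permutations, per-comparison alpha %.4f: %s\n",
              x$n_permutations, x$pairwise_alpha,
              if (x$significant) sprintf("significant (P < %.2f)", x$alpha)
              else "not significant"))
  invisible(x)
}
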