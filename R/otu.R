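#' Furthest-neighbor (complete-linkage) OTU clustering
#'
#' Agglomerative clustering in which two clusters merge only when *every*
#' inter-cluster sequence pair is within the distance cutoff -- the
#' DOTUR-style OTU definition. Merges proceed in non-decreasing
#' complete-linkage distance and stop when the smallest possible merge
#' would exceed the cutoff, so every OTU's diameter (max intra-OTU
#' distance) is at most the cutoff.
#'
#' Ties between equally distant merge candidates are broken by the
#' lexicographically smallest pair of member ids (smallest minimum id,
#' then smallest maximum id), making the partition deterministic across
#' platforms. Distances are used at full precision; no 0.01 binning.
#'
#' @param dm A [dist_matrix()].
#' @param cutoff Maximum permitted OTU diameter (p-distance scale for the
#'   98%/95% similarity criteria: 0.02 and 0.05).
#' @return An object of class `"otu_clustering"`: list with `cutoff`,
#'   `otu_of` (named integer vector, 1-based OTU index per id, OTUs
#'   numbered by first-seen member) and `merge_trace` (data frame of
#'   `distance`, `cluster_a`, `cluster_b`, clusters named by their
#'   smallest member id).
#' @export
cluster_furthest_neighbor <- function(dm, cutoff) {
  if (cutoff < 0) stopf("cutoff must be non-negative")
  n <- length(dm$labels)
  if (n == 0L)
    return(structure(list(cutoff = cutoff,
                          otu_of = stats::setNames(integer(0), character(0)),
                          merge_trace = empty_trace()),
                     class = "otu_clustering"))
  if (anyNA(dm$values)) stopf("distance matrix contains NaN", class = "data_error")
  labels <- dm$labels
  members <- as.list(seq_len(n))          # cluster -> row indices
  active <- rep(TRUE, n)
  cl <- dm$values                         # complete-linkage distances
  diag(cl) <- NA_real_
  cl[!upper.tri(cl)] <- NA_real_
  trace <- list()
  repeat {
    if (sum(active) < 2L) break
    dmin <- suppressWarnings(min(cl, na.rm = TRUE))
    if (!is.finite(dmin) || dmin > cutoff) break
    cand <- which(cl == dmin, arr.ind = TRUE)
    pick <- cand[1, ]
    if (nrow(cand) > 1L) {
      keys <- apply(cand, 1, function(ij) {
        ids <- labels[c(members[[ij[1]]], members[[ij[2]]])]
        c(min(ids), max(ids))
      })
      ord <- order(keys[1, ], keys[2, ])
      pick <- cand[ord[1], ]
    }
    i <- pick[1]; j <- pick[2]
    trace[[length(trace) + 1L]] <- data.frame(
      distance = dmin,
      cluster_a = min(labels[members[[i]]]),
      cluster_b = min(labels[members[[j]]]),
      stringsAsFactors = FALSE)
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- integer(0)
    active[j] <- FALSE
    for (k in which(active)) {
      if (k == i) next
      a <- min(i, k); b <- max(i, k)
      cl[a, b] <- max(ifelse(i < k, cl[i, k], cl[k, i]),
                      ifelse(j < k, cl[j, k], cl[k, j]), na.rm = FALSE)
    }
    cl[j, ] <- NA_real_
    cl[, j] <- NA_real_
  }
  alive <- which(active)
  first_seen <- vapply(members[alive], min, integer(1))
  ord <- order(first_seen)
  otu_of <- integer(n)
  for (k in seq_along(ord)) otu_of[members[[alive[ord[k]]]]] <- k
  names(otu_of) <- labels
  structure(list(cutoff = cutoff, otu_of = otu_of,
                 merge_trace = if (length(trace)) do.call(rbind, trace)
                               else empty_trace()),
            class = "otu_clustering")
}

empty_trace <- function() {
  data.frame(distance = numeric(0), cluster_a = character(0),
             cluster_b = character(0), stringsAsFactors = FALSE)
}

#' @export
print.otu_clustering <- function(x, ...) {
  cat(sprintf("OTU clustering: %d sequence(s) in %d OTU(s) at cutoff %.4f\n",
              length(x$otu_of),
              if (length(x$otu_of)) max(x$otu_of) else 0L, x$cutoff))
  invisible(x)
}

#' OTU-by-library clone count table
#'
#' @param assignment An [cluster_furthest_neighbor()] result covering every
#'   alignment id.
#' @param aln The [alignment()] that supplied the library tags.
#' @return An object of class `"otu_table"`: an integer matrix with one row
#'   per OTU (named `OTU<k>` by cluster index) and one column per library
#'   (in order of first appearance), rows ordered by descending total
#'   clone count, then OTU index.
#' @export
otu_table <- function(assignment, aln) {
  missing <- setdiff(aln$ids, names(assignment$otu_of))
  if (length(missing))
    stopf("assignment does not cover id(s): %s", paste(missing, collapse = ", "))
  if (any(!nzchar(aln$libraries)))
    stopf("record(s) without a library tag", class = "tagging_error")
  otus <- assignment$otu_of[aln$ids]
  libs <- factor(aln$libraries, levels = unique(aln$libraries))
  counts <- table(factor(otus, levels = sort(unique(otus))), libs)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = list(paste0("OTU", rownames(counts)),
                                   colnames(counts)))
  ord <- order(-rowSums(counts), seq_len(nrow(counts)))
  structure(counts[ord, , drop = FALSE], class = "otu_table")
}

#' Build an OTU table directly from per-library count columns
#'
#' Convenience constructor for replaying published clone-count tables
#' through the diversity statistics.
#'
#' @param ... Named integer vectors of equal length, one per library.
#' @param otu_names Optional row names (default `OTU1..OTUn`).
#' @return An `"otu_table"`.
#' @export
otu_table_from_counts <- function(..., otu_names = NULL) {
  cols <- list(...)
  if (is.null(names(cols)) || any(!nzchar(names(cols))))
    stopf("library columns must be named")
  counts <- do.call(cbind, cols)
  rownames(counts) <- otu_names %||% paste0("OTU", seq_len(nrow(counts)))
  storage.mode(counts) <- "integer"
  structure(counts, class = "otu_table")
}

#' Nearest reference sequence per query
#'
#' For each query sequence, the reference at minimal distance, with
#' similarity reported on the p-distance scale -- the "nearest known
#' methanogen (similarity %)" column of a clone-library table. Ties are
#' broken by reference input order.
#'
#' @param query_aln,ref_aln [alignment()]s on common coordinates (equal
#'   lengths, same alphabet).
#' @param model Distance model used for ranking (default `"p_distance"`).
#' @return Data frame with columns `query`, `reference`,
#'   `percent_similarity`.
#' @export
nearest_reference <- function(query_aln, ref_aln, model = "p_distance") {
  if (query_aln$alphabet != ref_aln$alphabet)
    stopf("query and reference alignments must share an alphabet")
  if (alignment_length(query_aln) != alignment_length(ref_aln))
    stopf("query and reference alignments must share coordinates (lengths differ)")
  combined <- alignment(c(query_aln$ids, paste0("ref::", ref_aln$ids)),
                        c(query_aln$libraries, ref_aln$libraries),
                        c(query_aln$sequences, ref_aln$sequences),
                        query_aln$alphabet)
  dm <- distance_matrix(combined, model = model)
  nq <- length(query_aln$ids)
  cross <- dm$values[seq_len(nq), nq + seq_along(ref_aln$ids), drop = FALSE]
  best <- apply(cross, 1, which.min)   # which.min takes the first tie
  pd <- if (model == "p_distance") cross
        else distance_matrix(combined, model = "p_distance")$values[
          seq_len(nq), nq + seq_along(ref_aln$ids), drop = FALSE]
  data.frame(query = query_aln$ids,
             reference = ref_aln$ids[best],
             percent_similarity = percent_similarity(pd[cbind(seq_len(nq), best)]),
             stringsAsFactors = FALSE)
}
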