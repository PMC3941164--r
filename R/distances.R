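#' Pairwise evolutionary distance between two aligned sequences
#'
#' Distances are computed over *comparable* sites: positions where neither
#' sequence has a gap (`-`) or the ambiguity code (`N` for DNA, `X` for
#' protein). The uncorrected p-distance is the mismatch fraction over those
#' sites; `jc69` applies the Jukes-Cantor multiple-hit correction for DNA,
#' `poisson_corrected` the Poisson correction for protein.
#'
#' OTU similarity thresholds (98% for 16S rRNA, 95% for mcrA amino acids)
#' are defined on the p-distance scale, so `p_distance` is the default
#' throughout the pipeline.
#'
#' @param seq_a,seq_b Aligned sequences of equal length (character strings).
#' @param model `"p_distance"` (default), `"jc69"` (DNA only) or
#'   `"poisson_corrected"` (protein only).
#' @param alphabet `"dna"` or `"protein"`; determines the ambiguity code and
#'   which corrections are admissible.
#' @param gap_policy `"pairwise_delete"` (default) drops non-comparable
#'   sites per pair; `"complete_delete"` drops, before comparison, every
#'   site that is a gap/ambiguity in *either* sequence (identical for a
#'   single pair, distinct at the matrix level).
#' @return A non-negative distance.
#' @export
pairwise_distance <- function(seq_a, seq_b,
                              model = c("p_distance", "jc69", "poisson_corrected"),
                              alphabet = c("dna", "protein"),
                              gap_policy = c("pairwise_delete", "complete_delete")) {
  model <- match.arg(model)
  alphabet <- match.arg(alphabet)
  gap_policy <- match.arg(gap_policy)
  check_model_alphabet(model, alphabet)
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stopf("sequences have unequal lengths (%d vs %d)",
                                    length(a), length(b))
  amb <- ambiguity_char(alphabet)
  ok <- a != "-" & a != amb & b != "-" & b != amb
  n_comp <- sum(ok)
  if (n_comp == 0L)
    stopf("no comparable (gap-free, unambiguous) sites between the pair",
          class = "incomparable_pair_error")
  p <- sum(a[ok] != b[ok]) / n_comp
  correct_distance(p, model, pair = NULL)
}

check_model_alphabet <- function(model, alphabet) {
  if (model == "jc69" && alphabet != "dna")
    stopf("jc69 correction is only defined for DNA alignments")
  if (model == "poisson_corrected" && alphabet != "protein")
    stopf("poisson correction is only defined for protein alignments")
}

correct_distance <- function(p, model, pair = NULL) {
  who <- if (is.null(pair)) "the pair" else sprintf("pair (%s, %s)", pair[1], pair[2])
  switch(model,
    p_distance = p,
    jc69 = {
      if (p >= 0.75)
        stopf("p-distance %.4f for %s is beyond the Jukes-Cantor domain (p < 3/4)",
              p, who, class = "saturation_error")
      -0.75 * log(1 - 4 * p / 3)
    },
    poisson_corrected = {
      if (p >= 1)
        stopf("p-distance %.4f for %s is beyond the Poisson domain (p < 1)",
              p, who, class = "saturation_error")
      -log(1 - p)
    }
  )
}

#' Distance matrix over all records of an alignment
#'
#' Mismatch and comparable-site counts are accumulated with indicator
#' cross-products over the site matrix, so the whole matrix costs a few
#' dense matrix multiplies rather than a per-pair scan.
#'
#' @inheritParams pairwise_distance
#' @param aln An [alignment()].
#' @return A [dist_matrix()] over the alignment ids, in input order.
#' @export
distance_matrix <- function(aln,
                            model = c("p_distance", "jc69", "poisson_corrected"),
                            gap_policy = c("pairwise_delete", "complete_delete")) {
  model <- match.arg(model)
  gap_policy <- match.arg(gap_policy)
  check_model_alphabet(model, aln$alphabet)
  m <- seq_matrix(aln)
  amb <- ambiguity_char(aln$alphabet)
  ok <- m != "-" & m != amb
  if (gap_policy == "complete_delete") {
    keep <- apply(ok, 2, all)
    if (!any(keep))
      stopf("no comparable sites remain after complete deletion",
            class = "incomparable_pair_error")
    m <- m[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  symbols <- setdiff(alphabet_chars(aln$alphabet), c("-", amb))
  comparable <- tcrossprod(ok * 1)
  matches <- matrix(0, nrow(m), nrow(m))
  for (s in symbols) {
    ind <- (m == s) * 1
    matches <- matches + tcrossprod(ind)
  }
  off <- comparable == 0 & !diag(TRUE, nrow(m))
  if (any(off)) {
    idx <- which(off, arr.ind = TRUE)[1, ]
    stopf("no comparable sites between pair (%s, %s)",
          aln$ids[idx[1]], aln$ids[idx[2]], class = "incomparable_pair_error")
  }
  p <- 1 - matches / pmax(comparable, 1)
  diag(p) <- 0
  if (model != "p_distance") {
    d <- p
    up <- which(upper.tri(p), arr.ind = TRUE)
    for (k in seq_len(nrow(up))) {
      i <- up[k, 1]; j <- up[k, 2]
      d[i, j] <- d[j, i] <- correct_distance(p[i, j], model,
                                             pair = aln$ids[c(i, j)])
    }
    p <- d
  }
  dist_matrix(aln$ids, p)
}

#' Percent similarity corresponding to a p-distance
#'
#' Similarity = (1 - distance) x 100, the scale on which OTU criteria are
#' stated (distance 0.02 is the 98% criterion).
#'
#' @param distance p-distance(s) in `[0, 1]`.
#' @return Percent similarity in `[0, 100]`.
#' @export
percent_similarity <- function(distance) {
  if (any(distance < 0 | distance > 1))
    stopf(paste("similarity is only defined for distances in [0, 1];",
                "report corrected distances on the p-distance scale instead"),
          class = "domain_error")
  (1 - distance) * 100
}
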