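#' Specification of a synthetic clone-library community
#'
#' Describes the community a synthetic library is drawn from: number of
#' planted OTUs, their abundance model, how divergent clones are within an
#' OTU and how far apart OTU ancestors are. The defaults mirror a typical
#' hindgut methanogen clone library: one dominant OTU holding roughly
#' 60-70% of clones and a tail of singletons/doubletons (geometric
#' abundance, dominance theta = 0.6), 50 clones per library, 16S-length
#' sequences, intra-OTU divergence well inside the 0.02 OTU cutoff and
#' ancestors far outside it.
#'
#' @param S_true Number of planted OTUs.
#' @param abundance_model `"geometric"` (weights theta (1-theta)^(i-1),
#'   normalized) or `"explicit"` (use `counts` verbatim).
#' @param theta Geometric dominance parameter in (0, 1) (default 0.6).
#' @param counts Integer vector for the explicit model.
#' @param intra_otu_divergence Maximum planted p-distance between clones of
#'   one OTU (default 0.005).
#' @param inter_otu_divergence Minimum planted p-distance between OTU
#'   ancestors (default 0.20).
#' @param sequence_length Alignment length (default 1254, the 16S amplicon).
#' @param alphabet `"dna"` or `"protein"`.
#' @param seed Optional integer seed making generation deterministic.
#' @return An object of class `"community_spec"`.
#' @export
community_spec <- function(S_true, abundance_model = c("geometric", "explicit"),
                           theta = 0.6, counts = NULL,
                           intra_otu_divergence = 0.005,
                           inter_otu_divergence = 0.20,
                           sequence_length = 1254,
                           alphabet = c("dna", "protein"),
                           seed = NULL) {
  abundance_model <- match.arg(abundance_model)
  alphabet <- match.arg(alphabet)
  if (S_true < 1) stopf("S_true must be >= 1")
  if (abundance_model == "geometric" && (theta <= 0 || theta >= 1))
    stopf("theta must lie in (0, 1)")
  if (abundance_model == "explicit") {
    if (is.null(counts)) stopf("explicit abundance model requires counts")
    if (length(counts) != S_true)
      stopf("explicit counts must have length S_true = %d", S_true)
  }
  if (intra_otu_divergence < 0 || intra_otu_divergence >= 1 ||
      inter_otu_divergence < 0 || inter_otu_divergence >= 1)
    stopf("divergences must lie in [0, 1)")
  if (S_true > 1 && intra_otu_divergence >= inter_otu_divergence)
    stopf("intra_otu_divergence must be below inter_otu_divergence")
  structure(list(S_true = as.integer(S_true),
                 abundance_model = abundance_model, theta = theta,
                 counts = counts,
                 intra_otu_divergence = intra_otu_divergence,
                 inter_otu_divergence = inter_otu_divergence,
                 sequence_length = as.integer(sequence_length),
                 alphabet = alphabet, seed = seed),
            class = "community_spec")
}

#' Draw per-OTU clone counts from a community spec
#'
#' Geometric model: a multinomial draw of `n_clones` clones over weights
#' proportional to theta (1-theta)^(i-1), i = 1..S_true; OTUs may receive
#' zero clones at small n (zero classes are dropped by the diversity
#' statistics, not here, so counts stay aligned with the planted OTU
#' indices). Explicit model: returns the spec's counts verbatim.
#'
#' @param spec A [community_spec()]; its `seed`, when set, is applied first.
#' @param n_clones Total clones to draw.
#' @return Named integer vector of length `S_true` (`OTU1..OTUS`).
#' @export
sample_abundances <- function(spec, n_clones) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (spec$abundance_model == "explicit") {
    if (sum(spec$counts) != n_clones)
      stopf("explicit counts sum to %d, not n_clones = %d",
            sum(spec$counts), n_clones, class = "spec_error")
    counts <- as.integer(spec$counts)
  } else {
    w <- spec$theta * (1 - spec$theta)^(seq_len(spec$S_true) - 1)
    counts <- as.integer(stats::rmultinom(1, n_clones, w / sum(w)))
  }
  stats::setNames(counts, paste0("OTU", seq_len(spec$S_true)))
}

random_sequences <- function(n, len, alphabet) {
  chars <- if (alphabet == "dna") DNA_BASES else AA_RESIDUES
  matrix(sample(chars, n * len, replace = TRUE), nrow = n)
}

mutate_sites <- function(seq_chars, n_sites, alphabet) {
  if (n_sites == 0) return(seq_chars)
  chars <- if (alphabet == "dna") DNA_BASES else AA_RESIDUES
  pos <- sample.int(length(seq_chars), n_sites)
  for (p in pos) {
    seq_chars[p] <- sample(setdiff(chars, seq_chars[p]), 1)
  }
  seq_chars
}

# p-distance audit on a character matrix, no alignment object overhead
pdist_mat <- function(m, alphabet) {
  chars <- if (alphabet == "dna") DNA_BASES else AA_RESIDUES
  matches <- matrix(0, nrow(m), nrow(m))
  for (s in chars) matches <- matches + tcrossprod((m == s) * 1)
  1 - matches / ncol(m)
}

#' Generate a synthetic clone library with planted OTU structure
#'
#' Draws `S_true` ancestor sequences i.i.d. uniform over the alphabet
#' (rejection-checked so every ancestor pair is at least
#' `inter_otu_divergence` apart), then emits each clone as a copy of its
#' OTU's ancestor with at most floor(intra/2 x L) sites mutated, so any
#' two clones of one OTU are within `intra_otu_divergence` and clones of
#' different OTUs at least `inter - intra` apart -- both bounds are
#' asserted on the realized distance matrix before returning. Mutations
#' are i.i.d. per site, uniform over the other 3 bases (19 residues); no
#' indels, so the alignment is gap-free and p-distances exact.
#'
#' @param spec A [community_spec()].
#' @param n_clones Clones to draw (default 50, the study-size library).
#' @param library_name Library tag; clone ids are
#'   `<library_name>_c001` ...
#' @return An object of class `"synthetic_library"`: list with
#'   `alignment`, `truth` (named integer vector id -> planted OTU index)
#'   and `spec`.
#' @export
generate_library <- function(spec, n_clones = 50, library_name = "lib") {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  generate_library_impl(spec, n_clones, library_name)
}

# internal: assumes the RNG is already positioned; optional shared ancestors
generate_library_impl <- function(spec, n_clones, library_name,
                                  ancestors = NULL, counts = NULL) {
  L <- spec$sequence_length
  if (is.null(ancestors)) {
    ancestors <- draw_ancestors(spec)
  }
  if (is.null(counts)) {
    counts <- if (spec$abundance_model == "explicit") {
      if (sum(spec$counts) != n_clones)
        stopf("explicit counts sum to %d, not n_clones = %d",
              sum(spec$counts), n_clones, class = "spec_error")
      as.integer(spec$counts)
    } else {
      w <- spec$theta * (1 - spec$theta)^(seq_len(spec$S_true) - 1)
      as.integer(stats::rmultinom(1, n_clones, w / sum(w)))
    }
  }
  mmax <- floor(spec$intra_otu_divergence * L / 2)
  ids <- character(n_clones); seqs <- character(n_clones)
  truth <- integer(n_clones)
  k <- 0L
  for (i in seq_len(spec$S_true)) {
    if (counts[i] == 0) next
    for (cl in seq_len(counts[i])) {
      k <- k + 1L
      nmut <- if (mmax > 0) sample.int(mmax + 1L, 1L) - 1L else 0L
      seqs[k] <- paste(mutate_sites(ancestors[i, ], nmut, spec$alphabet),
                       collapse = "")
      ids[k] <- sprintf("%s_c%03d", library_name, k)
      truth[k] <- i
    }
  }
  aln <- alignment(ids, rep(library_name, n_clones), seqs, spec$alphabet)
  audit_planted_distances(aln, truth, spec)
  structure(list(alignment = aln,
                 truth = stats::setNames(truth, ids),
                 spec = spec),
            class = "synthetic_library")
}

draw_ancestors <- function(spec, max_attempts = 100) {
  for (attempt in seq_len(max_attempts)) {
    anc <- random_sequences(spec$S_true, spec$sequence_length, spec$alphabet)
    if (spec$S_true == 1) return(anc)
    pd <- pdist_mat(anc, spec$alphabet)
    if (min(pd[upper.tri(pd)]) >= spec$inter_otu_divergence) return(anc)
  }
  stopf(paste("could not draw %d ancestors at least %.3f apart with length %d",
              "after %d attempts; the spec is infeasible"),
        spec$S_true, spec$inter_otu_divergence, spec$sequence_length,
        max_attempts, class = "feasibility_error")
}

audit_planted_distances <- function(aln, truth, spec) {
  pd <- pdist_mat(seq_matrix(aln), spec$alphabet)
  same <- outer(truth, truth, `==`)
  up <- upper.tri(pd)
  intra <- pd[up & same]
  inter <- pd[up & !same]
  eps <- 1e-12
  if (length(intra) && max(intra) > spec$intra_otu_divergence + eps)
    stopf("realized intra-OTU distance %.4f exceeds the planted bound %.4f",
          max(intra), spec$intra_otu_divergence, class = "feasibility_error")
  floor_inter <- spec$inter_otu_divergence - spec$intra_otu_divergence
  if (length(inter) && min(inter) < floor_inter - eps)
    stopf("realized inter-OTU distance %.4f is below the planted floor %.4f",
          min(inter), floor_inter, class = "feasibility_error")
  invisible(TRUE)
}

#' Write a synthetic library's FASTA and truth table
#'
#' @param lib A [generate_library()] result.
#' @param fasta_path,truth_path Output paths (truth is a two-column TSV
#'   `id`, `otu`).
#' @return Invisibly, the two paths.
#' @export
write_synthetic_library <- function(lib, fasta_path, truth_path) {
  write_aligned_fasta(lib$alignment, fasta_path)
  utils::write.table(data.frame(id = names(lib$truth), otu = lib$truth),
                     truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, truth_path))
}

#' Generate paired cross-marker distances with planted proportionality
#'
#' Emulates the calibration input: for n_taxa reference taxa, all
#' n_taxa (n_taxa - 1) / 2 taxon-pair distances, with the reference-marker
#' distance x drawn uniform on `x_range` and the second-marker distance
#' y = slope x + Normal(0, noise_sd) noise, truncated at 0.
#'
#' @param n_taxa Number of reference taxa (23 taxa -> 253 pairs).
#' @param slope Planted proportionality constant.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer RNG seed.
#' @param x_range Range of reference-marker distances (default
#'   `c(0.01, 0.35)`).
#' @return A [paired_distances()] object.
#' @export
generate_paired_markers <- function(n_taxa, slope, noise_sd = 0, seed = 1,
                                    x_range = c(0.01, 0.35)) {
  if (slope <= 0) stopf("slope must be positive")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  set.seed(seed)
  n_pairs <- choose(n_taxa, 2)
  x <- stats::runif(n_pairs, x_range[1], x_range[2])
  y <- pmax(0, slope * x + stats::rnorm(n_pairs, 0, noise_sd))
  paired_distances(x, y)
}

#' Generate a pair of synthetic libraries for two-library comparison
#'
#' `shared = TRUE` draws both libraries from one community (same ancestor
#' pool; the LIBSHUFF null, where library labels are exchangeable);
#' `shared = FALSE` draws each library from its own independent ancestor
#' pool, so the dominant OTUs are disjoint (the LIBSHUFF alternative).
#'
#' @param spec_x,spec_y [community_spec()]s for the two libraries (under
#'   `shared = TRUE` the community structure is `spec_x`'s).
#' @param n_each Clones per library.
#' @param shared Draw from one community (`TRUE`) or two (`FALSE`).
#' @param seed Integer RNG seed (overrides the specs' own seeds).
#' @param names Library names (default `c("x", "y")`).
#' @return List of two `"synthetic_library"` objects.
#' @export
generate_library_pair <- function(spec_x, spec_y = spec_x, n_each = 50,
                                  shared = TRUE, seed = 1,
                                  names = c("x", "y")) {
  set.seed(seed)
  if (shared) {
    anc <- draw_ancestors(spec_x)
    lib_x <- generate_library_impl(spec_x, n_each, names[1], ancestors = anc)
    lib_y <- generate_library_impl(spec_x, n_each, names[2], ancestors = anc)
  } else {
    lib_x <- generate_library_impl(spec_x, n_each, names[1])
    lib_y <- generate_library_impl(spec_y, n_each, names[2])
  }
  list(lib_x, lib_y)
}

#' Pool two synthetic libraries into one alignment
#'
#' @param pair A [generate_library_pair()] result (or any list of two
#'   `"synthetic_library"` objects with distinct ids).
#' @return An [alignment()] containing both libraries' records.
#' @export
pool_libraries <- function(pair) {
  a <- pair[[1]]$alignment; b <- pair[[2]]$alignment
  alignment(c(a$ids, b$ids), c(a$libraries, b$libraries),
            c(a$sequences, b$sequences), a$alphabet)
}
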