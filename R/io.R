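#' Construct an aligned, library-tagged sequence set
#'
#' The central input container of the pipeline: equal-length sequences
#' (a multiple alignment), each carrying the name of the clone library it
#' came from. One FASTA file can hold several libraries; library identity
#' is per-record metadata, not per-file.
#'
#' @param ids Character vector of unique record identifiers.
#' @param libraries Character vector of non-empty library names, one per
#'   record.
#' @param sequences Character vector of aligned sequences, all the same
#'   length. Upper-cased on construction; `.` gaps are normalized to `-`.
#' @param alphabet `"dna"` (A/C/G/T plus N and `-`) or `"protein"` (the 20
#'   amino acids plus X and `-`).
#' @return An object of class `"alignment"`: a list with elements `ids`,
#'   `libraries`, `sequences` and `alphabet`.
#' @export
alignment <- function(ids, libraries, sequences, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  ids <- as.character(ids)
  libraries <- as.character(libraries)
  sequences <- toupper(as.character(sequences))
  sequences <- gsub(".", "-", sequences, fixed = TRUE)
  if (length(ids) != length(sequences) || length(libraries) != length(sequences))
    stopf("ids, libraries and sequences must have equal length")
  if (anyDuplicated(ids))
    stopf("duplicate record id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "),
          class = "duplicate_record_error")
  if (any(!nzchar(libraries)))
    stopf("record(s) without a library tag: %s",
          paste(ids[!nzchar(libraries)], collapse = ", "),
          class = "tagging_error")
  lens <- nchar(sequences)
  if (length(sequences) == 0L || lens[1] < 1L)
    stopf("alignment must contain at least one non-empty sequence")
  if (any(lens != lens[1])) {
    bad <- ids[which(lens != lens[1])[1]]
    stopf("unequal sequence lengths: '%s' has %d sites, expected %d",
          bad, nchar(sequences[ids == bad]), lens[1],
          class = "alignment_length_error")
  }
  ok <- alphabet_chars(alphabet)
  for (i in seq_along(sequences)) {
    chars <- unique(strsplit(sequences[i], "", fixed = TRUE)[[1]])
    bad <- setdiff(chars, ok)
    if (length(bad))
      stopf("record '%s' contains character(s) outside the %s alphabet: %s",
            ids[i], alphabet, paste(bad, collapse = ", "),
            class = "alphabet_error")
  }
  structure(list(ids = ids, libraries = libraries, sequences = sequences,
                 alphabet = alphabet),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d %s sequence(s) of length %d; libraries: %s\n",
              length(x$ids), x$alphabet, nchar(x$sequences[1]),
              paste(unique(x$libraries), collapse = ", ")))
  invisible(x)
}

#' Number of aligned sites
#' @param aln An [alignment()].
#' @return Integer alignment length.
#' @export
alignment_length <- function(aln) nchar(aln$sequences[1])

# character matrix view (records x sites), used by the distance engine
seq_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$sequences, "", fixed = TRUE), use.names = FALSE),
              nrow = length(aln$ids), byrow = TRUE)
  rownames(m) <- aln$ids
  m
}

#' Read an aligned multi-FASTA with library tags
#'
#' Reads a pre-aligned FASTA file (DNA or protein) and attaches a library
#' name to every record. By default the library is the part of the id
#' before the first underscore (`horse_c01` belongs to library `horse`);
#' alternatively pass a named character vector mapping ids to libraries.
#'
#' @param path Path to a FASTA file of equal-length sequences.
#' @param alphabet `"dna"` or `"protein"`.
#' @param library_rule Either the string `"prefix"` (default) or a named
#'   character vector `c(id = library, ...)` covering every record.
#' @return An [alignment()].
#' @export
read_aligned_fasta <- function(path, alphabet = c("dna", "protein"),
                               library_rule = "prefix") {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  libs <- resolve_libraries(ids, library_rule)
  alignment(ids, libs, seqs, alphabet)
}

resolve_libraries <- function(ids, library_rule) {
  if (identical(library_rule, "prefix"))
    return(sub("_.*$", "", ids))
  if (is.character(library_rule) && !is.null(names(library_rule))) {
    missing <- setdiff(ids, names(library_rule))
    if (length(missing))
      stopf("library map does not cover id(s): %s",
            paste(missing, collapse = ", "), class = "tagging_error")
    return(unname(library_rule[ids]))
  }
  stopf("library_rule must be \"prefix\" or a named id -> library vector")
}

#' Write an alignment as FASTA
#' @param aln An [alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(aln, path) {
  set <- Biostrings::BStringSet(aln$sequences)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

#' Construct a pairwise distance matrix
#'
#' @param labels Ordered unique sequence ids (row/column order).
#' @param values Numeric n x n matrix: symmetric, zero diagonal,
#'   non-negative.
#' @return An object of class `"dist_matrix"`: list with `labels` and
#'   `values` (a named numeric matrix).
#' @export
dist_matrix <- function(labels, values) {
  labels <- as.character(labels)
  values <- as.matrix(values)
  n <- length(labels)
  if (!all(dim(values) == c(n, n)))
    stopf("values must be %d x %d to match labels", n, n)
  if (anyDuplicated(labels)) stopf("distance-matrix labels must be unique")
  if (anyNA(values)) stopf("distance matrix contains NA/NaN", class = "data_error")
  if (any(values < 0)) stopf("distances must be non-negative")
  if (n > 0 && max(abs(values - t(values))) > 1e-8)
    stopf("matrix is asymmetric beyond tolerance 1e-8", class = "asymmetry_error")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values), class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("DistanceMatrix: %d taxa, max distance %.4f\n",
              length(x$labels), if (length(x$labels)) max(x$values) else 0))
  invisible(x)
}

#' Read a phylip-style distance matrix
#'
#' Supports the classic count-header square dialect and the lower-triangle
#' dialect (first row is a bare label, row i has i-1 values).
#'
#' @param path Input path.
#' @param dialect `"square"` or `"lower_triangle"`.
#' @return A [dist_matrix()].
#' @export
read_distance_matrix <- function(path, dialect = c("square", "lower_triangle")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty distance-matrix file: %s", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stopf("first line of %s must be the taxon count", path)
  if (length(lines) != n + 1L)
    stopf("expected %d taxon rows in %s, found %d", n, path, length(lines) - 1L,
          class = "parse_error")
  labels <- character(n)
  values <- matrix(0, n, n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    labels[i] <- tok[1]
    vals <- suppressWarnings(as.numeric(tok[-1]))
    expected <- if (dialect == "square") n else i - 1L
    if (length(vals) != expected || anyNA(vals))
      stopf("row '%s' in %s: expected %d values, found %d",
            labels[i], path, expected, length(vals), class = "parse_error")
    if (dialect == "square") {
      values[i, ] <- vals
    } else if (i > 1L) {
      values[i, seq_len(i - 1L)] <- vals
      values[seq_len(i - 1L), i] <- vals
    }
  }
  dist_matrix(labels, values)
}

#' Write a distance matrix in phylip square format
#'
#' Fixed-width values (10 decimal places), so written matrices diff
#' bit-stably and round-trip within 1e-10.
#'
#' @param dm A [dist_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  n <- length(dm$labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  for (i in seq_len(n)) {
    writeLines(paste(dm$labels[i],
                     paste(sprintf("%.10f", dm$values[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' Write an OTU table as TSV
#'
#' One row per OTU, one count column per library, plus a total column --
#' the familiar clone-library table layout.
#'
#' @param table An OTU table as returned by [otu_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  counts <- unclass(table)
  df <- data.frame(OTU = rownames(counts), counts, check.names = FALSE)
  df$Total <- as.integer(rowSums(counts))
  tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stopf("failed to write OTU table to %s: %s",
                              path, conditionMessage(e))
  )
  invisible(path)
}

#' Write a tree in Newick format
#'
#' @param tree An `ape` `"phylo"` object; integer bootstrap supports in
#'   `tree$node.label` are preserved.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stopf("tree must be an ape \"phylo\" object")
  tryCatch(ape::write.tree(tree, file = path),
           error = function(e) stopf("failed to write Newick to %s: %s",
                                     path, conditionMessage(e)))
  invisible(path)
}

#' Read a Newick tree
#' @param path Input path.
#' @return An `ape` `"phylo"` object.
#' @export
read_newick <- function(path) ape::read.tree(path)
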