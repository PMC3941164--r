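check_abundance <- function(counts) {
  counts <- as.numeric(counts)
  if (!length(counts))
    stopf("diversity statistics are undefined for an empty abundance vector",
          class = "undefined_statistic_error")
  if (any(counts < 1) || any(counts != round(counts)))
    stopf("abundance counts must be positive integers (drop zero-count OTUs first)")
  counts
}

#' Shannon-Wiener diversity index
#'
#' H' = -sum p_i ln p_i with p_i the relative clone abundance of OTU i,
#' in nats. Combines richness and evenness; maximal (ln S) for a uniform
#' community, 0 for a single OTU.
#'
#' @param counts Positive integer vector of clones per OTU.
#' @return H' in nats.
#' @export
shannon <- function(counts) {
  counts <- check_abundance(counts)
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Evenness of an OTU abundance vector
#'
#' E = H'/H_max. Two conventions for H_max are in circulation for
#' clone-library tables: the textbook `"formula"` convention H_max = ln(S)
#' (S = observed OTUs), and the `"printed"` convention H_max = ln(N)
#' (N = total clones), which is what published per-library tables of this
#' kind are often computed with. Default is `"printed"`; the convention
#' should always be reported alongside the value.
#'
#' @param counts Positive integer vector of clones per OTU.
#' @param convention `"printed"` (H'/ln N) or `"formula"` (H'/ln S).
#' @return Evenness value (in `[0, 1]` under the formula convention).
#' @export
evenness <- function(counts, convention = c("printed", "formula")) {
  convention <- match.arg(convention)
  counts <- check_abundance(counts)
  h <- shannon(counts)
  if (convention == "formula") {
    s <- length(counts)
    if (s < 2)
      stopf("evenness H'/ln(S) is undefined for a single OTU (ln S = 0)",
            class = "undefined_evenness_error")
    h / log(s)
  } else {
    n <- sum(counts)
    if (n < 2)
      stopf("evenness H'/ln(N) is undefined for a single clone",
            class = "undefined_evenness_error")
    h / log(n)
  }
}

#' Good's coverage of a clone library
#'
#' Coverage = (1 - F1/denominator) x 100, with F1 the number of singleton
#' OTUs. The `"clones"` denominator (total clones N) is Good's estimator of
#' the sampled fraction of the community; the `"otus"` denominator (observed
#' OTUs S) is the variant that published per-library tables of this kind
#' often print. Default is `"otus"`; the convention should be reported with
#' the value.
#'
#' @param counts Positive integer vector of clones per OTU.
#' @param denominator `"otus"` or `"clones"`.
#' @return Coverage percentage in `[0, 100]`.
#' @export
good_coverage <- function(counts, denominator = c("otus", "clones")) {
  denominator <- match.arg(denominator)
  counts <- check_abundance(counts)
  f1 <- sum(counts == 1)
  den <- if (denominator == "clones") sum(counts) else length(counts)
  (1 - f1 / den) * 100
}

#' Chao-1 richness estimator
#'
#' S_chao1 = S_obs + F1^2 / (2 F2), with F1 singleton and F2 doubleton OTU
#' counts. When F2 = 0 the additive fallback term F1 (F1 - 1) / 2 is used,
#' so the estimate is always finite and at least S_obs.
#'
#' @param counts Positive integer vector of clones per OTU.
#' @return Estimated total richness (>= S_obs).
#' @export
chao1 <- function(counts) {
  counts <- check_abundance(counts)
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Per-library diversity report
#'
#' Computes, for each library column of an OTU table (zero-count OTUs
#' dropped per library): total clones N, observed OTUs S, singletons F1,
#' doubletons F2, Shannon-Wiener H', evenness under both conventions,
#' Good's coverage under both denominators, and Chao-1 richness. Statistics
#' are kept at full precision; use [format_diversity_report()] for the
#' rounded table-style rendering.
#'
#' @param table An [otu_table()].
#' @return Data frame, one row per library, columns `library`, `N`,
#'   `S_obs`, `F1`, `F2`, `H_prime`, `evenness_printed`,
#'   `evenness_formula`, `coverage_otus_pct`, `coverage_clones_pct`,
#'   `chao1`.
#' @export
diversity_report <- function(table) {
  counts <- unclass(table)
  rows <- lapply(colnames(counts), function(lib) {
    v <- counts[, lib]
    v <- v[v > 0]
    if (!length(v)) {
      warning(sprintf("library '%s' has zero clones; skipped", lib))
      return(NULL)
    }
    data.frame(
      library = lib,
      N = sum(v),
      S_obs = length(v),
      F1 = sum(v == 1),
      F2 = sum(v == 2),
      H_prime = shannon(v),
      evenness_printed = evenness(v, "printed"),
      evenness_formula = if (length(v) >= 2) evenness(v, "formula") else NA_real_,
      coverage_otus_pct = good_coverage(v, "otus"),
      coverage_clones_pct = good_coverage(v, "clones"),
      chao1 = chao1(v),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Round a diversity report for display
#'
#' H' and evenness to 2 decimal places, coverage and Chao-1 to 1, matching
#' the usual clone-library table rendering.
#'
#' @param report A [diversity_report()] data frame.
#' @return Data frame with rounded display columns.
#' @export
format_diversity_report <- function(report) {
  out <- report
  for (col in c("H_prime", "evenness_printed", "evenness_formula"))
    out[[col]] <- round(out[[col]], 2)
  for (col in c("coverage_otus_pct", "coverage_clones_pct", "chao1"))
    out[[col]] <- round(out[[col]], 1)
  out
}
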