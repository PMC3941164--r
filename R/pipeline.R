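#' Run the full clone-library analysis
#'
#' Orchestrates the pipeline end to end in a fixed order: pairwise
#' distances, furthest-neighbor OTU clustering at the (possibly
#' calibrated) cutoff, per-library diversity report, LIBSHUFF two-library
#' comparison (skipped with a warning when fewer than two libraries are
#' present), and a bootstrapped neighbor-joining tree. Every artifact is
#' written under `out_dir` together with a machine-readable manifest
#' (JSON) echoing the full configuration, seed and convention choices, so
#' identical config + inputs reproduce identical artifacts. A stage
#' failure aborts the run with the stage name and removes partial
#' artifacts.
#'
#' @param aln An [alignment()] or a path to an aligned FASTA file.
#' @param alphabet Alphabet used when `aln` is a path.
#' @param cutoff Fixed OTU distance cutoff (default 0.02, the 98%
#'   similarity criterion). Ignored when `calibration` is supplied.
#' @param calibration Optional list with elements `paired` (a
#'   [paired_distances()]) and `reference_cutoff` (default 0.02): the
#'   cutoff is then mapped from the reference marker by through-origin
#'   regression.
#' @param model Distance model (default `"p_distance"`).
#' @param evenness_convention,coverage_denominator Reporting conventions
#'   recorded in the manifest (defaults `"printed"`, `"otus"`).
#' @param libshuff_permutations,libshuff_alpha,libshuff_step LIBSHUFF
#'   settings (defaults 999, 0.05, 0.01).
#' @param bootstrap_replicates NJ bootstrap replicates (default 100).
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the computed objects and the manifest.
#' @export
run_analysis <- function(aln, alphabet = c("dna", "protein"),
                         cutoff = 0.02, calibration = NULL,
                         model = "p_distance",
                         evenness_convention = "printed",
                         coverage_denominator = "otus",
                         libshuff_permutations = 999,
                         libshuff_alpha = 0.05, libshuff_step = 0.01,
                         bootstrap_replicates = 100,
                         seed = 1, out_dir = "methanodiv_run") {
  alphabet <- match.arg(alphabet)
  if (is.character(aln)) aln <- read_aligned_fasta(aln, alphabet)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(artifacts)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }
  emit <- function(name) {
    path <- file.path(out_dir, name)
    artifacts <<- c(artifacts, path)
    path
  }

  cal <- NULL
  if (!is.null(calibration)) {
    cal <- run_stage("calibration", {
      fit <- through_origin_regression(calibration$paired)
      map_cutoff(fit$slope, calibration$reference_cutoff %||% 0.02,
                 fit$r_squared_uncentered)
    })
    cutoff <- cal$mapped_cutoff
  }

  dm <- run_stage("distances", distance_matrix(aln, model = model))
  run_stage("distances", write_distance_matrix(dm, emit("distances.phylip")))

  clust <- run_stage("clustering", cluster_furthest_neighbor(dm, cutoff))
  tab <- run_stage("clustering", otu_table(clust, aln))
  run_stage("clustering", write_otu_table(tab, emit("otu_table.tsv")))

  report <- run_stage("diversity", diversity_report(tab))
  run_stage("diversity", utils::write.table(
    format_diversity_report(report), emit("diversity_report.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE))

  libs <- unique(aln$libraries)
  ls_result <- NULL
  if (length(libs) == 2) {
    ls_result <- run_stage("libshuff", {
      lab <- stats::setNames(aln$libraries, aln$ids)
      libshuff_test(dm, lab, n_permutations = libshuff_permutations,
                    seed = seed, alpha = libshuff_alpha, step = libshuff_step)
    })
    run_stage("libshuff", jsonlite::write_json(
      unclass(ls_result), emit("libshuff.json"), auto_unbox = TRUE, digits = NA))
  } else {
    warning(sprintf("LIBSHUFF stage skipped: %d library(ies) present", length(libs)))
  }

  tree <- run_stage("phylogeny",
                    bootstrap_support(aln, model = model,
                                      n_replicates = bootstrap_replicates,
                                      seed = seed))
  run_stage("phylogeny", write_newick(tree, emit("nj_tree.nwk")))

  manifest <- list(
    package = "methanodiv",
    version = as.character(utils::packageVersion("methanodiv")),
    seed = seed,
    n_sequences = length(aln$ids),
    libraries = libs,
    alphabet = aln$alphabet,
    distance_model = model,
    gap_policy = "pairwise_delete",
    cutoff = cutoff,
    cutoff_source = if (is.null(cal)) "fixed" else "calibration",
    calibration = if (is.null(cal)) NULL else unclass(cal),
    clustering = list(linkage = "furthest_neighbor",
                      tie_rule = "lexicographic smallest (min id, max id)",
                      binning = "none (full precision)"),
    conventions = list(evenness = evenness_convention,
                       coverage_denominator = coverage_denominator),
    libshuff = if (is.null(ls_result)) "skipped" else
      list(n_permutations = libshuff_permutations, alpha = libshuff_alpha,
           step = libshuff_step,
           integral = "one-sided squared shortfall x step",
           significant = ls_result$significant),
    bootstrap = list(n_replicates = bootstrap_replicates,
                     resampling = "alignment columns",
                     skipped_replicates = attr(tree, "skipped_replicates")),
    artifacts = basename(artifacts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(distance_matrix = dm, clustering = clust, otu_table = tab,
                 diversity = report, libshuff = ls_result, tree = tree,
                 calibration = cal, manifest = manifest,
                 artifacts = c(artifacts, file.path(out_dir, "manifest.json"))))
}
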