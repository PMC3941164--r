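#' Paired cross-marker distances
#'
#' Pairs of evolutionary distances for the same taxon pairs measured on two
#' markers: `x` on the reference marker (16S rRNA gene, DNA), `y` on the
#' marker to calibrate (mcrA deduced amino acids).
#'
#' @param x,y Non-negative numeric vectors of equal length (>= 2).
#' @param labels Optional taxon-pair labels.
#' @return An object of class `"paired_distances"`.
#' @export
paired_distances <- function(x, y, labels = NULL) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 2) stopf("at least 2 distance pairs are required")
  if (any(x < 0) || any(y < 0)) stopf("distances must be non-negative")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 labels = labels %||% paste0("pair", seq_along(x))),
            class = "paired_distances")
}

#' Through-origin least-squares regression of paired distances
#'
#' Fits y = b x with no intercept: b = sum(x y) / sum(x^2). The reported
#' R-squared is the uncentered form 1 - RSS / sum(y^2), the standard
#' definition for a line forced through the origin (the centered form can
#' be negative and misleading without an intercept).
#'
#' @param paired A [paired_distances()] object.
#' @return List with `slope` and `r_squared_uncentered`.
#' @export
through_origin_regression <- function(paired) {
  x <- paired$x; y <- paired$y
  sxx <- sum(x^2)
  if (sxx == 0)
    stopf("all x are zero: through-origin slope is undefined",
          class = "degenerate_regressor_error")
  slope <- sum(x * y) / sxx
  rss <- sum((y - slope * x)^2)
  syy <- sum(y^2)
  r2 <- if (syy == 0) 1 else 1 - rss / syy
  list(slope = slope, r_squared_uncentered = r2)
}

#' Map a reference-marker OTU cutoff onto a second marker
#'
#' Given the through-origin slope relating the second marker's distances to
#' the reference marker's, the reference cutoff X maps to Y = slope * X,
#' and the percent-similarity criterion is floor(100 * (1 - Y)) -- flooring
#' to a whole percent is what turns a mapped distance of 0.0439 into a 95%
#' similarity criterion.
#'
#' @param slope Positive through-origin slope.
#' @param reference_cutoff Reference-marker distance cutoff in (0, 1), or 0
#'   (boundary allowed; maps to 0 and 100%).
#' @param r_squared_uncentered Optional fit quality carried into the result.
#' @return An object of class `"calibration_result"`: list with `slope`,
#'   `r_squared_uncentered`, `mapped_cutoff`, `similarity_criterion_pct`
#'   and `r_squared_definition = "uncentered"`.
#' @export
map_cutoff <- function(slope, reference_cutoff, r_squared_uncentered = NA_real_) {
  if (slope <= 0) stopf("slope must be positive for a valid calibration")
  if (reference_cutoff < 0 || reference_cutoff >= 1)
    stopf("reference_cutoff must lie in [0, 1)")
  mapped <- slope * reference_cutoff
  if (mapped >= 1)
    stopf("mapped cutoff %.4f is >= 1: not a valid p-distance cutoff", mapped,
          class = "nonsense_cutoff_error")
  structure(list(slope = slope,
                 r_squared_uncentered = r_squared_uncentered,
                 r_squared_definition = "uncentered",
                 mapped_cutoff = mapped,
                 similarity_criterion_pct = as.integer(floor(100 * (1 - mapped)))),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration: slope %.4f (uncentered R^2 %s) -> cutoff %.4f, %d%% similarity criterion\n",
              x$slope,
              if (is.na(x$r_squared_uncentered)) "NA"
              else sprintf("%.4f", x$r_squared_uncentered),
              x$mapped_cutoff, x$similarity_criterion_pct))
  invisible(x)
}

#' Calibrate a second marker's OTU cutoff from reference alignments
#'
#' Builds the distance matrix for both markers over the same taxa, pairs
#' all n(n-1)/2 taxon-pair distances, fits the through-origin regression,
#' and maps the reference cutoff. Taxa are matched by alignment id; the
#' pairing convention (all pairwise taxon pairs) is recorded here rather
#' than per-taxon values because the regression relates distance to
#' distance.
#'
#' @param ref_x_aln Reference-marker [alignment()] (e.g. 16S rRNA, DNA).
#' @param ref_y_aln Second-marker [alignment()] over the same taxon ids
#'   (e.g. mcrA amino acids).
#' @param model Distance model applied to both markers (default
#'   `"p_distance"`).
#' @param reference_cutoff Reference-marker cutoff (default 0.02, the 98%
#'   similarity criterion).
#' @return A `"calibration_result"` with the fitted slope and uncentered
#'   R-squared.
#' @export
calibrate_from_alignments <- function(ref_x_aln, ref_y_aln,
                                      model = "p_distance",
                                      reference_cutoff = 0.02) {
  if (length(ref_x_aln$ids) < 3)
    stopf("calibration requires at least 3 shared taxa")
  only_x <- setdiff(ref_x_aln$ids, ref_y_aln$ids)
  only_y <- setdiff(ref_y_aln$ids, ref_x_aln$ids)
  if (length(only_x) || length(only_y))
    stopf("taxa present in one alignment only: %s",
          paste(c(only_x, only_y), collapse = ", "), class = "pairing_error")
  dx <- distance_matrix(ref_x_aln, model = model)
  dy <- distance_matrix(ref_y_aln, model = model)
  ids <- ref_x_aln$ids
  vy <- dy$values[ids, ids]
  up <- upper.tri(dx$values)
  labs <- outer(ids, ids, paste, sep = "|")[up]
  fit <- through_origin_regression(
    paired_distances(dx$values[up], vy[up], labels = labs))
  map_cutoff(fit$slope, reference_cutoff, fit$r_squared_uncentered)
}
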