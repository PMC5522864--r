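#' Population median
#'
#' Median of a set of positive trait values: the middle order statistic for
#' odd counts, the mean of the two middle order statistics for even counts.
#' The median (not the mean) is used as the normalization scale factor
#' because trait distributions within a segregating population are expected
#' to be non-normal (they are mixtures of genotype classes).
#'
#' @param values numeric vector; non-finite entries are dropped.
#' @return The median as a single number.
#' @export
population_median <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L)
    stop_validation("population_median needs at least one finite value")
  stats::median(values)
}

#' Normalize transgene-marker traits against the reference gene
#'
#' Applies the conversion `T = (X / Y) * Z` per sample and transgene
#' marker, where `X` is the sample's raw trait value for the transgene
#' marker, `Y` is the same sample's raw trait value for the single-copy
#' reference marker, and `Z` is the median reference-marker trait value of
#' the sample's normalization group (by default, its population). Dividing
#' by `Y` removes sample-to-sample amplification and loading variation;
#' multiplying by `Z` restores the values to the population's original
#' trait scale.
#'
#' Samples without a detected reference product cannot be normalized: all
#' their `T` values are `NA` and they are excluded from the `Z` median.
#'
#' @param matrix a `trait_matrix` from [build_trait_matrix()].
#' @param panel the [marker_panel()] the matrix was built over.
#' @param grouping named character vector mapping every sample id in the
#'   matrix to a normalization group (population) id. A single unnamed
#'   value recycles to all samples.
#' @return A `normalized_traits` data.frame with one row per sample x
#'   transgene marker and columns `sample_id`, `group_id`, `marker`,
#'   `trait`, `X`, `Y`, `Z`, `T`.
#' @export
normalize_traits <- function(matrix, panel, grouping) {
  assert_panel(panel)
  if (!inherits(matrix, "trait_matrix"))
    stop_validation("matrix must be a trait_matrix")
  samples <- rownames(matrix)
  if (length(grouping) == 1L && is.null(names(grouping)))
    grouping <- stats::setNames(rep(grouping, length(samples)), samples)
  if (!all(samples %in% names(grouping)))
    stop_validation("grouping must cover every sample in the matrix")
  group <- as.character(grouping[samples])

  ref <- matrix[, panel$reference_marker]
  z_by_group <- vapply(split(ref, group), function(y) {
    y <- y[is.finite(y)]
    if (length(y) == 0L) return(NA_real_)
    population_median(y)
  }, numeric(1))
  if (anyNA(z_by_group))
    stop_validation(sprintf(
      "group(s) with no finite reference values: %s",
      paste(names(z_by_group)[is.na(z_by_group)], collapse = ", ")))

  tg <- panel$transgene_markers
  long <- expand.grid(sample_id = samples, marker = tg,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$group_id <- group[match(long$sample_id, samples)]
  long$trait <- attr(matrix, "trait")
  long$X <- matrix[cbind(match(long$sample_id, samples), match(long$marker, colnames(matrix)))]
  long$Y <- ref[match(long$sample_id, samples)]
  long$Z <- z_by_group[long$group_id]
  long$T <- ifelse(is.finite(long$X) & is.finite(long$Y),
                   long$X / long$Y * long$Z, NA_real_)
  long <- long[c("sample_id", "group_id", "marker", "trait", "X", "Y", "Z", "T")]
  long <- long[order(long$group_id, long$sample_id, long$marker), , drop = FALSE]
  rownames(long) <- NULL
  structure(long, class = c("normalized_traits", "data.frame"))
}
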