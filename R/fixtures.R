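# Bundled reference tables: a genotyping experiment on nine cotton BC1S1
# populations segregating for a PHYA1 RNAi T-DNA construct, used as worked
# examples and as regression anchors for the summary operations.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "zygocall", mustWork = FALSE)
  if (p == "") stop_io(sprintf("bundled file %s not found", file))
  p
}

#' Reference segregation counts for nine cotton BC1S1 populations
#'
#' Presence-class counts (transgenic / null / missing out of 240 plants
#' genotyped per population) for nine backcross-derived populations
#' segregating for a single-locus PHYA1 RNAi T-DNA insertion in cotton.
#'
#' @return data.frame with columns `population_id`, `n_transgenic`,
#'   `n_null`, `n_missing`, `n_total`.
#' @seealso [population_totals()]
#' @export
cotton_segregation_counts <- function() {
  raw <- utils::read.delim(fixture_path("bc1s1_segregation.tsv"),
                           check.names = FALSE)
  data.frame(population_id = raw$Population,
             n_transgenic = raw$Transgenic, n_null = raw$Null,
             n_missing = raw$Missing, n_total = raw$Total,
             stringsAsFactors = FALSE)
}

#' Reference K-means cluster statistics for nine cotton BC1S1 populations
#'
#' Per-population homozygous and hemizygous cluster sizes, mean normalized
#' OCS_S peak heights and areas, and the cubic clustering criterion, for
#' the same nine populations as [cotton_segregation_counts()].
#'
#' Note: the MD51ne homozygous peak-area value is anomalously low relative
#' to every other population; it is transcribed as reported.
#'
#' @return data.frame with columns `population_id`, `n_homozygous`,
#'   `homozygous_height`, `homozygous_area`, `n_hemizygous`,
#'   `hemizygous_height`, `hemizygous_area`, `ccc`.
#' @seealso [cluster_mean_summary()]
#' @export
cotton_cluster_means <- function() {
  raw <- utils::read.delim(fixture_path("bc1s1_cluster_means.tsv"),
                           check.names = FALSE)
  data.frame(population_id = raw$Population,
             n_homozygous = raw$HomozygousN,
             homozygous_height = raw$HomozygousHeight,
             homozygous_area = raw$HomozygousArea,
             n_hemizygous = raw$HemizygousN,
             hemizygous_height = raw$HemizygousHeight,
             hemizygous_area = raw$HemizygousArea,
             ccc = raw$CCC, stringsAsFactors = FALSE)
}

#' Synthetic progeny-test family table (BC1S2)
#'
#' Per-family progeny class counts for 41 selfed BC1S1 parents (20
#' predicted homozygous, 21 predicted hemizygous). Only class-level
#' aggregates of the underlying experiment are available, so the
#' per-family counts here are synthetic: constructed to be consistent
#' with those aggregates (19/20 homozygous predictions confirmed, 21/21
#' hemizygous confirmed, class-mean progeny counts of roughly 22.5/0/0
#' and 5.0/11.6/6.3). Confirmation flags are not stored; they are
#' recomputed from the counts by [confirmation_summary()].
#'
#' @return data.frame with columns `family_id`, `prediction`,
#'   `n_homozygous`, `n_hemizygous`, `n_null`.
#' @export
cotton_progeny_families <- function() {
  raw <- utils::read.delim(fixture_path("bc1s2_families_synthetic.tsv"),
                           check.names = FALSE)
  data.frame(family_id = raw$Family, prediction = raw$Prediction,
             n_homozygous = raw$Homozygous, n_hemizygous = raw$Hemizygous,
             n_null = raw$Null, stringsAsFactors = FALSE)
}
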