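#' Pairwise correlations between marker traits
#'
#' Product-moment correlations between raw transgene-marker peak heights
#' and areas across samples (pairwise-complete), with a significance flag
#' from the standard correlation t-test at `alpha`. Markers whose
#' amplification is erratic show low, non-significant correlations with
#' the others.
#'
#' @param table a `peak_table`.
#' @param traits which traits to include (default height and area).
#' @param alpha significance level.
#' @param min_pairs minimum pairwise-complete samples for an entry;
#'   entries with fewer are `NA`.
#' @return A `correlation_matrix` object: list with matrices `r`, `p`,
#'   `n`, `significant` over "marker trait" variables.
#' @export
trait_correlations <- function(table, traits = c("height", "area"),
                               alpha = 0.05, min_pairs = 3L) {
  if (!inherits(table, "peak_table")) stop_validation("table must be a peak_table")
  panel <- attr(table, "panel")
  mats <- lapply(traits, function(tr) {
    m <- build_trait_matrix(table, tr)
    m[, panel$transgene_markers, drop = FALSE]
  })
  samples <- rownames(mats[[1]])
  cols <- do.call(cbind, mats)
  colnames(cols) <- unlist(lapply(seq_along(traits), function(i)
    paste(panel$transgene_markers, traits[i])))
  k <- ncol(cols)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(cols), colnames(cols)))
  npair <- matrix(0L, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- is.finite(cols[, i]) & is.finite(cols[, j])
    npair[i, j] <- sum(ok)
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    if (sum(ok) < min_pairs) next
    xi <- cols[ok, i]; xj <- cols[ok, j]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
    ct <- stats::cor.test(xi, xj)
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  structure(list(r = r, p = p, n = npair, significant = p < alpha,
                 alpha = alpha),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  m <- round(x$r, digits)
  flag <- ifelse(!is.na(x$significant) & x$significant, "*", "")
  out <- matrix(paste0(format(m), flag), nrow = nrow(m), dimnames = dimnames(m))
  print(out, quote = FALSE)
  invisible(x)
}

#' Run the full zygosity-calling pipeline
#'
#' Presence calling, normalization (height and area), zygosity calling,
#' per-population segregation tests (3:1 transgenic:null over presence
#' calls, 1:2:1 homozygous:hemizygous:null over final calls), summaries,
#' method concordance and the trait correlation matrix, in one call.
#' Missing-class samples are excluded from segregation counts.
#'
#' @param peaks a `peak_table` or path to a peak-table TSV.
#' @param sheet a `sample_sheet` or path to a sample-sheet TSV.
#' @param panel a [marker_panel()] (used when `peaks` is a path).
#' @param config a [zygosity_config()].
#' @param calls_out optional path; when set, calls are written there as
#'   TSV.
#' @param report_out optional path; when set, the report is written there
#'   as JSON (deterministic ordering, trait means at 1 decimal).
#' @return A `zygosity_report` list: `calls`, `summary`, `totals`,
#'   `segregation` (per-population test list), `concordance`,
#'   `correlations`, `diagnostics`.
#' @export
run_pipeline <- function(peaks, sheet, panel = marker_panel(),
                         config = zygosity_config(),
                         calls_out = NULL, report_out = NULL) {
  if (is.character(peaks)) peaks <- read_peak_table(peaks, panel)
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  panel <- attr(peaks, "panel")

  extra <- setdiff(unique(peaks$sample_id), sheet$sample_id)
  if (length(extra) > 0L)
    stop_integrity(sprintf("peak table sample(s) not in sample sheet: %s",
                           paste(utils::head(extra, 5L), collapse = ", ")))

  heights <- build_trait_matrix(peaks, "height")
  areas <- build_trait_matrix(peaks, "area")
  presence <- call_presence(heights, panel)
  # sheet samples with no detected peak at all are failed assays
  unseen <- setdiff(sheet$sample_id, presence$sample_id)
  if (length(unseen) > 0L) {
    presence <- rbind(presence,
                      data.frame(sample_id = unseen, status = "missing",
                                 stringsAsFactors = FALSE))
    class(presence) <- c("presence_calls", "data.frame")
  }
  grouping <- stats::setNames(sheet$population_id, sheet$sample_id)
  norm <- rbind(normalize_traits(heights, panel, grouping),
                normalize_traits(areas, panel, grouping))
  class(norm) <- c("normalized_traits", "data.frame")
  calls <- call_zygosity(norm, presence, config)
  if (length(unseen) > 0L) {
    extra <- data.frame(sample_id = unseen,
                        population_id = unname(grouping[unseen]),
                        presence = "missing", pit_call = NA_character_,
                        kmeans_call = NA_character_, final_call = "missing",
                        concordant = NA, normalized_height = NA_real_,
                        normalized_area = NA_real_, stringsAsFactors = FALSE)
    atts <- attributes(calls)[c("diagnostics", "marker", "trait")]
    calls <- rbind(as.data.frame(calls), extra)
    attributes(calls)[names(atts)] <- atts
    class(calls) <- c("zygosity_calls", "data.frame")
  }

  summary <- summarize_populations(presence, calls, sheet)
  seg <- lapply(split(summary, summary$population_id), function(row) {
    res <- list(population_id = row$population_id)
    if (row$n_transgenic + row$n_null > 0)
      res$presence_3to1 <- chisq_gof(c(row$n_transgenic, row$n_null), c(3, 1),
                                     alpha = config$alpha)
    if (!is.na(row$n_homozygous) &&
        row$n_homozygous + row$n_hemizygous + row$n_null > 0 &&
        all(c(row$n_homozygous, row$n_hemizygous, row$n_null) >= 0))
      res$zygosity_1to2to1 <- tryCatch(
        chisq_gof(c(row$n_homozygous, row$n_hemizygous, row$n_null),
                  c(1, 2, 1), alpha = config$alpha),
        zygocall_error = function(e) NULL)
    res
  })
  report <- list(calls = calls, summary = summary,
                 totals = attr(summary, "totals"),
                 segregation = seg, concordance = concordance(calls),
                 correlations = trait_correlations(peaks),
                 diagnostics = attr(calls, "diagnostics"),
                 config = config)
  class(report) <- "zygosity_report"

  if (!is.null(calls_out)) write_calls(calls, calls_out)
  if (!is.null(report_out)) write_report_json(report, report_out)
  report
}

# serialize the report deterministically; trait means at 1 decimal
write_report_json <- function(report, path) {
  summary <- as.data.frame(report$summary)
  for (col in c("homozygous_height", "hemizygous_height",
                "homozygous_area", "hemizygous_area"))
    summary[[col]] <- round(summary[[col]], 1)
  summary$ccc <- round(summary$ccc, 2)
  seg <- lapply(report$segregation, function(s) {
    keep <- function(t) if (is.null(t)) NULL else
      list(observed = t$observed, expected = round(t$expected, 2),
           pearson_chi2 = round(t$pearson_chi2, 4),
           g_statistic = round(t$g_statistic, 4), df = t$df,
           p_pearson = round(t$p_pearson, 6), p_g = round(t$p_g, 6),
           fits = t$fits)
    list(population_id = s$population_id,
         presence_3to1 = keep(s$presence_3to1),
         zygosity_1to2to1 = keep(s$zygosity_1to2to1))
  })
  diag <- lapply(report$diagnostics, function(d)
    list(population_id = d$population_id, n_transgenic = d$n_transgenic,
         ccc = if (is.na(d$ccc)) NULL else round(d$ccc, 2),
         ccc_ok = d$ccc_ok,
         hsd = if (is.null(d$hsd)) NULL else
           list(q = round(d$hsd$q_statistic, 2), df = d$hsd$df,
                p = signif(d$hsd$p_value, 4),
                significant = d$hsd$significant),
         flags = d$flags))
  obj <- list(summary = summary,
              totals = as.list(report$totals),
              segregation = seg,
              concordance = report$concordance,
              correlations = list(r = round(report$correlations$r, 3),
                                  significant = report$correlations$significant),
              diagnostics = diag)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null", digits = NA)
  invisible(NULL)
}

#' @export
print.zygosity_report <- function(x, ...) {
  cat("Zygosity pipeline report\n")
  tot <- x$totals
  cat(sprintf("  samples: %d (transgenic %d, null %d, missing %d)\n",
              tot$n_total, tot$n_transgenic, tot$n_null, tot$n_missing))
  cc <- x$concordance
  if (cc$n_both > 0)
    cat(sprintf("  pit/K-means concordance: %d/%d (%.1f%%)\n",
                cc$n_agree, cc$n_both, 100 * cc$fraction_agree))
  cat(sprintf("  populations: %d\n", nrow(x$summary)))
  invisible(x)
}
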