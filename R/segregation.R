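#' Goodness of fit to a Mendelian segregation ratio
#'
#' Tests observed genotype-class counts against an expected ratio (for
#' example 3:1 transgenic:null, or 1:2:1 homozygous:hemizygous:null for
#' progeny of a selfed hemizygote) with both the Pearson chi-square
#' statistic `sum((O - E)^2 / E)` and the likelihood-ratio G statistic
#' `2 sum(O log(O / E))` (taking `0 log 0 = 0`), each referred to the
#' chi-square distribution on `classes - 1` degrees of freedom, with no
#' continuity correction. The counts are declared to fit the ratio when
#' both tests are non-significant at `alpha`.
#'
#' @param observed vector of non-negative integer counts (at least 2
#'   classes, positive total).
#' @param ratio expected ratio, a vector of positive numbers the same
#'   length as `observed`; its scale is irrelevant (3:1 and 6:2 are the
#'   same ratio).
#' @param alpha significance level for the fit decision.
#' @return A `segregation_test` object: `observed`, `expected_ratio`,
#'   `expected`, `pearson_chi2`, `g_statistic`, `df`, `p_pearson`, `p_g`,
#'   `fits`.
#' @examples
#' chisq_gof(c(160, 68), c(3, 1))       # 3:1 transgenic : null
#' chisq_gof(c(57, 103, 68), c(1, 2, 1)) # 1:2:1
#' @export
chisq_gof <- function(observed, ratio, alpha = 0.05) {
  if (length(observed) != length(ratio) || length(observed) < 2L)
    stop_validation("observed and ratio must have equal length >= 2")
  if (any(!is.finite(observed)) || any(observed < 0))
    stop_validation("observed counts must be non-negative numbers")
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop_validation("ratio entries must be positive")
  total <- sum(observed)
  if (total <= 0) stop_validation("total count must be positive")
  expected <- total * ratio / sum(ratio)
  if (any(expected == 0)) stop_validation("expected counts must be positive")

  pearson <- sum((observed - expected)^2 / expected)
  terms <- ifelse(observed == 0, 0, observed * log(observed / expected))
  g <- 2 * sum(terms)
  df <- length(observed) - 1L
  p_pearson <- stats::pchisq(pearson, df, lower.tail = FALSE)
  p_g <- stats::pchisq(g, df, lower.tail = FALSE)
  structure(
    list(observed = observed, expected_ratio = ratio, expected = expected,
         pearson_chi2 = pearson, g_statistic = g, df = df,
         p_pearson = p_pearson, p_g = p_g, alpha = alpha,
         fits = min(p_pearson, p_g) >= alpha),
    class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf("Segregation test vs %s: observed (%s)\n",
              paste(x$expected_ratio, collapse = ":"),
              paste(x$observed, collapse = ", ")))
  cat(sprintf("  Pearson chi^2 = %.3f (p = %.4g), G = %.3f (p = %.4g), df = %d -> %s\n",
              x$pearson_chi2, x$p_pearson, x$g_statistic, x$p_g, x$df,
              if (x$fits) "fits" else "does not fit"))
  invisible(x)
}

# shared rule for confirming a parental zygosity prediction from
# progeny class counts (n_homozygous, n_hemizygous, n_null)
confirm_from_counts <- function(counts, prediction, alpha = 0.05) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(counts < 0) || any(!is.finite(counts)))
    stop_validation("progeny counts must be three non-negative numbers")
  test <- NULL
  if (prediction == "homozygous") {
    # a truly homozygous parent cannot produce null (or hemizygous) selfed
    # progeny: any segregation refutes the prediction
    confirmed <- counts[3] == 0 && counts[2] == 0
  } else if (prediction == "hemizygous") {
    test <- chisq_gof(counts, c(1, 2, 1), alpha = alpha)
    confirmed <- test$fits
  } else {
    stop_validation(sprintf("unknown prediction \"%s\"", prediction))
  }
  list(confirmed = confirmed, test = test)
}

#' Confirm a parent's predicted zygosity from its selfed progeny
#'
#' A parent predicted homozygous is confirmed when its selfed family shows
#' no construct segregation: zero null progeny and no hemizygous class
#' detected (when raw normalized trait values are supplied, the family's
#' distribution must additionally not be called bimodal). A parent
#' predicted hemizygous is confirmed when the family's
#' homozygous:hemizygous:null counts fit 1:2:1 by [chisq_gof()].
#'
#' @param progeny either a `zygosity_calls` data.frame for one family, or
#'   a numeric vector of three counts `(n_homozygous, n_hemizygous,
#'   n_null)`.
#' @param prediction `"homozygous"` or `"hemizygous"`.
#' @param alpha significance level for the 1:2:1 test.
#' @param min_progeny minimum number of called progeny.
#' @param values optional raw normalized trait values for the family, used
#'   for the bimodality check under a homozygous prediction (taken from
#'   the calls' normalized heights when `progeny` is a call set).
#' @param family_id optional label carried into the result.
#' @return A `family_confirmation` object: `family_id`, `prediction`,
#'   `progeny_counts`, `confirmed`, `test` (the 1:2:1 `segregation_test`,
#'   or `NULL`).
#' @export
classify_family <- function(progeny, prediction, alpha = 0.05,
                            min_progeny = 8L, values = NULL,
                            family_id = NA_character_) {
  if (!prediction %in% c("homozygous", "hemizygous"))
    stop_validation(sprintf("unknown prediction \"%s\"", prediction))
  from_calls <- inherits(progeny, "zygosity_calls") || is.data.frame(progeny)
  if (from_calls) {
    fc <- progeny$final_call
    counts <- c(sum(fc == "homozygous", na.rm = TRUE),
                sum(fc == "hemizygous", na.rm = TRUE),
                sum(fc == "null", na.rm = TRUE))
    n_transgenic <- sum(progeny$presence == "transgenic", na.rm = TRUE)
    if (is.null(values) && "normalized_height" %in% names(progeny))
      values <- progeny$normalized_height[progeny$presence == "transgenic"]
    if (prediction == "homozygous" && counts[1] + counts[2] == 0) {
      # no supported dosage split in the family: all transgenic progeny
      # form one class, which under a homozygous prediction is homozygous
      counts[1] <- n_transgenic
    }
  } else {
    counts <- as.numeric(progeny)
  }
  if (sum(counts) < min_progeny)
    stop_validation(sprintf("family needs at least %d called progeny (got %d)",
                            min_progeny, sum(counts)))
  if (from_calls && prediction == "homozygous") {
    # "no construct segregation": every progeny transgenic and the trait
    # distribution unimodal; forced AA/AB labels are not held against it
    confirmed <- counts[3] == 0
    res <- list(confirmed = confirmed, test = NULL)
  } else {
    res <- confirm_from_counts(counts, prediction, alpha = alpha)
  }
  if (prediction == "homozygous" && res$confirmed && !is.null(values)) {
    split <- tryCatch(find_pit(values), zygocall_error = function(e) NULL)
    if (!is.null(split) && split$is_bimodal) res$confirmed <- FALSE
  }
  structure(
    list(family_id = family_id, prediction = prediction,
         progeny_counts = stats::setNames(counts, c("n_homozygous", "n_hemizygous", "n_null")),
         confirmed = res$confirmed, test = res$test),
    class = "family_confirmation")
}

#' Summarize prediction success over progeny-test families
#'
#' Aggregates a set of family confirmations by predicted parental
#' genotype: number of families, number confirmed, percent confirmed, and
#' mean progeny counts per class. Accepts either a list of
#' `family_confirmation` objects from [classify_family()] or a data.frame
#' with columns `family_id`, `prediction`, `n_homozygous`,
#' `n_hemizygous`, `n_null` (confirmation is then computed from the counts
#' at `alpha`).
#'
#' @param families list of `family_confirmation` objects or a per-family
#'   counts data.frame.
#' @param alpha significance level used when confirmations must be
#'   computed from counts.
#' @return A `confirmation_summary` data.frame with one row per prediction
#'   class: `prediction`, `n_families`, `n_confirmed`,
#'   `percent_confirmed`, `mean_homozygous`, `mean_hemizygous`,
#'   `mean_null`.
#' @export
confirmation_summary <- function(families, alpha = 0.05) {
  if (is.data.frame(families)) {
    need <- c("prediction", "n_homozygous", "n_hemizygous", "n_null")
    if (!all(need %in% names(families)))
      stop_validation("family table needs prediction, n_homozygous, n_hemizygous, n_null")
    families <- lapply(seq_len(nrow(families)), function(i) {
      classify_family(
        as.numeric(families[i, c("n_homozygous", "n_hemizygous", "n_null")]),
        prediction = families$prediction[i], alpha = alpha,
        family_id = if ("family_id" %in% names(families))
          families$family_id[i] else NA_character_)
    })
  }
  if (length(families) == 0L) stop_validation("at least one family is required")
  if (!all(vapply(families, inherits, logical(1), "family_confirmation")))
    stop_validation("families must be family_confirmation objects")

  pred <- vapply(families, `[[`, character(1), "prediction")
  counts <- t(vapply(families, `[[`, numeric(3), "progeny_counts"))
  confirmed <- vapply(families, `[[`, logical(1), "confirmed")
  out <- do.call(rbind, lapply(unique(pred), function(p) {
    i <- pred == p
    data.frame(prediction = p, n_families = sum(i), n_confirmed = sum(confirmed[i]),
               percent_confirmed = 100 * sum(confirmed[i]) / sum(i),
               mean_homozygous = mean(counts[i, 1]),
               mean_hemizygous = mean(counts[i, 2]),
               mean_null = mean(counts[i, 3]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("confirmation_summary", "data.frame"))
}

#' Per-population summary of presence and zygosity calls
#'
#' Tabulates, for every population in the sample sheet, the transgenic /
#' null / missing presence counts and the homozygous / hemizygous call
#' counts, together with per-class mean normalized trait values and the
#' population CCC, plus a grand-total row attached as the `"totals"`
#' attribute.
#'
#' @param presence a `presence_calls` data.frame.
#' @param calls a `zygosity_calls` data.frame (may be `NULL` when only
#'   presence counts are wanted).
#' @param sheet a `sample_sheet` covering every sample in `presence`.
#' @return A `population_summary` data.frame, one row per population, with
#'   the totals row as `attr(x, "totals")`.
#' @export
summarize_populations <- function(presence, calls = NULL, sheet) {
  if (!inherits(presence, "presence_calls"))
    stop_validation("presence must be a presence_calls table")
  if (!inherits(sheet, "sample_sheet"))
    stop_validation("sheet must be a sample_sheet")
  absent <- setdiff(presence$sample_id, sheet$sample_id)
  if (length(absent) > 0L)
    stop_integrity(sprintf("sample(s) not in sample sheet: %s",
                           paste(utils::head(absent, 5L), collapse = ", ")))
  pop <- stats::setNames(sheet$population_id, sheet$sample_id)
  presence$population_id <- unname(pop[presence$sample_id])

  per_pop <- lapply(split(presence, presence$population_id), function(pp) {
    row <- data.frame(population_id = pp$population_id[1],
                      n_transgenic = sum(pp$status == "transgenic"),
                      n_null = sum(pp$status == "null"),
                      n_missing = sum(pp$status == "missing"),
                      n_total = nrow(pp),
                      n_homozygous = NA_integer_, n_hemizygous = NA_integer_,
                      homozygous_height = NA_real_, hemizygous_height = NA_real_,
                      homozygous_area = NA_real_, hemizygous_area = NA_real_,
                      ccc = NA_real_, stringsAsFactors = FALSE)
    if (!is.null(calls)) {
      cc <- calls[calls$sample_id %in% pp$sample_id, , drop = FALSE]
      hom <- cc$final_call == "homozygous" & !is.na(cc$final_call)
      hem <- cc$final_call == "hemizygous" & !is.na(cc$final_call)
      row$n_homozygous <- sum(hom)
      row$n_hemizygous <- sum(hem)
      row$homozygous_height <- mean(cc$normalized_height[hom], na.rm = TRUE)
      row$hemizygous_height <- mean(cc$normalized_height[hem], na.rm = TRUE)
      row$homozygous_area <- mean(cc$normalized_area[hom], na.rm = TRUE)
      row$hemizygous_area <- mean(cc$normalized_area[hem], na.rm = TRUE)
      diag <- attr(calls, "diagnostics")
      if (!is.null(diag) && !is.null(diag[[row$population_id]]))
        row$ccc <- diag[[row$population_id]]$ccc
    }
    row
  })
  out <- do.call(rbind, per_pop)
  rownames(out) <- NULL
  totals <- data.frame(population_id = "Total",
                       n_transgenic = sum(out$n_transgenic),
                       n_null = sum(out$n_null),
                       n_missing = sum(out$n_missing),
                       n_total = sum(out$n_total),
                       stringsAsFactors = FALSE)
  structure(out, totals = totals, class = c("population_summary", "data.frame"))
}

#' Grand totals of a population summary or segregation-count table
#'
#' Sums the presence-class counts over populations. Works on the output of
#' [summarize_populations()] or on any data.frame with columns
#' `n_transgenic`, `n_null`, `n_missing`, `n_total`.
#'
#' @param summary a `population_summary` or compatible data.frame.
#' @return Named numeric vector with `n_transgenic`, `n_null`,
#'   `n_missing`, `n_total`.
#' @export
population_totals <- function(summary) {
  need <- c("n_transgenic", "n_null", "n_missing", "n_total")
  if (!all(need %in% names(summary)))
    stop_validation("summary needs n_transgenic, n_null, n_missing, n_total columns")
  vapply(summary[need], sum, numeric(1))
}

#' Across-population means of cluster statistics
#'
#' Averages per-population cluster sizes, cluster trait means and CCC over
#' populations — the bottom "average" row of a per-population zygosity
#' cluster table. Input is the output of [summarize_populations()] (with
#' calls) or any data.frame carrying the cluster columns.
#'
#' @param clusters data.frame with columns `n_homozygous`,
#'   `n_hemizygous`, `homozygous_height`, `hemizygous_height`,
#'   `homozygous_area`, `hemizygous_area` and optionally `ccc`.
#' @return Named numeric vector of the across-population means.
#' @export
cluster_mean_summary <- function(clusters) {
  need <- c("n_homozygous", "n_hemizygous", "homozygous_height",
            "hemizygous_height", "homozygous_area", "hemizygous_area")
  if (!all(need %in% names(clusters)))
    stop_validation("cluster table is missing cluster-statistic columns")
  cols <- c(need, intersect("ccc", names(clusters)))
  vapply(clusters[cols], function(x) mean(x, na.rm = TRUE), numeric(1))
}
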