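#' Call transgene presence per sample
#'
#' A sample is `transgenic` when every transgene marker and the reference
#' marker produced a detectable product; `null` when only the reference
#' marker amplified; `missing` otherwise (reference failure, or partial
#' transgene amplification, which is treated conservatively as a failed
#' assay rather than evidence of absence).
#'
#' @param matrix a `trait_matrix` (any trait; only presence/absence is used).
#' @param panel the [marker_panel()].
#' @return A `presence_calls` data.frame with columns `sample_id`, `status`.
#' @export
call_presence <- function(matrix, panel) {
  assert_panel(panel)
  if (!inherits(matrix, "trait_matrix"))
    stop_validation("matrix must be a trait_matrix")
  present <- is.finite(matrix)
  ref_ok <- present[, panel$reference_marker]
  tg <- present[, panel$transgene_markers, drop = FALSE]
  n_tg <- rowSums(tg)
  status <- ifelse(ref_ok & n_tg == length(panel$transgene_markers), "transgenic",
            ifelse(ref_ok & n_tg == 0L, "null", "missing"))
  structure(
    data.frame(sample_id = rownames(matrix), status = unname(status),
               stringsAsFactors = FALSE),
    class = c("presence_calls", "data.frame"))
}

#' Locate the bimodal valley ("pit") of a trait distribution
#'
#' Estimates the density of normalized trait values with a Gaussian kernel
#' (Silverman's rule-of-thumb bandwidth, `0.9 min(sd, IQR/1.34) n^(-1/5)`)
#' on a fixed grid spanning the data range, finds its local maxima, and —
#' if two well-supported modes exist — reports the grid point of minimum
#' density strictly between them. In a population segregating for a single
#' transgene locus the two modes are the homozygous and hemizygous classes
#' and the pit is the natural split point between them.
#'
#' A local maximum only counts as a mode when its density is at least
#' `prominence` times the global maximum, and the split is only declared
#' bimodal when the pit density is below `valley_depth` times the smaller
#' mode density. Without these guards, sampling wiggles in the density
#' estimate of a unimodal population are routinely miscounted as second
#' modes.
#'
#' @param values numeric vector of normalized trait values.
#' @param min_n minimum number of finite values (default 20).
#' @param grid_n number of grid points for the density estimate.
#' @param prominence minimum mode density as a fraction of the highest mode.
#' @param valley_depth maximum pit density as a fraction of the smaller
#'   mode density for the distribution to be called bimodal.
#' @param bw bandwidth rule or value passed to [stats::density()];
#'   default `"nrd0"` (Silverman).
#' @return A `bimodal_split` object: list with `mode_locations`,
#'   `mode_densities`, `pit_location`, `pit_density`, `bandwidth`,
#'   `is_bimodal`, `n`.
#' @export
find_pit <- function(values, min_n = 20L, grid_n = 512L,
                     prominence = 0.05, valley_depth = 0.9, bw = "nrd0") {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < min_n)
    stop_validation(sprintf("find_pit needs at least %d finite values (got %d)",
                            min_n, n))
  if (stats::sd(values) == 0)
    stop_degenerate("find_pit: values have zero variance")
  d <- stats::density(values, bw = bw, n = grid_n,
                      from = min(values), to = max(values))
  y <- d$y
  # local maxima, boundary grid points included
  pad <- c(-Inf, y, -Inf)
  m <- length(y)
  is_max <- pad[2:(m + 1)] > pad[1:m] & pad[2:(m + 1)] >= pad[3:(m + 2)]
  peaks <- which(is_max)
  peaks <- peaks[y[peaks] >= prominence * max(y)]

  out <- list(mode_locations = NULL, mode_densities = NULL,
              pit_location = NA_real_, pit_density = NA_real_,
              bandwidth = d$bw, is_bimodal = FALSE, n = n)
  class(out) <- "bimodal_split"
  if (length(peaks) < 2L) return(out)

  modes <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  between <- (modes[1] + 1L):(modes[2] - 1L)
  pit <- between[which.min(y[between])]
  out$mode_locations <- d$x[modes]
  out$mode_densities <- y[modes]
  out$pit_location <- d$x[pit]
  out$pit_density <- y[pit]
  out$is_bimodal <- y[pit] < valley_depth * min(y[modes])
  out
}

#' @export
print.bimodal_split <- function(x, ...) {
  if (x$is_bimodal) {
    cat(sprintf("Bimodal split: modes at %.1f and %.1f, pit at %.1f (n = %d)\n",
                x$mode_locations[1], x$mode_locations[2], x$pit_location, x$n))
  } else {
    cat(sprintf("No bimodal split detected (n = %d)\n", x$n))
  }
  invisible(x)
}

#' Classify values by the pit natural split
#'
#' Values above the pit belong to the higher (homozygous, `"AA"`) mode;
#' values below — or exactly at — the pit go to the lower (hemizygous,
#' `"AB"`) mode. Ties at the pit default to the hemizygous class because it
#' is the larger expected class (2/4 of a selfed hemizygote's progeny),
#' which minimizes expected misassignment.
#'
#' @param values numeric vector.
#' @param split a bimodal `bimodal_split` from [find_pit()].
#' @return Character vector of `"AA"`/`"AB"` labels (`NA` for non-finite
#'   values).
#' @export
split_by_pit <- function(values, split) {
  if (!inherits(split, "bimodal_split"))
    stop_validation("split must be a bimodal_split")
  if (!isTRUE(split$is_bimodal))
    stop_state("split_by_pit requires a bimodal split")
  ifelse(!is.finite(values), NA_character_,
         ifelse(values > split$pit_location, "AA", "AB"))
}

# within-cluster sum of squares of x[i..j] from prefix sums
.seg_ss <- function(cs, cs2, i, j) {
  s <- cs[j + 1L] - cs[i]
  s2 <- cs2[j + 1L] - cs2[i]
  s2 - s^2 / (j - i + 1L)
}

#' Exact one-dimensional two-cluster K-means
#'
#' In one dimension the optimal 2-means partition is contiguous in sorted
#' order, so the global optimum is found exactly by scanning all `n - 1`
#' splits of the sorted values and keeping the one with minimal pooled
#' within-cluster sum of squares. A deterministic Lloyd iteration
#' (centroids initialized at the 10th and 90th percentiles) is available
#' via `method = "lloyd"`; the exact search is the default and the Lloyd
#' fixed point is verified against it in the package tests. The cluster
#' with the larger centroid is labeled `"AA"` (homozygous, two transgene
#' copies amplify to more product) and the other `"AB"`.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @param k number of clusters; only 2 is supported.
#' @param method `"exact"` (default) or `"lloyd"`.
#' @return A `kmeans1d` object: `assignments` (`"AA"`/`"AB"` per input
#'   value, `NA` for non-finite inputs), `centroids` (named, AB then AA),
#'   `n_per_cluster`, `within_ss`, `total_ss`, `r_squared`.
#' @export
kmeans_1d <- function(values, k = 2L, method = c("exact", "lloyd")) {
  method <- match.arg(method)
  if (k != 2L) stop_validation("only k = 2 is supported")
  finite <- is.finite(values)
  x <- values[finite]
  n <- length(x)
  if (length(unique(x)) < 2L)
    stop_degenerate("kmeans_1d needs at least 2 distinct values")

  ord <- order(x)
  xs <- x[ord]
  cs <- c(0, cumsum(xs))
  cs2 <- c(0, cumsum(xs^2))
  total_ss <- .seg_ss(cs, cs2, 1L, n)

  if (method == "exact") {
    wss <- vapply(1:(n - 1L), function(i)
      .seg_ss(cs, cs2, 1L, i) + .seg_ss(cs, cs2, i + 1L, n), numeric(1))
    cut <- which.min(wss)
    lower <- seq_len(n) <= cut
    within_ss <- wss[cut]
  } else {
    cen <- unname(stats::quantile(xs, c(0.1, 0.9), type = 7))
    if (cen[1] == cen[2]) cen <- range(xs)
    repeat {
      lower <- abs(xs - cen[1]) <= abs(xs - cen[2])
      if (all(lower) || !any(lower)) { # collapsed: fall back to range init
        cen <- range(xs); next
      }
      new_cen <- c(mean(xs[lower]), mean(xs[!lower]))
      if (isTRUE(all.equal(new_cen, cen))) break
      cen <- new_cen
    }
    within_ss <- .seg_ss(cs, cs2, 1L, sum(lower)) +
      .seg_ss(cs, cs2, sum(lower) + 1L, n)
  }

  centroids <- c(AB = mean(xs[lower]), AA = mean(xs[!lower]))
  labels_sorted <- ifelse(lower, "AB", "AA")
  assign_finite <- character(n)
  assign_finite[ord] <- labels_sorted
  assignments <- rep(NA_character_, length(values))
  assignments[finite] <- assign_finite

  structure(
    list(assignments = assignments,
         centroids = centroids,
         n_per_cluster = c(AB = sum(lower), AA = n - sum(lower)),
         within_ss = within_ss,
         total_ss = total_ss,
         r_squared = 1 - within_ss / total_ss,
         n = n),
    class = "kmeans1d")
}

#' @export
print.kmeans1d <- function(x, ...) {
  cat(sprintf("1-D 2-means: centroids AB = %.2f, AA = %.2f (n = %d/%d), R^2 = %.4f\n",
              x$centroids["AB"], x$centroids["AA"],
              x$n_per_cluster["AB"], x$n_per_cluster["AA"], x$r_squared))
  invisible(x)
}

#' Cubic clustering criterion (Sarle) for a 1-D two-cluster solution
#'
#' Compares the observed clustering R-squared with its expectation under a
#' uniform (no-cluster) null and returns
#' `CCC = ln[(1 - E(R^2)) / (1 - R^2)] * sqrt(n p / 2) / (0.001 + E(R^2))^1.2`.
#' For one dimension and `q = 2` clusters the null expectation reduces to
#' `E(R^2) = 1 - [(1/(n + 2))/4] * [(n - 2)^2 / n] * (1 + 4/n)`.
#' CCC is 0 when the observed R-squared equals its null expectation,
#' positive when clustering is stronger than expected, negative when
#' weaker; values of 2 or more are conventionally taken as evidence of real
#' cluster structure.
#'
#' @param result a `kmeans1d` object.
#' @param n number of observations clustered (defaults to the count stored
#'   in `result`).
#' @param p data dimensionality; only 1 is supported.
#' @return The CCC value; `Inf` with a warning when R-squared is exactly 1.
#' @export
compute_ccc <- function(result, n = result$n, p = 1L) {
  if (!inherits(result, "kmeans1d")) stop_validation("result must be a kmeans1d object")
  if (p != 1L) stop_validation("only p = 1 is supported")
  if (!is_scalar_number(n) || n < 4) stop_validation("n must be at least 4")
  r2 <- result$r_squared
  q <- 2
  u <- q  # p = 1: edge s, bin width s/q, so u = s / (s/q) = q
  e_r2 <- 1 - (1 / (n + u)) / u^2 * (n - q)^2 / n * (1 + 4 / n)
  if (r2 >= 1) {
    warning("R^2 = 1: clusters are perfectly separated, CCC is infinite", call. = FALSE)
    return(Inf)
  }
  log((1 - e_r2) / (1 - r2)) * sqrt(n * p / 2) / (0.001 + e_r2)^1.2
}

# null expectation of R^2 used by compute_ccc, exposed for testing
ccc_null_r2 <- function(n, q = 2) {
  1 - (1 / (n + q)) / q^2 * (n - q)^2 / n * (1 + 4 / n)
}

#' Tukey-Kramer HSD test for two groups
#'
#' Studentized-range test of the difference between two group means with
#' (possibly) unequal sizes:
#' `q = |mean_a - mean_b| / sqrt((MSW / 2) (1/n_a + 1/n_b))`
#' with `MSW` the pooled within-group mean square on
#' `df = n_a + n_b - 2` degrees of freedom. With two groups the
#' studentized range reduces to `q = t sqrt(2)`, so the p-value is the
#' two-sided t probability.
#'
#' @param group_a,group_b numeric vectors with at least 2 values each.
#' @param alpha significance level.
#' @return An `hsd_result`: `group_means`, `q_statistic`, `df`, `p_value`,
#'   `significant`.
#' @export
tukey_kramer <- function(group_a, group_b, alpha = 0.05) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop_validation("each group needs at least 2 values")
  df <- na + nb - 2L
  msw <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  if (msw == 0) stop_degenerate("pooled within-group variance is zero")
  q <- abs(mean(a) - mean(b)) / sqrt((msw / 2) * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-q / sqrt(2), df)
  structure(
    list(group_means = c(mean(a), mean(b)), q_statistic = q, df = df,
         p_value = p, significant = p < alpha, alpha = alpha),
    class = "hsd_result")
}

#' Zygosity-calling configuration
#'
#' @param marker transgene marker whose normalized trait is clustered
#'   (default `"OCS_S"`, the marker that amplifies most consistently and
#'   shows the clearest bimodal separation).
#' @param trait `"height"` or `"area"` (default height).
#' @param method which classifier(s) to run: `"both"` (default), `"pit"`
#'   or `"kmeans"`. Final calls are taken from K-means when it ran,
#'   otherwise from the pit split.
#' @param min_samples minimum transgenic samples per population to attempt
#'   clustering.
#' @param kde_grid,prominence,valley_depth,bandwidth_rule passed to
#'   [find_pit()] (the last as its `bw`).
#' @param alpha significance level for the Tukey-Kramer HSD.
#' @param ccc_threshold CCC value at or above which the two-cluster model
#'   is flagged as a good fit (default 2).
#' @return A list of class `zygosity_config`.
#' @export
zygosity_config <- function(marker = "OCS_S", trait = c("height", "area"),
                            method = c("both", "pit", "kmeans"),
                            min_samples = 20L, kde_grid = 512L,
                            prominence = 0.05, valley_depth = 0.9,
                            bandwidth_rule = "nrd0",
                            alpha = 0.05, ccc_threshold = 2) {
  structure(
    list(marker = marker, trait = match.arg(trait), method = match.arg(method),
         min_samples = as.integer(min_samples), kde_grid = as.integer(kde_grid),
         prominence = prominence, valley_depth = valley_depth,
         bandwidth_rule = bandwidth_rule,
         alpha = alpha, ccc_threshold = ccc_threshold),
    class = "zygosity_config")
}

#' Call zygosity for every sample
#'
#' For each normalization group (population), the normalized trait values
#' of the configured marker are clustered over transgenic samples only,
#' with the pit natural split and/or exact 1-D K-means. Final calls map
#' `AA` to `homozygous` and `AB` to `hemizygous`; presence-null samples are
#' `null` and presence-missing samples `missing`. Per-population
#' diagnostics (bimodal split, K-means result, CCC, Tukey-Kramer HSD) are
#' attached as the `"diagnostics"` attribute.
#'
#' @param normalized a `normalized_traits` table covering the configured
#'   marker and trait (it may contain additional traits; heights and areas
#'   present are carried through to the output columns).
#' @param presence a `presence_calls` data.frame from [call_presence()].
#' @param config a [zygosity_config()].
#' @return A `zygosity_calls` data.frame: `sample_id`, `population_id`,
#'   `presence`, `pit_call`, `kmeans_call`, `final_call`, `concordant`,
#'   `normalized_height`, `normalized_area`, plus `marker`/`trait` used as
#'   attributes.
#' @export
call_zygosity <- function(normalized, presence, config = zygosity_config()) {
  if (!inherits(normalized, "normalized_traits"))
    stop_validation("normalized must be a normalized_traits table")
  if (!inherits(presence, "presence_calls"))
    stop_validation("presence must be a presence_calls table")

  sel <- normalized[normalized$marker == config$marker &
                      normalized$trait == config$trait, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop_validation(sprintf("normalized table has no rows for marker %s, trait %s",
                            config$marker, config$trait))
  status <- stats::setNames(presence$status, presence$sample_id)
  if (!all(sel$sample_id %in% names(status)))
    stop_validation("presence calls missing for some normalized samples")

  pull_trait <- function(tr) {
    sub <- normalized[normalized$marker == config$marker &
                        normalized$trait == tr, , drop = FALSE]
    stats::setNames(sub$T, sub$sample_id)
  }
  t_height <- pull_trait("height")
  t_area <- pull_trait("area")

  calls <- data.frame(sample_id = sel$sample_id,
                      population_id = sel$group_id,
                      presence = unname(status[sel$sample_id]),
                      pit_call = NA_character_,
                      kmeans_call = NA_character_,
                      final_call = NA_character_,
                      stringsAsFactors = FALSE)
  values <- stats::setNames(sel$T, sel$sample_id)
  diagnostics <- list()
  supported <- logical(0)

  for (pop in unique(calls$population_id)) {
    in_pop <- calls$population_id == pop
    tg <- in_pop & calls$presence == "transgenic" & is.finite(values[calls$sample_id])
    d <- list(population_id = pop, n_transgenic = sum(tg),
              pit = NULL, kmeans = NULL, ccc = NA_real_, ccc_ok = NA,
              hsd = NULL, flags = character(0))
    if (sum(tg) < config$min_samples) {
      d$flags <- c(d$flags, "too_few_transgenic")
      diagnostics[[pop]] <- d
      next
    }
    v <- values[calls$sample_id[tg]]

    if (config$method %in% c("both", "pit")) {
      split <- tryCatch(
        find_pit(v, min_n = config$min_samples, grid_n = config$kde_grid,
                 prominence = config$prominence,
                 valley_depth = config$valley_depth,
                 bw = config$bandwidth_rule),
        zygocall_error = function(e) NULL)
      d$pit <- split
      if (!is.null(split) && split$is_bimodal) {
        calls$pit_call[tg] <- split_by_pit(v, split)
      } else {
        d$flags <- c(d$flags, "not_bimodal")
      }
    }
    if (config$method %in% c("both", "kmeans")) {
      km <- tryCatch(kmeans_1d(v), zygocall_error = function(e) NULL)
      d$kmeans <- km
      if (!is.null(km)) {
        calls$kmeans_call[tg] <- km$assignments
        d$ccc <- compute_ccc(km)
        d$ccc_ok <- is.finite(d$ccc) && d$ccc >= config$ccc_threshold
        grp <- split(v, km$assignments)
        if (all(c("AA", "AB") %in% names(grp)) &&
            length(grp$AA) >= 2L && length(grp$AB) >= 2L) {
          d$hsd <- tryCatch(tukey_kramer(grp$AA, grp$AB, alpha = config$alpha),
                            zygocall_error = function(e) NULL)
        }
      } else {
        d$flags <- c(d$flags, "kmeans_degenerate")
      }
    }
    # a two-class interpretation needs support from at least one method:
    # a bimodal pit, or a K-means fit passing the CCC criterion. Without
    # it, forcing every transgenic sample into AA/AB would split a
    # single-genotype population (e.g. a homozygous parent line) in half.
    pop_supported <- (!is.null(d$pit) && isTRUE(d$pit$is_bimodal)) ||
      isTRUE(d$ccc_ok)
    if (!pop_supported) d$flags <- c(d$flags, "two_cluster_unsupported")
    supported[pop] <- pop_supported
    diagnostics[[pop]] <- d
  }

  ok <- supported[calls$population_id]
  ok[is.na(ok)] <- FALSE
  primary <- ifelse(!is.na(calls$kmeans_call), calls$kmeans_call, calls$pit_call)
  primary[!ok] <- NA_character_
  calls$final_call <- ifelse(calls$presence == "null", "null",
                      ifelse(calls$presence == "missing", "missing",
                      ifelse(primary == "AA", "homozygous",
                      ifelse(primary == "AB", "hemizygous", NA_character_))))
  calls$concordant <- ifelse(is.na(calls$pit_call) | is.na(calls$kmeans_call), NA,
                             calls$pit_call == calls$kmeans_call)
  calls$normalized_height <- unname(t_height[calls$sample_id])
  calls$normalized_area <- if (length(t_area)) unname(t_area[calls$sample_id]) else NA_real_
  if (!length(t_height)) calls$normalized_height <- NA_real_
  rownames(calls) <- NULL
  structure(calls, diagnostics = diagnostics,
            marker = config$marker, trait = config$trait,
            class = c("zygosity_calls", "data.frame"))
}

#' Agreement between the pit and K-means classifiers
#'
#' @param calls a `zygosity_calls` data.frame with both `pit_call` and
#'   `kmeans_call` columns.
#' @return A list: `n_both` (samples with both calls), `n_agree`,
#'   `n_disagree`, `fraction_agree`.
#' @export
concordance <- function(calls) {
  if (!inherits(calls, "zygosity_calls"))
    stop_validation("calls must be a zygosity_calls object")
  both <- !is.na(calls$pit_call) & !is.na(calls$kmeans_call)
  n_both <- sum(both)
  n_agree <- sum(calls$pit_call[both] == calls$kmeans_call[both])
  list(n_both = n_both, n_agree = n_agree, n_disagree = n_both - n_agree,
       fraction_agree = if (n_both > 0) n_agree / n_both else NA_real_)
}
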