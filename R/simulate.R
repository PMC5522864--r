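#' Amplification and measurement parameters for the PCR simulator
#'
#' The simulator models a standard PCR run stopped in (or after) the
#' logarithmic phase, followed by capillary-electrophoresis peak
#' quantification. Product grows by the discrete logistic recursion
#' `P <- P + efficiency * P * (1 - P / capacity)` per cycle, so with few
#' cycles the final product is proportional to starting template (a
#' hemizygote yields half the product of a homozygote) while with many
#' cycles every reaction plateaus near `capacity` and allele dosage
#' becomes indistinguishable. Touchdown pre-cycles common to all samples
#' are absorbed into `initial_template` and the calibration scales.
#'
#' Defaults put simulated normalized peak heights on the scale typical of
#' fragment-analyzer exports (hemizygous around 400 RFU, homozygous around
#' 800 at 10 cycles) and set the detection threshold so that 5-cycle
#' products fall below it.
#'
#' @param efficiency per-cycle amplification gain in (0, 1].
#' @param initial_template product units per starting template copy.
#' @param capacity saturation ceiling of the reaction.
#' @param cycles number of amplification cycles after touchdown.
#' @param detection_threshold minimum peak height (RFU) for a peak to be
#'   reported.
#' @param height_scale,area_scale calibration from product quantity to
#'   peak height (RFU) and area.
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal measurement noise (independent for height and area, and
#'   between markers). Because normalized traits divide a transgene
#'   marker's value by the reference marker's, their dispersion compounds
#'   to about `sqrt(2) * noise_cv`; the default 0.085 therefore yields
#'   normalized trait classes with a CV of about 12%, the dispersion
#'   regime in which the homozygous/hemizygous split is reliably bimodal.
#' @param marker_failure_rate per-marker probability that amplification
#'   fails entirely for a sample.
#' @param failure_overrides named numeric vector of per-marker failure
#'   rates overriding `marker_failure_rate` (default: elevated for
#'   NPTII-3, which amplifies least consistently).
#' @param dilution factor applied to all of a sample's products before
#'   measurement (models diluting PCR product prior to electrophoresis).
#' @return An `amp_params` list.
#' @export
amp_params <- function(efficiency = 0.9, initial_template = 1,
                       capacity = 1e5, cycles = 10L,
                       detection_threshold = 50, height_scale = 0.65,
                       area_scale = 4.5, noise_cv = 0.085,
                       marker_failure_rate = 0.01,
                       failure_overrides = c("NPTII-3" = 0.05),
                       dilution = 1) {
  if (!is_scalar_number(efficiency) || efficiency <= 0 || efficiency > 1)
    stop_validation("efficiency must be in (0, 1]")
  for (nm in c("initial_template", "capacity", "height_scale", "area_scale", "dilution")) {
    v <- get(nm)
    if (!(is_scalar_number(v) || (nm == "capacity" && is.infinite(v))) ||
        v <= 0)
      stop_validation(sprintf("%s must be positive", nm))
  }
  if (!is_scalar_number(noise_cv) || noise_cv < 0)
    stop_validation("noise_cv must be non-negative")
  if (cycles < 0) stop_validation("cycles must be non-negative")
  rates <- c(marker_failure_rate, failure_overrides)
  if (any(rates < 0) || any(rates >= 1))
    stop_validation("failure rates must be in [0, 1)")
  structure(
    list(efficiency = efficiency, initial_template = initial_template,
         capacity = capacity, cycles = as.integer(cycles),
         detection_threshold = detection_threshold,
         height_scale = height_scale, area_scale = area_scale,
         noise_cv = noise_cv, marker_failure_rate = marker_failure_rate,
         failure_overrides = failure_overrides, dilution = dilution),
    class = "amp_params")
}

GENOTYPES <- c("homozygous", "hemizygous", "null")
genotype_copies <- c(homozygous = 2L, hemizygous = 1L, null = 0L)

#' Noise-free PCR product quantity from template copy number
#'
#' Iterates the discrete logistic recursion `P[0] = copies *
#' initial_template`; `P[i+1] = P[i] + efficiency * P[i] * (1 - P[i] /
#' capacity)` for `cycles` steps. In the unsaturated limit (`capacity`
#' much larger than the product) this is geometric growth `copies *
#' initial_template * (1 + efficiency)^cycles`, so the product ratio of 1
#' vs 2 template copies is exactly 0.5 — the log-phase window that makes
#' hemizygotes distinguishable from homozygotes. Near saturation the
#' ratio drifts toward 1 and dosage information is lost.
#'
#' @param copies non-negative number of starting template copies
#'   (vectorized).
#' @param params an [amp_params()] object.
#' @return Product quantity for each element of `copies`.
#' @examples
#' p <- amp_params(capacity = Inf)
#' amplify(1, p) / amplify(2, p) # exactly 0.5
#' @export
amplify <- function(copies, params = amp_params()) {
  if (!inherits(params, "amp_params")) stop_validation("params must be amp_params")
  if (any(copies < 0)) stop_validation("copies must be non-negative")
  P <- copies * params$initial_template
  for (i in seq_len(params$cycles))
    P <- P + params$efficiency * P * (1 - P / params$capacity)
  P
}

failure_rate_for <- function(params, marker) {
  if (marker %in% names(params$failure_overrides))
    unname(params$failure_overrides[marker])
  else params$marker_failure_rate
}

default_sizes <- c("35S_S" = 181, "OCS_S" = 142, "NPTII-3" = 216, "GhUBC1" = 123)

marker_size <- function(panel, marker) {
  if (!is.null(panel$expected_size_bp) && marker %in% names(panel$expected_size_bp))
    return(unname(panel$expected_size_bp[marker]))
  if (marker %in% names(default_sizes)) return(unname(default_sizes[marker]))
  100 + 7 * (match(marker, panel_markers(panel)) - 1L)
}

#' Simulate one sample's peak records
#'
#' Draws, for each panel marker, the measured peak from the amplification
#' model: template copies from the genotype (transgene markers 0/1/2,
#' reference always 2), logistic amplification, dilution, independent
#' multiplicative lognormal noise on height and area, a per-marker
#' amplification-failure draw, and censoring of peaks below the detection
#' threshold. Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param truth a single-row data.frame (or list) with `sample_id` and
#'   `genotype` (`"homozygous"`, `"hemizygous"` or `"null"`).
#' @param panel a [marker_panel()].
#' @param params an [amp_params()].
#' @return data.frame of peak records (possibly zero rows).
#' @export
simulate_sample <- function(truth, panel, params = amp_params()) {
  assert_panel(panel)
  genotype <- match.arg(truth$genotype, GENOTYPES)
  sdlog <- sqrt(log(1 + params$noise_cv^2))
  rows <- lapply(panel_markers(panel), function(mk) {
    copies <- if (mk == panel$reference_marker) 2L else
      genotype_copies[[genotype]]
    if (copies == 0L) return(NULL)
    if (stats::runif(1) < failure_rate_for(params, mk)) return(NULL)
    product <- amplify(copies, params) * params$dilution
    eps_h <- if (sdlog > 0) stats::rlnorm(1, -sdlog^2 / 2, sdlog) else 1
    eps_a <- if (sdlog > 0) stats::rlnorm(1, -sdlog^2 / 2, sdlog) else 1
    height <- params$height_scale * product * eps_h
    if (height < params$detection_threshold) return(NULL)
    data.frame(sample_id = truth$sample_id, marker = mk,
               size_bp = marker_size(panel, mk) + stats::rnorm(1, 0, 0.2),
               height = height,
               area = params$area_scale * product * eps_a,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(sample_id = character(0), marker = character(0),
                      size_bp = numeric(0), height = numeric(0),
                      area = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

simulate_cohort <- function(truth, panel, params) {
  recs <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i)
    simulate_sample(truth[i, ], panel, params)))
  peak_table(recs, panel)
}

#' Simulate a segregating population with ground truth
#'
#' Genotypes are drawn multinomially from `genotype_ratio`
#' (homozygous:hemizygous:null; the default 1:2:1 is the expectation for
#' selfed progeny of a hemizygote) and each sample's peak records are
#' simulated from the amplification model. Identical seeds give identical
#' tables.
#'
#' @param n number of individuals.
#' @param genotype_ratio length-3 non-negative weights for
#'   homozygous:hemizygous:null.
#' @param panel a [marker_panel()].
#' @param params an [amp_params()].
#' @param seed integer seed; all randomness flows from it.
#' @param population_id population label used in sample ids and the truth
#'   table.
#' @return list with `peaks` (a `peak_table`), `truth` (data.frame
#'   `sample_id`, `genotype`, `population_id`) and `sheet` (a
#'   [sample_sheet()] for the population).
#' @export
simulate_population <- function(n, genotype_ratio = c(1, 2, 1),
                                panel = marker_panel(),
                                params = amp_params(), seed = 1L,
                                population_id = "POP1") {
  if (n < 1) stop_validation("n must be at least 1")
  if (length(genotype_ratio) != 3L || any(genotype_ratio < 0) ||
      sum(genotype_ratio) <= 0)
    stop_validation("genotype_ratio must be 3 non-negative weights with positive sum")
  set.seed(seed)
  genotype <- sample(GENOTYPES, n, replace = TRUE,
                     prob = genotype_ratio / sum(genotype_ratio))
  truth <- data.frame(
    sample_id = sprintf("%s_%04d", population_id, seq_len(n)),
    genotype = genotype, population_id = population_id,
    stringsAsFactors = FALSE)
  list(peaks = simulate_cohort(truth, panel, params), truth = truth,
       sheet = sample_sheet(truth$sample_id, population_id, "BC1S1"))
}

#' Simulate a selfed progeny-test family
#'
#' Selfing a homozygous parent yields only homozygous progeny; selfing a
#' hemizygous parent yields progeny in the Mendelian 1:2:1
#' homozygous:hemizygous:null ratio.
#'
#' @param parent_genotype `"homozygous"` or `"hemizygous"`.
#' @param size number of progeny.
#' @param panel a [marker_panel()].
#' @param params an [amp_params()].
#' @param seed integer seed.
#' @param family_id family label.
#' @return list with `peaks`, `truth` (including `family_id`) and `sheet`
#'   (generation BC1S2, with the parental prediction filled in).
#' @export
simulate_family <- function(parent_genotype = c("hemizygous", "homozygous"),
                            size, panel = marker_panel(),
                            params = amp_params(), seed = 1L,
                            family_id = "FAM1") {
  parent_genotype <- match.arg(parent_genotype)
  if (size < 1) stop_validation("size must be at least 1")
  set.seed(seed)
  genotype <- if (parent_genotype == "homozygous") {
    rep("homozygous", size)
  } else {
    sample(GENOTYPES, size, replace = TRUE, prob = c(1, 2, 1) / 4)
  }
  truth <- data.frame(
    sample_id = sprintf("%s_%04d", family_id, seq_len(size)),
    genotype = genotype, population_id = family_id,
    family_id = family_id, stringsAsFactors = FALSE)
  list(peaks = simulate_cohort(truth, panel, params), truth = truth,
       sheet = sample_sheet(truth$sample_id, family_id, "BC1S2",
                            family_id = family_id,
                            parent_prediction = parent_genotype))
}

#' Simulate several segregating populations
#'
#' Convenience wrapper running [simulate_population()] once per
#' population with seeds derived deterministically from `seed`, and
#' row-binding the results.
#'
#' @param n_populations number of populations.
#' @param n individuals per population.
#' @inheritParams simulate_population
#' @return list with combined `peaks`, `truth` and `sheet`.
#' @export
simulate_experiment <- function(n_populations = 9L, n = 240L,
                                genotype_ratio = c(1, 2, 1),
                                panel = marker_panel(),
                                params = amp_params(), seed = 1L) {
  sims <- lapply(seq_len(n_populations), function(i)
    simulate_population(n, genotype_ratio, panel, params,
                        seed = seed + i - 1L,
                        population_id = sprintf("POP%02d", i)))
  peaks <- peak_table(do.call(rbind, lapply(sims, function(s)
    as.data.frame(s$peaks))), panel)
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  sheet <- do.call(rbind, lapply(sims, `[[`, "sheet"))
  class(sheet) <- c("sample_sheet", "data.frame")
  list(peaks = peaks, truth = truth, sheet = sheet)
}
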