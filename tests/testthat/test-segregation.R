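test_that("chi-square and G statistics match hand-evaluated worked cases", {
  t1 <- chisq_gof(c(57, 103, 68), c(1, 2, 1))
  expect_equal(t1$pearson_chi2, 121 / 114 + 121 / 57, tolerance = 1e-12)
  expect_equal(t1$pearson_chi2, 3.1842, tolerance = 1e-4)
  expect_equal(t1$g_statistic,
               2 * (103 * log(103 / 114) + 68 * log(68 / 57)),
               tolerance = 1e-12)
  expect_equal(t1$g_statistic, 3.0954, tolerance = 1e-4)
  expect_equal(t1$df, 2L)
  expect_true(t1$fits)

  t2 <- chisq_gof(c(160, 68), c(3, 1))
  expect_equal(t2$pearson_chi2, 2.8304, tolerance = 1e-4)
  expect_equal(t2$df, 1L)
  expect_true(t2$fits)

  t3 <- chisq_gof(c(75, 25), c(3, 1))
  expect_equal(t3$pearson_chi2, 0)
  expect_equal(t3$g_statistic, 0)
  expect_equal(t3$p_pearson, 1)
  expect_equal(t3$p_g, 1)
})

test_that("chisq_gof is invariant to ratio scaling and validates input", {
  a <- chisq_gof(c(160, 68), c(3, 1))
  b <- chisq_gof(c(160, 68), c(6, 2))
  expect_equal(b$pearson_chi2, a$pearson_chi2)
  expect_equal(b$g_statistic, a$g_statistic)
  expect_equal(b$expected, a$expected)

  expect_error(chisq_gof(c(-1, 10), c(1, 1)), class = "zygocall_validation_error")
  expect_error(chisq_gof(c(10, 10), c(1, 0)), class = "zygocall_validation_error")
  expect_error(chisq_gof(c(10, 10, 10), c(1, 1)), class = "zygocall_validation_error")
  expect_error(chisq_gof(c(0, 0), c(1, 1)), class = "zygocall_validation_error")
})

test_that("zero observed cells contribute 0 * log(0) = 0 to G", {
  t <- chisq_gof(c(24, 0, 0), c(1, 2, 1))
  expect_true(is.finite(t$g_statistic))
  expect_false(t$fits)
})

test_that("G and Pearson agree to first order under the null", {
  set.seed(314)
  draws <- stats::rmultinom(200, 240, c(1, 2, 1) / 4)
  rel <- apply(draws, 2, function(o) {
    t <- chisq_gof(o, c(1, 2, 1))
    abs(t$g_statistic - t$pearson_chi2) /
      max(t$g_statistic, t$pearson_chi2, 1e-9)
  })
  expect_lt(stats::median(rel), 0.05)
})

test_that("family confirmation applies the zygosity-specific rules", {
  f1 <- classify_family(c(22, 0, 0), "homozygous")
  expect_true(f1$confirmed)

  f2 <- classify_family(c(5, 12, 6), "hemizygous")
  expect_true(f2$confirmed)
  expect_equal(f2$test$pearson_chi2, 0.1304, tolerance = 1e-3)

  f3 <- classify_family(c(10, 9, 8), "homozygous")
  expect_false(f3$confirmed)

  # a homozygous family whose trait values are bimodal is not confirmed
  set.seed(8)
  vals <- c(rnorm(12, 406, 40), rnorm(12, 800, 60))
  f4 <- classify_family(c(24, 0, 0), "homozygous", values = vals)
  expect_false(f4$confirmed)

  expect_error(classify_family(c(5, 5, 5), "heterozygous"),
               class = "zygocall_validation_error")
  expect_error(classify_family(c(2, 2, 1), "hemizygous"),
               class = "zygocall_validation_error")   # below min progeny
})

test_that("confirmation_summary reproduces the progeny-test success rates", {
  cs <- confirmation_summary(cotton_progeny_families())
  hom <- cs[cs$prediction == "homozygous", ]
  hem <- cs[cs$prediction == "hemizygous", ]
  expect_equal(hom$n_families, 20L)
  expect_equal(hom$n_confirmed, 19L)
  expect_equal(hom$percent_confirmed, 95)
  expect_equal(hem$n_families, 21L)
  expect_equal(hem$n_confirmed, 21L)
  expect_equal(hem$percent_confirmed, 100)
  expect_equal(hom$mean_homozygous, 22.6, tolerance = 0.01)
  expect_equal(hem$mean_hemizygous, 11.6, tolerance = 0.05)
  expect_equal(hem$mean_null, 6.3, tolerance = 0.1)

  fails <- data.frame(family_id = paste0("F", 1:5), prediction = "hemizygous",
                      n_homozygous = 20, n_hemizygous = 1, n_null = 1)
  cs0 <- confirmation_summary(fails)
  expect_equal(cs0$percent_confirmed, 0)
})

test_that("population summaries conserve counts and catch unknown samples", {
  sim <- simulate_experiment(n_populations = 2, n = 80, seed = 3)
  rep <- run_pipeline(sim$peaks, sim$sheet)
  s <- rep$summary
  expect_equal(s$n_transgenic + s$n_null + s$n_missing, s$n_total)
  expect_equal(sum(s$n_total), nrow(sim$truth))
  tot <- attr(s, "totals")
  expect_equal(tot$n_transgenic, sum(s$n_transgenic))
  called <- !is.na(s$n_homozygous)
  expect_equal(s$n_homozygous[called] + s$n_hemizygous[called],
               vapply(s$population_id[called], function(p) {
                 cc <- rep$calls
                 sum(cc$population_id == p & cc$final_call %in%
                       c("homozygous", "hemizygous"), na.rm = TRUE)
               }, numeric(1), USE.NAMES = FALSE))

  heights <- build_trait_matrix(sim$peaks, "height")
  presence <- call_presence(heights, attr(sim$peaks, "panel"))
  short_sheet <- sim$sheet[-1, ]
  class(short_sheet) <- class(sim$sheet)
  expect_error(summarize_populations(presence, rep$calls, short_sheet),
               class = "zygocall_integrity_error")
})

test_that("bundled reference tables aggregate to the published-scale totals", {
  totals <- population_totals(cotton_segregation_counts())
  expect_equal(unname(totals),
               c(1514, 527, 119, 2160))

  means <- cluster_mean_summary(cotton_cluster_means())
  expect_equal(round(unname(means["homozygous_height"]), 1), 784.6)
  expect_equal(round(unname(means["hemizygous_height"]), 1), 406.1)
  expect_equal(round(unname(means["hemizygous_area"]), 1), 2822.1)
  expect_equal(round(unname(means["ccc"]), 2), 5.89)
  expect_true(all(cotton_cluster_means()$ccc >= 2))
})
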