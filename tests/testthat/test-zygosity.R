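test_that("presence calls follow the all-markers / reference-only rule", {
  m <- matrix_from_values(
    list("35S_S"  = c(800, NA,  NA,  700),
         "OCS_S"  = c(850, NA,  NA,  720),
         "NPTII-3" = c(640, NA,  NA,  NA),
         "GhUBC1" = c(400, 410, NA,  390)),
    samples = c("A", "B", "C", "D"))
  pc <- call_presence(m, default_panel)
  expect_equal(pc$status, c("transgenic",  # all four markers
                            "null",        # reference only
                            "missing",     # reference absent
                            "missing"))    # partial transgene amplification
})

test_that("find_pit locates a valley between two modes and rejects unimodal data", {
  set.seed(42)
  x <- c(rnorm(150, 406, 50), rnorm(75, 785, 80))
  split <- find_pit(x)
  expect_true(split$is_bimodal)
  expect_gt(split$pit_location, 500)
  expect_lt(split$pit_location, 700)
  expect_lt(split$mode_locations[1], split$pit_location)
  expect_gt(split$mode_locations[2], split$pit_location)
  expect_lte(split$pit_density, min(split$mode_densities))

  # unimodal control: a homozygous parent line shows one mode
  n_bimodal <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    if (find_pit(rnorm(125, 500, 60))$is_bimodal) n_bimodal <- n_bimodal + 1L
  }
  expect_lte(n_bimodal, 1L)
})

test_that("find_pit brackets the valley for near-point-mass clusters", {
  set.seed(7)
  x <- c(rnorm(15, 400, 1), rnorm(15, 800, 1))
  split <- find_pit(x, min_n = 20)
  expect_true(split$is_bimodal)
  expect_gt(split$pit_location, 400)
  expect_lt(split$pit_location, 800)
})

test_that("find_pit validates input size and variance", {
  expect_error(find_pit(rnorm(5)), class = "zygocall_validation_error")
  expect_error(find_pit(rep(5, 30)), class = "zygocall_degenerate_error")
})

test_that("split_by_pit assigns above-pit to AA and ties to AB", {
  set.seed(42)
  x <- c(rnorm(150, 406, 50), rnorm(75, 785, 80))
  split <- find_pit(x)
  split$pit_location <- 600
  expect_equal(split_by_pit(c(300, 900), split), c("AB", "AA"))
  expect_equal(split_by_pit(600, split), "AB")
  expect_equal(split_by_pit(c(700, 800), split), c("AA", "AA"))

  split$is_bimodal <- FALSE
  expect_error(split_by_pit(1, split), class = "zygocall_state_error")
})

test_that("kmeans_1d reproduces worked examples exactly", {
  km <- kmeans_1d(c(1, 2, 9, 10))
  expect_equal(unname(km$centroids), c(1.5, 9.5))
  expect_equal(km$within_ss, 1.0)
  expect_equal(km$assignments, c("AB", "AB", "AA", "AA"))

  km2 <- kmeans_1d(c(1, 2, 3, 10, 11, 12))
  expect_equal(unname(km2$centroids), c(2, 11))
  expect_equal(km2$within_ss, 4.0)
  expect_equal(km2$total_ss, 125.5)
  expect_equal(km2$r_squared, 1 - 4 / 125.5)
  expect_equal(unname(km2$n_per_cluster), c(3L, 3L))

  expect_error(kmeans_1d(c(5, 5, 5)), class = "zygocall_degenerate_error")
})

test_that("kmeans_1d matches the brute-force oracle and the Lloyd fixed point", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(4:120, 1)
    x <- switch(sample(3, 1),
                rnorm(n, 0, 1),
                c(rnorm(ceiling(n / 2), 0), rnorm(floor(n / 2), 4)),
                runif(n, 0, 10))
    if (length(unique(x)) < 2) next
    km <- kmeans_1d(x)
    oracle <- oracle_kmeans2(x)
    expect_equal(km$within_ss, oracle$wss, tolerance = 1e-10)
    # the exact optimum is a Lloyd fixed point: nearest-centroid
    # reassignment reproduces the same partition
    mid <- mean(km$centroids)
    expect_equal(km$assignments[is.finite(x)],
                 ifelse(x[is.finite(x)] > mid, "AA",
                        ifelse(x[is.finite(x)] < mid, "AB",
                               km$assignments[is.finite(x)])))
    # larger centroid is always the AA (homozygous) cluster
    expect_gt(km$centroids["AA"], km$centroids["AB"])
  }
})

test_that("deterministic Lloyd refinement is never better and agrees when clusters separate", {
  set.seed(123)
  for (i in 1:25) {
    x <- c(rnorm(60, 400, 55), rnorm(30, 800, 90))
    exact <- kmeans_1d(x, method = "exact")
    lloyd <- kmeans_1d(x, method = "lloyd")
    # the exhaustive search is globally optimal; Lloyd can only tie it
    expect_gte(lloyd$within_ss, exact$within_ss - 1e-9)
    # Lloyd's answer is a genuine fixed point of the update
    mid <- mean(lloyd$centroids)
    xs <- x[is.finite(x)]
    expect_equal(lloyd$assignments, ifelse(xs > mid, "AA", "AB"))
  }
  # with clean separation the two routes coincide
  set.seed(124)
  for (i in 1:10) {
    x <- c(rnorm(60, 400, 40), rnorm(30, 820, 50))
    exact <- kmeans_1d(x, method = "exact")
    lloyd <- kmeans_1d(x, method = "lloyd")
    expect_equal(lloyd$assignments, exact$assignments)
    expect_equal(lloyd$within_ss, exact$within_ss, tolerance = 1e-9)
  }
})

test_that("CCC honours the sign contract and flags well-separated clusters", {
  set.seed(5)
  x <- c(rnorm(85, 406, 50), rnorm(85, 785, 50))
  km <- kmeans_1d(x)

  null_r2 <- zygocall:::ccc_null_r2(km$n)
  km_null <- km; km_null$r_squared <- null_r2
  expect_equal(compute_ccc(km_null), 0)
  km_low <- km; km_low$r_squared <- null_r2 - 0.1
  expect_lt(compute_ccc(km_low), 0)
  km_high <- km; km_high$r_squared <- null_r2 + 0.1
  expect_gt(compute_ccc(km_high), 0)

  expect_gte(compute_ccc(km), 2)                  # real separation
  expect_warning(ccc_inf <- compute_ccc(kmeans_1d(c(1, 1, 2, 2))), "infinite")
  expect_identical(ccc_inf, Inf)

  # unimodal data must not look like two clusters
  set.seed(6)
  km_uni <- kmeans_1d(rnorm(125, 500, 60))
  expect_lt(compute_ccc(km_uni), 2)
})

test_that("tukey_kramer matches the closed form and the studentized range", {
  h <- tukey_kramer(c(1, 2, 3), c(11, 12, 13))
  expect_equal(h$q_statistic, 10 / sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(h$df, 4L)
  expect_lt(h$p_value, 0.001)
  expect_true(h$significant)
  # q = t * sqrt(2) identity vs the studentized-range distribution
  # (ptukey is itself numerical quadrature, hence the loose tolerance)
  expect_equal(h$p_value,
               stats::ptukey(h$q_statistic, 2, h$df, lower.tail = FALSE),
               tolerance = 0.05)

  h0 <- tukey_kramer(c(5, 6), c(5, 6))
  expect_equal(h0$q_statistic, 0)
  expect_false(h0$significant)

  hu <- tukey_kramer(c(1, 2), c(1, 2, 3, 4))
  msw <- (0.5 + 5) / 4
  expect_equal(hu$q_statistic,
               abs(1.5 - 2.5) / sqrt((msw / 2) * (1 / 2 + 1 / 4)))

  expect_error(tukey_kramer(c(1, 1), c(1, 1)),
               class = "zygocall_degenerate_error")
  expect_error(tukey_kramer(1, c(1, 2)), class = "zygocall_validation_error")
})

test_that("call_zygosity recovers simulated genotypes in a 1:2:1 population", {
  sim <- simulate_population(240, c(1, 2, 1), seed = 31)
  rep <- run_pipeline(sim$peaks, sim$sheet)
  calls <- rep$calls
  truth <- setNames(sim$truth$genotype, sim$truth$sample_id)
  tg <- calls$presence == "transgenic" & !is.na(calls$final_call)
  acc <- mean(calls$final_call[tg] == truth[calls$sample_id[tg]])
  expect_gte(acc, 0.95)
  d <- rep$diagnostics$POP1
  # homozygous cluster centroid always exceeds the hemizygous one
  expect_gt(d$kmeans$centroids["AA"], d$kmeans$centroids["AB"])
  expect_true(d$hsd$significant)
})

test_that("an all-homozygous line is rarely forced into two classes", {
  # selfed homozygous parent line: unimodal normalized heights; the pit
  # should almost never be declared and the two-cluster CCC should reject
  n_bimodal <- 0L
  n_ccc_ok <- 0L
  for (seed in 1:12) {
    sim <- simulate_population(125, c(1, 0, 0), seed = 200 + seed,
                               population_id = "E176")
    rep <- run_pipeline(sim$peaks, sim$sheet)
    d <- rep$diagnostics$E176
    if (is.null(d$pit) || d$pit$is_bimodal) n_bimodal <- n_bimodal + 1L
    if (isTRUE(d$ccc_ok)) n_ccc_ok <- n_ccc_ok + 1L
    if (!is.null(d$pit) && !d$pit$is_bimodal) {
      expect_true("not_bimodal" %in% d$flags)
      expect_true(all(is.na(rep$calls$pit_call)))
    }
  }
  expect_lte(n_bimodal, 2L)
  expect_lte(n_ccc_ok, 1L)
})

test_that("concordance counts agreements between the two classifiers", {
  sim <- simulate_population(240, c(1, 2, 1), seed = 7)
  rep <- run_pipeline(sim$peaks, sim$sheet)
  calls <- rep$calls
  cc <- concordance(calls)
  expect_equal(cc$n_agree + cc$n_disagree, cc$n_both)

  both <- which(!is.na(calls$pit_call) & !is.na(calls$kmeans_call))
  expect_gte(length(both), 10L)
  flipped <- calls
  i <- both[1]
  flipped$pit_call[i] <- setdiff(c("AA", "AB"), flipped$pit_call[i])
  cc2 <- concordance(flipped)
  expect_equal(cc2$n_disagree, cc$n_disagree + 1L)

  same <- calls
  same$pit_call <- same$kmeans_call
  expect_equal(concordance(same)$fraction_agree, 1.0)
})
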