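test_that("a peak table round-trips through TSV exactly", {
  recs <- tiny_records(heights = c(800.125, 820.5, 790.0625, 400.73))
  path <- write_tsv_fixture(data.frame(Sample = recs$sample_id,
                                       Marker = recs$marker,
                                       Size = recs$size_bp,
                                       Height = recs$height,
                                       Area = recs$area))
  tab <- read_peak_table(path, default_panel)
  expect_equal(nrow(tab), 4L)

  out <- tempfile(fileext = ".tsv")
  write_peak_table(tab, out)
  back <- read_peak_table(out, default_panel)
  expect_identical(as.data.frame(back), as.data.frame(tab))
})

test_that("duplicate (sample, marker) rows are an integrity error", {
  recs <- rbind(tiny_records(), tiny_records()[2, ])
  path <- write_tsv_fixture(data.frame(Sample = recs$sample_id,
                                       Marker = recs$marker, Size = recs$size_bp,
                                       Height = recs$height, Area = recs$area))
  expect_error(read_peak_table(path, default_panel),
               class = "zygocall_integrity_error")
})

test_that("rows with markers outside the panel are skipped with a warning", {
  recs <- tiny_records()
  extra <- data.frame(Sample = "S1", Marker = "ROX_std", Size = 100,
                      Height = 5000, Area = 20000)
  path <- write_tsv_fixture(rbind(
    data.frame(Sample = recs$sample_id, Marker = recs$marker,
               Size = recs$size_bp, Height = recs$height, Area = recs$area),
    extra))
  expect_warning(tab <- read_peak_table(path, default_panel), "ROX_std")
  expect_equal(nrow(tab), 4L)
  expect_false("ROX_std" %in% tab$marker)
})

test_that("malformed headers and invalid values are rejected", {
  bad <- write_tsv_fixture(data.frame(Sample = "S1", Probe = "OCS_S",
                                      Size = 142, Height = 1, Area = 1))
  expect_error(read_peak_table(bad, default_panel),
               class = "zygocall_format_error")
  expect_error(peak_table(transform(tiny_records(), height = -c(1, 2, 3, 4)),
                          default_panel),
               class = "zygocall_validation_error")
  expect_error(peak_table(transform(tiny_records(), size_bp = 0),
                          default_panel),
               class = "zygocall_validation_error")
})

test_that("sample sheets validate generations, duplicates and BC1S2 families", {
  path <- write_tsv_fixture(data.frame(
    Sample = sprintf("C%03d", 1:240), Population = "Coker312",
    Generation = "BC1S1", Family = "", ParentPrediction = ""))
  sheet <- read_sample_sheet(path)
  expect_equal(nrow(sheet), 240L)
  expect_true(all(sheet$generation == "BC1S1"))
  expect_true(all(is.na(sheet$family_id)))
  expect_true(all(is.na(sheet$parent_prediction)))

  expect_warning(
    s2 <- sample_sheet("a", "P", generation = "F7"),
    "other")
  expect_equal(s2$generation, "other")

  expect_error(sample_sheet(c("a", "a"), "P"),
               class = "zygocall_integrity_error")
  expect_error(sample_sheet("a", "P", generation = "BC1S2"),
               class = "zygocall_validation_error")
})

test_that("trait matrices flag absent markers and never invent values", {
  recs <- rbind(tiny_records("S1"),
                tiny_records("S2")[-3, ])           # S2 lacks NPTII-3
  recs <- rbind(recs, tiny_records("S3", heights = c(0, 750, 760, 390)))
  tab <- peak_table(recs, default_panel)
  m <- build_trait_matrix(tab, "height")
  expect_equal(sum(is.finite(m["S1", ])), 4L)
  expect_true(is.na(m["S2", "NPTII-3"]))
  expect_true(is.na(m["S3", "35S_S"]))             # zero height == absent
  expect_equal(sum(is.finite(m)), sum(tab$height > 0))
  expect_error(build_trait_matrix(tab, "slope"),
               class = "zygocall_validation_error")
})

test_that("zygosity calls round-trip through write_calls", {
  sim <- simulate_population(60, c(1, 2, 1), seed = 11)
  rep <- run_pipeline(sim$peaks, sim$sheet)
  path <- tempfile(fileext = ".tsv")
  write_calls(rep$calls, path)
  back <- read_calls(path)
  orig <- as.data.frame(rep$calls)
  orig <- orig[order(orig$sample_id), names(back)]
  rownames(orig) <- NULL
  expect_equal(back, structure(orig, class = class(back)))

  empty <- rep$calls[0, ]
  class(empty) <- class(rep$calls)
  expect_error(write_calls(empty, path), class = "zygocall_validation_error")
})
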