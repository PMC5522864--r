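# shared builders and independent oracles for the test suite

default_panel <- marker_panel()

# a minimal one-sample peak table covering the default panel
tiny_records <- function(sample_id = "S1",
                         heights = c(800, 820, 790, 400),
                         areas = heights * 6) {
  data.frame(sample_id = sample_id,
             marker = c("35S_S", "OCS_S", "NPTII-3", "GhUBC1"),
             size_bp = c(181, 142, 216, 123),
             height = heights, area = areas,
             stringsAsFactors = FALSE)
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent brute-force 2-means oracle: evaluates every contiguous split
# of the sorted values with plain mean()/sum() arithmetic
oracle_kmeans2 <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- list(wss = Inf)
  for (i in 1:(n - 1)) {
    lo <- xs[1:i]; hi <- xs[(i + 1):n]
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (wss < best$wss)
      best <- list(wss = wss, cut = i, centroids = c(mean(lo), mean(hi)))
  }
  best
}

# trait matrix straight from values, bypassing the peak-table reader
matrix_from_values <- function(values_by_marker, samples) {
  m <- do.call(cbind, values_by_marker)
  rownames(m) <- samples
  structure(m, trait = "height", panel = default_panel,
            class = c("trait_matrix", class(m)))
}
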