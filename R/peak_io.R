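#' Construct a peak table in memory
#'
#' A peak table holds one row per (sample, marker) with the three traits a
#' fragment analyzer reports for an amplicon: size in base pairs, peak
#' height (RFU) and peak area. A missing row and a zero-height row both mean
#' "no product detected"; zero-height rows are dropped on construction so
#' absence has a single representation.
#'
#' @param records data.frame with columns `sample_id`, `marker`, `size_bp`,
#'   `height`, `area`.
#' @param panel a [marker_panel()]; every record's marker must belong to it.
#' @return A `peak_table`: the records data.frame with the panel attached as
#'   an attribute.
#' @export
peak_table <- function(records, panel) {
  assert_panel(panel)
  required <- c("sample_id", "marker", "size_bp", "height", "area")
  if (!is.data.frame(records) || !all(required %in% names(records)))
    stop_format("records must have columns sample_id, marker, size_bp, height, area")
  records <- records[required]
  records$sample_id <- as.character(records$sample_id)
  records$marker <- as.character(records$marker)
  for (col in c("size_bp", "height", "area")) records[[col]] <- as.numeric(records[[col]])

  bad <- !records$marker %in% panel_markers(panel)
  if (any(bad))
    stop_validation(sprintf("markers not in panel: %s",
                            paste(unique(records$marker[bad]), collapse = ", ")))
  if (any(records$height < 0, na.rm = TRUE) || any(records$area < 0, na.rm = TRUE))
    stop_validation("peak height and area must be non-negative")
  detected <- records$height > 0
  if (any(detected & !(records$size_bp > 0)))
    stop_validation("size_bp must be positive for detected peaks")
  # absence canonicalisation: zero-height rows are equivalent to missing rows
  records <- records[detected, , drop = FALSE]
  key <- paste(records$sample_id, records$marker, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop_integrity(sprintf("duplicate (sample, marker) row: %s",
                           gsub("\r", " / ", dup, fixed = TRUE)))
  }
  rownames(records) <- NULL
  structure(records, panel = panel, class = c("peak_table", "data.frame"))
}

#' Read a tab-delimited peak table
#'
#' Reads a "Genotypes Table"-style export: strict TSV with header columns
#' Sample, Marker, Size, Height, Area (case-insensitive, any order). Rows
#' whose marker is not in the panel (e.g. size-standard peaks) are skipped
#' with a warning; duplicate (sample, marker) rows are an integrity error.
#'
#' @param source path to a TSV file or a connection.
#' @inheritParams peak_table
#' @return A `peak_table`.
#' @export
read_peak_table <- function(source, panel) {
  assert_panel(panel)
  raw <- utils::read.delim(source, check.names = FALSE,
                           colClasses = "character", strip.white = TRUE)
  idx <- vapply(c("Sample", "Marker", "Size", "Height", "Area"),
                function(nm) match_column(names(raw), nm), integer(1))
  if (anyNA(idx))
    stop_format(sprintf(
      "peak table header must contain Sample, Marker, Size, Height, Area (missing: %s)",
      paste(names(idx)[is.na(idx)], collapse = ", ")))
  df <- data.frame(sample_id = raw[[idx["Sample"]]],
                   marker = raw[[idx["Marker"]]],
                   size_bp = suppressWarnings(as.numeric(raw[[idx["Size"]]])),
                   height = suppressWarnings(as.numeric(raw[[idx["Height"]]])),
                   area = suppressWarnings(as.numeric(raw[[idx["Area"]]])),
                   stringsAsFactors = FALSE)
  if (anyNA(df$height) || anyNA(df$area))
    stop_format("non-numeric Height or Area value in peak table")
  foreign <- !df$marker %in% panel_markers(panel)
  if (any(foreign)) {
    warning(sprintf("skipping %d row(s) with markers outside the panel: %s",
                    sum(foreign),
                    paste(unique(df$marker[foreign]), collapse = ", ")),
            call. = FALSE)
    df <- df[!foreign, , drop = FALSE]
  }
  peak_table(df, panel)
}

#' Write a peak table to TSV
#'
#' Numeric values are written at full precision so a write/read cycle
#' reproduces the table exactly.
#'
#' @param table a `peak_table`.
#' @param dest output path or connection.
#' @export
write_peak_table <- function(table, dest) {
  if (!inherits(table, "peak_table")) stop_validation("table must be a peak_table")
  out <- data.frame(Sample = table$sample_id, Marker = table$marker,
                    Size = format_full(table$size_bp),
                    Height = format_full(table$height),
                    Area = format_full(table$area))
  tryCatch(
    utils::write.table(out, dest, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop_io(conditionMessage(e)))
  invisible(NULL)
}

GENERATIONS <- c("parent", "F1", "BC1S1", "BC1S2", "other")

#' Construct a sample sheet
#'
#' @param sample_id,population_id character vectors (recycled lengths must
#'   match).
#' @param generation one of `"parent"`, `"F1"`, `"BC1S1"`, `"BC1S2"`,
#'   `"other"` per sample.
#' @param family_id optional per-sample family label; required for BC1S2
#'   samples (progeny-test families).
#' @param parent_prediction optional predicted zygosity
#'   (`"homozygous"`/`"hemizygous"`) of the selfed parent, for BC1S2
#'   families.
#' @return A `sample_sheet` data.frame.
#' @export
sample_sheet <- function(sample_id, population_id, generation = "other",
                         family_id = NA_character_,
                         parent_prediction = NA_character_) {
  df <- data.frame(sample_id = as.character(sample_id),
                   population_id = as.character(population_id),
                   generation = as.character(generation),
                   family_id = as.character(family_id),
                   parent_prediction = as.character(parent_prediction),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    stop_integrity(sprintf("duplicate sample id(s): %s",
                           paste(unique(df$sample_id[duplicated(df$sample_id)]),
                                 collapse = ", ")))
  unknown <- !df$generation %in% GENERATIONS
  if (any(unknown)) {
    warning(sprintf("unknown generation value(s) %s mapped to \"other\"",
                    paste(unique(df$generation[unknown]), collapse = ", ")),
            call. = FALSE)
    df$generation[unknown] <- "other"
  }
  need_family <- df$generation == "BC1S2" & (is.na(df$family_id) | df$family_id == "")
  if (any(need_family))
    stop_validation("family_id is required for BC1S2 samples")
  bad_pred <- !is.na(df$parent_prediction) & df$parent_prediction != "" &
    !df$parent_prediction %in% c("homozygous", "hemizygous")
  if (any(bad_pred))
    stop_validation("parent_prediction must be homozygous or hemizygous when set")
  df$family_id[df$family_id == ""] <- NA_character_
  df$parent_prediction[df$parent_prediction == ""] <- NA_character_
  structure(df, class = c("sample_sheet", "data.frame"))
}

#' Read a tab-delimited sample sheet
#'
#' Expected header: Sample, Population, Generation, and optionally Family
#' and ParentPrediction (case-insensitive).
#'
#' @param source path to a TSV file or a connection.
#' @return A `sample_sheet` data.frame.
#' @export
read_sample_sheet <- function(source) {
  raw <- utils::read.delim(source, check.names = FALSE,
                           colClasses = "character", strip.white = TRUE)
  idx <- vapply(c("Sample", "Population", "Generation"),
                function(nm) match_column(names(raw), nm), integer(1))
  if (anyNA(idx))
    stop_format("sample sheet header must contain Sample, Population, Generation")
  fam <- match_column(names(raw), "Family")
  pred <- match_column(names(raw), "ParentPrediction")
  sample_sheet(
    sample_id = raw[[idx["Sample"]]],
    population_id = raw[[idx["Population"]]],
    generation = raw[[idx["Generation"]]],
    family_id = if (is.na(fam)) NA_character_ else raw[[fam]],
    parent_prediction = if (is.na(pred)) NA_character_ else raw[[pred]])
}

#' Write a sample sheet to TSV
#'
#' @param sheet a `sample_sheet`.
#' @param dest output path or connection.
#' @export
write_sample_sheet <- function(sheet, dest) {
  out <- data.frame(Sample = sheet$sample_id, Population = sheet$population_id,
                    Generation = sheet$generation,
                    Family = ifelse(is.na(sheet$family_id), "", sheet$family_id),
                    ParentPrediction = ifelse(is.na(sheet$parent_prediction), "",
                                              sheet$parent_prediction))
  tryCatch(
    utils::write.table(out, dest, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop_io(conditionMessage(e)))
  invisible(NULL)
}

#' Assemble a per-sample trait matrix
#'
#' Pivots a peak table to a samples x markers matrix of one trait. Markers
#' with no detected product for a sample are `NA` ("absent"), never zero:
#' presence calling downstream distinguishes absence from a small peak.
#'
#' @param table a `peak_table`.
#' @param trait `"height"`, `"area"` or `"size"`.
#' @return A numeric matrix (class `trait_matrix`) with samples as rows and
#'   panel markers as columns, the trait name and panel attached as
#'   attributes.
#' @export
build_trait_matrix <- function(table, trait = c("height", "area", "size")) {
  if (!inherits(table, "peak_table")) stop_validation("table must be a peak_table")
  if (!is.character(trait) || !all(trait %in% c("height", "area", "size")))
    stop_validation(sprintf("unknown trait \"%s\"", paste(trait, collapse = ",")))
  trait <- match.arg(trait)
  panel <- attr(table, "panel")
  col <- switch(trait, height = "height", area = "area", size = "size_bp")
  samples <- sort(unique(table$sample_id))
  markers <- panel_markers(panel)
  m <- matrix(NA_real_, nrow = length(samples), ncol = length(markers),
              dimnames = list(samples, markers))
  m[cbind(match(table$sample_id, samples), match(table$marker, markers))] <-
    table[[col]]
  structure(m, trait = trait, panel = panel,
            class = c("trait_matrix", class(m)))
}

#' Write a zygosity call set to TSV
#'
#' Columns: Sample, Population, PresenceCall, PitCall, KMeansCall,
#' FinalCall, NormalizedHeight, NormalizedArea; rows sorted by sample id so
#' output is deterministic.
#'
#' @param calls a `zygosity_calls` data.frame from [call_zygosity()].
#' @param dest output path or connection.
#' @export
write_calls <- function(calls, dest) {
  if (!inherits(calls, "zygosity_calls"))
    stop_validation("calls must be a zygosity_calls object")
  if (nrow(calls) == 0L) stop_validation("call set is empty")
  calls <- calls[order(calls$sample_id), , drop = FALSE]
  blank <- function(x) ifelse(is.na(x), "", as.character(x))
  out <- data.frame(Sample = calls$sample_id,
                    Population = calls$population_id,
                    PresenceCall = calls$presence,
                    PitCall = blank(calls$pit_call),
                    KMeansCall = blank(calls$kmeans_call),
                    FinalCall = blank(calls$final_call),
                    NormalizedHeight = format_full(calls$normalized_height),
                    NormalizedArea = format_full(calls$normalized_area))
  tryCatch(
    utils::write.table(out, dest, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop_io(conditionMessage(e)))
  invisible(NULL)
}

#' Read a zygosity call set written by [write_calls()]
#'
#' @param source path to the TSV file.
#' @return A `zygosity_calls` data.frame.
#' @export
read_calls <- function(source) {
  raw <- utils::read.delim(source, check.names = FALSE,
                           colClasses = "character", strip.white = TRUE)
  need <- c("Sample", "Population", "PresenceCall", "PitCall", "KMeansCall",
            "FinalCall", "NormalizedHeight", "NormalizedArea")
  idx <- vapply(need, function(nm) match_column(names(raw), nm), integer(1))
  if (anyNA(idx)) stop_format("calls file header is missing required columns")
  unblank <- function(x) { x[x == ""] <- NA_character_; x }
  df <- data.frame(sample_id = raw[[idx["Sample"]]],
                   population_id = raw[[idx["Population"]]],
                   presence = raw[[idx["PresenceCall"]]],
                   pit_call = unblank(raw[[idx["PitCall"]]]),
                   kmeans_call = unblank(raw[[idx["KMeansCall"]]]),
                   final_call = unblank(raw[[idx["FinalCall"]]]),
                   normalized_height = suppressWarnings(as.numeric(raw[[idx["NormalizedHeight"]]])),
                   normalized_area = suppressWarnings(as.numeric(raw[[idx["NormalizedArea"]]])),
                   stringsAsFactors = FALSE)
  df$concordant <- ifelse(is.na(df$pit_call) | is.na(df$kmeans_call), NA,
                          df$pit_call == df$kmeans_call)
  structure(df, class = c("zygosity_calls", "data.frame"))
}
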