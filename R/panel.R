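#' Define a marker panel
#'
#' A panel is the set of PCR markers scored for every sample: one or more
#' transgene-specific markers (amplifying conserved construct elements such
#' as the 35S promoter, OCS terminator and NPTII resistance gene) plus a
#' single-copy native reference gene used for normalization and as an
#' internal PCR control.
#'
#' @param transgene_markers character vector of transgene marker names.
#' @param reference_marker single reference marker name; must not appear in
#'   `transgene_markers`.
#' @param expected_size_bp optional named numeric vector of expected amplicon
#'   sizes (base pairs) per marker; names must be panel markers.
#' @return An object of class `marker_panel`.
#' @examples
#' marker_panel()
#' marker_panel(c("35S_S", "OCS_S"), "GhUBC1")
#' @export
marker_panel <- function(transgene_markers = c("35S_S", "OCS_S", "NPTII-3"),
                         reference_marker = "GhUBC1",
                         expected_size_bp = NULL) {
  if (!is.character(transgene_markers) || length(transgene_markers) < 1L)
    stop_validation("at least one transgene marker is required")
  if (!is.character(reference_marker) || length(reference_marker) != 1L)
    stop_validation("reference_marker must be a single marker name")
  all_markers <- c(transgene_markers, reference_marker)
  if (anyDuplicated(all_markers))
    stop_validation("marker names must be unique and the reference marker must not be a transgene marker")
  if (!is.null(expected_size_bp)) {
    if (is.null(names(expected_size_bp)) ||
        !all(names(expected_size_bp) %in% all_markers))
      stop_validation("expected_size_bp must be named with panel markers")
    if (any(!is.finite(expected_size_bp)) || any(expected_size_bp <= 0))
      stop_validation("expected_size_bp values must be positive")
  }
  structure(
    list(transgene_markers = transgene_markers,
         reference_marker = reference_marker,
         expected_size_bp = expected_size_bp),
    class = "marker_panel"
  )
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel\n")
  cat("  transgene markers:", paste(x$transgene_markers, collapse = ", "), "\n")
  cat("  reference marker: ", x$reference_marker, "\n")
  invisible(x)
}

# all marker names, reference last
panel_markers <- function(panel) c(panel$transgene_markers, panel$reference_marker)

assert_panel <- function(panel) {
  if (!inherits(panel, "marker_panel"))
    stop_validation("panel must be a marker_panel object")
  invisible(panel)
}
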