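#' Measure every cell of a study
#'
#' Runs the 3D computed vector measures and (optionally) the automated 2D
#' reference measures over all cells, applying the study rule that the
#' central compartment slices are selected once per specimen on its unloaded
#' intact cell and reused for the other five cells.
#'
#' @param cells A named list of `measurement_cell`s (e.g. from
#'   [read_study()] or [phantom_specimen()]) or a study directory path.
#' @param measures Which measure families to compute: any of `"3d"`, `"2d"`.
#' @param fill Passed to [axis_surface_intersection()].
#' @return A validated measure table (tibble), one row per cell x measure.
#' @export
measure_study <- function(cells, measures = c("3d", "2d"), fill = TRUE) {
  if (is.character(cells) && length(cells) == 1L) cells <- read_study(cells)
  measures <- match.arg(measures, several.ok = TRUE)
  specs <- vapply(cells, function(c) c$landmarks$specimen_id, character(1))
  rows <- list()
  for (sid in unique(specs)) {
    sc <- cells[specs == sid]
    slice_idx <- NULL
    if ("2d" %in% measures) {
      base <- Filter(
        function(c) c$landmarks$condition == "intact" && c$landmarks$configuration == "d0",
        sc
      )
      if (!length(base)) {
        rlang::abort(sprintf(
          "Specimen %s has no unloaded intact cell to fix the compartment slices on.", sid
        ))
      }
      slice_idx <- c(
        medial = select_central_slice(base[[1]], "medial"),
        lateral = select_central_slice(base[[1]], "lateral")
      )
    }
    for (cell in sc) {
      if ("3d" %in% measures) {
        rows[[length(rows) + 1L]] <- compute_cell_measures(cell, fill = fill)
      }
      if ("2d" %in% measures) {
        rows[[length(rows) + 1L]] <- compute_reference_measures(cell, slice_idx)
      }
    }
  }
  validate_measure_table(dplyr::bind_rows(rows))
}
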