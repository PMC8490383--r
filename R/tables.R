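#' Validate a measure table
#'
#' A measure table is a tibble with one row per specimen x condition x
#' configuration x measure, holding the measured value in mm. Vector
#' magnitudes (`vector_ASI`, `vector_FT`) must be non-negative; signed
#' components and 2D measures may be negative.
#'
#' @param table A data frame with columns `specimen_id, condition,
#'   configuration, measure, value`.
#' @return The table as a tibble, invisibly validated.
#' @export
validate_measure_table <- function(table) {
  need <- c("specimen_id", "condition", "configuration", "measure", "value")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    rlang::abort(sprintf(
      "Measure table misses column(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  table <- tibble::as_tibble(table)
  table$condition <- normalize_condition(table$condition)
  table$configuration <- normalize_configuration(table$configuration)
  dup <- duplicated(table[, c("specimen_id", "condition", "configuration", "measure")])
  if (any(dup)) {
    d <- table[dup, ][1, ]
    rlang::abort(sprintf(
      "Duplicate measure-table row for (%s, %s, %s, %s).",
      d$specimen_id, d$condition, d$configuration, d$measure
    ))
  }
  mags <- table$measure %in% c("vector_ASI", "vector_FT")
  if (any(mags & table$value < 0)) {
    rlang::abort("Vector magnitudes (vector_ASI / vector_FT) must be >= 0.")
  }
  table
}

#' Write a measure (or delta) table to CSV
#'
#' Fixed column order `specimen_id, condition, configuration, measure, value`
#' (or `delta`); re-reading with [read_measure_table()] round-trips exactly.
#'
#' @param table A valid measure or delta table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measure_table <- function(table, path) {
  value_col <- if ("delta" %in% names(table)) "delta" else "value"
  if (value_col == "value") table <- validate_measure_table(table)
  cols <- c("specimen_id", "condition", "configuration", "measure", value_col)
  utils::write.csv(as.data.frame(table[, cols]), path, row.names = FALSE)
  invisible(path)
}

#' Read a measure (or delta) table from CSV
#'
#' @param path CSV written by [write_measure_table()].
#' @return A validated tibble.
#' @export
read_measure_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("delta" %in% names(df)) {
    tibble::as_tibble(df)
  } else {
    validate_measure_table(df)
  }
}

#' Differences of every measure against the unloaded intact baseline
#'
#' For each specimen and measure, subtracts the value of the unloaded intact
#' cell (d0, intact) from every cell:
#' `delta[condition, configuration] = value[condition, configuration] -
#' value[intact, d0]`. Baseline rows are exactly zero by construction.
#'
#' @param table A measure table containing the (intact, d0) baseline row for
#'   every specimen x measure.
#' @return A tibble like the input with `value` replaced by `delta` (mm).
#' @export
compute_deltas <- function(table) {
  table <- validate_measure_table(table)
  base <- table |>
    dplyr::filter(.data$condition == "intact", .data$configuration == "d0") |>
    dplyr::select("specimen_id", "measure", baseline = "value")
  missing <- table |>
    dplyr::distinct(.data$specimen_id, .data$measure) |>
    dplyr::anti_join(base, by = c("specimen_id", "measure"))
  if (nrow(missing) > 0L) {
    rlang::abort(sprintf(
      "Missing (intact, d0) baseline for specimen(s): %s.",
      paste(unique(missing$specimen_id), collapse = ", ")
    ))
  }
  table |>
    dplyr::left_join(base, by = c("specimen_id", "measure")) |>
    dplyr::mutate(delta = .data$value - .data$baseline) |>
    dplyr::select("specimen_id", "condition", "configuration", "measure", "delta")
}

#' Mean and SD of deltas per condition x configuration column
#'
#' Summarises a delta table across specimens the way laxity studies tabulate
#' their results: one row per measure, one mean +/- SD per condition x
#' configuration column. The (intact, d0) column is identically zero and is
#' dropped.
#'
#' @param deltas A delta table from [compute_deltas()].
#' @return A tibble with columns `measure, condition, configuration, n, mean,
#'   sd` (long form).
#' @export
summarize_deltas <- function(deltas) {
  deltas |>
    dplyr::filter(!(.data$condition == "intact" & .data$configuration == "d0")) |>
    dplyr::group_by(.data$measure, .data$condition, .data$configuration) |>
    dplyr::summarize(
      n = dplyr::n(),
      mean = mean(.data$delta),
      sd = if (dplyr::n() > 1L) stats::sd(.data$delta) else 0,
      .groups = "drop"
    )
}
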