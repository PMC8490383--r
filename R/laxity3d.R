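#' The eight 3D computed vector measures of one cell
#'
#' Computes two 3D Euclidean vectors per cell and their signed projections in
#' the anatomical frame (+x lateral, +y posterior, +z cranial):
#' * `vector_FT` (with `x_FT, y_FT, z_FT`): from the femoral trochlea apex
#'   (FT) to the tibial tuberosity centre (TT), both manually registered.
#' * `vector_ASI` (with `x_ASI, y_ASI, z_ASI`): from the femoral to the
#'   tibial axis-surface intersection, the fixpoints where each central bone
#'   axis exits the articular cortical surface of its own bone.
#'
#' All values are in millimetres after voxel-to-mm conversion on the
#' anisotropic grid.
#'
#' @param cell A `measurement_cell`.
#' @param fill Passed to [axis_surface_intersection()].
#' @return A tibble with 8 rows: `specimen_id, condition, configuration,
#'   measure, value`.
#' @export
compute_cell_measures <- function(cell, fill = TRUE) {
  stopifnot(inherits(cell, "measurement_cell"))
  lm <- cell$landmarks
  grid <- cell$grid
  mm <- lapply(
    stats::setNames(LANDMARK_NAMES, LANDMARK_NAMES),
    function(nm) voxel_to_mm(lm[[nm]], grid)
  )
  res <- withCallingHandlers(
    {
      femur_axis <- fit_bone_axis(mm$femur_proximal, mm$femur_distal, joint = "distal")
      tibia_axis <- fit_bone_axis(mm$tibia_proximal, mm$tibia_distal, joint = "proximal")
      fASI <- axis_surface_intersection(femur_axis, cell$masks$femur, grid, fill = fill)
      tASI <- axis_surface_intersection(tibia_axis, cell$masks$tibia, grid, fill = fill)
      list(
        ASI = euclidean_vector(
          to_anatomical_frame(fASI, grid),
          to_anatomical_frame(tASI, grid),
          name = "vector_ASI"
        ),
        FT = euclidean_vector(
          to_anatomical_frame(mm$FT, grid),
          to_anatomical_frame(mm$TT, grid),
          name = "vector_FT"
        )
      )
    },
    error = function(e) {
      rlang::abort(
        sprintf("While measuring cell %s: %s", cell_key(cell), conditionMessage(e)),
        parent = e
      )
    }
  )
  tibble::tibble(
    specimen_id = lm$specimen_id,
    condition = lm$condition,
    configuration = lm$configuration,
    measure = MEASURE_NAMES_3D,
    value = unname(c(
      res$ASI$magnitude, res$ASI$components,
      res$FT$magnitude, res$FT$components
    ))
  )
}

#' Intra-reader landmark registration reproducibility
#'
#' Compares two registration sessions of the same cells and reports the
#' Euclidean deviation (in mm, after voxel-to-mm conversion) of each landmark
#' between sessions, pooled across cells as mean +/- SD per landmark, plus a
#' per-specimen breakdown.
#'
#' @param session_a,session_b Tidy landmark tibbles (see
#'   [landmarks_to_tibble()]) or lists of `landmark_set`s covering the same
#'   specimen/condition/configuration cells.
#' @param grid The `image_grid` used for mm conversion.
#' @return A list of class `repro_report` with tibbles `per_landmark`
#'   (landmark, n, mean_mm, sd_mm) and `per_specimen`.
#' @export
landmark_reproducibility <- function(session_a, session_b, grid) {
  stopifnot(inherits(grid, "image_grid"))
  if (!is.data.frame(session_a)) session_a <- landmarks_to_tibble(session_a)
  if (!is.data.frame(session_b)) session_b <- landmarks_to_tibble(session_b)
  key <- c("specimen_id", "condition", "configuration", "landmark")
  a_keys <- do.call(paste, c(session_a[key], sep = "/"))
  b_keys <- do.call(paste, c(session_b[key], sep = "/"))
  unmatched <- c(setdiff(a_keys, b_keys), setdiff(b_keys, a_keys))
  if (length(unmatched)) {
    rlang::abort(sprintf(
      "Sessions do not cover the same cells; unmatched: %s.",
      paste(utils::head(unmatched, 5L), collapse = ", ")
    ))
  }
  sp <- grid_spacing(grid)
  joined <- dplyr::inner_join(
    session_a, session_b,
    by = key, suffix = c("_a", "_b")
  ) |>
    dplyr::mutate(
      deviation_mm = sqrt(
        ((.data$x_a - .data$x_b) * sp[1])^2 +
          ((.data$y_a - .data$y_b) * sp[2])^2 +
          ((.data$z_a - .data$z_b) * sp[3])^2
      )
    )
  per_landmark <- joined |>
    dplyr::group_by(.data$landmark) |>
    dplyr::summarize(
      n = dplyr::n(),
      mean_mm = mean(.data$deviation_mm),
      sd_mm = if (dplyr::n() > 1L) stats::sd(.data$deviation_mm) else 0,
      .groups = "drop"
    )
  per_specimen <- joined |>
    dplyr::group_by(.data$specimen_id, .data$landmark) |>
    dplyr::summarize(
      n = dplyr::n(),
      mean_mm = mean(.data$deviation_mm),
      sd_mm = if (dplyr::n() > 1L) stats::sd(.data$deviation_mm) else 0,
      .groups = "drop"
    )
  structure(
    list(per_landmark = per_landmark, per_specimen = per_specimen),
    class = "repro_report"
  )
}

#' @export
print.repro_report <- function(x, ...) {
  cat("<repro_report> landmark registration deviation between sessions\n")
  df <- as.data.frame(x$per_landmark)
  for (i in seq_len(nrow(df))) {
    cat(sprintf(
      "  %-15s %.2f +/- %.2f mm (n = %d)\n",
      df$landmark[i], df$mean_mm[i], df$sd_mm[i], df$n[i]
    ))
  }
  invisible(x)
}

#' Write a reproducibility report (CSV + text)
#'
#' @param report A `repro_report`.
#' @param path_csv CSV output path for the pooled per-landmark table.
#' @param path_txt Optional plain-text summary path.
#' @return `path_csv`, invisibly.
#' @export
write_repro_report <- function(report, path_csv, path_txt = NULL) {
  utils::write.csv(as.data.frame(report$per_landmark), path_csv, row.names = FALSE)
  if (!is.null(path_txt)) {
    lines <- c(
      "Landmark registration reproducibility (Euclidean deviation, mm)",
      sprintf(
        "  %-15s %.2f +/- %.2f (n = %d)",
        report$per_landmark$landmark,
        report$per_landmark$mean_mm,
        report$per_landmark$sd_mm,
        report$per_landmark$n
      )
    )
    writeLines(lines, path_txt)
  }
  invisible(path_csv)
}
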