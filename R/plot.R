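#' Mean +/- SD delta plot per condition x configuration
#'
#' Summarises a delta table across specimens and draws one panel per
#' measure: points at the mean delta against the unloaded intact baseline,
#' error bars at +/- 1 SD, cells along the x axis in study order.
#'
#' @param deltas A delta table from [compute_deltas()].
#' @param measures Optional subset of measures to plot.
#' @return A ggplot object.
#' @export
plot_deltas <- function(deltas, measures = NULL) {
  summ <- summarize_deltas(deltas)
  if (!is.null(measures)) summ <- summ[summ$measure %in% measures, ]
  summ$cell <- factor(
    paste(summ$condition, summ$configuration, sep = "/"),
    levels = c("intact/d1", "partial/d0", "partial/d1", "complete/d0", "complete/d1")
  )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$cell, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.25
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(
      x = "PCL condition / loading configuration",
      y = "Δ vs unloaded intact baseline (mm)"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' QC overlay of one compartment slice
#'
#' Raster overlay of the femur, tibia and meniscus masks on a sagittal
#' (constant-x) slice, in mm coordinates — a quick check that structures,
#' compartment selection, and anteroposterior orientation look right.
#'
#' @param cell A `measurement_cell`.
#' @param compartment `"medial"` or `"lateral"`.
#' @param slice_index Optional 0-based x index (default: the compartment's
#'   central slice).
#' @return A ggplot object.
#' @export
plot_slice_qc <- function(cell, compartment = c("medial", "lateral"),
                          slice_index = NULL) {
  compartment <- match.arg(compartment)
  if (is.null(slice_index)) slice_index <- select_central_slice(cell, compartment)
  sl <- compartment_slice(cell, compartment, slice_index)
  sp <- grid_spacing(cell$grid)
  df <- purrr::map_dfr(names(sl$masks), function(nm) {
    m <- sl$masks[[nm]]
    idx <- which(m, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    tibble::tibble(
      structure = nm,
      y = (idx[, 1] - 1L) * sp[2],
      z = (idx[, 2] - 1L) * sp[3]
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$z, fill = .data$structure)) +
    ggplot2::geom_tile(width = sp[2], height = sp[3], alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf(
        "%s, %s compartment, slice %d", cell_key(cell), compartment, sl$slice_index
      ),
      x = "anteroposterior y (mm, +posterior)", y = "craniocaudal z (mm)"
    ) +
    ggplot2::theme_minimal()
}
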