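#' Central sagittal slice of a femorotibial compartment
#'
#' Picks the constant-x plane at the mediolateral midpoint of the
#' compartment's tibial plateau extent. The plateau is the set of tibia
#' voxels within `plateau_depth` mm of the tibia's most cranial extent; the
#' plateau's mediolateral span is split at its midpoint into the medial and
#' lateral halves according to the knee side. For even spans the lower
#' median index is taken (fixed tie-break).
#'
#' In study use the slice is chosen once on the unloaded intact cell of each
#' specimen and reused for all six cells ([measure_study()] does this).
#'
#' @param cell A `measurement_cell`.
#' @param compartment `"medial"` or `"lateral"`.
#' @param plateau_depth Craniocaudal depth in mm defining the plateau region
#'   (default 15).
#' @return Integer 0-based x slice index (stored-volume orientation).
#' @export
select_central_slice <- function(cell, compartment = c("medial", "lateral"),
                                 plateau_depth = 15) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(cell, "measurement_cell"))
  grid <- cell$grid
  tib <- cell$masks$tibia != 0
  sp_z <- grid$slice_thickness + grid$slice_gap
  zs <- which(apply(tib, 3, any))
  z_max <- max(zs)
  z_lo <- z_max - ceiling(plateau_depth / sp_z)
  plateau <- tib[, , max(1L, z_lo):z_max, drop = FALSE]
  cols <- which(apply(plateau, 1, any)) # 1-based stored x indices
  if (!length(cols)) rlang::abort("Tibial plateau not found in the tibia mask.")
  lo <- min(cols)
  hi <- max(cols)
  mid <- (lo + hi) / 2
  # lateral is +x anatomically: high stored x for right knees, low for left
  lateral_high <- grid$side == "right"
  in_half <- if ((compartment == "lateral") == lateral_high) cols > mid else cols <= mid
  cols_c <- cols[in_half]
  if (!length(cols_c)) {
    rlang::abort(sprintf("The %s compartment is not represented in the tibia mask.", compartment))
  }
  as.integer(floor((min(cols_c) + max(cols_c)) / 2)) - 1L # back to 0-based
}

#' Extract the 2D masks of one compartment slice
#'
#' @param cell A `measurement_cell`.
#' @param compartment `"medial"` or `"lateral"`; selects which meniscus mask
#'   accompanies the slice.
#' @param slice_index 0-based x index, e.g. from [select_central_slice()].
#' @return A `compartment_slice` with 2D (y, z) masks `femur`, `tibia`,
#'   `meniscus`, the grid, compartment and slice index.
#' @export
compartment_slice <- function(cell, compartment = c("medial", "lateral"), slice_index) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(cell, "measurement_cell"))
  i <- as.integer(slice_index) + 1L
  if (i < 1L || i > cell$grid$shape[1]) {
    rlang::abort(sprintf("slice_index %d outside the grid.", slice_index))
  }
  meniscus_name <- paste0("meniscus_", compartment)
  sl <- list(
    femur = cell$masks$femur[i, , ] != 0,
    tibia = cell$masks$tibia[i, , ] != 0,
    meniscus = cell$masks[[meniscus_name]][i, , ] != 0
  )
  if (!any(sl$tibia)) {
    rlang::abort(sprintf("Tibia absent on slice %d.", slice_index))
  }
  structure(
    list(
      compartment = compartment, slice_index = as.integer(slice_index),
      masks = sl, grid = cell$grid
    ),
    class = "compartment_slice"
  )
}

# y index range (1-based) of the plateau region of the tibia on a slice
slice_plateau <- function(slice, plateau_depth = 15) {
  sp_z <- slice$grid$slice_thickness + slice$grid$slice_gap
  tib <- slice$masks$tibia
  zs <- which(apply(tib, 2, any))
  z_max <- max(zs)
  z_lo <- max(1L, z_max - ceiling(plateau_depth / sp_z))
  reg <- tib[, z_lo:z_max, drop = FALSE]
  which(apply(reg, 1, any))
}

# split the meniscus slice mask into anterior/posterior horn runs along y
slice_horns <- function(slice) {
  men <- slice$masks$meniscus
  occ <- apply(men, 1, any)
  if (!any(occ)) rlang::abort("Meniscus absent on this slice.")
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  runs
}

# centroid (fractional 1-based y index) of a horn's plateau-contact row:
# the horn's most caudal occupied z row
horn_base_y <- function(slice, run) {
  men <- slice$masks$meniscus[run$start:run$end, , drop = FALSE]
  z_base <- min(which(apply(men, 2, any)))
  ys <- which(men[, z_base]) + run$start - 1L
  mean(ys)
}

#' Posterior tibial translation on a compartment slice
#'
#' Signed anteroposterior distance between the most posterior point of the
#' tibial plateau and the most posterior point of the femoral condyle on the
#' slice; posterior displacement of the tibia relative to the femur is
#' positive.
#'
#' @param slice A `compartment_slice`.
#' @param plateau_depth,condyle_depth Craniocaudal depth (mm) of the plateau
#'   and condylar regions used to isolate the joint-level boundary points.
#' @return PTT in mm (`mPTT` or `lPTT` depending on the compartment).
#' @export
measure_ptt <- function(slice, plateau_depth = 15, condyle_depth = 20) {
  stopifnot(inherits(slice, "compartment_slice"))
  if (!any(slice$masks$femur)) rlang::abort("Femur absent on this slice.")
  dy <- slice$grid$in_plane_spacing[2]
  sp_z <- slice$grid$slice_thickness + slice$grid$slice_gap
  y_tib <- max(slice_plateau(slice, plateau_depth))
  fem <- slice$masks$femur
  zs <- which(apply(fem, 2, any))
  z_min <- min(zs)
  z_hi <- min(max(zs), z_min + ceiling(condyle_depth / sp_z))
  condyle <- fem[, z_min:z_hi, drop = FALSE]
  y_fem <- max(which(apply(condyle, 1, any)))
  (y_tib - y_fem) * dy
}

#' Meniscal horn displacement relative to the tibial plateau border
#'
#' Anteroposterior distance between the anterior (or posterior) border of the
#' tibial plateau and the base of the anterior (or posterior) meniscal horn
#' on the slice. The base is the centroid of the horn's plateau-contact row.
#' Posterior displacement of the horn relative to the plateau is positive.
#' Yields AD-MM/AD-LM for anterior horns, PD-MM/PD-LM for posterior horns.
#'
#' @param slice A `compartment_slice`.
#' @param horn `"anterior"` or `"posterior"`.
#' @param plateau_depth Passed to the plateau-region rule (mm).
#' @return Displacement in mm.
#' @export
measure_meniscus_displacement <- function(slice, horn = c("anterior", "posterior"),
                                          plateau_depth = 15) {
  horn <- match.arg(horn)
  stopifnot(inherits(slice, "compartment_slice"))
  runs <- slice_horns(slice)
  run <- if (horn == "anterior") runs[1, ] else runs[nrow(runs), ]
  dy <- slice$grid$in_plane_spacing[2]
  plat <- slice_plateau(slice, plateau_depth)
  y_border <- if (horn == "anterior") min(plat) else max(plat)
  (horn_base_y(slice, run) - y_border) * dy
}

#' Anterior-posterior interval between the inner meniscal horn edges
#'
#' Anteroposterior distance between the inner (facing) edges of the anterior
#' and posterior horns of the compartment's meniscus (API-MM / API-LM).
#'
#' @param slice A `compartment_slice`.
#' @return API in mm.
#' @export
measure_api <- function(slice) {
  stopifnot(inherits(slice, "compartment_slice"))
  runs <- slice_horns(slice)
  if (nrow(runs) < 2L) {
    rlang::abort("Fewer than two meniscal horn components on this slice; API undefined.")
  }
  dy <- slice$grid$in_plane_spacing[2]
  (runs$start[nrow(runs)] - runs$end[1]) * dy
}

#' The eight automated 2D reference measures of one cell
#'
#' Computes, per femorotibial compartment on its central sagittal slice:
#' meniscal horn displacements (AD-, PD-), the anterior-posterior interval
#' (API-), and the posterior tibial translation (mPTT / lPTT).
#'
#' @param cell A `measurement_cell`.
#' @param slice_indices Optional named integer vector
#'   `c(medial = ..., lateral = ...)` of 0-based slice indices fixed per
#'   specimen (study rule: chosen on the unloaded intact cell). If `NULL`,
#'   slices are selected on this cell.
#' @return A tibble with 8 rows: `specimen_id, condition, configuration,
#'   measure, value`.
#' @export
compute_reference_measures <- function(cell, slice_indices = NULL) {
  stopifnot(inherits(cell, "measurement_cell"))
  lm <- cell$landmarks
  rows <- purrr::map_dfr(c("medial", "lateral"), function(comp) {
    idx <- if (is.null(slice_indices)) {
      select_central_slice(cell, comp)
    } else {
      slice_indices[[comp]]
    }
    sl <- compartment_slice(cell, comp, idx)
    suffix <- if (comp == "medial") "MM" else "LM"
    ptt_name <- if (comp == "medial") "mPTT" else "lPTT"
    tibble::tibble(
      measure = c(
        paste0(c("AD-", "PD-", "API-"), suffix), ptt_name
      ),
      value = c(
        measure_meniscus_displacement(sl, "anterior"),
        measure_meniscus_displacement(sl, "posterior"),
        measure_api(sl),
        measure_ptt(sl)
      )
    )
  })
  tibble::tibble(
    specimen_id = lm$specimen_id,
    condition = lm$condition,
    configuration = lm$configuration,
    measure = rows$measure,
    value = rows$value
  )
}
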