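#' One measurement cell: label volumes plus landmarks
#'
#' A cell bundles the four binary structure masks (femur, tibia, medial and
#' lateral meniscus), the grid geometry, and the registered landmark set for
#' one specimen x PCL-condition x loading-configuration acquisition.
#'
#' @param masks Named list of 3D binary arrays for `femur`, `tibia`,
#'   `meniscus_medial`, `meniscus_lateral`, all with the grid's shape.
#' @param grid An `image_grid`.
#' @param landmarks A `landmark_set` registered on the same grid.
#' @param provenance Optional named list (file paths, checksums) carried
#'   along for logging.
#' @return A validated `measurement_cell`.
#' @export
measurement_cell <- function(masks, grid, landmarks, provenance = list()) {
  stopifnot(inherits(grid, "image_grid"), inherits(landmarks, "landmark_set"))
  missing <- setdiff(STRUCTURE_NAMES, names(masks))
  if (length(missing)) {
    rlang::abort(sprintf("Missing structure mask(s): %s.", paste(missing, collapse = ", ")))
  }
  for (nm in STRUCTURE_NAMES) {
    m <- masks[[nm]]
    if (!identical(dim(m), as.integer(grid$shape))) {
      rlang::abort(sprintf(
        "Mask '%s' has shape %s but the grid is %s.",
        nm, paste(dim(m), collapse = " x "), paste(grid$shape, collapse = " x ")
      ))
    }
  }
  for (nm in c("femur", "tibia")) {
    if (!any(masks[[nm]] != 0)) {
      rlang::abort(sprintf("Structure mask '%s' is empty.", nm))
    }
  }
  if (any(masks$femur != 0 & masks$tibia != 0)) {
    rlang::abort("Femur and tibia masks overlap: bone masks must be disjoint.")
  }
  validate_landmarks_in_grid(landmarks, grid)
  structure(
    list(masks = masks, grid = grid, landmarks = landmarks, provenance = provenance),
    class = "measurement_cell"
  )
}

#' @export
print.measurement_cell <- function(x, ...) {
  vox <- vapply(x$masks, function(m) sum(m != 0), numeric(1))
  cat(sprintf(
    "<measurement_cell> specimen %s, %s / %s (%s knee)\n",
    x$landmarks$specimen_id, x$landmarks$condition,
    x$landmarks$configuration, x$grid$side
  ))
  cat(sprintf(
    "  masks: %s\n",
    paste(sprintf("%s=%d vox", names(vox), vox), collapse = ", ")
  ))
  invisible(x)
}

cell_key <- function(cell) {
  lm <- cell$landmarks
  sprintf("%s/%s/%s", lm$specimen_id, lm$condition, lm$configuration)
}

#' Write a measurement cell to a directory
#'
#' Writes one NIfTI file per structure mask, a JSON landmark file, and a JSON
#' grid sidecar (the inter-slice gap and knee side have no NIfTI field). The
#' NIfTI pixdim carries the effective spacing (in-plane, in-plane,
#' thickness + gap).
#'
#' @param cell A `measurement_cell`.
#' @param dir Output directory (created if absent).
#' @param compress Write `.nii.gz` (default) rather than `.nii`.
#' @return `dir`, invisibly.
#' @export
write_cell <- function(cell, dir, compress = TRUE) {
  stopifnot(inherits(cell, "measurement_cell"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (compress) ".nii.gz" else ".nii"
  sp <- grid_spacing(cell$grid)
  for (nm in STRUCTURE_NAMES) {
    img <- RNifti::asNifti(
      array(as.integer(cell$masks[[nm]] != 0), dim = cell$grid$shape),
      pixdim = sp
    )
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ext)))
  }
  write_landmarks(cell$landmarks, file.path(dir, "landmarks.json"))
  jsonlite::write_json(
    list(
      schema_version = 1L,
      shape = cell$grid$shape,
      in_plane_spacing = cell$grid$in_plane_spacing,
      slice_thickness = cell$grid$slice_thickness,
      slice_gap = cell$grid$slice_gap,
      side = cell$grid$side
    ),
    file.path(dir, "grid.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

read_grid_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  image_grid(
    shape = obj$shape,
    in_plane_spacing = obj$in_plane_spacing,
    slice_thickness = obj$slice_thickness,
    slice_gap = obj$slice_gap,
    side = obj$side
  )
}

#' Read a measurement cell from a directory
#'
#' Expects the layout written by [write_cell()]: `<structure>.nii[.gz]` for
#' femur, tibia, meniscus_medial, meniscus_lateral; `landmarks.json` (or
#' `landmarks.csv`); `grid.json`. All invariants (shapes, non-empty disjoint
#' bones, in-bounds landmarks) are validated and violations reported with the
#' offending field named.
#'
#' @param dir Directory holding one cell.
#' @return A validated `measurement_cell`.
#' @export
read_cell <- function(dir) {
  grid_path <- file.path(dir, "grid.json")
  if (!file.exists(grid_path)) {
    rlang::abort(sprintf("No grid.json in '%s'.", dir))
  }
  grid <- read_grid_json(grid_path)
  masks <- list()
  for (nm in STRUCTURE_NAMES) {
    candidates <- file.path(dir, paste0(nm, c(".nii.gz", ".nii")))
    path <- candidates[file.exists(candidates)][1]
    if (is.na(path)) {
      rlang::abort(sprintf("Missing structure mask '%s' in '%s'.", nm, dir))
    }
    arr <- RNifti::readNifti(path)
    masks[[nm]] <- array(as.integer(arr != 0), dim = dim(arr))
  }
  lm_path <- file.path(dir, "landmarks.json")
  if (!file.exists(lm_path)) lm_path <- file.path(dir, "landmarks.csv")
  if (!file.exists(lm_path)) {
    rlang::abort(sprintf("No landmarks.json/.csv in '%s'.", dir))
  }
  landmarks <- read_landmarks(lm_path)
  measurement_cell(masks, grid, landmarks, provenance = list(dir = dir))
}
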