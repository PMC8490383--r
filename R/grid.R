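#' Voxel grid geometry of a sagittal MRI stack
#'
#' An `image_grid` captures everything needed to convert voxel indices of a
#' label volume into millimetres: the array shape, the in-plane pixel size,
#' the slice thickness, the inter-slice gap, and the knee side (left/right).
#' Array axes map onto anatomy as x = mediolateral, y = anteroposterior,
#' z = craniocaudal; the slice axis is z, so the effective spacing along z is
#' `slice_thickness + slice_gap`.
#'
#' Voxel indices are 0-based; world coordinates are millimetres with the
#' origin at voxel (0, 0, 0). Fractional indices are allowed (landmarks may
#' sit between voxel centres).
#'
#' @param shape Integer vector of length 3: voxels along x, y, z.
#' @param in_plane_spacing Numeric length-2 (or 1, recycled): mm per pixel
#'   along x and y. Default 0.6 mm, the study acquisition.
#' @param slice_thickness Slice thickness in mm (default 3.0).
#' @param slice_gap Inter-slice gap in mm (default 0.3).
#' @param side `"left"` or `"right"` knee.
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(c(120, 160, 56), side = "right")
#' voxel_to_mm(c(10, 10, 10), g) # 6, 6, 33
#' @export
image_grid <- function(shape,
                       in_plane_spacing = c(0.6, 0.6),
                       slice_thickness = 3.0,
                       slice_gap = 0.3,
                       side = c("right", "left")) {
  side <- match.arg(side)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L)) {
    rlang::abort("`shape` must be three positive integers (n_x, n_y, n_z).")
  }
  in_plane_spacing <- rep_len(as.numeric(in_plane_spacing), 2L)
  if (any(in_plane_spacing <= 0)) {
    rlang::abort("`in_plane_spacing` must be strictly positive.")
  }
  if (!is.numeric(slice_thickness) || slice_thickness <= 0) {
    rlang::abort("`slice_thickness` must be strictly positive.")
  }
  if (!is.numeric(slice_gap) || slice_gap < 0) {
    rlang::abort("`slice_gap` must be non-negative.")
  }
  structure(
    list(
      shape = shape,
      in_plane_spacing = in_plane_spacing,
      slice_thickness = as.numeric(slice_thickness),
      slice_gap = as.numeric(slice_gap),
      side = side,
      axis_labels = c(x = "mediolateral", y = "anteroposterior", z = "craniocaudal")
    ),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf(
    "<image_grid> %d x %d x %d voxels, %.3g x %.3g mm in-plane, %.3g + %.3g mm slices, %s knee\n",
    x$shape[1], x$shape[2], x$shape[3],
    x$in_plane_spacing[1], x$in_plane_spacing[2],
    x$slice_thickness, x$slice_gap, x$side
  ))
  invisible(x)
}

#' The default acquisition grid used throughout the package
#'
#' 0.6 x 0.6 mm in-plane, 3.0 mm slices with a 0.3 mm inter-slice gap
#' (effective 3.3 mm along z).
#'
#' @inheritParams image_grid
#' @return An `image_grid`.
#' @export
study_grid <- function(shape = c(126L, 160L, 56L), side = "right") {
  image_grid(shape, c(0.6, 0.6), 3.0, 0.3, side)
}

#' Per-axis voxel spacing in mm (x, y, effective z)
#' @param grid An `image_grid`.
#' @return Numeric length 3.
#' @export
grid_spacing <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  c(grid$in_plane_spacing, grid$slice_thickness + grid$slice_gap)
}

#' Physical extent of the grid in mm along each axis
#' @param grid An `image_grid`.
#' @return Numeric length 3.
#' @export
grid_extent <- function(grid) {
  grid$shape * grid_spacing(grid)
}

#' Convert voxel indices to millimetres
#'
#' In-plane axes scale by the pixel size; the slice axis (z) scales by
#' slice thickness plus inter-slice gap. Accepts a single point (length-3
#' vector) or an n x 3 matrix; fractional indices are allowed.
#'
#' @param index Voxel indices, 0-based.
#' @param grid An `image_grid`.
#' @return Millimetre coordinates, same shape as `index`.
#' @export
voxel_to_mm <- function(index, grid) {
  sp <- grid_spacing(grid)
  if (is.matrix(index)) {
    sweep(index, 2L, sp, `*`)
  } else {
    as.numeric(index) * sp
  }
}

#' Convert millimetre coordinates to (fractional) voxel indices
#' @inheritParams voxel_to_mm
#' @param point Millimetre coordinates (vector or n x 3 matrix).
#' @return Fractional 0-based voxel indices.
#' @export
mm_to_voxel <- function(point, grid) {
  sp <- grid_spacing(grid)
  if (is.matrix(point)) sweep(point, 2L, sp, `/`) else as.numeric(point) / sp
}

#' Map millimetre coordinates into the anatomical frame
#'
#' The anatomical frame has fixed sign conventions: +x lateral, +y posterior,
#' +z cranial. Volumes are stored with +x lateral for right knees; for left
#' knees the x component is mirrored about the grid extent so that +x is
#' lateral on both sides. y and z are unchanged. The mapping is an involution
#' for left knees and the identity for right knees.
#'
#' @param point Millimetre point (length-3 vector) or n x 3 matrix in
#'   stored-volume coordinates.
#' @param grid An `image_grid` carrying the knee side.
#' @return The point(s) in the anatomical frame, mm.
#' @export
to_anatomical_frame <- function(point, grid) {
  stopifnot(inherits(grid, "image_grid"))
  if (!grid$side %in% c("left", "right")) {
    rlang::abort("Grid side must be 'left' or 'right'.")
  }
  if (grid$side == "right") return(point)
  w <- grid_extent(grid)[1]
  if (is.matrix(point)) {
    point[, 1] <- w - point[, 1]
    point
  } else {
    c(w - point[1], point[2], point[3])
  }
}
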