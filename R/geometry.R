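#' Central bone axis through two shaft centre points
#'
#' The axis runs through the manually registered centres of the proximal and
#' distal shaft, oriented from the shaft toward the joint: for the femur the
#' joint-side point is the distal centre, for the tibia the proximal one.
#'
#' @param proximal,distal Millimetre points (length-3) on the shaft centre
#'   line.
#' @param joint Which end faces the joint: `"distal"` (femur) or
#'   `"proximal"` (tibia).
#' @return A `bone_axis` with fields `anchor` (the joint-side point) and
#'   `direction` (unit vector pointing toward the joint).
#' @examples
#' fit_bone_axis(c(0, 0, 10), c(0, 0, 0), joint = "distal")
#' @export
fit_bone_axis <- function(proximal, distal, joint = c("distal", "proximal")) {
  joint <- match.arg(joint)
  proximal <- as.numeric(proximal)
  distal <- as.numeric(distal)
  stopifnot(length(proximal) == 3L, length(distal) == 3L)
  d <- if (joint == "distal") distal - proximal else proximal - distal
  len <- sqrt(sum(d^2))
  if (len < 1e-12) {
    rlang::abort("Degenerate bone axis: proximal and distal shaft centres coincide.")
  }
  structure(
    list(
      anchor = if (joint == "distal") distal else proximal,
      direction = d / len
    ),
    class = "bone_axis"
  )
}

#' @export
print.bone_axis <- function(x, ...) {
  cat(sprintf(
    "<bone_axis> anchor (%.1f, %.1f, %.1f) mm, direction (%.3f, %.3f, %.3f)\n",
    x$anchor[1], x$anchor[2], x$anchor[3],
    x$direction[1], x$direction[2], x$direction[3]
  ))
  invisible(x)
}

# Nearest-sample membership test of mm points in a binary mask.
# Points outside the grid are outside the mask.
mask_contains <- function(points, mask, grid) {
  idx <- round(mm_to_voxel(points, grid))
  n <- dim(mask)
  ok <- idx[, 1] >= 0 & idx[, 1] < n[1] &
    idx[, 2] >= 0 & idx[, 2] < n[2] &
    idx[, 3] >= 0 & idx[, 3] < n[3]
  out <- logical(nrow(points))
  if (any(ok)) {
    lin <- 1L + idx[ok, 1] + n[1] * (idx[ok, 2] + n[2] * idx[ok, 3])
    out[ok] <- mask[lin] != 0
  }
  out
}

#' Fill internal cavities of a binary mask
#'
#' Applies a 2D hole fill to every slice along the z axis, so that a hollow
#' cortical shell becomes a solid bone region. Uses `EBImage::fillHull` when
#' available and falls back to a run-based scanline fill otherwise.
#'
#' @param mask 3D binary array.
#' @return The filled mask (integer 0/1 array of the same shape).
#' @export
fill_mask <- function(mask) {
  n <- dim(mask)
  out <- array(0L, n)
  has_ebimage <- requireNamespace("EBImage", quietly = TRUE)
  for (k in seq_len(n[3])) {
    sl <- mask[, , k] != 0
    if (!any(sl)) next
    if (has_ebimage) {
      out[, , k] <- as.integer(EBImage::fillHull(sl) != 0)
    } else {
      out[, , k] <- fill_slice_scanline(sl)
    }
  }
  out
}

# Flood-fill the background of a 2D slice from its border; holes are the
# non-mask pixels the flood never reaches.
fill_slice_scanline <- function(sl) {
  n <- dim(sl)
  reach <- matrix(FALSE, n[1], n[2])
  border <- which(!sl & (row(sl) %in% c(1L, n[1]) | col(sl) %in% c(1L, n[2])))
  reach[border] <- TRUE
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-n[1], ]
    grown[-n[1], ] <- grown[-n[1], ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -n[2]]
    grown[, -n[2]] <- grown[, -n[2]] | reach[, -1]
    grown <- grown & !sl
    if (identical(grown, reach)) break
    reach <- grown
  }
  matrix(as.integer(sl | !reach), n[1], n[2])
}

#' Intersection of a bone axis with the articular surface of a mask
#'
#' Marches along the axis (step = 1/4 of the smallest voxel spacing) from the
#' shaft toward the joint and returns the sub-voxel point where the line last
#' leaves the bone mask, i.e. the joint-side cortical exit. The sub-voxel
#' position interpolates linearly between the last inside and first outside
#' sample. If the line enters and leaves the mask in several disjoint runs,
#' the joint-side crossing is used and a warning is emitted.
#'
#' @param axis A `bone_axis` (direction pointing toward the joint).
#' @param mask 3D binary array of the bone.
#' @param grid The `image_grid` of the mask.
#' @param fill Fill internal cavities first (default `TRUE`), so hollow
#'   cortical shells behave like solid bone.
#' @param step Marching step in mm; default `min(grid_spacing(grid)) / 4`.
#' @return Millimetre point (stored-volume coordinates) on the articular
#'   surface.
#' @export
axis_surface_intersection <- function(axis, mask, grid,
                                      fill = TRUE,
                                      step = min(grid_spacing(grid)) / 4) {
  stopifnot(inherits(axis, "bone_axis"), inherits(grid, "image_grid"))
  if (fill) mask <- fill_mask(mask)
  ext <- grid_extent(grid)
  # march across the whole grid: t range from projecting the bounding box
  t_max <- sqrt(sum(ext^2))
  ts <- seq(-t_max, t_max, by = step)
  pts <- cbind(
    axis$anchor[1] + ts * axis$direction[1],
    axis$anchor[2] + ts * axis$direction[2],
    axis$anchor[3] + ts * axis$direction[3]
  )
  inside <- mask_contains(pts, mask, grid)
  if (!any(inside)) {
    rlang::abort("Axis never passes through the bone mask: no axis-surface intersection.")
  }
  # run starts: inside samples whose predecessor is outside
  starts <- which(inside & !c(FALSE, inside[-length(inside)]))
  if (length(starts) > 1L) {
    rlang::warn(sprintf(
      "Axis crosses the mask in %d disjoint runs; using the joint-side crossing.",
      length(starts)
    ))
  }
  last_in <- max(which(inside))
  if (last_in == length(ts)) {
    rlang::abort("Bone mask reaches the marching bound; cannot locate the cortical exit.")
  }
  t_star <- (ts[last_in] + ts[last_in + 1L]) / 2 # linear interp of a 1->0 step
  axis$anchor + t_star * axis$direction
}

#' 3D Euclidean vector between two landmark or fixpoint positions
#'
#' Components are head minus tail (`q - p`); by convention the tail is the
#' femoral point and the head the tibial point, so a posteriorly displaced
#' tibia increases the +y (posterior) component. The magnitude is the
#' Euclidean norm, hence always non-negative.
#'
#' @param p Tail point, mm (femoral landmark/fixpoint), anatomical frame.
#' @param q Head point, mm (tibial landmark/fixpoint), anatomical frame.
#' @param name Measure label, e.g. `"vector_FT"` or `"vector_ASI"`.
#' @return A `vector_measure` with fields `name`, `magnitude`, `components`.
#' @examples
#' euclidean_vector(c(0, 0, 0), c(3, 4, 0))$magnitude # 5
#' @export
euclidean_vector <- function(p, q, name = "vector") {
  p <- as.numeric(p)
  q <- as.numeric(q)
  stopifnot(length(p) == 3L, length(q) == 3L)
  comp <- q - p
  structure(
    list(
      name = name,
      magnitude = sqrt(sum(comp^2)),
      components = stats::setNames(comp, c("x", "y", "z"))
    ),
    class = "vector_measure"
  )
}

#' @export
print.vector_measure <- function(x, ...) {
  cat(sprintf(
    "<vector_measure> %s: |v| = %.2f mm, (x, y, z) = (%.2f, %.2f, %.2f) mm\n",
    x$name, x$magnitude, x$components[1], x$components[2], x$components[3]
  ))
  invisible(x)
}
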