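CONDITIONS_FOR_TEST <- c("intact", "partial", "complete")

# Helpers to build controlled phantom cells (no random draws unless asked):
# a cell with a prescribed rigid transform of the tibia + menisci, zero
# landmark jitter, and a chosen knee side.

make_cell <- function(translation = c(0, 0, 0),
                      rot_int_deg = 0, rot_flex_deg = 0,
                      side = "right",
                      condition = "intact", configuration = "d0",
                      specimen_id = "phantom-test",
                      grid_shape = c(126L, 160L, 56L)) {
  geom <- kneelax:::phantom_geometry()
  grid <- image_grid(grid_shape, c(0.6, 0.6), 3.0, 0.3, side)
  tf <- kneelax:::rigid_transform(translation, rot_int_deg, rot_flex_deg, geom$pivot)
  co <- kneelax:::voxel_coordinates(grid)
  masks <- c(
    list(femur = kneelax:::voxelize_femur(geom, grid, co)),
    kneelax:::voxelize_tibia_group(geom, grid, tf, co)
  )
  lm_anat <- geom$landmarks
  for (nm in c("TT", "tibia_proximal", "tibia_distal")) {
    lm_anat[[nm]] <- kneelax:::apply_transform(tf, lm_anat[[nm]])
  }
  sp <- grid_spacing(grid)
  w <- grid_extent(grid)[1]
  lm_vox <- lapply(lm_anat, function(p) {
    if (side == "left") p[1] <- w - p[1]
    p / sp
  })
  lm <- do.call(landmark_set, c(lm_vox, list(
    specimen_id = specimen_id, condition = condition, configuration = configuration
  )))
  measurement_cell(masks, grid, lm)
}

# independent brute-force oracle for the axis-surface intersection: a dense
# fixed-step scan along the line, nearest-voxel membership, last inside
# sample on the direction side
asi_oracle <- function(anchor, direction, mask, grid, fine_step = 0.02) {
  sp <- grid_spacing(grid)
  n <- dim(mask)
  t_max <- sqrt(sum((n * sp)^2))
  ts <- seq(-t_max, t_max, by = fine_step)
  inside <- vapply(ts, function(t) {
    p <- anchor + t * direction
    i <- round(p / sp)
    if (any(i < 0) || any(i >= n)) return(FALSE)
    mask[i[1] + 1L, i[2] + 1L, i[3] + 1L] != 0
  }, logical(1))
  if (!any(inside)) return(NULL)
  anchor + ts[max(which(inside))] * direction
}

measure_value <- function(table, ms, cond = NULL, conf = NULL) {
  sel <- table$measure == ms
  if (!is.null(cond)) sel <- sel & table$condition == cond
  if (!is.null(conf)) sel <- sel & table$configuration == conf
  col <- if ("delta" %in% names(table)) "delta" else "value"
  table[[col]][sel]
}
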