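#' Specification of a synthetic knee-phantom study
#'
#' Defines the population and kinematic parameters of a synthetic stress-MRI
#' study: stylized rigid femur and tibia plus two meniscal wedges voxelized
#' onto the anisotropic study grid, with a condition/configuration-dependent
#' rigid transform applied to the tibia and menisci and Gaussian
#' between-specimen variability. Defaults emulate the study design: 11
#' specimens (6 left, 5 right), three PCL conditions x two loading
#' configurations, loaded-configuration posterior translations whose medial
#' means rise with PCL deficiency and whose lateral excess arises from
#' internal tibial rotation about a medial pivot.
#'
#' The per-condition loaded (d1) defaults — medial posterior translation
#' 2.4 / 3.7 / 11.8 mm (SD 1.2 / 2.1 / 4.9) for intact / partial / complete
#' and internal rotation chosen so the lateral compartment translates about
#' 4.2 / 4.0 / 0.9 mm further — mirror the compartmental translation summary
#' statistics the measurement method is expected to resolve. Unloaded (d0)
#' cells of the partial/complete conditions receive small residual offsets
#' (SD 2 mm); the unloaded intact cell is the exact identity (it is the
#' baseline).
#'
#' @param n_specimens Number of specimens (default 11).
#' @param grid_shape Voxel grid shape (default `c(126, 160, 56)` at
#'   0.6 x 0.6 x (3.0 + 0.3) mm).
#' @param sides Character vector of knee sides per specimen; default
#'   alternates starting at left, giving 6 left / 5 right at n = 11.
#' @param loading Named list per condition with elements `ty_mean, ty_sd`
#'   (posterior translation at the medial pivot, mm) and `rot_mean, rot_sd`
#'   (internal rotation, degrees) for the loaded configuration.
#' @param residual_sd SD (mm) of the in-plane residual offsets of unloaded
#'   partial/complete cells.
#' @param jitter_sd SD (mm) of the Gaussian landmark registration jitter.
#' @param seed Base random seed; fixes the full dataset bit-for-bit.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(n_specimens = 11L,
                         grid_shape = c(126L, 160L, 56L),
                         sides = NULL,
                         loading = list(
                           intact = list(ty_mean = 2.4, ty_sd = 1.2, rot_mean = 7.5, rot_sd = 2),
                           partial = list(ty_mean = 3.7, ty_sd = 2.1, rot_mean = 7.2, rot_sd = 2),
                           complete = list(ty_mean = 11.8, ty_sd = 4.9, rot_mean = 1.6, rot_sd = 2)
                         ),
                         residual_sd = 2,
                         jitter_sd = 0.5,
                         seed = 1L) {
  n_specimens <- as.integer(n_specimens)
  stopifnot(n_specimens >= 1L)
  if (is.null(sides)) {
    sides <- rep(c("left", "right"), length.out = n_specimens)
  }
  sides <- rep_len(sides, n_specimens)
  stopifnot(all(sides %in% c("left", "right")))
  for (cond in CONDITIONS) {
    l <- loading[[cond]]
    if (is.null(l) || any(!c("ty_mean", "ty_sd", "rot_mean", "rot_sd") %in% names(l))) {
      rlang::abort(sprintf("`loading$%s` needs ty_mean, ty_sd, rot_mean, rot_sd.", cond))
    }
    if (l$ty_sd < 0 || l$rot_sd < 0) rlang::abort("Loading SDs must be >= 0.")
  }
  if (residual_sd < 0 || jitter_sd < 0) rlang::abort("SDs must be >= 0.")
  structure(
    list(
      n_specimens = n_specimens,
      grid_shape = as.integer(grid_shape),
      sides = sides,
      loading = loading,
      residual_sd = residual_sd,
      jitter_sd = jitter_sd,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d specimens (%d left / %d right), grid %s, jitter SD %.2g mm, seed %d\n",
    x$n_specimens, sum(x$sides == "left"), sum(x$sides == "right"),
    paste(x$grid_shape, collapse = "x"), x$jitter_sd, x$seed
  ))
  invisible(x)
}

# run code under a local seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

deg2rad <- function(d) d * pi / 180

# Stylized joint geometry of one specimen, in the anatomical frame (mm):
# +x lateral, +y posterior, +z cranial. The femur sits cranially and never
# moves; the tibia + menisci form the rigid group the transform acts on.
phantom_geometry <- function(offset = c(0, 0, 0), plateau_jitter = 0) {
  cx <- 36 + offset[1]
  cy <- 48 + offset[2]
  oz <- offset[3]
  plateau_a <- 30 + plateau_jitter # mediolateral semi-axis
  plateau_b <- 24 # anteroposterior semi-axis
  comp_dx <- 16 # compartment centre offset from midline
  g <- list(
    cx = cx, cy = cy,
    plateau = list(a = plateau_a, b = plateau_b, z0 = 76 + oz, z1 = 88 + oz),
    tibia_shaft = list(r = 14, z0 = 14 + oz, z1 = 76 + oz),
    boss = list(c = c(cx, cy - 16, 66 + oz), r = 8),
    meniscus = list(
      dx = comp_dx, r_in = 7.5, r_out = 13,
      z0 = 88 + oz, z1 = 94 + oz
    ),
    femur_shaft = list(r = 13, z0 = 122 + oz, z1 = 178 + oz),
    condyle_block = list(c = c(cx, cy + 2, 112 + oz), s = c(32, 24, 18)),
    condyle = list(dx = comp_dx, dy = 6, z = 109 + oz, r = 15),
    trochlea = list(c = c(cx, cy - 18, 116 + oz), s = c(10, 8, 14))
  )
  g$landmarks <- list(
    FT = c(cx, cy - 18, g$trochlea$c[3] + g$trochlea$s[3]),
    TT = c(cx, g$boss$c[2] - g$boss$r, g$boss$c[3]),
    femur_proximal = c(cx, cy, 172 + oz),
    femur_distal = c(cx, cy, 126 + oz),
    tibia_proximal = c(cx, cy, 70 + oz),
    tibia_distal = c(cx, cy, 16 + oz)
  )
  g$pivot <- c(cx - comp_dx, cy, 82 + oz) # medial compartment centre
  # analytic reference material points (pre-transform) used for truth
  lat_edge_y <- cy + g$plateau$b * sqrt(1 - (comp_dx / g$plateau$a)^2)
  g$ref_points <- list(
    tASI = c(cx, cy, g$plateau$z1),
    lateral_edge = c(cx + comp_dx, lat_edge_y, 82 + oz),
    medial_edge = c(cx - comp_dx, lat_edge_y, 82 + oz)
  )
  g
}

rigid_transform <- function(translation = c(0, 0, 0),
                            rot_int_deg = 0, rot_flex_deg = 0,
                            pivot = c(0, 0, 0)) {
  a <- deg2rad(rot_int_deg)
  b <- deg2rad(rot_flex_deg)
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(b), sin(b), 0, -sin(b), cos(b)), 3, 3)
  list(
    R = Rz %*% Rx,
    t = as.numeric(translation),
    pivot = as.numeric(pivot),
    rot_int_deg = rot_int_deg,
    rot_flex_deg = rot_flex_deg
  )
}

apply_transform <- function(tf, p) {
  as.numeric(tf$R %*% (p - tf$pivot) + tf$pivot + tf$t)
}

#' Ground-truth displacement of a material point under a cell's transform
#'
#' @param truth One cell's truth record (from [phantom_specimen()] or read
#'   from a study's `truth.json`), holding `translation`,
#'   `rotation_internal_deg`, `rotation_flexion_deg`, `pivot`.
#' @param point Material point in the anatomical frame (mm), pre-transform.
#' @return Displacement vector (mm): transformed minus original position.
#' @export
phantom_truth_displacement <- function(truth, point) {
  tf <- rigid_transform(
    unlist(truth$translation),
    truth$rotation_internal_deg,
    truth$rotation_flexion_deg,
    unlist(truth$pivot)
  )
  apply_transform(tf, as.numeric(point)) - as.numeric(point)
}

# anatomical-frame sample coordinates of every voxel (stored index order);
# for left knees stored x runs opposite to anatomical x (mirror about the
# grid extent), matching to_anatomical_frame()
voxel_coordinates <- function(grid) {
  sp <- grid_spacing(grid)
  n <- grid$shape
  xa <- (0:(n[1] - 1L)) * sp[1]
  if (grid$side == "left") xa <- grid_extent(grid)[1] - xa
  list(
    x = rep(xa, times = n[2] * n[3]),
    y = rep(rep((0:(n[2] - 1L)) * sp[2], each = n[1]), times = n[3]),
    z = rep((0:(n[3] - 1L)) * sp[3], each = n[1] * n[2])
  )
}

voxelize_femur <- function(geom, grid, co = voxel_coordinates(grid)) {
  X <- co$x; Y <- co$y; Z <- co$z
  s <- geom$femur_shaft
  mask <- (X - geom$cx)^2 + (Y - geom$cy)^2 <= s$r^2 & Z >= s$z0 & Z <= s$z1
  cb <- geom$condyle_block
  mask <- mask | ((X - cb$c[1])^2 / cb$s[1]^2 +
    (Y - cb$c[2])^2 / cb$s[2]^2 +
    (Z - cb$c[3])^2 / cb$s[3]^2 <= 1)
  cd <- geom$condyle
  for (sgn in c(-1, 1)) {
    mask <- mask | ((X - (geom$cx + sgn * cd$dx))^2 +
      (Y - (geom$cy + cd$dy))^2 +
      (Z - cd$z)^2 <= cd$r^2)
  }
  tr <- geom$trochlea
  mask <- mask | ((X - tr$c[1])^2 / tr$s[1]^2 +
    (Y - tr$c[2])^2 / tr$s[2]^2 +
    (Z - tr$c[3])^2 / tr$s[3]^2 <= 1)
  array(as.integer(mask), dim = grid$shape)
}

voxelize_tibia_group <- function(geom, grid, tf, co = voxel_coordinates(grid)) {
  # inverse transform: q = R^T (p - pivot - t) + pivot, then test the
  # untransformed primitives at q
  Rt <- t(tf$R)
  ux <- co$x - tf$pivot[1] - tf$t[1]
  uy <- co$y - tf$pivot[2] - tf$t[2]
  uz <- co$z - tf$pivot[3] - tf$t[3]
  X <- Rt[1, 1] * ux + Rt[1, 2] * uy + Rt[1, 3] * uz + tf$pivot[1]
  Y <- Rt[2, 1] * ux + Rt[2, 2] * uy + Rt[2, 3] * uz + tf$pivot[2]
  Z <- Rt[3, 1] * ux + Rt[3, 2] * uy + Rt[3, 3] * uz + tf$pivot[3]
  pl <- geom$plateau
  tib <- ((X - geom$cx)^2 / pl$a^2 + (Y - geom$cy)^2 / pl$b^2 <= 1) &
    Z >= pl$z0 & Z <= pl$z1
  sh <- geom$tibia_shaft
  tib <- tib | ((X - geom$cx)^2 + (Y - geom$cy)^2 <= sh$r^2 & Z >= sh$z0 & Z <= sh$z1)
  bo <- geom$boss
  tib <- tib | ((X - bo$c[1])^2 + (Y - bo$c[2])^2 + (Z - bo$c[3])^2 <= bo$r^2)
  men <- list()
  for (comp in c("medial", "lateral")) {
    sgn <- if (comp == "medial") -1 else 1
    mc_x <- geom$cx + sgn * geom$meniscus$dx
    r2 <- (X - mc_x)^2 + (Y - geom$cy)^2
    m <- r2 >= geom$meniscus$r_in^2 & r2 <= geom$meniscus$r_out^2 &
      Z > geom$meniscus$z0 & Z <= geom$meniscus$z1
    men[[paste0("meniscus_", comp)]] <- array(as.integer(m), dim = grid$shape)
  }
  c(list(tibia = array(as.integer(tib), dim = grid$shape)), men)
}

draw_cell_transform <- function(spec, geom, condition, configuration) {
  if (configuration == "d0") {
    if (condition == "intact") {
      return(rigid_transform(pivot = geom$pivot))
    }
    rigid_transform(
      translation = c(
        stats::rnorm(1, 0, spec$residual_sd),
        stats::rnorm(1, 0, spec$residual_sd),
        stats::rnorm(1, 0, spec$residual_sd / 2)
      ),
      rot_int_deg = stats::rnorm(1, 0, 1),
      rot_flex_deg = stats::rnorm(1, 0, 0.5),
      pivot = geom$pivot
    )
  } else {
    l <- spec$loading[[condition]]
    rigid_transform(
      translation = c(
        stats::rnorm(1, 0, 1.5),
        stats::rnorm(1, l$ty_mean, l$ty_sd),
        stats::rnorm(1, 0, 1)
      ),
      rot_int_deg = stats::rnorm(1, l$rot_mean, l$rot_sd),
      rot_flex_deg = stats::rnorm(1, 0, 1),
      pivot = geom$pivot
    )
  }
}

transform_in_bounds <- function(tf, geom, grid) {
  # extreme material points of the tibia group must stay >= 1 voxel inside
  pl <- geom$plateau
  pts <- rbind(
    c(geom$cx - pl$a, geom$cy, pl$z1), c(geom$cx + pl$a, geom$cy, pl$z1),
    c(geom$cx, geom$cy - pl$b, pl$z1), c(geom$cx, geom$cy + pl$b, pl$z1),
    c(geom$cx, geom$cy, geom$tibia_shaft$z0),
    geom$landmarks$TT
  )
  moved <- t(apply(pts, 1, function(p) apply_transform(tf, p)))
  sp <- grid_spacing(grid)
  lo <- sp
  hi <- grid_extent(grid) - sp
  all(sweep(moved, 2, lo, `>=`) & sweep(moved, 2, hi, `<=`))
}

#' Generate one synthetic specimen (six measurement cells + ground truth)
#'
#' Builds the specimen's stylized joint geometry with Gaussian
#' between-specimen variability, then for every condition x configuration
#' cell draws a rigid transform of the tibia + menisci from the condition's
#' response distribution, voxelizes all structures onto the grid, and emits
#' landmarks as the analytic positions plus registration jitter. The
#' transform of the unloaded intact cell is the exact identity. Transforms
#' that would push the tibia outside the grid are redrawn (error after 10
#' attempts).
#'
#' Determinism: the full specimen derives from `spec$seed + specimen_index`,
#' so regeneration is bit-identical; restricting `cells` does not change the
#' draws of the remaining cells.
#'
#' @param spec A `phantom_spec`.
#' @param specimen_index Specimen number (1-based).
#' @param cells Optional character vector of `"condition/configuration"`
#'   keys (e.g. `"complete/d1"`) to voxelize; default all six. Truth records
#'   are always produced for all six.
#' @return A list with `cells` (named list of `measurement_cell`), `truth`
#'   (named list of per-cell transform records plus `ref_points`), `grid`.
#' @export
phantom_specimen <- function(spec, specimen_index, cells = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  stopifnot(specimen_index >= 1L, specimen_index <= spec$n_specimens)
  side <- spec$sides[specimen_index]
  grid <- image_grid(spec$grid_shape, c(0.6, 0.6), 3.0, 0.3, side)
  specimen_id <- sprintf("specimen-%02d", specimen_index)
  with_local_seed(spec$seed + 1000L * as.integer(specimen_index), {
    # specimen-level variability is truncated at +/- 2 SD: the acquisition
    # adapts the field of view to the anatomy, so the joint always sits
    # inside the grid (and the identity baseline cell needs no redraw)
    trunc2 <- function(n, sd) pmin(pmax(stats::rnorm(n, 0, sd), -2 * sd), 2 * sd)
    geom <- phantom_geometry(
      offset = c(trunc2(2, 1.5), trunc2(1, 2)),
      plateau_jitter = trunc2(1, 1)
    )
    all_keys <- as.vector(t(outer(CONDITIONS, CONFIGURATIONS, paste, sep = "/")))
    tfs <- list()
    for (key in all_keys) {
      parts <- strsplit(key, "/")[[1]]
      for (attempt in 1:10) {
        tf <- draw_cell_transform(spec, geom, parts[1], parts[2])
        if (transform_in_bounds(tf, geom, grid)) break
        if (attempt == 10) {
          rlang::abort(sprintf(
            "Could not draw an in-bounds transform for %s %s after 10 attempts.",
            specimen_id, key
          ))
        }
      }
      tfs[[key]] <- tf
    }
    jitter <- matrix(
      stats::rnorm(length(all_keys) * length(LANDMARK_NAMES) * 3, 0, spec$jitter_sd),
      ncol = 3
    )
    wanted <- if (is.null(cells)) all_keys else cells
    bad <- setdiff(wanted, all_keys)
    if (length(bad)) {
      rlang::abort(sprintf("Unknown cell key(s): %s.", paste(bad, collapse = ", ")))
    }
    femur_mask <- NULL
    if (length(wanted)) {
      co <- voxel_coordinates(grid)
      femur_mask <- voxelize_femur(geom, grid, co)
    }
    out_cells <- list()
    truth <- list()
    sp <- grid_spacing(grid)
    w <- grid_extent(grid)[1]
    jrow <- 0L
    for (key in all_keys) {
      parts <- strsplit(key, "/")[[1]]
      tf <- tfs[[key]]
      # analytic landmark positions: femoral ones static, tibial ones moved
      lm_anat <- geom$landmarks
      for (nm in c("TT", "tibia_proximal", "tibia_distal")) {
        lm_anat[[nm]] <- apply_transform(tf, lm_anat[[nm]])
      }
      lm_vox <- list()
      for (nm in LANDMARK_NAMES) {
        jrow <- jrow + 1L
        p <- lm_anat[[nm]]
        if (side == "left") p[1] <- w - p[1]
        lm_vox[[nm]] <- p / sp + jitter[jrow, ] / sp
      }
      truth[[key]] <- list(
        specimen_id = specimen_id,
        condition = parts[1],
        configuration = parts[2],
        side = side,
        translation = tf$t,
        rotation_internal_deg = tf$rot_int_deg,
        rotation_flexion_deg = tf$rot_flex_deg,
        pivot = tf$pivot,
        landmarks_anatomical = lm_anat
      )
      if (!key %in% wanted) next
      masks <- c(
        list(femur = femur_mask),
        voxelize_tibia_group(geom, grid, tf, co)
      )
      lm_set <- do.call(landmark_set, c(lm_vox, list(
        specimen_id = specimen_id,
        condition = parts[1],
        configuration = parts[2]
      )))
      out_cells[[key]] <- measurement_cell(masks, grid, lm_set)
    }
    list(
      cells = out_cells,
      truth = truth,
      ref_points = geom$ref_points,
      grid = grid,
      specimen_id = specimen_id
    )
  })
}

#' Generate and write a full synthetic study to disk
#'
#' Writes the directory tree `specimen/condition/configuration` with NIfTI
#' masks, landmark JSON and grid sidecars per cell, a `truth.json` manifest
#' of every applied transform, and a `README.txt` with the generation
#' parameters.
#'
#' @param spec A `phantom_spec` (its `seed` fixes the dataset bit-for-bit).
#' @param dir Output directory.
#' @return Invisibly, a tibble manifest with one row per written cell.
#' @export
phantom_study <- function(spec, dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  truth_all <- list()
  for (i in seq_len(spec$n_specimens)) {
    sp_i <- phantom_specimen(spec, i)
    for (key in names(sp_i$cells)) {
      cell <- sp_i$cells[[key]]
      cdir <- file.path(dir, sp_i$specimen_id, dirname(key), basename(key))
      write_cell(cell, cdir)
      manifest[[length(manifest) + 1L]] <- tibble::tibble(
        specimen_id = sp_i$specimen_id,
        condition = cell$landmarks$condition,
        configuration = cell$landmarks$configuration,
        side = cell$grid$side,
        dir = cdir
      )
    }
    truth_all[[sp_i$specimen_id]] <- c(
      sp_i$truth,
      list(ref_points = sp_i$ref_points)
    )
  }
  jsonlite::write_json(
    truth_all, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  writeLines(
    c(
      "Synthetic stress-MRI knee phantom study",
      sprintf("specimens: %d (%d left / %d right)", spec$n_specimens,
              sum(spec$sides == "left"), sum(spec$sides == "right")),
      sprintf("grid: %s voxels at 0.6 x 0.6 x (3.0 + 0.3) mm",
              paste(spec$grid_shape, collapse = " x ")),
      sprintf("landmark jitter SD: %g mm", spec$jitter_sd),
      sprintf("unloaded residual SD (partial/complete): %g mm", spec$residual_sd),
      "loaded-configuration response distributions (medial translation mm, internal rotation deg):",
      vapply(CONDITIONS, function(cond) {
        l <- spec$loading[[cond]]
        sprintf("  %-9s ty %g +/- %g, rot %g +/- %g",
                cond, l$ty_mean, l$ty_sd, l$rot_mean, l$rot_sd)
      }, character(1)),
      sprintf("seed: %d", spec$seed)
    ),
    file.path(dir, "README.txt")
  )
  invisible(dplyr::bind_rows(manifest))
}

#' Read every cell of a study directory
#'
#' @param dir Study root as written by [phantom_study()].
#' @return Named list of `measurement_cell`s keyed
#'   `specimen/condition/configuration`.
#' @export
read_study <- function(dir) {
  grids <- list.files(dir, pattern = "^grid\\.json$", recursive = TRUE, full.names = TRUE)
  if (!length(grids)) rlang::abort(sprintf("No cells found under '%s'.", dir))
  cells <- list()
  for (g in sort(grids)) {
    cdir <- dirname(g)
    cell <- read_cell(cdir)
    cells[[cell_key(cell)]] <- cell
  }
  cells
}
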