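#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
NULL

LANDMARK_NAMES <- c(
  "FT", "TT",
  "femur_proximal", "femur_distal",
  "tibia_proximal", "tibia_distal"
)

STRUCTURE_NAMES <- c("femur", "tibia", "meniscus_medial", "meniscus_lateral")

MEASURE_NAMES_3D <- c(
  "vector_ASI", "x_ASI", "y_ASI", "z_ASI",
  "vector_FT", "x_FT", "y_FT", "z_FT"
)

MEASURE_NAMES_2D <- c(
  "AD-MM", "PD-MM", "API-MM", "mPTT",
  "AD-LM", "PD-LM", "API-LM", "lPTT"
)

CONDITIONS <- c("intact", "partial", "complete")
CONFIGURATIONS <- c("d0", "d1")

normalize_condition <- function(x) {
  x <- as.character(x)
  if (!all(x %in% CONDITIONS)) {
    rlang::abort(sprintf(
      "Unknown PCL condition '%s' (expected %s).",
      paste(setdiff(x, CONDITIONS), collapse = ", "),
      paste(CONDITIONS, collapse = "/")
    ))
  }
  x
}

normalize_configuration <- function(x) {
  x <- as.character(x)
  x[x %in% c("δ0", "delta0")] <- "d0"
  x[x %in% c("δ1", "delta1")] <- "d1"
  if (!all(x %in% CONFIGURATIONS)) {
    rlang::abort(sprintf(
      "Unknown loading configuration '%s' (expected d0/d1).",
      paste(setdiff(x, CONFIGURATIONS), collapse = ", ")
    ))
  }
  x
}

#' Registered anatomic landmarks for one measurement cell
#'
#' Holds the six manually registered landmark coordinates of one specimen x
#' PCL-condition x loading-configuration cell, in 0-based (fractional) voxel
#' indices: the femoral trochlea apex (FT), the tibial tuberosity centre (TT),
#' and the proximal/distal shaft centres of femur and tibia that define the
#' central bone axes.
#'
#' @param FT,TT,femur_proximal,femur_distal,tibia_proximal,tibia_distal
#'   Length-3 numeric voxel-index points.
#' @param specimen_id Specimen identifier.
#' @param condition PCL condition: `"intact"`, `"partial"`, `"complete"`.
#' @param configuration Loading configuration: `"d0"` (unloaded) or `"d1"`
#'   (loaded, 147 N).
#' @return A `landmark_set`.
#' @export
landmark_set <- function(FT, TT, femur_proximal, femur_distal,
                         tibia_proximal, tibia_distal,
                         specimen_id, condition, configuration) {
  pts <- list(
    FT = FT, TT = TT,
    femur_proximal = femur_proximal, femur_distal = femur_distal,
    tibia_proximal = tibia_proximal, tibia_distal = tibia_distal
  )
  for (nm in names(pts)) {
    p <- as.numeric(pts[[nm]])
    if (length(p) != 3L || any(!is.finite(p))) {
      rlang::abort(sprintf("Landmark '%s' must be a finite length-3 point.", nm))
    }
    pts[[nm]] <- p
  }
  if (isTRUE(all.equal(pts$femur_proximal, pts$femur_distal))) {
    rlang::abort("femur_proximal and femur_distal coincide: femoral axis undefinable.")
  }
  if (isTRUE(all.equal(pts$tibia_proximal, pts$tibia_distal))) {
    rlang::abort("tibia_proximal and tibia_distal coincide: tibial axis undefinable.")
  }
  structure(
    c(pts, list(
      specimen_id = as.character(specimen_id),
      condition = normalize_condition(condition),
      configuration = normalize_configuration(configuration)
    )),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf(
    "<landmark_set> specimen %s, %s / %s\n",
    x$specimen_id, x$condition, x$configuration
  ))
  for (nm in LANDMARK_NAMES) {
    cat(sprintf("  %-15s (%.2f, %.2f, %.2f)\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  }
  invisible(x)
}

validate_landmarks_in_grid <- function(landmarks, grid) {
  for (nm in LANDMARK_NAMES) {
    p <- landmarks[[nm]]
    if (any(p < 0) || any(p > grid$shape - 1L)) {
      rlang::abort(sprintf(
        "Landmark '%s' at (%.2f, %.2f, %.2f) lies outside the grid bounds %s.",
        nm, p[1], p[2], p[3], paste(grid$shape, collapse = " x ")
      ))
    }
  }
  invisible(landmarks)
}

#' Write a landmark set as versioned JSON
#'
#' Coordinates are stored as 0-based voxel indices under a `schema_version`
#' field so files remain interpretable across releases.
#'
#' @param landmarks A `landmark_set`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  obj <- list(
    schema_version = 1L,
    indexing = "0-based voxel",
    specimen_id = landmarks$specimen_id,
    condition = landmarks$condition,
    configuration = landmarks$configuration,
    landmarks = lapply(
      stats::setNames(LANDMARK_NAMES, LANDMARK_NAMES),
      function(nm) landmarks[[nm]]
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a landmark set from JSON (primary) or CSV (alternate dialect)
#'
#' The CSV dialect has columns `specimen_id, condition, configuration,
#' landmark, x, y, z`, one row per landmark; all rows must share the same
#' cell key.
#'
#' @param path Path to a `.json` or `.csv` landmark file.
#' @return A `landmark_set`.
#' @export
read_landmarks <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    missing <- setdiff(LANDMARK_NAMES, names(obj$landmarks))
    if (length(missing)) {
      rlang::abort(sprintf("Landmark file misses: %s.", paste(missing, collapse = ", ")))
    }
    args <- lapply(obj$landmarks[LANDMARK_NAMES], as.numeric)
    do.call(landmark_set, c(args, list(
      specimen_id = obj$specimen_id,
      condition = obj$condition,
      configuration = obj$configuration
    )))
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("specimen_id", "condition", "configuration", "landmark", "x", "y", "z")
    if (!all(need %in% names(df))) {
      rlang::abort(sprintf(
        "Landmark CSV must have columns: %s.", paste(need, collapse = ", ")
      ))
    }
    if (nrow(unique(df[c("specimen_id", "condition", "configuration")])) != 1L) {
      rlang::abort("Landmark CSV mixes several specimen/condition/configuration cells.")
    }
    args <- lapply(stats::setNames(LANDMARK_NAMES, LANDMARK_NAMES), function(nm) {
      row <- df[df$landmark == nm, , drop = FALSE]
      if (nrow(row) != 1L) {
        rlang::abort(sprintf("Landmark CSV needs exactly one row for '%s'.", nm))
      }
      as.numeric(row[1, c("x", "y", "z")])
    })
    do.call(landmark_set, c(args, list(
      specimen_id = df$specimen_id[1],
      condition = df$condition[1],
      configuration = df$configuration[1]
    )))
  } else {
    rlang::abort("Landmark files must be .json or .csv.")
  }
}

#' Landmark sets as a tidy tibble
#'
#' One row per landmark with voxel-index coordinates; useful for
#' reproducibility analyses across registration sessions.
#'
#' @param landmark_sets A `landmark_set` or a list of them.
#' @return A tibble with columns `specimen_id, condition, configuration,
#'   landmark, x, y, z`.
#' @export
landmarks_to_tibble <- function(landmark_sets) {
  if (inherits(landmark_sets, "landmark_set")) landmark_sets <- list(landmark_sets)
  purrr::map_dfr(landmark_sets, function(ls) {
    tibble::tibble(
      specimen_id = ls$specimen_id,
      condition = ls$condition,
      configuration = ls$configuration,
      landmark = LANDMARK_NAMES,
      x = purrr::map_dbl(LANDMARK_NAMES, ~ ls[[.x]][1]),
      y = purrr::map_dbl(LANDMARK_NAMES, ~ ls[[.x]][2]),
      z = purrr::map_dbl(LANDMARK_NAMES, ~ ls[[.x]][3])
    )
  })
}
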