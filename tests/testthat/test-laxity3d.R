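test_that("a cell compared to itself yields zero differences", {
  cell <- make_cell()
  m1 <- compute_cell_measures(cell)
  m2 <- compute_cell_measures(cell)
  expect_equal(m1$value, m2$value)
  expect_setequal(m1$measure, kneelax:::MEASURE_NAMES_3D)
  expect_true(all(m1$value[m1$measure %in% c("vector_ASI", "vector_FT")] >= 0))
})

test_that("a pure posterior tibial shift appears in the y components", {
  base <- make_cell()
  shifted <- make_cell(translation = c(0, 10, 0), configuration = "d1")
  m0 <- compute_cell_measures(base)
  m1 <- compute_cell_measures(shifted)
  d <- m1$value - m0$value
  names(d) <- m1$measure
  tol_asi <- 0.6 + min(grid_spacing(base$grid)) / 4 # in-plane spacing + marching step
  expect_equal(d[["y_ASI"]], 10, tolerance = tol_asi)
  expect_equal(d[["y_FT"]], 10, tolerance = 1e-6)
  expect_equal(d[["x_FT"]], 0, tolerance = 1e-6)
  expect_equal(d[["z_FT"]], 0, tolerance = 1e-6)
  expect_lt(abs(d[["x_ASI"]]), tol_asi)
})

test_that("a pure cranial tibial shift moves only the z components", {
  base <- make_cell()
  up <- make_cell(translation = c(0, 0, 3.3), configuration = "d1")
  d <- compute_cell_measures(up)$value - compute_cell_measures(base)$value
  names(d) <- kneelax:::MEASURE_NAMES_3D
  expect_equal(d[["z_FT"]], 3.3, tolerance = 1e-6)
  expect_equal(d[["x_FT"]], 0, tolerance = 1e-6)
  expect_equal(d[["y_FT"]], 0, tolerance = 1e-6)
  expect_equal(d[["z_ASI"]], 3.3, tolerance = 3.3) # slice-axis quantisation
  expect_lt(abs(d[["y_ASI"]]), 0.2)
  expect_lt(abs(d[["x_ASI"]]), 0.2)
})

test_that("measures are invariant under whole-grid translation (rigid motion)", {
  cell <- make_cell()
  shift <- c(3L, 5L, 2L) # voxels
  n <- cell$grid$shape
  moved_masks <- lapply(cell$masks, function(m) {
    out <- array(0L, n)
    out[
      (1 + shift[1]):n[1], (1 + shift[2]):n[2], (1 + shift[3]):n[3]
    ] <- m[1:(n[1] - shift[1]), 1:(n[2] - shift[2]), 1:(n[3] - shift[3])]
    out
  })
  lm <- cell$landmarks
  for (nm in kneelax:::LANDMARK_NAMES) lm[[nm]] <- lm[[nm]] + shift
  moved <- measurement_cell(moved_masks, cell$grid, lm)
  m0 <- compute_cell_measures(cell)
  m1 <- compute_cell_measures(moved)
  expect_equal(m1$value, m0$value, tolerance = 1e-9)
})

test_that("left and right knees give identical measures after side normalization", {
  r <- compute_cell_measures(make_cell(side = "right", translation = c(2, 6, 0), rot_int_deg = 4))
  l <- compute_cell_measures(make_cell(side = "left", translation = c(2, 6, 0), rot_int_deg = 4))
  expect_equal(l$value, r$value, tolerance = 1e-6)
})

test_that("delta tables are exact arithmetic against the unloaded intact baseline", {
  tb <- tidyr::expand_grid(
    specimen_id = c("s1", "s2"),
    condition = c("intact", "partial"),
    configuration = c("d0", "d1"),
    measure = "y_ASI"
  )
  tb$value <- c(10, 17.9, 11.5, 14.25, 20, 22.5, 21.25, 25)
  d <- compute_deltas(tb)
  expect_equal(
    measure_value(d, "y_ASI", "intact", "d1")[1], 7.9, # 17.9 - 10.0
    tolerance = 1e-12
  )
  expect_true(all(measure_value(d, "y_ASI", "intact", "d0") == 0))
  # re-adding the baseline reproduces the original values bit-for-bit
  # (dyadic values keep the subtraction exact in floating point)
  base <- tb$value[tb$condition == "intact" & tb$configuration == "d0"]
  readd <- d$delta + base[match(d$specimen_id, unique(d$specimen_id))]
  expect_identical(readd, tb$value)
  # missing baseline names the specimen
  expect_error(compute_deltas(tb[tb$specimen_id != "s2" |
    tb$condition != "intact" | tb$configuration != "d0", ]), "s2")
})

test_that("study-level delta bookkeeping loses no rows", {
  spec <- phantom_spec(n_specimens = 2, seed = 5)
  cells <- c(phantom_specimen(spec, 1)$cells, phantom_specimen(spec, 2)$cells)
  mt <- measure_study(cells)
  expect_equal(nrow(mt), 2 * 6 * 16) # 2 specimens x 6 cells x 16 measures
  d <- compute_deltas(mt)
  expect_equal(nrow(d), nrow(mt))
  expect_true(all(d$delta[d$condition == "intact" & d$configuration == "d0"] == 0))
})

test_that("landmark reproducibility reports Euclidean deviations in mm", {
  grid <- study_grid(side = "right")
  cell <- make_cell()
  a <- landmarks_to_tibble(cell$landmarks)
  # identical sessions: zero deviation
  r0 <- landmark_reproducibility(a, a, grid)
  expect_true(all(r0$per_landmark$mean_mm == 0))
  # one in-plane pixel shift: 0.6 mm everywhere
  b <- dplyr::mutate(a, x = x + 1)
  r1 <- landmark_reproducibility(a, b, grid)
  expect_equal(r1$per_landmark$mean_mm, rep(0.6, 6), tolerance = 1e-12)
  expect_equal(r1$per_landmark$sd_mm, rep(0, 6), tolerance = 1e-12)
  # mismatched keys are reported
  expect_error(
    landmark_reproducibility(a, dplyr::mutate(b, specimen_id = "other"), grid),
    "unmatched"
  )
})

test_that("Gaussian jitter gives the chi-distribution mean deviation", {
  grid <- image_grid(c(200, 200, 200), c(1, 1), 1, 0, side = "right")
  set.seed(7)
  n <- 4000L
  a <- tibble::tibble(
    specimen_id = sprintf("s%04d", seq_len(n)),
    condition = "intact", configuration = "d0",
    landmark = "FT",
    x = 100, y = 100, z = 100
  )
  sigma <- 0.5
  b <- dplyr::mutate(a,
    x = x + rnorm(n, 0, sigma),
    y = y + rnorm(n, 0, sigma),
    z = z + rnorm(n, 0, sigma)
  )
  r <- landmark_reproducibility(a, b, grid)
  chi3_mean <- sigma * sqrt(2) * gamma(2) / gamma(1.5) # E||N(0, I3)|| scaled
  expect_equal(r$per_landmark$mean_mm, chi3_mean, tolerance = 0.05)
})
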