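# small handmade cell: two-compartment plateau, blocky femur, ring menisci
# replaced by explicit horn blocks so every boundary is known exactly
make_toy_cell <- function(nx = 16, ny = 40, nz = 20, side = "right",
                          plateau_x = 2:13, # 1-based stored columns
                          tib_shift_y = 0L, men_shift_y = 0L) {
  grid <- image_grid(c(nx, ny, nz), c(1, 1), 1, 0, side = side)
  z_plat <- 8:10
  tib <- array(0L, c(nx, ny, nz))
  tib[plateau_x, (6 + tib_shift_y):(30 + tib_shift_y), z_plat] <- 1L
  tib[plateau_x[5:8], 15:20, 1:7] <- 1L # shaft below the plateau
  fem <- array(0L, c(nx, ny, nz))
  fem[plateau_x, 8:28, 13:19] <- 1L
  men <- function(y_lo, y_hi) {
    m <- array(0L, c(nx, ny, nz))
    m[plateau_x, (y_lo + men_shift_y):(y_hi + men_shift_y), 11:12] <- 1L
    m
  }
  ant <- men(8, 11)
  post <- men(25, 28)
  meni <- ant | post
  masks <- list(
    femur = fem, tibia = tib,
    meniscus_medial = array(as.integer(meni), c(nx, ny, nz)),
    meniscus_lateral = array(as.integer(meni), c(nx, ny, nz))
  )
  lm <- landmark_set(
    FT = c(8, 18, 16), TT = c(8, 10, 4),
    femur_proximal = c(8, 18, 19), femur_distal = c(8, 18, 14),
    tibia_proximal = c(8, 17, 6), tibia_distal = c(8, 17, 1),
    specimen_id = "toy", condition = "intact", configuration = "d0"
  )
  measurement_cell(masks, grid, lm)
}

test_that("central slice is the lower-median column of the compartment plateau", {
  # plateau columns 2..13 (1-based): mid 7.5; right knee lateral = cols 8..13
  cell <- make_toy_cell()
  lat <- select_central_slice(cell, "lateral")
  med <- select_central_slice(cell, "medial")
  expect_equal(lat, floor((8 + 13) / 2) - 1L) # 0-based 9
  expect_equal(med, floor((2 + 7) / 2) - 1L) # 0-based 3
  # left knee: the lateral compartment sits on the low-x side
  cl <- make_toy_cell(side = "left")
  expect_equal(select_central_slice(cl, "lateral"), med)
  expect_equal(select_central_slice(cl, "medial"), lat)
  # single-column compartment returns that column
  one <- make_toy_cell(plateau_x = c(2:7, 13))
  expect_equal(select_central_slice(one, "lateral"), 12L)
  # a single-column plateau has no lateral half beyond the midline
  half <- make_toy_cell(plateau_x = 7)
  expect_equal(select_central_slice(half, "medial"), 6L)
  expect_error(select_central_slice(half, "lateral"), "lateral")
})

test_that("PTT responds to posterior tibial shifts with the right sign", {
  base <- make_toy_cell()
  sl0 <- compartment_slice(base, "lateral", select_central_slice(base, "lateral"))
  p0 <- measure_ptt(sl0)
  fwd <- make_toy_cell(tib_shift_y = 8L, men_shift_y = 8L)
  sl1 <- compartment_slice(fwd, "lateral", select_central_slice(base, "lateral"))
  expect_equal(measure_ptt(sl1) - p0, 8, tolerance = 1e-9)
  back <- make_toy_cell(tib_shift_y = -5L, men_shift_y = -5L)
  sl2 <- compartment_slice(back, "lateral", select_central_slice(base, "lateral"))
  expect_equal(measure_ptt(sl2) - p0, -5, tolerance = 1e-9)
})

test_that("meniscal displacement tracks the horn base against the plateau border", {
  base <- make_toy_cell()
  idx <- select_central_slice(base, "medial")
  sl0 <- compartment_slice(base, "medial", idx)
  ad0 <- measure_meniscus_displacement(sl0, "anterior")
  pd0 <- measure_meniscus_displacement(sl0, "posterior")
  # meniscus rigidly attached to the tibia: co-displacement cancels
  both <- make_toy_cell(tib_shift_y = 6L, men_shift_y = 6L)
  slb <- compartment_slice(both, "medial", idx)
  expect_equal(measure_meniscus_displacement(slb, "anterior"), ad0, tolerance = 1e-9)
  expect_equal(measure_meniscus_displacement(slb, "posterior"), pd0, tolerance = 1e-9)
  # horn shifted 3 mm posteriorly relative to the plateau
  men3 <- make_toy_cell(men_shift_y = 3L)
  sl3 <- compartment_slice(men3, "medial", idx)
  expect_equal(measure_meniscus_displacement(sl3, "anterior") - ad0, 3, tolerance = 1e-9)
  expect_equal(measure_meniscus_displacement(sl3, "posterior") - pd0, 3, tolerance = 1e-9)
})

test_that("API measures the inner horn gap and internal invariances hold", {
  cell <- make_toy_cell()
  idx <- select_central_slice(cell, "lateral")
  sl <- compartment_slice(cell, "lateral", idx)
  # inner edges: anterior horn ends at column 11, posterior starts at 25
  expect_equal(measure_api(sl), 25 - 11)
  # rigid whole-joint translation leaves API unchanged
  moved <- make_toy_cell(tib_shift_y = 4L, men_shift_y = 4L)
  slm <- compartment_slice(moved, "lateral", idx)
  expect_equal(measure_api(slm), measure_api(sl))
  # a single meniscal component has no API
  onehorn <- make_toy_cell()
  m <- onehorn$masks$meniscus_lateral
  m[, 20:40, ] <- 0L
  onehorn$masks$meniscus_lateral <- m
  slo <- compartment_slice(onehorn, "lateral", idx)
  expect_error(measure_api(slo), "Fewer than two")
})

test_that("2D measures are invariant under whole-image translation", {
  cell <- make_toy_cell()
  idx <- c(
    medial = select_central_slice(cell, "medial"),
    lateral = select_central_slice(cell, "lateral")
  )
  m0 <- compute_reference_measures(cell, idx)
  shifted <- make_toy_cell(tib_shift_y = 5L, men_shift_y = 5L)
  # femur must move too for a whole-image translation
  f <- array(0L, dim(shifted$masks$femur))
  f[, 6:40, ] <- cell$masks$femur[, 1:35, ]
  shifted$masks$femur <- f
  m1 <- compute_reference_measures(shifted, idx)
  expect_equal(m1$value, m0$value, tolerance = 1e-9)
})

test_that("internal rotation raises lateral over medial translation on the phantom", {
  base <- make_cell()
  rot <- make_cell(rot_int_deg = 6, configuration = "d1")
  idx <- c(
    medial = select_central_slice(base, "medial"),
    lateral = select_central_slice(base, "lateral")
  )
  m0 <- compute_reference_measures(base, idx)
  m1 <- compute_reference_measures(rot, idx)
  d_lat <- measure_value(m1, "lPTT") - measure_value(m0, "lPTT")
  d_med <- measure_value(m1, "mPTT") - measure_value(m0, "mPTT")
  expect_gt(d_lat, d_med) # lateral excess under internal rotation
  expect_gt(d_lat, 2) # ~0.105 rad x 32 mm lever
  expect_lt(abs(d_med), 1.5) # pivot sits in the medial compartment
})
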