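test_that("variety_shape validates its geometry", {
  expect_error(variety_shape("x", -1, 2), class = "carposort_parameter_error")
  expect_error(variety_shape("x", 3, 4), class = "carposort_parameter_error")
  expect_error(variety_shape("x", 5, 4, infold_separation = 4.5),
               class = "carposort_parameter_error")
  expect_error(variety_shape("x", 5, 4, beak_fraction = 0.6),
               class = "carposort_parameter_error")
  # equal axes (a sphere) are legal
  expect_s3_class(variety_shape("sphere", 3, 3, 3, infold_depth = 0),
                  "variety_shape")
})

test_that("fresh clouds track the requested dimensions", {
  cl <- generate_fresh_cloud(cabernet_shape(), 600, rng_seed = 1)
  m <- morphometrics(cl)
  expect_lt(abs(m$length_mm - 5.81) / 5.81, 0.02)
  expect_lt(abs(m$width_mm - 3.81) / 3.81, 0.02)

  sphere <- variety_shape("sphere", 3, 3, 3, infold_depth = 0,
                          beak_fraction = 0, asymmetry = 0)
  ms <- morphometrics(generate_fresh_cloud(sphere, 600, rng_seed = 2))
  expect_equal(ms$lw_ratio, 1, tolerance = 0.02)
})

test_that("cloud generation is deterministic in the seed", {
  a <- generate_fresh_cloud(cabernet_shape(), 400, rng_seed = 11)
  b <- generate_fresh_cloud(cabernet_shape(), 400, rng_seed = 11)
  expect_identical(unclass(a), unclass(b))
  c <- generate_fresh_cloud(cabernet_shape(), 400, rng_seed = 12)
  expect_false(identical(unclass(a), unclass(c)))
  expect_error(generate_fresh_cloud(cabernet_shape(), 100),
               class = "carposort_parameter_error")
})

test_that("deformation model reproduces tabulated shrink factors", {
  model <- table2_model()
  f <- shrink_factors(model, "Cabernet Sauvignon", 350, 8)
  expect_equal(f$length, 2.7 / 5.81, tolerance = 1e-12)
  expect_equal(f$width, 2.43 / 3.81, tolerance = 1e-12)
  expect_identical(shrink_factors(model, "Cabernet Sauvignon", "fresh"),
                   list(length = 1, width = 1, cv_length = 0, cv_width = 0))
})

test_that("shrink factors interpolate linearly in temperature", {
  model <- table2_model()
  f250 <- shrink_factors(model, "Cabernet Sauvignon", 250, 2)
  f300 <- shrink_factors(model, "Cabernet Sauvignon", 300, 2)
  f275 <- shrink_factors(model, "Cabernet Sauvignon", 275, 2)
  expect_equal(f275$length, (f250$length + f300$length) / 2,
               tolerance = 1e-12)
  expect_equal(f275$width, (f250$width + f300$width) / 2,
               tolerance = 1e-12)
  expect_error(shrink_factors(model, "Cabernet Sauvignon", 180, 2),
               class = "carposort_coverage_error")
  expect_error(shrink_factors(model, "Cabernet Sauvignon", 300, 4),
               class = "carposort_coverage_error")
})

test_that("calibration requires a fresh reference row", {
  tab <- charring_reference_means()
  expect_error(calibrate_deformation(tab[tab$temperature_C != "fresh", ]),
               class = "carposort_calibration_error")
})

test_that("charring scales the cloud by the calibrated factors", {
  model <- table2_model()
  cl <- generate_fresh_cloud(cabernet_shape(), 600, rng_seed = 3)
  # fresh condition is the identity
  expect_identical(
    unclass(apply_charring(cl, charring_condition("fresh"), model)),
    unclass(cl))
  ch <- apply_charring(cl, charring_condition(350, 8), model, rng_seed = 4,
                       variety = "Cabernet Sauvignon", variability = FALSE)
  m <- morphometrics(canonicalize_pose(ch))
  expect_equal(m$lw_ratio, 2.7 / 2.43, tolerance = 0.05)
  # mild charring barely moves the ratio
  mild <- apply_charring(cl, charring_condition(200, 2), model,
                         rng_seed = 4, variety = "Cabernet Sauvignon",
                         variability = FALSE)
  r0 <- morphometrics(cl)$lw_ratio
  expect_lt(abs(morphometrics(canonicalize_pose(mild))$lw_ratio - r0) / r0,
            0.03)
})

test_that("measured shrinkage matches the calibration across the grid", {
  model <- table2_model()
  cl <- generate_fresh_cloud(cabernet_shape(), 800, rng_seed = 5,
                             surface_noise = 0)
  m0 <- measure_length_width(cl)
  grid <- expand.grid(temp = c(200, 250, 300, 350), dur = c(2, 8))
  for (k in seq_len(nrow(grid))) {
    cond <- charring_condition(grid$temp[k], grid$dur[k])
    fac <- shrink_factors(model, "Cabernet Sauvignon", grid$temp[k],
                          grid$dur[k])
    ch <- apply_charring(cl, cond, model, rng_seed = 6,
                         variety = "Cabernet Sauvignon",
                         variability = FALSE)
    m1 <- measure_length_width(canonicalize_pose(ch))
    expect_lt(abs(m1$length_mm / m0$length_mm - fac$length) / fac$length,
              0.02)
    expect_lt(abs(m1$width_mm / m0$width_mm - fac$width) / fac$width,
              0.02)
  }
})

test_that("cracks remove points above 300 degrees C only", {
  expect_identical(crack_intensity(250, 8), 0)
  expect_identical(crack_intensity("fresh"), 0)
  expect_gt(crack_intensity(300, 2), 0)
  expect_gt(crack_intensity(350, 8), crack_intensity(300, 2))
  model <- table2_model()
  cl <- generate_fresh_cloud(cabernet_shape(), 800, rng_seed = 7)
  hot <- apply_charring(cl, charring_condition(350, 8), model,
                        rng_seed = 8, variety = "Cabernet Sauvignon")
  expect_lt(nrow(hot), nrow(cl))
  mild <- apply_charring(cl, charring_condition(250, 2), model,
                         rng_seed = 8, variety = "Cabernet Sauvignon")
  expect_identical(nrow(mild), nrow(cl))
})

test_that("mean synthetic L/W is non-increasing in temperature above 250", {
  model <- table2_model()
  for (dur in c(2, 8)) {
    means <- vapply(c(250, 300, 350), function(temp) {
      b <- generate_seed_batch(cabernet_shape(), 8,
                               charring_condition(temp, dur), model,
                               n_points = 400, rng_seed = 20 + dur)
      mean(morphometrics_table(preprocess_clouds(b))$lw_ratio)
    }, numeric(1))
    expect_true(all(diff(means) <= 0))
  }
})

test_that("scans project the ventral surface onto the pixel grid", {
  # one point at the origin lands on the principal point
  one <- seed_cloud(matrix(c(0, 0, 0), 1))
  sc <- simulate_scan(one, scan_intrinsics(1, 1, c(3, 2)), rows = 5,
                      cols = 7)
  expect_identical(which(sc > 0), as.integer(3 * 5 + (2 + 1)))  # col 4, row 3
  expect_identical(sum(sc > 0), 1L)

  cl <- generate_fresh_cloud(cabernet_shape(), 500, rng_seed = 9)
  s1 <- simulate_scan(cl, scan_intrinsics(0.05, 0.05, c(80, 64)),
                      rows = 128, cols = 160)
  s2 <- simulate_scan(cl, scan_intrinsics(0.1, 0.1, c(40, 32)),
                      rows = 64, cols = 80)
  ext_cols <- function(s) diff(range(which(colSums(s) > 0)))
  expect_equal(ext_cols(s2), ext_cols(s1) / 2, tolerance = 0.05)
  expect_error(simulate_scan(cl, scan_intrinsics(0.05, 0.05, c(2, 2)),
                             rows = 10, cols = 10),
               class = "carposort_bounds_error")
})
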