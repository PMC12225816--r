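test_that("a zero BV/TV target leaves the spongiosa all-marrow", {
  ph <- voxelize_shape(shape_spec("box", 5, 5, 5), 0.1)
  out <- generate_spongiosa(ph, micro_params(0, 0.2, 0, 0.6, 0), seed = 1)
  expect_identical(sum(out$labels == 2L), 0L)
  m <- measure_morphometry(out, spacing = FALSE)
  expect_identical(m$bvtv, 0)
})

test_that("zero intra-specimen variability gives identical rod diameters", {
  ph <- voxelize_shape(shape_spec("box", 6, 6, 6), 0.05)
  out <- generate_spongiosa(ph, micro_params(0.15, 0.2, 0, 0.7, 0), seed = 3)
  radii <- out$generation$rods[, 7]
  expect_gt(length(radii), 10)
  expect_equal(max(radii) - min(radii), 0)
  expect_equal(unique(radii), 0.1)
})

test_that("BV/TV calibration hits the target within tolerance and is seed-deterministic", {
  # adult male femoral neck microarchitecture in a 10 mm test cube
  mp <- micro_params(0.17, 0.19, 22, 0.78, 23)
  mk <- function() voxelize_shape(shape_spec("box", 10, 10, 10),
                                  0.7 * 0.19)
  a <- generate_spongiosa(mk(), mp, seed = 42)
  expect_lt(abs(a$generation$bvtv_measured - 0.17), 0.004)
  b <- generate_spongiosa(mk(), mp, seed = 42)
  expect_identical(a$labels, b$labels)
  c <- generate_spongiosa(mk(), mp, seed = 43)
  expect_false(identical(a$labels, c$labels))
})

test_that("an unattainable target fails naming the best achieved BV/TV", {
  # granularity trap: rods each convert far more than 2% of the target
  ph <- voxelize_shape(shape_spec("box", 1.2, 1.2, 1.2), 0.1)
  expect_error(
    generate_spongiosa(ph, micro_params(0.05, 0.6, 0, 0.6, 0), seed = 5,
                       max_batches = 2),
    "best achieved")
})

test_that("local thickness of a single spanning rod recovers its diameter", {
  # rod crosses the whole box: no free-end taper; diameter 10 voxels.
  # the grid-aligned orientation is the worst lattice case: the maximal-ball
  # centre falls between voxel centres, costing up to ~1.5 voxels
  ph <- single_rod_phantom(axis = c(0, 0, 1), diameter = 1.0, length = 30)
  m <- measure_morphometry(ph, spacing = FALSE)
  expect_lt(abs(m$tb_th[["mean"]] - 1.0), 0.2)
  expect_lt(m$tb_th[["cv_pct"]], 5)
  # oblique orientation (the generic lattice case)
  ph2 <- single_rod_phantom(axis = c(1, 1, 1), diameter = 1.0, length = 30)
  m2 <- measure_morphometry(ph2, spacing = FALSE)
  expect_lt(abs(m2$tb_th[["mean"]] - 1.0), 0.1)
})

test_that("all-marrow spongiosa measures BV/TV of zero and empty regions error", {
  ph <- voxelize_shape(shape_spec("box", 4, 4, 4), 0.2)
  expect_identical(measure_morphometry(ph, spacing = FALSE)$bvtv, 0)
  ph$labels[] <- 0L
  expect_error(measure_morphometry(ph), "empty spongiosa")
  expect_error(generate_spongiosa(ph, micro_params(0.2, 0.2, 0, 0.6, 0)),
               "empty spongiosa")
})

test_that("measured thickness statistics track the lognormal diameter law", {
  # CV 22% diameters, ~>300 rods, voxel = Tb.Th / 5 so rods are ~5 voxels
  mp <- micro_params(0.17, 0.19, 22, 0.78, 23)
  ph <- generate_spongiosa(voxelize_shape(shape_spec("box", 8, 8, 8),
                                          0.19 / 5), mp, seed = 7)
  expect_gt(ph$generation$rods_used, 300)
  m <- suppressWarnings(measure_morphometry(ph, spacing = TRUE,
                                            tb_sp_reference = 0.78))
  expect_lt(abs(m$tb_th[["mean"]] - 0.19) / 0.19, 0.10)
  expect_lt(abs(m$tb_th[["cv_pct"]] - 22), 8)
  expect_true(is.finite(m$tb_sp[["mean"]]))
})

test_that("an excessive emergent separation deviation raises the logged warning", {
  mp <- micro_params(0.3, 0.2, 0, 0.4, 0)
  ph <- generate_spongiosa(voxelize_shape(shape_spec("box", 6, 6, 6), 0.05),
                           mp, seed = 11)
  expect_warning(measure_morphometry(ph, tb_sp_reference = 5), "emergent Tb.Sp")
})
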