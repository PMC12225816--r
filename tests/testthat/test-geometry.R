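test_that("closed-form volumes match independent oracles", {
  # elliptic cylinder, adult lumbar body dimensions
  expect_equal(analytic_volume(shape_spec("cylinder", 27, 35, 47)),
               pi * 27 * 35 * 47 / 4, tolerance = 1e-12)
  expect_equal(analytic_volume(shape_spec("cylinder", 27, 35, 47)), 34883.5,
               tolerance = 1e-4)
  # tube (acetabulum) and prism (sacral ala) worked examples
  expect_equal(analytic_volume(shape_spec("tube", 29, 26, 21)), 5352.5,
               tolerance = 1e-4)
  expect_equal(analytic_volume(shape_spec("prism", 19, 18, 38.5)), 6401.1,
               tolerance = 1e-4)
  expect_equal(analytic_volume(shape_spec("ellipsoid", 7.8, 12, 7.8)), 382.3,
               tolerance = 1e-3)
  # a deformed cylinder with equal bases is exactly an elliptic cylinder
  expect_identical(analytic_volume(shape_spec("deformed_cylinder",
                                              10, 8, 6, 8, 6)) -
                     analytic_volume(shape_spec("cylinder", 10, 8, 6)) < 1e-9,
                   TRUE)
})

test_that("invalid shape specifications are rejected with the violated invariant", {
  expect_error(shape_spec("tube", 10, 5, 6), "outer diameter")
  expect_error(shape_spec("prism", 10, 20, 9), "equal side")
  expect_error(shape_spec("box", -1, 2, 3), "positive")
  expect_error(shape_spec("cylinder", 10, 5, 5, c = 3, d = 3), "only defined")
})

test_that("default voxel size follows the 0.7 x Tb.Th rule with clamping", {
  v <- default_voxel_size(0.29)
  expect_equal(as.numeric(v), 0.203)
  expect_false(attr(v, "clamped"))
  expect_equal(as.numeric(default_voxel_size(0.10)), 0.07)
  v2 <- default_voxel_size(0.02)
  expect_equal(as.numeric(v2), 0.04)
  expect_true(attr(v2, "clamped"))
})

test_that("centre-point rasterization is exact for boxes and convergent for curved shapes", {
  ph <- voxelize_shape(shape_spec("box", 10, 10, 10), 0.5)
  expect_identical(sum(ph$labels != 0L), 8000L)

  shapes <- list(cyl = shape_spec("cylinder", 12, 9, 7),
                 dc = shape_spec("deformed_cylinder", 10, 9, 7, 5, 4),
                 ell = shape_spec("ellipsoid", 7.8, 12, 7.8),
                 pr = shape_spec("prism", 10, 9, 8),
                 tb = shape_spec("tube", 10, 9, 6))
  for (nm in names(shapes)) {
    s <- shapes[[nm]]
    va <- analytic_volume(s)
    err <- vapply(c(0.4, 0.2, 0.1), function(v) {
      abs(sum(voxelize_shape(s, v)$labels != 0L) * v^3 - va) / va
    }, 1.0)
    expect_lt(err[3], 0.01)            # 1% at 0.1 mm
    expect_lt(err[3], err[1])          # first-order convergence
  }
})

test_that("volume conservation: labels partition the grid", {
  rec <- get_record("10y/any/Pelvis/Ilium flat part 1")
  ph <- voxelize_shape(record_shape(rec), 0.2, cortical = record_cortical(rec))
  tab <- tabulate(ph$labels + 1L, nbins = 4L)
  expect_identical(sum(tab), length(ph$labels))
  va <- analytic_volume(record_shape(rec))
  expect_lt(abs(sum(tab[2:4]) * 0.2^3 - va) / va, 0.01)
})

test_that("cortex-free records yield zero cortical voxels", {
  rec <- get_record("newborn/any/Sacrum/Body 1")
  expect_null(record_cortical(rec))
  ph <- voxelize_shape(record_shape(rec), 0.1, cortical = record_cortical(rec))
  expect_identical(sum(ph$labels == 3L), 0L)
})

test_that("cylinder bases stay uncovered by a lateral-only shell", {
  ph <- voxelize_shape(shape_spec("cylinder", 10, 8, 8), 0.2,
                       cortical = data.frame(face = "lateral", thickness = 1.8))
  nz <- dim(ph$labels)[3]
  expect_gt(sum(ph$labels[, , 1] == 1L), 0)   # marrow at the bottom base
  expect_gt(sum(ph$labels[, , nz] == 1L), 0)  # and at the top base
  # but the lateral surface ring is cortical: the outermost x column
  mid <- ph$labels[, , nz %/% 2]
  edge <- mid[max(which(rowSums(mid != 0L) > 0)), ]
  expect_true(all(edge[edge != 0L] == 3L))
})

test_that("asymmetric plate shells reproduce the slab closed form", {
  # two ab faces with different thicknesses: shell volume ~ (t1+t2) a b
  rec <- get_record("newborn/any/Pelvis/Ilium part 1")
  ph <- voxelize_shape(record_shape(rec), 0.1, cortical = record_cortical(rec))
  shell <- sum(ph$labels == 3L) * 0.1^3
  expect_lt(abs(shell - (1.2 + 0.5) * 24 * 24) / ((1.2 + 0.5) * 24 * 24), 0.05)
})

test_that("shells thicker than the segment are rejected, as are invalid faces", {
  s <- shape_spec("box", 4, 20, 20)
  expect_error(voxelize_shape(s, 0.2,
                              cortical = data.frame(face = "ab",
                                                    thickness = 2.5)),
               "no spongiosa")
  expect_error(voxelize_shape(s, 0.2,
                              cortical = data.frame(face = "lateral",
                                                    thickness = 0.5)),
               "invalid")
  expect_error(apply_cortical_shell(voxelize_shape(s, 0.5),
                                    data.frame(face = "abb", thickness = 1)),
               "invalid")
})

test_that("grids beyond the memory budget are refused with the required size", {
  expect_error(voxelize_shape(shape_spec("box", 100, 100, 100), 0.01),
               "exceeds the budget")
})
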