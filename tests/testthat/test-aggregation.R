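test_that("cortex-free plate: spongiosa equals the full box and BMV follows BV/TV", {
  rec <- get_record("newborn/any/Skull/Flat bones")  # 2 x 30 x 30 box, no cortex
  m <- segment_media_volumes(rec, corrected = FALSE)
  expect_equal(m[["spongiosa"]] * 1000, 2 * 30 * 30)
  expect_equal(m[["bmv"]] * 1000, (1 - rec$bvtv) * 1800)
  expect_equal(m[["cbv"]], 0)
})

test_that("analytic split satisfies tbv/(tbv+bmv) = BV/TV exactly", {
  for (key in c("adult/male/Femur/Neck", "newborn/any/Vertebra/C-body",
                "15y/male/Pelvis/Acetabulum", "adult/female/Sacrum/Ala 3-4")) {
    rec <- get_record(key)
    m <- segment_media_volumes(rec, corrected = FALSE)
    expect_equal(m[["tbv"]] / (m[["tbv"]] + m[["bmv"]]), rec$bvtv)
    expect_equal(m[["tbv"]] + m[["bmv"]], m[["spongiosa"]])
    expect_equal(m[["spongiosa"]] + m[["cbv"]], m[["total"]])
  }
})

test_that("lateral erosion closed form matches the voxel path for the adult lumbar body", {
  rec <- get_record("adult/male/Vertebra/L-body")  # cylinder 27 x 35 x 47, Ct.Th 1.3
  ma <- segment_media_volumes(rec, corrected = FALSE)
  expect_equal(ma[["spongiosa"]] * 1000,
               pi * 27 * (35 - 2.6) * (47 - 2.6) / 4, tolerance = 1e-12)
  mv <- segment_media_volumes(rec, mode = "voxel", voxel_size = 0.15,
                              seed = 9, corrected = FALSE)
  expect_lt(abs(mv[["spongiosa"]] - ma[["spongiosa"]]) / ma[["spongiosa"]], 0.02)
  expect_lt(abs(mv[["tbv"]] - ma[["tbv"]]) / ma[["tbv"]], 0.03)
})

test_that("analytic and voxel media agree at default resolution across the database", {
  # tolerance: 2% or one voxel layer over the thinnest spongiosa extent,
  # whichever is larger (thin plates are bounded by the +/- 1 voxel shell
  # realization, not by a relative tolerance)
  seg <- DB$segments
  for (i in seq_len(nrow(seg))) {
    rec <- seg[i, , drop = FALSE]
    va <- segment_media_volumes(rec, "analytic", corrected = FALSE) * 1000
    vox <- as.numeric(default_voxel_size(rec$tb_th))
    ph <- voxelize_shape(record_shape(rec), vox,
                         cortical = record_cortical(rec))
    pv <- phantom_volumes(ph)
    min_ext <- min(rec$h, rec$a, rec$b, na.rm = TRUE)
    tol_sp <- max(0.02 * va[["spongiosa"]],
                  1.5 * vox * va[["total"]] / min_ext)
    expect_lt(abs(pv[["total"]] - va[["total"]]), 0.02 * va[["total"]],
              label = paste("total volume error at", rec$key))
    expect_lt(abs(pv[["spongiosa"]] - va[["spongiosa"]]), tol_sp,
              label = paste("spongiosa volume error at", rec$key))
  }
})

test_that("skeleton totals are linear in the multiplicities", {
  tot1 <- skeleton_totals(DB, "newborn", "male")
  seg <- spsd_segments(DB, "newborn", "male")
  dbl <- setNames(seg$n_s * 2, seg$key)
  tot2 <- skeleton_totals(DB, "newborn", "male", multiplicity = dbl)
  expect_equal(unclass(tot2$totals), unclass(tot1$totals) * 2)
  # additivity: totals exceed any single site sum
  expect_true(all(tot1$per_site$bmv < tot1$totals[["bmv"]]))
  expect_equal(sum(tot1$per_site$bmv), tot1$totals[["bmv"]])
  # unknown override key is an explicit failure
  expect_error(skeleton_totals(DB, "newborn", "male",
                               multiplicity = c(nope = 2)), "unknown segment")
})

test_that("masses derive from the age-specific media densities", {
  tot <- skeleton_totals(DB, "adult", "female")
  expect_equal(tot$masses[["bone"]],
               (tot$totals[["tbv"]] + tot$totals[["cbv"]]) * 1.90)
  expect_equal(tot$masses[["marrow"]], tot$totals[["bmv"]] * 0.98)
})

test_that("effective-parameter weights normalize and bound effective BV/TV", {
  for (a in c("newborn", "adult")) {
    e <- effective_parameters(DB, a, "male")
    expect_equal(sum(e$weights$weight), 1)
    expect_gte(e$bvtv, min(e$weights$bvtv))
    expect_lte(e$bvtv, max(e$weights$bvtv))
    expect_gte(e$ct_th_mm, 0)
  }
  # the childhood skeleton is denser: newborn effective BV/TV above adult
  expect_gt(effective_parameters(DB, "newborn", "male")$bvtv,
            effective_parameters(DB, "adult", "male")$bvtv)
})

test_that("lumbar vertebral body fraction matches the closed-form oracle", {
  # adult male: body = elliptic cylinder 27 x 35 x 47; processes are boxes
  # with per-vertebra multiplicities 1 spinous, 2 transverse, 2 superior,
  # 2 lamina+inferior
  v_body <- pi * 27 * 35 * 47 / 4
  v_proc <- 24 * 31 * 6 + 2 * (12 * 23 * 8) + 2 * (14 * 15 * 12) +
    2 * (20.4 * 12.7 * 4.1)
  f <- vertebral_body_fraction(DB, "adult", "male")
  expect_equal(as.numeric(f), v_body / (v_body + v_proc), tolerance = 1e-12)
  expect_lt(abs(as.numeric(f) - 0.68), 0.05)
  expect_lt(abs(vertebral_body_fraction(DB, "adult", "female") - 0.68), 0.05)
  # a vertebra modelled without processes degenerates to fraction 1
  expect_equal(as.numeric(vertebral_body_fraction(DB, "newborn", "male")), 1.0)
})
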