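test_that("normalized volume and area/volume ratio honour their contracts", {
  expect_equal(normalized_volume(3000, 1.5), 2000.0)
  expect_equal(normalized_volume(0, 1.7), 0.0)
  expect_true(is.na(normalized_volume(2500, NA)))
  expect_true(is.na(normalized_volume(2500, 0)))
  expect_true(is.na(area_volume_ratio(60, 0)))
})

test_that("area/volume ratio of a sphere is 3/r", {
  vol <- sphere_volume(5, 0.5)
  a <- mesh_surface_area(extract_surface(vol, "mM"))
  v <- voxel_volume(vol, "mM")
  expect_lt(abs(area_volume_ratio(a, v) - 0.6), 0.02)
})

test_that("constructed meniscus shift is measured exactly", {
  v0 <- constructed_extrusion_volume(0)
  expect_equal(meniscal_extrusion(v0, "medial"), 0.0)
  v4 <- constructed_extrusion_volume(4)
  expect_equal(meniscal_extrusion(v4, "medial"), 2.0)
  # mirror the volume on the ML axis and flip the side flag: same value
  mirrored <- label_volume(v4$array[dim(v4$array)[1]:1, , ],
                           v4$spacing_mm, side = "left")
  expect_equal(meniscal_extrusion(mirrored, "medial"), 2.0)
  expect_error(meniscal_extrusion(
    label_volume(array(2L, c(4, 4, 4)), c(1, 1, 1)), "medial"), "meniscus")
})

test_that("tibial coverage counts footprint columns", {
  arr <- array(0L, c(20, 20, 6))
  arr[5:14, 5:14, 2] <- 4L           # 10x10 cartilage columns
  arr[5:14, 5:9, 4] <- 6L            # meniscus over exactly half of them
  vol <- label_volume(arr, c(1, 1, 1))
  expect_equal(tibial_coverage(vol, "medial"), 50.0)
  arr2 <- arr
  arr2[5:14, 5:14, 4] <- 6L          # superset
  expect_equal(tibial_coverage(label_volume(arr2, c(1, 1, 1)), "medial"), 100.0)
  arr3 <- arr
  arr3[, , 4] <- 0L
  arr3[16:18, 16:18, 4] <- 6L        # disjoint
  expect_equal(tibial_coverage(label_volume(arr3, c(1, 1, 1)), "medial"), 0.0)
  expect_error(tibial_coverage(
    label_volume(array(0L, c(4, 4, 4)), c(1, 1, 1)), "medial"), "cartilage")
})

test_that("compute_meas assembles 14 named features and flags missing", {
  cfg <- planted_config(seed = 8)
  co <- sample_cohort(cfg)
  vol <- voxelize(co$meshes[[1]], c(1, 1, 1), side = co$records$side[1])
  mv <- compute_meas(vol, 1.7)
  expect_named(mv, meas_feature_names())
  expect_true(all(!is.na(mv)))
  expect_equal(mv[["E_mM"]], 0.0)  # zero severity effects
  expect_equal(mv[["E_lM"]], 0.0)
  expect_lt(abs(mv[["V_TC"]] * 1.7 - (mv[["V_mTC"]] + mv[["V_lTC"]]) * 1.7), 1e-6)
  # absent structure: features missing, no crash
  arr <- vol$array
  arr[arr == knee_labels[["mM"]]] <- 0L
  mv2 <- compute_meas(label_volume(arr, vol$spacing_mm, vol$side, vol$origin), 1.7)
  expect_true(is.na(mv2[["V_mM"]]) && is.na(mv2[["A_mM"]]) &&
                is.na(mv2[["R_AV_mM"]]) && is.na(mv2[["E_mM"]]))
  expect_false(is.na(mv2[["V_lM"]]))
})

test_that("all 14 features are mirror invariant", {
  cfg <- cohort_config(n_knees = 1, seed = 17)
  co <- sample_cohort(cfg)
  vol <- voxelize(co$meshes[[1]], c(1, 1, 1), side = co$records$side[1])
  flipped <- label_volume(vol$array[dim(vol$array)[1]:1, , ], vol$spacing_mm,
                          side = setdiff(c("left", "right"), vol$side),
                          origin = vol$origin)
  a <- compute_meas(vol, 1.7)
  b <- compute_meas(flipped, 1.7)
  # surface-derived features agree to voxel tolerance only: a reflection
  # re-orients the tetrahedral decomposition of the iso-surface extractor
  expect_equal(unname(a), unname(b), tolerance = 1e-3)
})

test_that("extrusion and coverage anti-correlate over a planted sweep", {
  eff <- planted_config(extrusion_mm_medial = 5)$severity_effects
  tpl <- build_templates()
  sev <- seq(0, 1, length.out = 21)
  ext <- cov <- numeric(length(sev))
  for (i in seq_along(sev)) {
    km <- kneemorph:::deform_knee(tpl, sev[i], eff)
    vol <- voxelize(km[c("TB", "mTC", "mM")], c(1, 1, 1))
    ext[i] <- meniscal_extrusion(vol, "medial")
    cov[i] <- tibial_coverage(vol, "medial")
  }
  expect_true(all(diff(ext)[ext[-1] > 0 & ext[-21] > 0] >= 0))
  expect_lt(stats::cor(ext, cov, method = "spearman"), 0)
})

test_that("feature units scale correctly with the voxel spacing", {
  vol <- constructed_extrusion_volume(4)
  s <- 2
  scaled <- label_volume(vol$array, vol$spacing_mm * s, vol$side)
  expect_equal(voxel_volume(scaled, "mM"), voxel_volume(vol, "mM") * s^3)
  expect_equal(meniscal_extrusion(scaled, "medial"),
               meniscal_extrusion(vol, "medial") * s)
  arr <- array(0L, c(20, 20, 6))
  arr[5:14, 5:14, 2] <- 4L; arr[5:14, 5:9, 4] <- 6L
  v1 <- label_volume(arr, c(1, 1, 1))
  v2 <- label_volume(arr, c(2, 2, 2))
  expect_equal(tibial_coverage(v1, "medial"), tibial_coverage(v2, "medial"))
})
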