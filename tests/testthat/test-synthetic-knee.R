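test_that("templates are closed, outward-wound, deterministic, in-frame", {
  t1 <- build_templates()
  t2 <- build_templates()
  expect_setequal(names(t1), names(knee_labels))
  for (nm in names(t1)) {
    expect_gt(nrow(t1[[nm]]$faces), 0)
    expect_true(mesh_is_closed(t1[[nm]]))
    expect_gt(mesh_enclosed_volume(t1[[nm]]), 0)
    expect_identical(t1[[nm]]$vertices, t2[[nm]]$vertices)
  }
  # menisci sit on the tibial-plateau footprint: baseline extrusion ~ 0
  vol <- voxelize(t1, c(0.5, 0.5, 0.5))
  expect_lte(meniscal_extrusion(vol, "medial"), 0.5)
  expect_lte(meniscal_extrusion(vol, "lateral"), 0.5)
})

test_that("cohort sampling is deterministic in the config seed", {
  cfg <- cohort_config(n_knees = 5, seed = 123)
  a <- sample_cohort(cfg)
  b <- sample_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$meshes[[3]]$FB$vertices, b$meshes[[3]]$FB$vertices)
  c <- sample_cohort(cohort_config(n_knees = 5, seed = 124))
  expect_false(identical(a$records$severity, c$records$severity))
})

test_that("records-only sampling matches the meshed records", {
  cfg <- cohort_config(n_knees = 8, seed = 3)
  expect_identical(sample_cohort(cfg, meshes = FALSE)$records,
                   sample_cohort(cfg)$records)
})

test_that("noise-free grades are determined by thresholds and monotone", {
  cfg <- planted_config(n_knees = 50, seed = 2)
  rec <- sample_cohort(cfg, meshes = FALSE)$records
  expected <- vapply(rec$severity, function(s)
    sum(s > cfg$grade_thresholds$klg), integer(1))
  expect_identical(rec$klg, expected)
  ord <- order(rec$severity)
  expect_true(all(diff(rec$klg[ord]) >= 0))
})

test_that("incident knee OA is not at risk once baseline KLG >= 2", {
  rec <- sample_cohort(cohort_config(n_knees = 200, seed = 9),
                       meshes = FALSE)$records
  sick <- !is.na(rec$klg) & rec$klg >= 2
  for (h in 1:5)
    expect_true(all(rec[[sprintf("inc_koa_%dyr", h)]][sick] == "not_at_risk"))
  # events are nested over horizons
  yes1 <- rec$tkr_1yr == "yes"
  expect_true(all(rec$tkr_5yr[yes1] == "yes"))
})

test_that("planted medial extrusion is recovered within one voxel", {
  cfg <- planted_config(seed = 5, extrusion_mm_medial = 4)
  tpl <- build_templates()
  km <- kneemorph:::deform_knee(tpl, 0.5, cfg$severity_effects)
  vol <- voxelize(km, cfg$voxel_spacing_mm)
  expect_lt(abs(meniscal_extrusion(vol, "medial") - 2.0), 0.5 + 1e-9)
  expect_lte(meniscal_extrusion(vol, "lateral"), 0.5)
})

test_that("planted cartilage shrink is recovered in the voxel volumes", {
  tpl <- build_templates()
  eff <- planted_config(cartilage_shrink = 0.4)$severity_effects
  v0 <- voxelize(build_templates(), c(0.5, 0.5, 0.5))
  km <- kneemorph:::deform_knee(tpl, 1, eff)
  v1 <- voxelize(km, c(0.5, 0.5, 0.5))
  ratio <- voxel_volume(v1, "FC") / voxel_volume(v0, "FC")
  expect_lt(abs(ratio - 0.6), 0.03)
})

test_that("meniscal flattening preserves volume and raises the A/V ratio", {
  tpl <- build_templates()
  eff <- planted_config(flatten_medial = 0.3)$severity_effects
  km <- kneemorph:::deform_knee(tpl, 1, eff)
  expect_lt(abs(mesh_enclosed_volume(km$mM) / mesh_enclosed_volume(tpl$mM) - 1),
            1e-6)
  rav0 <- mesh_surface_area(tpl$mM) / mesh_enclosed_volume(tpl$mM)
  rav1 <- mesh_surface_area(km$mM) / mesh_enclosed_volume(km$mM)
  expect_gt(rav1, rav0)
})

test_that("empirical TKR frequency matches the logistic model at n = 2000", {
  cfg <- cohort_config(n_knees = 2000, seed = 31)
  rec <- sample_cohort(cfg, meshes = FALSE)$records
  p <- stats::plogis(cfg$outcome_betas$tkr$b0[1] +
                       cfg$outcome_betas$tkr$b1 * rec$severity)
  phat <- mean(rec$tkr_1yr == "yes")
  se <- sqrt(mean(p) * (1 - mean(p)) / nrow(rec))
  expect_lt(abs(phat - mean(p)), 3.5 * se)
})

test_that("config validation rejects malformed inputs", {
  expect_error(cohort_config(grade_thresholds = list(
    klg = c(0.4, 0.2, 0.6, 0.8), mjsn = c(0.45, 0.65, 0.85),
    ljsn = c(0.55, 0.75, 0.9))), "ascending")
  expect_error(cohort_config(mode_sd_mm = c(1, 2, 3, 4, 5)), "descending")
  expect_error(cohort_config(voxel_spacing_mm = c(1, 0, 1)), "positive")
})

test_that("left knees are mirrored and standardize_side undoes it", {
  cfg <- cohort_config(n_knees = 12, seed = 77)
  co <- sample_cohort(cfg)
  left <- which(co$records$side == "left")[1]
  expect_false(is.na(left))
  m <- co$meshes[[left]]$mM
  # medial meniscus of a left knee sits at negative ML in image frame
  expect_lt(mean(m$vertices[, 1]), 0)
  std <- standardize_side(co$meshes[[left]], "left")
  expect_gt(mean(std$mM$vertices[, 1]), 0)
  expect_gt(mesh_enclosed_volume(std$mM), 0)
})
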