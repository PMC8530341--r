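# Shared fixtures: analytic solids, constructed label volumes, small configs.

# Closed axis-aligned box mesh [a, b]^3 (or per-axis ranges), outward winding.
box_mesh <- function(xr = c(0, 10), yr = xr, zr = xr) {
  v <- as.matrix(expand.grid(xr, yr, zr))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
    c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
    c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6)
  )
  m <- surface_mesh(v, f)
  if (mesh_enclosed_volume(m) < 0) m <- surface_mesh(v, f[, c(1, 3, 2)])
  m
}

# Binary sphere label volume: radius mm, spacing mm, given label.
sphere_volume <- function(radius = 10, spacing = 0.5, label = 6L, pad = 8L) {
  n <- as.integer(2 * radius / spacing) + 2L * pad
  ctr <- (n - 1) / 2 * spacing
  g <- (seq_len(n) - 1) * spacing - ctr
  d2 <- outer(outer(g^2, g^2, "+"), g^2, "+")
  arr <- array(as.integer(d2 <= radius^2) * label, dim = c(n, n, n))
  label_volume(arr, rep(spacing, 3L))
}

# Label volume with a rectangular tibial "plateau" (TB), a cartilage slab
# (mTC or lTC) and a meniscus block shifted `shift_vox` voxels past the
# plateau outer edge on the requested compartment's outer side.
constructed_extrusion_volume <- function(shift_vox = 0L, spacing = 0.5,
                                         compartment = "medial",
                                         side = "right") {
  nx <- 60L; ny <- 30L; nz <- 16L
  arr <- array(0L, c(nx, ny, nz))
  arr[10:50, 5:25, 2:6] <- 2L # TB plateau footprint: x index 10..50
  tc_lab <- if (compartment == "medial") 4L else 5L
  men_lab <- if (compartment == "medial") 6L else 7L
  arr[20:45, 8:22, 7:8] <- tc_lab
  # outer side: medial & right => +x
  medial_dir <- if (side == "right") 1L else -1L
  outer_pos <- (compartment == "medial") == (medial_dir == 1L)
  if (outer_pos) {
    x0 <- 38L + shift_vox; x1 <- 50L + shift_vox
  } else {
    x0 <- 10L - shift_vox; x1 <- 22L - shift_vox
  }
  arr[x0:x1, 9:21, 10:12] <- men_lab
  label_volume(arr, rep(spacing, 3L), side = side)
}

# Cohort configuration with every severity effect switched off except those
# supplied, no grade noise, no missing labels, no shape modes.
planted_config <- function(n_knees = 2L, seed = 1L, spacing = 0.5, ...) {
  effects <- list(cartilage_shrink = 0, extrusion_mm_medial = 0,
                  extrusion_mm_lateral = 0, flatten_medial = 0,
                  flatten_lateral = 0, bone_bump_mm_fb = 0, bone_bump_mm_tb = 0)
  effects[names(list(...))] <- list(...)
  cohort_config(n_knees = n_knees, seed = seed,
                voxel_spacing_mm = rep(spacing, 3L),
                n_shape_modes = 0L, mode_sd_mm = numeric(0L),
                severity_effects = effects,
                structure_severity_sd = 0,
                grade_noise_sd = 0, label_na_rate = 0)
}

# Random rigid motion applied to a vertex array (seeded by caller).
random_rigid <- function(v) {
  th <- stats::runif(3, -pi, pi)
  rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
  rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  sweep(v %*% (rx %*% ry %*% rz), 2, stats::runif(3, -20, 20), "+")
}

# Corresponded cohort generated from planted orthonormal modes.
make_planted_set <- function(n, sds, structure = "mM", seed = 7,
                             rigid = TRUE) {
  tpl <- build_templates()[[structure]]
  modes <- structure_modes(tpl, length(sds), mode_seed = 99)
  set.seed(seed)
  shapes <- lapply(seq_len(n), function(i) {
    coefs <- stats::rnorm(length(sds), 0, sds)
    v <- tpl$vertices + matrix(modes %*% coefs, ncol = 3)
    if (rigid) random_rigid(v) else v
  })
  list(set = corresponded_shapes(structure, tpl$faces, shapes),
       modes = modes, template = tpl)
}

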