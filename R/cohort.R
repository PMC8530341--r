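# Synthetic knee cohort generator.
#
# Disease severity is a scalar latent in [0, 1] per knee. Shapes are the
# templates plus (a) smooth random variation modes with per-mode SDs and
# (b) deterministic severity-coupled deformations: cartilage thinning,
# volume-preserving meniscal flattening, medio-lateral meniscal extrusion,
# and marginal bone bumps (osteophyte-like). Ordinal grades are thresholded
# noisy severity; event outcomes follow a logistic link on severity.

#' Configuration of a synthetic knee cohort
#'
#' Validates and returns the full generator configuration. Defaults define
#' the package's reference study conditions; see the methods vignette for
#' the rationale behind each value.
#'
#' @param n_knees number of knees.
#' @param seed integer master seed; the whole cohort is a deterministic
#'   function of the configuration including this seed.
#' @param voxel_spacing_mm length-3 positive voxel spacing for voxelization.
#' @param n_shape_modes number of random variation modes per structure.
#' @param mode_sd_mm strictly descending positive per-mode coefficient SDs
#'   (mm, in the unit-norm mode convention).
#' @param severity_effects named list of severity slopes:
#'   `cartilage_shrink` (volume fraction lost at severity 1),
#'   `extrusion_mm_medial` / `extrusion_mm_lateral` (medio-lateral meniscal
#'   shift in mm per unit severity), `flatten_medial` / `flatten_lateral`
#'   (relative height loss of the meniscus at severity 1, volume-preserving),
#'   `bone_bump_mm_fb` / `bone_bump_mm_tb` (marginal bone bump amplitude in
#'   mm at severity 1).
#' @param grade_thresholds list with strictly ascending severity cut-points
#'   `klg` (length 4), `mjsn`, `ljsn` (length 3 each).
#' @param grade_noise_sd SD of the ordinal reading noise added to severity
#'   before thresholding.
#' @param outcome_betas list with elements `incident_koa` and `tkr`, each a
#'   list of `b0` (length-5 intercepts for horizons 1..5 years, ascending)
#'   and `b1` (severity slope) of the logistic event model.
#' @param structure_severity_sd SD of the per-structure perturbation of the
#'   latent severity: each structure's deformation reads the knee's severity
#'   with independent noise, so different anatomies carry complementary
#'   information (set 0 for perfectly coupled structures).
#' @param height_mean_m,height_sd_m subject height distribution (m).
#' @param label_na_rate fraction of knees with missing ordinal grades.
#' @param visit visit tag attached to every record.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_knees = 300L,
                          seed = 1L,
                          voxel_spacing_mm = c(1, 1, 1),
                          n_shape_modes = 5L,
                          mode_sd_mm = c(4, 3, 2, 1.5, 1),
                          severity_effects = list(
                            cartilage_shrink = 0.35,
                            extrusion_mm_medial = 4,
                            extrusion_mm_lateral = 2,
                            flatten_medial = 0.25,
                            flatten_lateral = 0,
                            bone_bump_mm_fb = 2,
                            bone_bump_mm_tb = 1.5
                          ),
                          grade_thresholds = list(
                            klg = c(0.2, 0.4, 0.6, 0.8),
                            mjsn = c(0.45, 0.65, 0.85),
                            ljsn = c(0.55, 0.75, 0.9)
                          ),
                          grade_noise_sd = 0.05,
                          outcome_betas = list(
                            incident_koa = list(b0 = c(-2.5, -2.2, -1.9, -1.6, -1.3), b1 = 3),
                            tkr = list(b0 = c(-5, -4.5, -4, -3.5, -3), b1 = 5)
                          ),
                          structure_severity_sd = 0.15,
                          height_mean_m = 1.68,
                          height_sd_m = 0.09,
                          label_na_rate = 0.02,
                          visit = "v00") {
  if (n_knees < 1L) stop("n_knees must be >= 1")
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0))
    stop("voxel_spacing_mm must be three positive values")
  if (n_shape_modes > 0L) {
    if (length(mode_sd_mm) != n_shape_modes)
      stop("mode_sd_mm must have length n_shape_modes")
    if (any(mode_sd_mm <= 0) || any(diff(mode_sd_mm) >= 0))
      stop("mode_sd_mm must be strictly descending and positive")
  }
  for (nm in c("klg", "mjsn", "ljsn")) {
    th <- grade_thresholds[[nm]]
    if (is.null(th) || any(diff(th) <= 0))
      stop("grade_thresholds$", nm, " must be strictly ascending")
  }
  if (length(grade_thresholds$klg) != 4L) stop("klg thresholds must have length 4")
  if (length(grade_thresholds$mjsn) != 3L || length(grade_thresholds$ljsn) != 3L)
    stop("JSN thresholds must have length 3")
  for (nm in c("incident_koa", "tkr")) {
    ob <- outcome_betas[[nm]]
    if (is.null(ob$b0) || length(ob$b0) != 5L || is.null(ob$b1))
      stop("outcome_betas$", nm, " must provide b0 (length 5) and b1")
    if (any(diff(ob$b0) < 0))
      stop("outcome_betas$", nm, "$b0 must be non-decreasing over horizons")
  }
  if (structure_severity_sd < 0) stop("structure_severity_sd must be >= 0")
  if (height_mean_m <= 0 || height_sd_m < 0) stop("invalid height parameters")
  if (label_na_rate < 0 || label_na_rate >= 1) stop("label_na_rate must be in [0, 1)")
  structure(list(
    n_knees = as.integer(n_knees), seed = as.integer(seed),
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    n_shape_modes = as.integer(n_shape_modes),
    mode_sd_mm = as.numeric(mode_sd_mm),
    severity_effects = severity_effects,
    grade_thresholds = grade_thresholds,
    grade_noise_sd = grade_noise_sd,
    outcome_betas = outcome_betas,
    structure_severity_sd = structure_severity_sd,
    height_mean_m = height_mean_m, height_sd_m = height_sd_m,
    label_na_rate = label_na_rate, visit = visit
  ), class = "cohort_config")
}

#' Smooth orthonormal variation-mode fields for a structure
#'
#' Builds `k` orthonormal vertex-displacement fields (unit Euclidean norm in
#' the stacked-coordinate convention, x then y then z blocks) from random
#' combinations of low-order polynomial displacement fields, projected
#' orthogonal to the rigid-motion tangent space (translations and
#' linearized rotations) so that Procrustes alignment leaves planted modes
#' intact. Deterministic given the template and `mode_seed`.
#'
#' @param template a [surface_mesh()].
#' @param k number of modes.
#' @param mode_seed RNG seed for the random combination.
#' @return A `3V x k` matrix with orthonormal columns.
#' @export
structure_modes <- function(template, k, mode_seed = 20211021L) {
  v <- template$vertices
  nV <- nrow(v)
  if (k == 0L) return(matrix(0, 3L * nV, 0L))
  ctr <- colMeans(v)
  q <- sweep(v, 2L, ctr)
  q <- q / max(abs(q))
  polys <- cbind(1, q[, 1L], q[, 2L], q[, 3L],
                 q[, 1L]^2, q[, 2L]^2, q[, 3L]^2,
                 q[, 1L] * q[, 2L], q[, 1L] * q[, 3L], q[, 2L] * q[, 3L])
  nb <- ncol(polys)
  basis <- matrix(0, 3L * nV, 3L * nb)
  for (d in 1:3)
    for (b in seq_len(nb)) {
      field <- matrix(0, nV, 3L)
      field[, d] <- polys[, b]
      basis[, (d - 1L) * nb + b] <- as.vector(field)
    }
  # rigid-motion tangent space: 3 translations + 3 linearized rotations
  rig <- matrix(0, 3L * nV, 6L)
  for (d in 1:3) {
    field <- matrix(0, nV, 3L)
    field[, d] <- 1
    rig[, d] <- as.vector(field)
  }
  qc <- sweep(v, 2L, ctr)
  rot <- list(cbind(0, -qc[, 3L], qc[, 2L]),
              cbind(qc[, 3L], 0, -qc[, 1L]),
              cbind(-qc[, 2L], qc[, 1L], 0))
  for (d in 1:3) rig[, 3L + d] <- as.vector(rot[[d]])
  rig <- qr.Q(qr(rig))
  basis <- basis - rig %*% (t(rig) %*% basis)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(mode_seed)
  g <- matrix(stats::rnorm(ncol(basis) * k), ncol(basis), k)
  qr.Q(qr(basis %*% g))[, seq_len(k), drop = FALSE]
}

# Apply severity-coupled deterministic deformations to one knee's meshes
# (right-knee frame). `severity` is a scalar or a vector named by structure
# (per-structure severity reads). Operates on the named mesh list.
deform_knee <- function(meshes, severity, effects) {
  p <- knee_template_info()
  eff <- function(nm) if (is.null(effects[[nm]])) 0 else effects[[nm]]
  sev <- function(st) {
    if (length(severity) == 1L && is.null(names(severity))) return(unname(severity))
    if (!st %in% names(severity)) stop("no severity entry for structure ", st)
    unname(severity[[st]])
  }

  thin <- function(mesh, z_center, factor) {
    v <- mesh$vertices
    v[, 3L] <- z_center + (v[, 3L] - z_center) * factor
    surface_mesh(v, mesh$faces)
  }
  for (nm in c("FC", "mTC", "lTC"))
    meshes[[nm]] <- thin(meshes[[nm]], p[[nm]]$center[3L],
                         1 - eff("cartilage_shrink") * sev(nm))

  men <- function(mesh, info, flatten_slope, shift_mm) {
    v <- mesh$vertices
    f <- 1 - flatten_slope
    if (f != 1) { # volume-preserving: height x f, radial width / f
      dx <- v[, 1L] - info$center[1L]
      dy <- v[, 2L] - info$center[2L]
      r <- sqrt(dx^2 + dy^2)
      rs <- info$radius + (r - info$radius) / f
      scale <- ifelse(r > 1e-9, rs / r, 1)
      v[, 1L] <- info$center[1L] + dx * scale
      v[, 2L] <- info$center[2L] + dy * scale
      v[, 3L] <- info$z_mid + (v[, 3L] - info$z_mid) * f
    }
    v[, 1L] <- v[, 1L] + shift_mm
    surface_mesh(v, mesh$faces)
  }
  meshes$mM <- men(meshes$mM, p$mM, eff("flatten_medial") * sev("mM"),
                   +eff("extrusion_mm_medial") * sev("mM"))
  meshes$lM <- men(meshes$lM, p$lM, eff("flatten_lateral") * sev("lM"),
                   -eff("extrusion_mm_lateral") * sev("lM"))

  bump <- function(mesh, sites, sigma, amp_mm) {
    if (amp_mm == 0) return(mesh)
    v <- mesh$vertices
    rad <- sqrt(v[, 1L]^2 + v[, 2L]^2)
    dirx <- ifelse(rad > 1e-9, v[, 1L] / rad, 0)
    diry <- ifelse(rad > 1e-9, v[, 2L] / rad, 0)
    for (i in seq_len(nrow(sites))) {
      d2 <- (v[, 1L] - sites[i, 1L])^2 + (v[, 2L] - sites[i, 2L])^2 +
        (v[, 3L] - sites[i, 3L])^2
      w <- exp(-d2 / (2 * sigma^2)) * amp_mm
      v[, 1L] <- v[, 1L] + w * dirx
      v[, 2L] <- v[, 2L] + w * diry
    }
    surface_mesh(v, mesh$faces)
  }
  meshes$FB <- bump(meshes$FB, p$FB$bump_sites, p$FB$bump_sigma,
                    eff("bone_bump_mm_fb") * sev("FB"))
  meshes$TB <- bump(meshes$TB, p$TB$bump_sites, p$TB$bump_sigma,
                    eff("bone_bump_mm_tb") * sev("TB"))
  meshes
}

#' Sample a synthetic knee cohort
#'
#' Draws per-knee latent severities, shape-mode coefficients, grades and
#' outcomes, and produces the deformed structure meshes per knee. All
#' randomness is driven by `cfg$seed`: identical configurations yield
#' identical cohorts. Left knees are generated in the right-knee frame and
#' mirrored on the medio-lateral axis.
#'
#' @param cfg a [cohort_config()].
#' @param meshes if `FALSE`, only records are generated (fast path for
#'   large-n calibration checks).
#' @return A list with `records` (data frame: one row per knee with side,
#'   height, latent severity, KLG, mJSN, lJSN and event indicators per
#'   horizon), `meshes` (per-knee named lists of [surface_mesh()], or
#'   `NULL`), `templates`, and `config`.
#' @export
sample_cohort <- function(cfg, meshes = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"))
  templates <- build_templates()
  modes <- NULL
  if (meshes && cfg$n_shape_modes > 0L) {
    modes <- lapply(seq_along(templates), function(i)
      structure_modes(templates[[i]], cfg$n_shape_modes,
                      mode_seed = 20211021L + i))
    names(modes) <- names(templates)
  }

  set.seed(cfg$seed)
  n <- cfg$n_knees
  severity <- stats::runif(n)
  side <- sample(c("left", "right"), n, replace = TRUE)
  height <- pmax(1.40, stats::rnorm(n, cfg$height_mean_m, cfg$height_sd_m))

  grade <- function(thresholds) {
    noisy <- severity + stats::rnorm(n, 0, cfg$grade_noise_sd)
    vapply(noisy, function(s) sum(s > thresholds), integer(1L))
  }
  klg <- grade(cfg$grade_thresholds$klg)
  mjsn <- grade(cfg$grade_thresholds$mjsn)
  ljsn <- grade(cfg$grade_thresholds$ljsn)
  if (cfg$label_na_rate > 0) {
    na_mask <- stats::runif(n) < cfg$label_na_rate
    klg[na_mask] <- NA_integer_
    mjsn[na_mask] <- NA_integer_
    ljsn[na_mask] <- NA_integer_
  }

  # one latent uniform per knee and outcome type: nested events over horizons
  u_inc <- stats::runif(n)
  u_tkr <- stats::runif(n)
  rec <- data.frame(
    knee_id = sprintf("K%05d", seq_len(n)),
    visit = cfg$visit, side = side, height_m = height,
    severity = severity, klg = klg, mjsn = mjsn, ljsn = ljsn,
    stringsAsFactors = FALSE
  )
  for (h in 1:5) {
    p_inc <- stats::plogis(cfg$outcome_betas$incident_koa$b0[h] +
                             cfg$outcome_betas$incident_koa$b1 * severity)
    status <- ifelse(u_inc < p_inc, "yes", "no")
    status[!is.na(klg) & klg >= 2L] <- "not_at_risk"
    status[is.na(klg)] <- NA_character_
    rec[[sprintf("inc_koa_%dyr", h)]] <- status
    p_tkr <- stats::plogis(cfg$outcome_betas$tkr$b0[h] +
                             cfg$outcome_betas$tkr$b1 * severity)
    rec[[sprintf("tkr_%dyr", h)]] <- ifelse(u_tkr < p_tkr, "yes", "no")
  }

  mesh_list <- NULL
  if (meshes) {
    coefs <- NULL
    if (cfg$n_shape_modes > 0L)
      coefs <- lapply(names(templates), function(nm)
        matrix(stats::rnorm(n * cfg$n_shape_modes, 0,
                            rep(cfg$mode_sd_mm, each = n)),
               n, cfg$n_shape_modes))
    if (!is.null(coefs)) names(coefs) <- names(templates)
    mesh_list <- vector("list", n)
    for (i in seq_len(n)) {
      km <- templates
      if (cfg$n_shape_modes > 0L) {
        for (nm in names(km)) {
          disp <- modes[[nm]] %*% coefs[[nm]][i, ]
          v <- km[[nm]]$vertices + matrix(disp, ncol = 3L)
          km[[nm]] <- surface_mesh(v, km[[nm]]$faces)
        }
      }
      sev_st <- severity[i]
      if (cfg$structure_severity_sd > 0) {
        sev_st <- pmin(1, pmax(0, severity[i] +
          stats::rnorm(length(km), 0, cfg$structure_severity_sd)))
        names(sev_st) <- names(km)
      }
      km <- deform_knee(km, sev_st, cfg$severity_effects)
      if (side[i] == "left")
        km <- lapply(km, mesh_mirror, axis = 1L)
      mesh_list[[i]] <- km
    }
  }
  list(records = rec, meshes = mesh_list, templates = templates, config = cfg)
}

#' Mirror a left knee's meshes into the right-knee reference frame
#'
#' Statistical shape models are fitted in a single side convention; left
#' knees are reflected on the medio-lateral axis (winding corrected) before
#' model fitting or encoding.
#'
#' @param knee_meshes named list of [surface_mesh()] for one knee.
#' @param side the knee's side.
#' @return The meshes in right-knee convention.
#' @export
standardize_side <- function(knee_meshes, side) {
  if (identical(side, "left")) lapply(knee_meshes, mesh_mirror, axis = 1L)
  else knee_meshes
}
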