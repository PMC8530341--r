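# Direct morphometric (MEAS) features from a labeled knee volume:
# height-normalized volumes, meniscal surface areas and area/volume ratios,
# medio-lateral meniscal extrusion, tibial coverage.

#' Names of the 14 MEAS features
#' @return Character vector of feature column names in canonical order.
#' @export
meas_feature_names <- function() {
  c("V_FC", "V_TC", "V_mTC", "V_lTC", "V_mM", "V_lM",
    "A_mM", "A_lM", "R_AV_mM", "R_AV_lM",
    "E_mM", "E_lM", "TC_mTC", "TC_lTC")
}

#' Height-normalized volume
#'
#' Structure volumes correlate with body size, so raw voxel volumes are
#' divided by subject height. A missing or non-positive height marks the
#' feature missing (`NA`); rows with missing features are excluded at
#' evaluation time.
#'
#' @param raw_mm3 raw volume in mm^3.
#' @param height_m subject height in m.
#' @return Volume in mm^3 per m, or `NA` if the height is unusable.
#' @export
normalized_volume <- function(raw_mm3, height_m) {
  ifelse(is.na(height_m) | height_m <= 0, NA_real_, raw_mm3 / height_m)
}

#' Surface-area-to-volume ratio
#'
#' Flattening at preserved volume increases this ratio, which is why it is
#' tracked for the menisci. Volume is the raw (un-normalized) voxel volume.
#'
#' @param area mm^2.
#' @param volume mm^3.
#' @return Ratio in 1/mm, or `NA` when the volume is not positive.
#' @export
area_volume_ratio <- function(area, volume) {
  ifelse(is.na(volume) | volume <= 0, NA_real_, area / volume)
}

# axial (ML x AP) footprint of a label set: logical [nx, ny]
axial_footprint <- function(vol, labels) {
  d <- dim(vol$array)
  mask <- vol$array %in% labels
  dim(mask) <- c(d[1L] * d[2L], d[3L])
  fp <- rowSums(mask) > 0L
  dim(fp) <- d[1:2]
  fp
}

compartment_structs <- function(compartment) {
  compartment <- match.arg(compartment, c("medial", "lateral"))
  if (compartment == "medial") list(men = "mM", tc = "mTC")
  else list(men = "lM", tc = "lTC")
}

#' Medio-lateral meniscal extrusion
#'
#' Meniscus voxels and the tibial-plateau footprint (tibial bone plus the
#' compartment's tibial cartilage) are projected onto the axial plane. The
#' extrusion is the maximum, over antero-posterior rows containing both
#' footprints, of the medio-lateral overhang of the meniscus outer edge past
#' the plateau outer edge on the compartment's outer side, clamped at zero.
#' The volume's side metadata determines which ML direction is "outer".
#'
#' @param vol a [label_volume()].
#' @param compartment `"medial"` or `"lateral"`.
#' @return Extrusion in mm (>= 0).
#' @export
meniscal_extrusion <- function(vol, compartment) {
  st <- compartment_structs(compartment)
  men_lab <- knee_labels[[st$men]]
  if (!any(vol$array == men_lab)) stop("empty meniscus label: ", st$men)
  if (!any(vol$array == knee_labels[["TB"]])) stop("empty tibial bone label")
  men <- axial_footprint(vol, men_lab)
  plateau <- axial_footprint(vol, c(knee_labels[["TB"]], knee_labels[[st$tc]]))
  medial_dir <- if (vol$side == "right") 1 else -1
  outer_sign <- if (compartment == "medial") medial_dir else -medial_dir
  sx <- vol$spacing_mm[1L]
  xw <- vol$origin[1L] + (seq_len(nrow(men)) - 1L) * sx
  xs <- xw * outer_sign # outer edge = maximum of signed coordinate
  best <- 0
  for (j in seq_len(ncol(men))) {
    mrow <- men[, j]
    prow <- plateau[, j]
    if (!any(mrow) || !any(prow)) next
    over <- max(xs[mrow]) - max(xs[prow])
    if (over > best) best <- over
  }
  max(0, best)
}

#' Tibial coverage by the meniscus
#'
#' Percentage of the compartment tibial-cartilage axial footprint (voxel
#' columns) overlapped by the compartment meniscus footprint.
#'
#' @param vol a [label_volume()].
#' @param compartment `"medial"` or `"lateral"`.
#' @return Coverage in percent, in `[0, 100]`.
#' @export
tibial_coverage <- function(vol, compartment) {
  st <- compartment_structs(compartment)
  tc_lab <- knee_labels[[st$tc]]
  if (!any(vol$array == tc_lab)) stop("empty tibial cartilage label: ", st$tc)
  tc <- axial_footprint(vol, tc_lab)
  men <- axial_footprint(vol, knee_labels[[st$men]])
  100 * sum(tc & men) / sum(tc)
}

#' Compute the 14 MEAS features for one knee
#'
#' Assembles height-normalized voxel volumes (femoral cartilage, total /
#' medial / lateral tibial cartilage, both menisci), meniscal surface areas
#' from extracted boundary surfaces, area-to-volume ratios, medio-lateral
#' meniscal extrusions, and tibial coverages. An absent structure marks its
#' dependent features missing (`NA`) rather than failing.
#'
#' @param vol a [label_volume()].
#' @param height_m subject height in m.
#' @return Named numeric vector of length 14 ([meas_feature_names()]).
#' @export
compute_meas <- function(vol, height_m) {
  out <- stats::setNames(rep(NA_real_, 14L), meas_feature_names())
  vol_of <- function(lab) {
    v <- voxel_volume(vol, lab)
    if (v > 0) v else NA_real_
  }
  v_fc <- vol_of("FC"); v_mtc <- vol_of("mTC"); v_ltc <- vol_of("lTC")
  v_mm <- vol_of("mM"); v_lm <- vol_of("lM")
  v_tc <- if (is.na(v_mtc) && is.na(v_ltc)) NA_real_ else sum(v_mtc, v_ltc, na.rm = TRUE)
  out["V_FC"] <- normalized_volume(v_fc, height_m)
  out["V_TC"] <- normalized_volume(v_tc, height_m)
  out["V_mTC"] <- normalized_volume(v_mtc, height_m)
  out["V_lTC"] <- normalized_volume(v_ltc, height_m)
  out["V_mM"] <- normalized_volume(v_mm, height_m)
  out["V_lM"] <- normalized_volume(v_lm, height_m)
  area_of <- function(lab) {
    tryCatch(mesh_surface_area(extract_surface(vol, lab)),
             error = function(e) NA_real_)
  }
  out["A_mM"] <- area_of("mM")
  out["A_lM"] <- area_of("lM")
  out["R_AV_mM"] <- area_volume_ratio(out["A_mM"], v_mm)
  out["R_AV_lM"] <- area_volume_ratio(out["A_lM"], v_lm)
  out["E_mM"] <- tryCatch(meniscal_extrusion(vol, "medial"), error = function(e) NA_real_)
  out["E_lM"] <- tryCatch(meniscal_extrusion(vol, "lateral"), error = function(e) NA_real_)
  out["TC_mTC"] <- tryCatch(tibial_coverage(vol, "medial"), error = function(e) NA_real_)
  out["TC_lTC"] <- tryCatch(tibial_coverage(vol, "lateral"), error = function(e) NA_real_)
  out
}
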