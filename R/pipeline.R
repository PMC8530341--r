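# Pipeline glue: feature-table assembly, the standard task grid, tidy
# result aggregation, and run manifests.

hash_object <- function(obj) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 10,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

ldse_col_names <- function(structure, k) {
  sprintf("ldse_%s_%03d", tolower(structure), seq_len(k) - 1L)
}

#' Assemble the per-knee feature table
#'
#' Voxelizes every knee's meshes, computes the 14 MEAS features, and (by
#' default) fits per-structure shape models on the cohort and appends the
#' LDSE coefficient blocks (`ldse_fb_000` ...). Rows are keyed by
#' `(knee_id, visit)`; missing features are `NA`.
#'
#' @param cohort result of [sample_cohort()] with meshes.
#' @param include_ldse append LDSE coefficient blocks.
#' @param n_coef LDSE coefficients per structure (default 300; capped by the
#'   cohort size).
#' @param spacing_mm voxel spacing for the MEAS computation (defaults to
#'   the cohort configuration).
#' @param progress print a dot every 25 knees.
#' @return Data frame with key columns, 14 MEAS columns, optional LDSE
#'   blocks, and a `config_hash` provenance attribute/column.
#' @export
build_feature_table <- function(cohort, include_ldse = TRUE, n_coef = 300L,
                                spacing_mm = NULL, progress = FALSE) {
  if (is.null(spacing_mm)) spacing_mm <- cohort$config$voxel_spacing_mm
  rec <- cohort$records
  n <- nrow(rec)
  meas <- matrix(NA_real_, n, 14L, dimnames = list(NULL, meas_feature_names()))
  for (i in seq_len(n)) {
    vol <- voxelize(cohort$meshes[[i]], spacing_mm, side = rec$side[i])
    meas[i, ] <- compute_meas(vol, rec$height_m[i])
    if (progress && i %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  out <- cbind(rec[, c("knee_id", "visit")], as.data.frame(meas))
  if (include_ldse) {
    enc <- ldse_encode_cohort(cohort, n_coef = n_coef)
    for (st in names(enc$coefs)) {
      cm <- enc$coefs[[st]]
      colnames(cm) <- ldse_col_names(st, ncol(cm))
      out <- cbind(out, as.data.frame(cm))
    }
    attr(out, "ldse_models") <- enc$models
  }
  out$config_hash <- hash_object(unclass(cohort$config))
  out
}

#' The standard evaluation task grid
#'
#' Classification of Kellgren-Lawrence grade (5-class, 3-class, binary
#' non-arthritic vs diseased, 0 vs 2, 0 vs 4) and of medial/lateral joint
#' space narrowing (4-class each), plus prediction of incident knee
#' osteoarthritis and total knee replacement within 1..5 years, crossed with
#' the requested feature sets.
#'
#' @param feature_sets character vector of feature set names.
#' @param horizons prediction horizons in years.
#' @param include character subset of `c("klg", "jsn", "incident_koa",
#'   "tkr")` selecting task families.
#' @return List of [task_spec()] objects.
#' @export
standard_task_grid <- function(feature_sets = c("MEAS", "LDSE-FB", "LDSE-TB",
                                                "LDSE-mM", "LDSE-lM",
                                                "LDSE-COMB", "LDSE-COMB + MEAS"),
                               horizons = 1:5,
                               include = c("klg", "jsn", "incident_koa", "tkr")) {
  tasks <- list()
  add <- function(t) tasks[[length(tasks) + 1L]] <<- t
  for (fs in feature_sets) {
    if ("klg" %in% include) {
      add(task_spec("classification", "klg", list(0, 1, 2, 3, 4), feature_set = fs))
      add(task_spec("classification", "klg", list(0:1, 2, 3:4), feature_set = fs))
      add(task_spec("classification", "klg", list(0:1, 2:4), feature_set = fs))
      add(task_spec("classification", "klg", list(0, 2), feature_set = fs))
      add(task_spec("classification", "klg", list(0, 4), feature_set = fs))
    }
    if ("jsn" %in% include) {
      add(task_spec("classification", "mjsn", list(0, 1, 2, 3), feature_set = fs))
      add(task_spec("classification", "ljsn", list(0, 1, 2, 3), feature_set = fs))
    }
    for (h in horizons) {
      if ("incident_koa" %in% include)
        add(task_spec("prediction", "incident_koa", horizon_years = h, feature_set = fs))
      if ("tkr" %in% include)
        add(task_spec("prediction", "tkr", horizon_years = h, feature_set = fs))
    }
  }
  tasks
}

#' Run a grid of tasks and tidy the results
#'
#' Tasks that are infeasible on the given cohort (e.g. an empty class after
#' filtering) are reported with `NA` metrics instead of aborting the grid.
#'
#' @param feature_table from [build_feature_table()].
#' @param records cohort records aligned with the table.
#' @param tasks list of [task_spec()].
#' @param cfg a [split_config()].
#' @return Data frame: one row per task x feature set x metric with mean,
#'   sd, n_included, n_repeats.
#' @export
run_task_grid <- function(feature_table, records, tasks, cfg) {
  rows <- list()
  for (task in tasks) {
    res <- tryCatch(run_task(feature_table, records, task, cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        task = task_name(task), feature_set = task$feature_set,
        metric = "BA", mean = NA_real_, sd = NA_real_,
        n_included = NA_integer_, n_repeats = cfg$n_repeats,
        note = conditionMessage(res))
      next
    }
    metrics <- list(BA = c(res$ba_mean, res$ba_sd))
    if (res$kind == "classification")
      metrics$weighted_kappa <- c(res$kappa_mean, res$kappa_sd)
    if (!is.na(res$auc_mean))
      metrics$AUC <- c(res$auc_mean, res$auc_sd)
    for (mname in names(metrics)) {
      rows[[length(rows) + 1L]] <- data.frame(
        task = res$task, feature_set = res$feature_set, metric = mname,
        mean = metrics[[mname]][1L], sd = metrics[[mname]][2L],
        n_included = res$n_included, n_repeats = res$n_repeats,
        note = "")
    }
  }
  do.call(rbind, rows)
}

#' Build a run manifest
#'
#' Captures everything needed to regenerate outputs byte-for-byte: package
#' version, configuration snapshot, master seed, and input checksums.
#' Wall-clock timestamps are omitted by default so re-runs are
#' byte-identical.
#'
#' @param config configuration object (list-like).
#' @param seed master seed.
#' @param inputs named character vector of input file paths to checksum.
#' @param timestamps include the wall-clock time.
#' @return List (serializable to JSON).
#' @export
run_manifest <- function(config, seed, inputs = character(0L),
                         timestamps = FALSE) {
  list(
    tool = "kneemorph",
    version = as.character(utils::packageVersion("kneemorph")),
    seed = seed,
    config = unclass(config),
    config_hash = hash_object(unclass(config)),
    input_checksums = if (length(inputs)) as.list(tools::md5sum(inputs)) else list(),
    timestamp = if (timestamps) format(Sys.time(), tz = "UTC") else NULL
  )
}

#' Run the full synthetic pipeline
#'
#' Generation, feature computation, shape-model fitting/encoding, and the
#' evaluation grid, optionally writing the tidy results CSV and a JSON
#' manifest to `out_dir`.
#'
#' @param cohort_cfg a [cohort_config()].
#' @param tasks list of [task_spec()]; default grid over all families.
#' @param split_cfg a [split_config()].
#' @param out_dir optional output directory.
#' @return List with `feature_table`, `records`, `results`, `manifest`.
#' @export
run_pipeline <- function(cohort_cfg,
                         tasks = standard_task_grid(),
                         split_cfg = split_config(),
                         out_dir = NULL) {
  cohort <- sample_cohort(cohort_cfg)
  feature_table <- build_feature_table(cohort)
  results <- run_task_grid(feature_table, cohort$records, tasks, split_cfg)
  manifest <- run_manifest(cohort_cfg, cohort_cfg$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    utils::write.csv(feature_table, file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(cohort$records, file.path(out_dir, "records.csv"), row.names = FALSE)
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                digits = 10, null = "null"),
               file.path(out_dir, "manifest.json"))
  }
  list(feature_table = feature_table, records = cohort$records,
       results = results, manifest = manifest)
}
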