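# Evaluation harness: task construction, balanced Monte-Carlo
# cross-validation with linear SVMs, metric aggregation, and
# logistic-regression odds ratios.

#' Specification of a classification or prediction task
#'
#' @param kind `"classification"` (ordinal grades) or `"prediction"`
#'   (binary event within a horizon).
#' @param label_source `"klg"`, `"mjsn"`, `"ljsn"` for classification;
#'   `"incident_koa"` or `"tkr"` for prediction.
#' @param groups list of disjoint grade vectors defining the classes, e.g.
#'   `list(0:1, 2, 3:4)`; required for classification.
#' @param horizon_years event horizon (1..5); required for prediction.
#' @param feature_set feature set name: `"MEAS"`, `"LDSE-FB"`, `"LDSE-TB"`,
#'   `"LDSE-mM"`, `"LDSE-lM"`, `"LDSE-COMB"`, or any of these plus
#'   `" + MEAS"`.
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(kind, label_source, groups = NULL, horizon_years = NULL,
                      feature_set = "MEAS") {
  kind <- match.arg(kind, c("classification", "prediction"))
  label_source <- match.arg(label_source,
                            c("klg", "mjsn", "ljsn", "incident_koa", "tkr"))
  if (kind == "classification") {
    if (is.null(groups)) stop("classification tasks require groups")
    if (!is.null(horizon_years)) stop("horizon_years only applies to predictions")
    all_grades <- unlist(groups)
    if (anyDuplicated(all_grades)) stop("groups must be disjoint")
  } else {
    if (is.null(horizon_years) || !horizon_years %in% 1:5)
      stop("prediction tasks require horizon_years in 1..5")
    if (!label_source %in% c("incident_koa", "tkr"))
      stop("prediction label source must be incident_koa or tkr")
  }
  structure(list(kind = kind, label_source = label_source, groups = groups,
                 horizon_years = horizon_years, feature_set = feature_set),
            class = "task_spec")
}

#' Name of a task (for reporting)
#' @param task a [task_spec()].
#' @return Character scalar.
#' @export
task_name <- function(task) {
  if (task$kind == "classification") {
    grp <- vapply(task$groups, function(g)
      if (length(g) > 1L) paste0("[", paste(g, collapse = ";"), "]") else as.character(g),
      character(1L))
    paste0(toupper(task$label_source), " ", paste(grp, collapse = " vs "))
  } else {
    sprintf("%s within %d yr", task$label_source, task$horizon_years)
  }
}

#' Build class labels and the inclusion mask for a task
#'
#' Classification: grades are mapped to group indices (0-based); knees with
#' a missing grade are excluded. Incident knee osteoarthritis: the risk set
#' is knees with baseline KLG < 2; an at-risk knee is positive if it reaches
#' KLG >= 2 with joint space narrowing within the horizon. Total knee
#' replacement: positive if the event occurs within the horizon.
#'
#' @param records cohort records data frame (see [sample_cohort()]).
#' @param task a [task_spec()].
#' @return List with `labels` (integer class per knee, `NA` when excluded)
#'   and `include` (logical mask).
#' @export
build_task_labels <- function(records, task) {
  n <- nrow(records)
  labels <- rep(NA_integer_, n)
  if (task$kind == "classification") {
    grades <- records[[task$label_source]]
    for (g in seq_along(task$groups))
      labels[grades %in% task$groups[[g]]] <- g - 1L
  } else if (task$label_source == "incident_koa") {
    col <- sprintf("inc_koa_%dyr", task$horizon_years)
    status <- records[[col]]
    at_risk <- !is.na(status) & status != "not_at_risk" &
      !is.na(records$klg) & records$klg < 2L
    labels[at_risk & status == "no"] <- 0L
    labels[at_risk & status == "yes"] <- 1L
  } else {
    col <- sprintf("tkr_%dyr", task$horizon_years)
    status <- records[[col]]
    labels[!is.na(status) & status == "no"] <- 0L
    labels[!is.na(status) & status == "yes"] <- 1L
  }
  include <- !is.na(labels)
  if (length(unique(labels[include])) < 2L)
    stop("task infeasible after filtering: ", task_name(task))
  list(labels = labels, include = include)
}

#' Derive incident knee osteoarthritis from longitudinal records
#'
#' For cohorts carrying several visits per knee: the index visit is each
#' knee's earliest visit; knees with index KLG >= 2 (or missing KLG) are not
#' at risk. An at-risk knee is positive within `horizon_years` if any later
#' visit no more than that many years after the index shows KLG >= 2
#' together with medial or lateral joint space narrowing >= 1. Visit tags
#' are `"v<months>"` (e.g. `"v24"` = 2 years).
#'
#' @param records multi-visit records data frame.
#' @param horizon_years horizon in years (1..5).
#' @return Character vector per row of `records`: `"yes"`, `"no"`, or
#'   `"not_at_risk"` for index-visit rows; `NA` for later visits.
#' @export
derive_incident_koa <- function(records, horizon_years) {
  months <- as.numeric(sub("^v", "", records$visit))
  if (anyNA(months)) stop("visit tags must look like v00, v12, ...")
  out <- rep(NA_character_, nrow(records))
  for (id in unique(records$knee_id)) {
    rows <- which(records$knee_id == id)
    rows <- rows[order(months[rows])]
    idx <- rows[1L]
    base_klg <- records$klg[idx]
    if (is.na(base_klg)) next
    if (base_klg >= 2L) {
      out[idx] <- "not_at_risk"
      next
    }
    later <- rows[-1L]
    later <- later[(months[later] - months[idx]) / 12 <= horizon_years]
    hit <- any(!is.na(records$klg[later]) & records$klg[later] >= 2L &
                 ((!is.na(records$mjsn[later]) & records$mjsn[later] >= 1L) |
                    (!is.na(records$ljsn[later]) & records$ljsn[later] >= 1L)))
    out[idx] <- if (hit) "yes" else "no"
  }
  out
}

#' Monte-Carlo split configuration
#'
#' @param n_repeats number of random splits (default 1000).
#' @param test_fraction held-out fraction (default 0.10).
#' @param seed master seed; each repeat draws from its own child seed so any
#'   single repeat is reproducible in isolation.
#' @return An object of class `split_config`.
#' @export
split_config <- function(n_repeats = 1000L, test_fraction = 0.10, seed = 1L) {
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  structure(list(n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "split_config")
}

#' Balanced Monte-Carlo train/test splits
#'
#' Per repeat: every class is subsampled without replacement to the minority
#' class size, then split into train and test stratified by class. Repeats
#' are independent draws.
#'
#' @param labels class label vector (no `NA`).
#' @param cfg a [split_config()].
#' @return List of `n_repeats` lists with integer `train` and `test` indices
#'   into `labels`.
#' @export
balanced_monte_carlo <- function(labels, cfg) {
  stopifnot(inherits(cfg, "split_config"))
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes")
  idx_by_class <- lapply(classes, function(cl) which(labels == cl))
  m <- min(lengths(idx_by_class))
  if (m < 10L)
    stop("minority class has ", m, " cases (< 10); split degenerate")
  n_test <- max(1L, round(cfg$test_fraction * m))
  set.seed(cfg$seed)
  child_seeds <- sample.int(.Machine$integer.max, cfg$n_repeats)
  lapply(child_seeds, function(s) {
    set.seed(s)
    train <- integer(0L)
    test <- integer(0L)
    for (ic in idx_by_class) {
      sub <- sample(ic, m)
      test <- c(test, sub[seq_len(n_test)])
      train <- c(train, sub[(n_test + 1L):m])
    }
    list(train = train, test = test)
  })
}

#' Min-max normalization fitted on the training split
#'
#' Per feature: `z = (x - train_min) / (train_max - train_min)`; the same
#' transform is applied to the other split, so held-out values may fall
#' outside `[0, 1]`. A constant training feature maps to zero everywhere
#' (with a warning).
#'
#' @param train,other numeric matrices with identical columns.
#' @param warn_constant warn when a constant training feature is found (the
#'   evaluation loop disables this, since zero-padded encoding blocks are
#'   constant by construction).
#' @return List with normalized `train` and `other`.
#' @export
minmax_normalize <- function(train, other, warn_constant = TRUE) {
  lo <- apply(train, 2L, min)
  hi <- apply(train, 2L, max)
  rng <- hi - lo
  if (any(rng == 0)) {
    if (warn_constant)
      warning("constant training feature(s) mapped to 0: ",
              paste(which(rng == 0), collapse = ", "))
    rng[rng == 0] <- 1
  }
  norm <- function(x) sweep(sweep(x, 2L, lo), 2L, rng, "/")
  list(train = norm(train), other = norm(other))
}

# orient a binary decision score so that higher favors `positive`
oriented_scores <- function(fit, x, positive) {
  pred <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  score <- as.numeric(dv[, 1L])
  favored <- strsplit(colnames(dv)[1L], "/")[[1L]][1L]
  if (favored != positive) score <- -score
  list(labels = as.character(pred), scores = score)
}

#' Linear support vector machine: fit and predict
#'
#' L2-regularized linear SVM at default regularization strength
#' (`cost = 1`), without internal rescaling (features are min-max normalized
#' upstream). Binary problems return one decision score per case, oriented
#' so that higher favors the larger class label; multi-class problems use
#' one-vs-rest with the arg-max decision rule.
#'
#' @param train_x,train_y training features and labels.
#' @param test_x held-out features.
#' @return List with `labels` (predicted classes, character) and `scores`
#'   (binary: oriented decision values; multi-class: `n x k` margin matrix).
#' @export
fit_predict_linear_svm <- function(train_x, train_y, test_x) {
  classes <- sort(unique(as.character(train_y)))
  if (length(classes) < 2L) stop("single-class training set")
  if (length(classes) == 2L) {
    y <- factor(as.character(train_y), levels = classes)
    fit <- e1071::svm(train_x, y, kernel = "linear", cost = 1, scale = FALSE)
    out <- oriented_scores(fit, test_x, positive = classes[2L])
    return(out)
  }
  # one-vs-rest
  margins <- matrix(0, nrow(test_x), length(classes),
                    dimnames = list(NULL, classes))
  for (cl in classes) {
    y <- factor(ifelse(as.character(train_y) == cl, "pos", "rest"),
                levels = c("rest", "pos"))
    fit <- e1071::svm(train_x, y, kernel = "linear", cost = 1, scale = FALSE)
    margins[, cl] <- oriented_scores(fit, test_x, positive = "pos")$scores
  }
  list(labels = classes[max.col(margins, ties.method = "first")],
       scores = margins)
}

#' Logistic-regression odds ratios for event prediction
#'
#' Maximum-likelihood logistic regression of a binary outcome on the
#' supplied features, standardized to unit SD beforehand so odds ratios are
#' comparable across features with different units. Returns the per-SD odds
#' ratio with its Wald 95% confidence interval for every feature. Perfect
#' separation is flagged per feature and its interval reported as
#' unbounded.
#'
#' @param features data frame or matrix of numeric features (e.g. the 14
#'   MEAS columns).
#' @param outcome binary outcome vector (logical or 0/1).
#' @return Data frame with columns `feature`, `or`, `ci_low`, `ci_high`,
#'   `separated`.
#' @export
logistic_odds_ratios <- function(features, outcome) {
  x <- as.data.frame(features)
  outcome <- as.numeric(as.logical(outcome))
  keep <- stats::complete.cases(x) & !is.na(outcome)
  x <- x[keep, , drop = FALSE]
  outcome <- outcome[keep]
  if (length(unique(outcome)) < 2L)
    stop("outcome must contain both classes")
  xs <- as.data.frame(scale(x))
  dat <- cbind(xs, .y = outcome)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged) stop("logistic regression did not converge")
  est <- stats::coef(fit)[-1L]
  se <- sqrt(diag(stats::vcov(fit)))[-1L]
  flag <- separated | se > 50
  ci_low <- exp(est - 1.96 * se)
  ci_high <- exp(est + 1.96 * se)
  ci_low[flag] <- 0
  ci_high[flag] <- Inf
  data.frame(feature = names(est), or = exp(est),
             ci_low = ci_low, ci_high = ci_high,
             separated = flag, row.names = NULL)
}

#' Resolve a feature-set name to a feature matrix
#'
#' Understands `"MEAS"`, the per-structure encodings `"LDSE-FB"`,
#' `"LDSE-TB"`, `"LDSE-mM"`, `"LDSE-lM"`, the combined encoding
#' `"LDSE-COMB"` (first 75 coefficients of FB, TB, mM, lM, zero-padded),
#' and any `"<set> + MEAS"` concatenation.
#'
#' @param feature_table feature table from [build_feature_table()].
#' @param name feature set name.
#' @return Numeric matrix (rows = knees).
#' @export
resolve_feature_set <- function(feature_table, name) {
  name <- trimws(name)
  if (grepl("\\+", name)) {
    parts <- trimws(strsplit(name, "\\+")[[1L]])
    return(do.call(cbind, lapply(parts, resolve_feature_set,
                                 feature_table = feature_table)))
  }
  ldse_block <- function(code, block = NULL) {
    cols <- grep(sprintf("^ldse_%s_", tolower(code)), names(feature_table),
                 value = TRUE)
    if (!length(cols)) stop("no LDSE columns for structure ", code)
    m <- as.matrix(feature_table[, cols, drop = FALSE])
    if (!is.null(block)) {
      if (ncol(m) < block)
        m <- cbind(m, matrix(0, nrow(m), block - ncol(m)))
      m <- m[, seq_len(block), drop = FALSE]
    }
    m
  }
  switch(name,
    "MEAS" = as.matrix(feature_table[, meas_feature_names(), drop = FALSE]),
    "LDSE-FB" = ldse_block("fb"),
    "LDSE-TB" = ldse_block("tb"),
    "LDSE-mM" = ldse_block("mm"),
    "LDSE-lM" = ldse_block("lm"),
    "LDSE-COMB" = cbind(ldse_block("fb", 75L), ldse_block("tb", 75L),
                        ldse_block("mm", 75L), ldse_block("lm", 75L)),
    stop("unknown feature set: ", name)
  )
}

#' Run one evaluation task
#'
#' Builds the task labels, drops knees with a missing label or any missing
#' feature, and runs balanced Monte-Carlo cross-validation of a linear SVM:
#' per repeat, classes are subsampled to the minority size, split into
#' train/test, min-max normalized on the training split, fitted and scored.
#' Classification tasks aggregate balanced accuracy and weighted kappa;
#' binary prediction tasks additionally aggregate ROC AUC from the decision
#' margins.
#'
#' @param feature_table feature table from [build_feature_table()] aligned
#'   row-wise with `records`.
#' @param records cohort records.
#' @param task a [task_spec()].
#' @param cfg a [split_config()].
#' @param kappa_weights weighting scheme passed to [weighted_kappa()].
#' @return An `eval_result`: list with `task`, `feature_set`, per-repeat
#'   metric vectors (`ba`, `kappa`, `auc`), their means and SDs, and the
#'   inclusion bookkeeping (`n_included`, `n_dropped`).
#' @export
run_task <- function(feature_table, records, task, cfg,
                     kappa_weights = "linear") {
  stopifnot(nrow(feature_table) == nrow(records))
  x_all <- resolve_feature_set(feature_table, task$feature_set)
  lab <- build_task_labels(records, task)
  complete <- stats::complete.cases(x_all)
  include <- lab$include & complete
  y <- lab$labels[include]
  x <- x_all[include, , drop = FALSE]
  if (length(unique(y)) < 2L)
    stop("task infeasible after filtering: ", task_name(task))
  splits <- balanced_monte_carlo(y, cfg)
  binary <- length(unique(y)) == 2L
  ba <- kap <- auc <- rep(NA_real_, length(splits))
  for (r in seq_along(splits)) {
    sp <- splits[[r]]
    nm <- minmax_normalize(x[sp$train, , drop = FALSE],
                           x[sp$test, , drop = FALSE], warn_constant = FALSE)
    pred <- fit_predict_linear_svm(nm$train, y[sp$train], nm$other)
    truth <- y[sp$test]
    ba[r] <- balanced_accuracy(truth, pred$labels)
    kap[r] <- tryCatch(
      weighted_kappa(as.integer(truth), as.integer(pred$labels),
                     weights = kappa_weights,
                     levels = sort(unique(y))),
      error = function(e) NA_real_)
    if (binary)
      auc[r] <- roc_auc(pred$scores, truth == max(y))
  }
  structure(list(
    task = task_name(task), feature_set = task$feature_set,
    kind = task$kind, ba = ba, kappa = kap, auc = auc,
    ba_mean = mean(ba), ba_sd = stats::sd(ba),
    kappa_mean = mean(kap, na.rm = TRUE), kappa_sd = stats::sd(kap, na.rm = TRUE),
    auc_mean = if (binary) mean(auc) else NA_real_,
    auc_sd = if (binary) stats::sd(auc) else NA_real_,
    n_included = sum(include), n_dropped = sum(!include),
    n_repeats = length(splits)
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("%s | %s: BA %.2f +/- %.2f", x$task, x$feature_set,
              x$ba_mean, x$ba_sd))
  if (!is.na(x$kappa_mean)) cat(sprintf(", kappa %.2f +/- %.2f", x$kappa_mean, x$kappa_sd))
  if (!is.na(x$auc_mean)) cat(sprintf(", AUC %.2f +/- %.2f", x$auc_mean, x$auc_sd))
  cat(sprintf(" (n=%d, %d repeats)\n", x$n_included, x$n_repeats))
  invisible(x)
}
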