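test_that("classification labels map grades to groups and drop NA", {
  rec <- data.frame(klg = c(0, 1, 2, 3, 4, NA))
  task <- task_spec("classification", "klg", list(0:1, 2, 3:4))
  lab <- build_task_labels(rec, task)
  expect_equal(lab$labels[1:5], c(0, 0, 1, 2, 2))
  expect_false(lab$include[6])
  expect_error(task_spec("classification", "klg", list(0:1, 1:2)), "disjoint")
})

test_that("incident-KOA risk set excludes prevalent disease", {
  rec <- data.frame(klg = c(0, 3, 1, NA),
                    inc_koa_1yr = c("yes", "not_at_risk", "no", NA))
  lab <- build_task_labels(rec, task_spec("prediction", "incident_koa",
                                          horizon_years = 1))
  expect_equal(lab$labels[1], 1L)
  expect_false(lab$include[2]) # KLG 3 at index: not in the risk set
  expect_equal(lab$labels[3], 0L)
  expect_false(lab$include[4])
})

test_that("incidence can be derived from longitudinal visits", {
  rec <- data.frame(
    knee_id = c("A", "A", "B", "C", "C"),
    visit = c("v00", "v12", "v00", "v00", "v12"),
    klg = c(0, 2, 3, 0, 1),
    mjsn = c(0, 1, 2, 0, 0),
    ljsn = c(0, 0, 0, 0, 0))
  inc <- derive_incident_koa(rec, 1)
  expect_equal(inc[1], "yes")          # KLG 0 -> KLG 2 with mJSN 1 in 1 yr
  expect_equal(inc[3], "not_at_risk")  # KLG 3 at index
  expect_equal(inc[4], "no")           # KLG 1 without JSN at follow-up
  expect_true(is.na(inc[2]))           # follow-up rows carry no status
  # beyond the horizon: the v12 transition does not count for 0 years... but
  # a 2-year horizon still sees it
  expect_equal(derive_incident_koa(rec, 2)[1], "yes")
})

test_that("balanced splits equalize classes and stay disjoint", {
  labels <- rep(c(0, 1), times = c(500, 50))
  splits <- balanced_monte_carlo(labels, split_config(n_repeats = 4, seed = 2))
  for (sp in splits) {
    expect_length(sp$train, 90)
    expect_length(sp$test, 10)
    expect_equal(as.integer(table(labels[sp$test])), c(5L, 5L))
    expect_equal(as.integer(table(labels[sp$train])), c(45L, 45L))
    expect_length(intersect(sp$train, sp$test), 0)
  }
  again <- balanced_monte_carlo(labels, split_config(n_repeats = 4, seed = 2))
  expect_identical(splits, again)
  expect_error(balanced_monte_carlo(rep(c(0, 1), times = c(50, 9)),
                                    split_config()), "minority")
})

test_that("min-max normalization follows the training range", {
  train <- cbind(c(2, 10, 6))
  nm <- minmax_normalize(train, cbind(c(6, 12)))
  expect_equal(nm$train[, 1], c(0, 1, 0.5))
  expect_equal(nm$other[, 1], c(0.5, 1.25)) # out-of-range allowed
  expect_warning(res <- minmax_normalize(cbind(rep(3, 4)), cbind(5)),
                 "constant")
  expect_true(all(res$train == 0))
})

test_that("linear SVM separates separable blobs and is deterministic", {
  set.seed(6)
  x <- rbind(matrix(stats::rnorm(200), 100), matrix(stats::rnorm(200) + 10, 100))
  y <- rep(c(0, 1), each = 100)
  idx <- sample(200, 160)
  nm <- minmax_normalize(x[idx, ], x[-idx, ])
  p1 <- fit_predict_linear_svm(nm$train, y[idx], nm$other)
  expect_gte(balanced_accuracy(y[-idx], p1$labels), 0.99)
  p2 <- fit_predict_linear_svm(nm$train, y[idx], nm$other)
  expect_identical(p1, p2)
  expect_error(fit_predict_linear_svm(nm$train, rep(1, 160), nm$other),
               "single-class")
})

test_that("multi-class one-vs-rest recovers three separated blobs", {
  set.seed(8)
  x <- rbind(matrix(stats::rnorm(100), 50),
             matrix(stats::rnorm(100) + 8, 50),
             cbind(stats::rnorm(50) + 8, stats::rnorm(50) - 8))
  y <- rep(0:2, each = 50)
  idx <- sample(150, 120)
  nm <- minmax_normalize(x[idx, ], x[-idx, ])
  pred <- fit_predict_linear_svm(nm$train, y[idx], nm$other)
  expect_gte(balanced_accuracy(y[-idx], pred$labels), 0.95)
  expect_equal(dim(pred$scores), c(30L, 3L))
})

test_that("label permutation drives balanced accuracy to chance", {
  set.seed(10)
  n <- 120
  x <- matrix(stats::rnorm(n * 3), n)
  y <- rep(c(0, 1), each = n / 2)
  ba <- vapply(seq_len(200), function(r) {
    set.seed(600 + r)
    yp <- sample(y) # fresh permutation per repeat: the exchangeable null
    sp <- balanced_monte_carlo(yp, split_config(n_repeats = 1,
                                                seed = 700 + r))[[1]]
    nm <- minmax_normalize(x[sp$train, , drop = FALSE],
                           x[sp$test, , drop = FALSE])
    balanced_accuracy(yp[sp$test],
                      fit_predict_linear_svm(nm$train, yp[sp$train],
                                             nm$other)$labels)
  }, numeric(1))
  se <- stats::sd(ba) / sqrt(length(ba))
  expect_lt(abs(mean(ba) - 0.5), 3 * se)
})

test_that("logistic odds ratios recover a planted effect", {
  set.seed(12)
  x <- stats::rnorm(5000)
  y <- stats::rbinom(5000, 1, stats::plogis(log(2) * x))
  or <- logistic_odds_ratios(data.frame(f = x), y)
  expect_gt(or$or, 1.8); expect_lt(or$or, 2.2)
  expect_true(or$ci_low <= 2 && 2 <= or$ci_high)
  expect_true(or$ci_low <= or$or && or$or <= or$ci_high)
  expect_error(logistic_odds_ratios(data.frame(f = x), rep(1, 5000)),
               "both classes")
})

test_that("null odds ratios cover one at roughly the nominal rate", {
  cover <- vapply(1:40, function(s) {
    set.seed(100 + s)
    x <- stats::rnorm(400)
    y <- stats::rbinom(400, 1, 0.3)
    or <- logistic_odds_ratios(data.frame(f = x), y)
    or$ci_low <= 1 && 1 <= or$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("separation is flagged with an unbounded interval", {
  x <- c(stats::rnorm(20, -5), stats::rnorm(20, 5))
  y <- rep(0:1, each = 20)
  or <- logistic_odds_ratios(data.frame(f = x), y)
  expect_true(or$separated)
  expect_equal(or$ci_high, Inf)
})

test_that("feature-set resolution yields the documented dimensions", {
  d <- data.frame(matrix(stats::rnorm(5 * 14), 5))
  names(d) <- meas_feature_names()
  for (st in c("fb", "tb", "mm", "lm")) {
    block <- data.frame(matrix(stats::rnorm(5 * 30), 5))
    names(block) <- sprintf("ldse_%s_%03d", st, 0:29)
    d <- cbind(d, block)
  }
  expect_equal(ncol(resolve_feature_set(d, "MEAS")), 14)
  expect_equal(ncol(resolve_feature_set(d, "LDSE-FB")), 30)
  expect_equal(ncol(resolve_feature_set(d, "LDSE-COMB")), 300)
  expect_equal(ncol(resolve_feature_set(d, "LDSE-COMB + MEAS")), 314)
  expect_error(resolve_feature_set(d, "LDSE-XX"), "unknown feature set")
})

test_that("run_task is deterministic and drops incomplete rows", {
  set.seed(14)
  n <- 80
  rec <- data.frame(klg = rep(c(0, 4), each = n / 2))
  ft <- data.frame(matrix(stats::rnorm(n * 14), n))
  names(ft) <- meas_feature_names()
  ft$V_FC <- ft$V_FC + rec$klg # signal
  ft$V_mM[1] <- NA
  task <- task_spec("classification", "klg", list(0, 4), feature_set = "MEAS")
  cfg <- split_config(n_repeats = 5, seed = 21)
  r1 <- run_task(ft, rec, task, cfg)
  r2 <- run_task(ft, rec, task, cfg)
  expect_identical(r1$ba, r2$ba)
  expect_equal(r1$n_included, n - 1L)
  expect_equal(r1$n_dropped, 1L)
  expect_equal(r1$n_repeats, 5L)
  expect_true(all(r1$ba >= 0 & r1$ba <= 1))
})
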