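test_that("balanced accuracy matches its closed forms", {
  truth <- c(rep(1, 10), rep(0, 10))
  pred <- c(rep(1, 8), rep(0, 2), rep(1, 4), rep(0, 6))
  expect_equal(balanced_accuracy(truth, pred), 0.7) # sens .8, spec .6
  expect_equal(balanced_accuracy(c(0, 1, 2), c(0, 1, 2)), 1.0)
  truth3 <- rep(c(0, 1, 2), times = c(6, 2, 2))
  expect_equal(balanced_accuracy(truth3, rep(0, 10)), 1 / 3)
  expect_error(balanced_accuracy(c(0, 0), c(0, 1), levels = c(0, 1)),
               "zero true cases")
})

test_that("weighted kappa equals the brute-force definition", {
  set.seed(5)
  true <- sample(0:2, 200, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  pred <- pmin(2, pmax(0, true + sample(-1:1, 200, replace = TRUE)))
  for (w in c("linear", "quadratic")) {
    expect_equal(
      weighted_kappa(true, pred, weights = w),
      brute_force_weighted_kappa(true, pred, 0:2, quadratic = w == "quadratic"))
  }
  expect_equal(weighted_kappa(c(0, 1, 2, 2), c(0, 1, 2, 2)), 1.0)
  # symmetry for symmetric weights
  expect_equal(weighted_kappa(true, pred), weighted_kappa(pred, true))
  expect_error(weighted_kappa(rep(1, 5), rep(1, 5)), "undefined")
})

test_that("independent uniform labels give near-zero kappa", {
  set.seed(9)
  a <- sample(0:4, 10000, replace = TRUE)
  b <- sample(0:4, 10000, replace = TRUE)
  expect_lt(abs(weighted_kappa(a, b)), 0.05)
})

test_that("AUC equals exhaustive pair counting and handles ties", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(roc_auc(scores, labels), brute_force_auc(scores, labels))
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1.0)
  expect_equal(roc_auc(rep(2, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)), 0.5)
  set.seed(3)
  s <- round(stats::rnorm(60), 1) # some ties
  l <- stats::runif(60) < 0.4
  expect_equal(roc_auc(s, l), brute_force_auc(s, l))
  expect_error(roc_auc(s, rep(TRUE, 60)), "both classes")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(11)
  s <- stats::rnorm(100)
  l <- stats::runif(100) < plogis(s)
  base <- roc_auc(s, l)
  expect_equal(roc_auc(exp(s), l), base)
  expect_equal(roc_auc(2 * s + 7, l), base)
  expect_equal(roc_auc(atan(s), l), base)
})

test_that("rank-based AUC agrees with an established implementation", {
  set.seed(13)
  s <- stats::rnorm(150)
  l <- stats::runif(150) < plogis(1.5 * s)
  ref <- as.numeric(pROC::auc(pROC::roc(as.integer(l), s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(s, l), ref)
})
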