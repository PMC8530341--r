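test_that("Procrustes alignment removes rigid motions", {
  tpl <- build_templates()$mTC
  set.seed(4)
  shapes <- lapply(1:6, function(i) random_rigid(tpl$vertices))
  al <- align_shapes(corresponded_shapes("mTC", tpl$faces, shapes))
  for (i in 2:6)
    expect_lt(sqrt(mean((al$coords[i, ] - al$coords[1, ])^2)), 1e-6)
})

test_that("alignment is idempotent and rejects vertex-count mismatch", {
  p <- make_planted_set(10, c(3, 1))
  al <- align_shapes(p$set)
  al2 <- align_shapes(al)
  expect_lt(max(abs(al2$coords - al$coords)), 1e-6)
  expect_error(
    corresponded_shapes("mM", p$template$faces,
                        list(p$template$vertices, p$template$vertices[-1, ])),
    "mismatch in shape 2")
})

test_that("identical shapes give a modeless model; rank bound holds", {
  tpl <- build_templates()$mTC
  same <- corresponded_shapes("mTC", tpl$faces,
                              list(tpl$vertices, tpl$vertices, tpl$vertices))
  model <- fit_shape_model(align_shapes(same))
  expect_equal(ncol(model$modes), 0L)
  expect_error(fit_shape_model(
    corresponded_shapes("mTC", tpl$faces, list(tpl$vertices))), "at least 2")
  p <- make_planted_set(50, c(4, 2, 1, 0.5, 0.25))
  model50 <- fit_shape_model(align_shapes(p$set))
  expect_lte(ncol(model50$modes), 49L)
})

test_that("planted modes and variances are recovered", {
  p <- make_planted_set(200, c(4, 1), seed = 11)
  model <- fit_shape_model(align_shapes(p$set))
  expect_lt(abs(model$variances[1] / 16 - 1), 0.15)
  expect_lt(abs(model$variances[2] / 1 - 1), 0.15)
  framed <- align_model_frame(model, p$template$vertices)
  expect_gt(abs(sum(framed$modes[, 1] * p$modes[, 1])), 0.99)
  expect_gt(abs(sum(framed$modes[, 2] * p$modes[, 2])), 0.99)
  # orthonormality and variance ordering
  gram <- crossprod(model$modes)
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
  expect_true(all(diff(model$variances) <= 1e-12))
})

test_that("encoding is exact on the model's own span", {
  p <- make_planted_set(40, c(3, 1.5, 0.5), seed = 13)
  model <- fit_shape_model(align_shapes(p$set))
  expect_equal(max(abs(encode_shape(model, model$mean))), 0)
  shifted <- model$mean + matrix(2 * model$modes[, 1], ncol = 3)
  enc <- encode_shape(model, shifted)
  expect_lt(abs(enc[1] - 2), 1e-8)
  expect_lt(max(abs(enc[-1])), 1e-8)
  expect_error(encode_shape(model, model$mean[-1, ]), "mismatch")
})

test_that("truncated reconstruction error is bounded by the residual variance", {
  p <- make_planted_set(60, c(4, 2, 1, 0.5, 0.25), seed = 17, rigid = FALSE)
  al <- align_shapes(p$set)
  model <- fit_shape_model(al)
  k <- 2L
  # total squared reconstruction error over the cohort at k modes equals the
  # discarded variance (Parseval in the orthonormal mode basis)
  total_err <- 0
  for (i in seq_len(nrow(al$coords))) {
    s <- matrix(al$coords[i, ], ncol = 3)
    enc <- encode_shape(model, s, n_coef = k)
    rec <- decode_shape(model, enc)
    total_err <- total_err + sum((rec - s)^2)
  }
  residual <- sum(model$variances[-seq_len(k)]) * (model$n_train - 1)
  expect_lt(abs(total_err / residual - 1), 1e-6)
})

test_that("rigidly moving the whole training set leaves variances unchanged", {
  p <- make_planted_set(30, c(2, 1), seed = 19, rigid = FALSE)
  m1 <- fit_shape_model(align_shapes(p$set))
  # one fixed rigid motion applied identically to every training shape
  moved <- lapply(seq_len(nrow(p$set$coords)), function(i) {
    set.seed(23)
    random_rigid(matrix(p$set$coords[i, ], ncol = 3))
  })
  m2 <- fit_shape_model(align_shapes(
    corresponded_shapes("mM", p$template$faces, moved)))
  expect_lt(max(abs(m1$variances - m2$variances)), 1e-8)
})

test_that("cumulative variance share is monotone and reaches one", {
  p <- make_planted_set(25, c(3, 2, 1, 0.5, 0.2), seed = 29)
  model <- fit_shape_model(align_shapes(p$set))
  share <- cumsum(model$variances) / sum(model$variances)
  expect_true(all(diff(share) >= 0))
  expect_equal(share[length(share)], 1)
})

test_that("combined encoding concatenates 75-coefficient blocks", {
  mk <- function(n) structure(seq_len(n) / 10, class = "ldse_vector")
  comb <- combine_encodings(mk(300), mk(300), mk(300), mk(300))
  expect_length(comb, 300)
  expect_equal(as.numeric(comb[1:75]), seq_len(75) / 10)
  comb2 <- combine_encodings(mk(75), mk(75), mk(75), mk(75))
  expect_equal(as.numeric(comb2), rep(seq_len(75) / 10, 4))
  expect_message(comb3 <- combine_encodings(mk(60), mk(75), mk(75), mk(75)),
                 "padded")
  expect_equal(as.numeric(comb3[61:75]), rep(0, 15))
})

test_that("shape model archives round-trip with provenance", {
  p <- make_planted_set(12, c(2, 1), seed = 31)
  model <- fit_shape_model(align_shapes(p$set))
  path <- tempfile(fileext = ".rds")
  save_shape_model(model, path)
  back <- load_shape_model(path)
  expect_equal(back$mean, model$mean)
  expect_equal(back$variances, model$variances)
  expect_equal(back$n_train, 12L)
  expect_equal(back$structure, "mM")
  unlink(path)
})

test_that("models fitted on disjoint cohorts share no state", {
  pa <- make_planted_set(15, c(2, 1), seed = 41)
  pb <- make_planted_set(15, c(2, 1), seed = 42)
  mb_alone <- fit_shape_model(align_shapes(pb$set))
  invisible(fit_shape_model(align_shapes(pa$set)))
  mb_after <- fit_shape_model(align_shapes(pb$set))
  expect_identical(mb_alone$variances, mb_after$variances)
  expect_identical(mb_alone$mean, mb_after$mean)
})
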