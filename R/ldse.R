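# Low-dimensional shape encoding (LDSE): rigid generalized Procrustes
# alignment of corresponded meshes, tangent-space principal component
# analysis about the Procrustes mean, and projection of individual shapes
# onto the leading variation modes.
#
# Vertex arrays are V x 3; stacked vectors are column-major (all x, then y,
# then z), matching the mode fields of the synthetic generator.

#' A set of corresponded shapes
#'
#' Shapes of one structure sharing a single triangulation vertex-for-vertex.
#'
#' @param structure structure code (e.g. `"FB"`).
#' @param faces shared `m x 3` triangle index matrix.
#' @param shapes list of `V x 3` vertex matrices (equal `V` across shapes).
#' @param tag cohort/visit tag for provenance.
#' @return An object of class `corresponded_shapes` storing shapes as an
#'   `n x 3V` coordinate matrix.
#' @export
corresponded_shapes <- function(structure, faces, shapes, tag = "") {
  nv <- vapply(shapes, nrow, integer(1L))
  if (length(unique(nv)) != 1L) {
    bad <- which(nv != nv[1L])[1L]
    stop("vertex-count mismatch in shape ", bad, " (", nv[bad],
         " vs ", nv[1L], ")")
  }
  coords <- do.call(rbind, lapply(shapes, as.vector))
  structure(list(structure = structure, faces = faces, coords = coords,
                 n_vertices = nv[1L], tag = tag),
            class = "corresponded_shapes")
}

shape_matrix <- function(set, i) matrix(set$coords[i, ], ncol = 3L)

#' @export
print.corresponded_shapes <- function(x, ...) {
  cat(sprintf("corresponded_shapes[%s]: %d shapes, %d vertices%s\n",
              x$structure, nrow(x$coords), x$n_vertices,
              if (nzchar(x$tag)) paste0(", tag=", x$tag) else ""))
  invisible(x)
}

# Optimal rigid (rotation + translation, no scaling, no reflection)
# alignment of shape X (V x 3) onto Y; returns the transformed X.
kabsch_align <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2L, cx); yc <- sweep(y, 2L, cy)
  h <- crossprod(xc, yc)
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(xc %*% r, 2L, cy, "+")
}

#' Generalized Procrustes alignment of corresponded shapes
#'
#' Iterated rigid (rotation + translation, no scaling) alignment of every
#' shape to the evolving mean until the mean moves less than `tol` mm (RMS)
#' or `max_iter` iterations. Scale is deliberately retained: structure size
#' carries disease information (e.g. osteophytes).
#'
#' @param set a [corresponded_shapes()].
#' @param tol convergence tolerance on the RMS mean movement (mm).
#' @param max_iter iteration cap.
#' @return The aligned [corresponded_shapes()].
#' @export
align_shapes <- function(set, tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(set, "corresponded_shapes"))
  n <- nrow(set$coords)
  v <- set$n_vertices
  shapes <- lapply(seq_len(n), function(i) {
    s <- shape_matrix(set, i)
    sweep(s, 2L, colMeans(s)) # center
  })
  mean_shape <- shapes[[1L]]
  for (it in seq_len(max_iter)) {
    shapes <- lapply(shapes, kabsch_align, y = mean_shape)
    new_mean <- Reduce(`+`, shapes) / n
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  out <- set
  out$coords <- do.call(rbind, lapply(shapes, as.vector))
  out
}

#' Fit a statistical shape model
#'
#' Tangent-space principal component analysis about the vertex-wise mean of
#' an aligned corresponded set: modes are the orthonormal eigenvectors of
#' the centered coordinate covariance, ordered by explained variance. The
#' number of retained modes is capped at `min(max_modes, n - 1, 3V - 7)`.
#' Each mode's sign is fixed so its largest-magnitude component is positive,
#' making encodings reproducible across platforms.
#'
#' @param set an aligned [corresponded_shapes()] with at least 2 shapes.
#' @param max_modes upper bound on retained modes (default 300).
#' @return An object of class `shape_model` with fields `structure`, `mean`
#'   (`V x 3`), `modes` (`3V x k`, orthonormal columns), `variances`
#'   (non-increasing, mm^2), `n_train`, `faces`, `tag`.
#' @export
fit_shape_model <- function(set, max_modes = 300L) {
  stopifnot(inherits(set, "corresponded_shapes"))
  n <- nrow(set$coords)
  if (n < 2L) stop("at least 2 shapes are required to fit a shape model")
  mean_vec <- colMeans(set$coords)
  centered <- sweep(set$coords, 2L, mean_vec)
  k_cap <- min(max_modes, n - 1L, 3L * set$n_vertices - 7L)
  sv <- svd(centered, nu = 0L, nv = min(n, ncol(centered)))
  variances <- sv$d^2 / (n - 1L)
  keep <- which(variances > max(variances[1L], 1) * 1e-12)
  keep <- keep[seq_len(min(length(keep), k_cap))]
  modes <- sv$v[, keep, drop = FALSE]
  variances <- variances[keep]
  if (length(keep) == 0L) { # all shapes identical
    modes <- matrix(0, ncol(centered), 0L)
    variances <- numeric(0L)
  }
  for (j in seq_len(ncol(modes))) {
    if (modes[which.max(abs(modes[, j])), j] < 0)
      modes[, j] <- -modes[, j]
  }
  structure(list(structure = set$structure,
                 mean = matrix(mean_vec, ncol = 3L),
                 modes = modes, variances = variances,
                 n_train = n, faces = set$faces, tag = set$tag),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("shape_model[%s]: %d vertices, %d modes, n_train=%d\n",
              x$structure, nrow(x$mean), ncol(x$modes), x$n_train))
  invisible(x)
}

#' Encode a shape against a shape model
#'
#' Projects the deviation of a shape from the model mean onto the leading
#' variation modes. The shape must be in the model's Procrustes frame;
#' `align = TRUE` applies the rigid alignment to the mean first.
#'
#' @param model a [fit_shape_model()] result.
#' @param shape `V x 3` vertex matrix corresponded with the model.
#' @param n_coef number of coefficients (truncated to the available modes;
#'   default 300).
#' @param align rigidly align the shape to the model mean first.
#' @return Numeric coefficient vector (class `ldse_vector`, attribute
#'   `structure`), length `min(n_coef, available modes)`.
#' @export
encode_shape <- function(model, shape, n_coef = 300L, align = FALSE) {
  if (nrow(shape) != nrow(model$mean))
    stop("vertex-count mismatch: shape has ", nrow(shape),
         ", model expects ", nrow(model$mean))
  if (align) shape <- kabsch_align(shape, model$mean)
  k <- min(n_coef, ncol(model$modes))
  dev <- as.vector(shape) - as.vector(model$mean)
  coefs <- as.numeric(crossprod(model$modes[, seq_len(k), drop = FALSE], dev))
  structure(coefs, structure = model$structure, class = "ldse_vector")
}

#' Reconstruct a shape from its encoding
#'
#' @param model a `shape_model`.
#' @param coefs coefficient vector from [encode_shape()].
#' @return `V x 3` vertex matrix.
#' @export
decode_shape <- function(model, coefs) {
  k <- length(coefs)
  vec <- as.vector(model$mean) +
    as.vector(model$modes[, seq_len(k), drop = FALSE] %*% as.numeric(coefs))
  matrix(vec, ncol = 3L)
}

#' Express a shape model in a reference frame
#'
#' A Procrustes mean is defined only up to a global rigid motion. This
#' helper rotates/translates the model (mean and every mode, block-wise)
#' into the frame of a reference vertex array — e.g. the generator template
#' — so that fitted modes can be compared coefficient-wise with planted
#' ones. Variances and encodings are unaffected.
#'
#' @param model a `shape_model`.
#' @param reference `V x 3` vertex array in the target frame.
#' @return The re-framed `shape_model`.
#' @export
align_model_frame <- function(model, reference) {
  if (nrow(reference) != nrow(model$mean)) stop("vertex-count mismatch")
  x <- model$mean
  cx <- colMeans(x); cy <- colMeans(reference)
  xc <- sweep(x, 2L, cx); yc <- sweep(reference, 2L, cy)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$u %*% t(s$v)))
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  model$mean <- sweep(xc %*% r, 2L, cy, "+")
  for (j in seq_len(ncol(model$modes)))
    model$modes[, j] <- as.vector(matrix(model$modes[, j], ncol = 3L) %*% r)
  model
}

#' Combined multi-structure encoding
#'
#' Concatenates the first 75 coefficients of the femoral bone, tibial bone,
#' medial and lateral meniscus encodings (block order fixed as FB, TB, mM,
#' lM) into one 300-coefficient vector. Shorter inputs are zero-padded to
#' 75 with a message.
#'
#' @param fb,tb,mm,lm coefficient vectors from [encode_shape()].
#' @param block length of each structure block (default 75).
#' @return Numeric vector of length `4 * block`.
#' @export
combine_encodings <- function(fb, tb, mm, lm, block = 75L) {
  take <- function(x, nm) {
    x <- as.numeric(x)
    if (length(x) < block) {
      message("combine_encodings: ", nm, " block padded from ",
              length(x), " to ", block, " coefficients")
      x <- c(x, rep(0, block - length(x)))
    }
    x[seq_len(block)]
  }
  structure(c(take(fb, "FB"), take(tb, "TB"), take(mm, "mM"), take(lm, "lM")),
            structure = "COMB", class = "ldse_vector")
}

#' Save / load a shape model archive
#'
#' Serializes mean, modes, variances and provenance (structure, cohort tag,
#' training size) to a single RDS archive.
#'
#' @param model a `shape_model`.
#' @param path file path.
#' @return `path` (write) or the `shape_model` (read).
#' @export
save_shape_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_shape_model
#' @export
load_shape_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "shape_model")) stop("not a shape_model archive")
  model
}

#' Fit per-structure shape models and encode a whole cohort
#'
#' For each requested structure: collects the cohort's meshes (left knees
#' mirrored to the right-knee convention), runs generalized Procrustes
#' alignment, fits the shape model, and encodes every aligned shape. Each
#' cohort/visit is processed independently; no state is shared.
#'
#' @param cohort result of [sample_cohort()] (with meshes).
#' @param structures structure codes to model (default the four LDSE
#'   anatomies FB, TB, mM, lM).
#' @param n_coef coefficients retained per structure (default 300).
#' @return List with `models` (named list of `shape_model`) and `coefs`
#'   (named list of `n x k` coefficient matrices, rows = knees).
#' @export
ldse_encode_cohort <- function(cohort, structures = c("FB", "TB", "mM", "lM"),
                               n_coef = 300L) {
  stopifnot(!is.null(cohort$meshes))
  n <- nrow(cohort$records)
  models <- list()
  coefs <- list()
  for (st in structures) {
    shapes <- lapply(seq_len(n), function(i) {
      m <- standardize_side(cohort$meshes[[i]][st], cohort$records$side[i])[[1L]]
      m$vertices
    })
    set <- corresponded_shapes(st, cohort$meshes[[1L]][[st]]$faces, shapes,
                               tag = cohort$config$visit)
    aligned <- align_shapes(set)
    model <- fit_shape_model(aligned, max_modes = n_coef)
    cm <- t(vapply(seq_len(n), function(i)
      as.numeric(encode_shape(model, shape_matrix(aligned, i), n_coef = n_coef)),
      numeric(min(n_coef, ncol(model$modes)))))
    models[[st]] <- model
    coefs[[st]] <- cm
  }
  list(models = models, coefs = coefs)
}
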