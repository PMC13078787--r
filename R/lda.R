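#' Linear discriminant analysis of spectra by condition
#'
#' Finds the axes maximizing the ratio of between-condition to
#' within-condition scatter. Because spectra have far more channels than
#' cells, the data are first projected onto the span of the total scatter
#' (singular vectors with relative tolerance 1e-10); the scatter
#' eigenproblem is solved there with a pseudo-inverse within-scatter metric
#' and loadings are mapped back to channel space. Returns at most
#' `nlevels(labels) - 1` axes ordered by decreasing discriminability, with
#' a deterministic sign convention (the largest-magnitude loading element
#' is positive).
#'
#' @param X cells x channels matrix (or a [spectra_set()]).
#' @param labels per-cell class (condition) labels; >= 2 classes with >= 2
#'   cells each.
#' @param tol relative rank tolerance.
#' @return object of class `lda_model`: `projection` (channels x k),
#'   `eigenvalues` (k, non-increasing), `grand_mean`, `class_means`
#'   (classes x k score matrix), `class_labels`, `n_axes`.
#' @export
fit_lda <- function(X, labels, tol = 1e-10) {
  if (inherits(X, "spectra_set")) {
    if (missing(labels)) labels <- X$condition
    X <- X$intensities
  }
  X <- as.matrix(X)
  labels <- factor(labels)
  counts <- table(labels)
  if (nlevels(labels) < 2) stop("at least 2 classes required", call. = FALSE)
  if (any(counts < 2)) {
    stop(sprintf("every class needs >= 2 cells (violated by: %s)",
                 paste(names(counts)[counts < 2], collapse = ", ")),
         call. = FALSE)
  }
  gm <- colMeans(X)
  Xc <- sweep(X, 2, gm)
  sv <- svd(Xc, nu = 0)
  keep <- sv$d > tol * sv$d[1]
  V <- sv$v[, keep, drop = FALSE]          # channels x r
  Z <- Xc %*% V                            # cells x r, grand mean 0

  cls <- levels(labels)
  k_cls <- length(cls)
  means_z <- t(vapply(cls, function(g) colMeans(Z[labels == g, , drop = FALSE]),
                      numeric(ncol(Z))))
  Sb <- crossprod(means_z * sqrt(as.numeric(counts)))
  Zw <- Z - means_z[as.integer(labels), , drop = FALSE]
  Sw <- crossprod(Zw)

  ew <- eigen(Sw, symmetric = TRUE)
  pos <- ew$values > tol * max(ew$values, 0)
  if (any(pos)) {
    W <- ew$vectors[, pos, drop = FALSE] %*% diag(1 / sqrt(ew$values[pos]),
                                                  sum(pos))
  } else {
    # degenerate within-class scatter (e.g. duplicated cells): fall back to
    # the unit metric on the total-scatter span
    W <- diag(ncol(Z))
  }
  M <- crossprod(W, Sb %*% W)
  M <- (M + t(M)) / 2
  eb <- eigen(M, symmetric = TRUE)
  evals <- pmax(eb$values, 0)
  n_axes <- min(k_cls - 1L, sum(evals > max(evals, 0) * 1e-8))
  if (n_axes == 0) {
    warning("identical class means: no discriminant axes", call. = FALSE)
  }
  load_z <- W %*% eb$vectors[, seq_len(n_axes), drop = FALSE]
  projection <- V %*% load_z               # channels x n_axes
  # sign convention: largest-|loading| element positive
  for (j in seq_len(n_axes)) {
    i <- which.max(abs(projection[, j]))
    if (projection[i, j] < 0) projection[, j] <- -projection[, j]
  }
  # class means in the discriminant space (grand mean maps to the origin)
  class_means <- t(vapply(cls, function(g) {
    as.numeric(colMeans(sweep(X[labels == g, , drop = FALSE], 2, gm) %*%
                          projection))
  }, numeric(n_axes)))
  if (n_axes == 1) class_means <- matrix(class_means, ncol = 1)
  colnames(projection) <- colnames(class_means) <-
    if (n_axes > 0) paste0("LDA", seq_len(n_axes)) else character(0)
  rownames(class_means) <- cls
  structure(list(projection = projection,
                 eigenvalues = evals[seq_len(n_axes)],
                 grand_mean = gm,
                 class_means = class_means,
                 class_labels = cls,
                 n_axes = n_axes),
            class = "lda_model")
}

#' Project spectra onto fitted discriminant axes
#'
#' Centers `newdata` by the training grand mean and multiplies by the
#' loading matrix.
#'
#' @param object an `lda_model`.
#' @param newdata cells x channels matrix or [spectra_set()]; channel count
#'   must match the training data.
#' @param ... unused.
#' @return cells x k score matrix.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_set")) newdata <- newdata$intensities
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$grand_mean)) {
    stop("channel count does not match the fitted model", call. = FALSE)
  }
  sweep(newdata, 2, object$grand_mean) %*% object$projection
}

#' Per-condition mean scores in the discriminant space
#'
#' @param scores cells x k score matrix from [predict.lda_model()].
#' @param labels per-cell condition labels.
#' @param condition_order optional vector fixing the row order; every
#'   condition listed must be present in `labels`.
#' @return conditions x k matrix of mean scores (rows named by condition).
#' @export
condition_means <- function(scores, labels, condition_order = NULL) {
  labels <- as.character(labels)
  if (is.null(condition_order)) condition_order <- unique(labels)
  missing_c <- setdiff(condition_order, labels)
  if (length(missing_c)) {
    stop(sprintf("conditions with no cells: %s",
                 paste(missing_c, collapse = ", ")), call. = FALSE)
  }
  scores <- as.matrix(scores)
  out <- t(vapply(condition_order, function(g) {
    colMeans(scores[labels == g, , drop = FALSE])
  }, numeric(ncol(scores))))
  if (ncol(scores) == 1) out <- matrix(out, ncol = 1)
  rownames(out) <- condition_order
  colnames(out) <- colnames(scores)
  out
}

#' Correlation between a discriminant axis and growth rate
#'
#' Pearson correlation of the per-condition mean scores on one axis
#' (default the first) with the conditions' growth rates. Because the sign
#' of a discriminant axis is arbitrary, the absolute correlation is
#' reported alongside the signed one.
#'
#' @param R_hat conditions x k condition-mean score matrix.
#' @param growth_rates per-condition growth rates in matching row order.
#' @param axis axis index.
#' @return list with `r`, `abs_r`, `p_value`.
#' @export
growth_rate_correlation <- function(R_hat, growth_rates, axis = 1L) {
  R_hat <- as.matrix(R_hat)
  if (nrow(R_hat) < 3) stop("at least 3 conditions required", call. = FALSE)
  if (nrow(R_hat) != length(growth_rates)) {
    stop("growth rates do not match the condition means", call. = FALSE)
  }
  x <- R_hat[, axis]
  if (sd(x) == 0 || sd(growth_rates) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ct <- cor.test(x, growth_rates)
  list(r = unname(ct$estimate), abs_r = abs(unname(ct$estimate)),
       p_value = ct$p.value)
}
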