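#' Fit the linear spectra-to-proteome coefficient matrix B
#'
#' Per-protein ordinary least squares of abundance across conditions on the
#' design `[1 | R_hat[, 1..K]]`. When the system is underdetermined (more
#' unknowns than training conditions) the minimum-norm least-squares
#' solution is returned.
#'
#' @param P proteins x conditions abundance matrix.
#' @param R_hat conditions x (m-1) condition-mean score matrix from
#'   [condition_means()].
#' @param K number of discriminant axes used (default 4, the leading major
#'   axes; `K <= ncol(R_hat)`).
#' @return object of class `correspondence_model`: `B` (n x (K+1),
#'   column 1 = intercept), `K`, `design`, `protein_ids`.
#' @export
fit_b <- function(P, R_hat, K = 4L) {
  P <- as.matrix(P)
  R_hat <- as.matrix(R_hat)
  if (nrow(R_hat) != ncol(P)) {
    stop("R_hat rows must match proteome conditions", call. = FALSE)
  }
  if (K > ncol(R_hat)) stop("K exceeds the available axes", call. = FALSE)
  X <- cbind(intercept = 1, R_hat[, seq_len(K), drop = FALSE])
  if (qr(X)$rank == 0) stop("design matrix has rank 0", call. = FALSE)
  B <- t(MASS::ginv(X) %*% t(P))           # n x (K+1), min-norm when needed
  rownames(B) <- rownames(P)
  colnames(B) <- c("b0", paste0("b", seq_len(K)))
  structure(list(B = B, K = as.integer(K), design = X,
                 protein_ids = rownames(P)),
            class = "correspondence_model")
}

#' Predict a condition's expression profile from its spectral coordinates
#'
#' Computes `B [1; r_hat]`. Predictions are not clipped: negative estimated
#' abundances are possible and left as is.
#'
#' @param object a `correspondence_model`.
#' @param r_hat K-vector of discriminant scores, or a conditions x K matrix
#'   (one prediction per row).
#' @param ... unused.
#' @return n-vector, or n x conditions matrix for matrix input.
#' @export
predict.correspondence_model <- function(object, r_hat, ...) {
  if (is.matrix(r_hat)) {
    if (ncol(r_hat) != object$K) stop("r_hat has wrong length", call. = FALSE)
    return(object$B %*% t(cbind(1, r_hat)))
  }
  if (length(r_hat) != object$K) stop("r_hat has wrong length", call. = FALSE)
  as.vector(object$B %*% c(1, r_hat))
}

#' Distances between expression profiles
#'
#' @param x,y numeric vectors of equal length.
#' @param metric one of `euclidean_sq` (squared Euclidean distance, PRESS),
#'   `manhattan`, `cosine_dist` (1 - cosine similarity), or
#'   `one_minus_pearson`.
#' @return non-negative scalar.
#' @export
distance_measure <- function(x, y, metric = c("euclidean_sq", "manhattan",
                                              "cosine_dist",
                                              "one_minus_pearson")) {
  metric <- match.arg(metric)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  switch(metric,
    euclidean_sq = sum((x - y)^2),
    manhattan = sum(abs(x - y)),
    cosine_dist = {
      nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
      if (nx == 0 || ny == 0) {
        stop("cosine distance undefined for a zero vector", call. = FALSE)
      }
      1 - sum(x * y) / (nx * ny)
    },
    one_minus_pearson = {
      if (sd(x) == 0 || sd(y) == 0) {
        stop("Pearson distance undefined for a constant vector",
             call. = FALSE)
      }
      1 - cor(x, y)
    })
}

#' Leave-one-out cross-validation of the linear correspondence
#'
#' For each held-out condition j, fits B on the remaining conditions,
#' predicts condition j's profile from its spectral coordinates, and
#' records the distance to the measured profile under each metric. Also
#' returns the average of the leave-one-out coefficient estimates, which is
#' the default B used in downstream coefficient analyses.
#'
#' @inheritParams fit_b
#' @param metrics character vector of [distance_measure()] metrics.
#' @return object of class `loocv_report`: `predictions` (n x m),
#'   `distances` (m x metrics), `overall` (named per-metric sums),
#'   `B_average`, `K`, `condition_ids`.
#' @export
loocv <- function(P, R_hat, K = 4L, metrics = "euclidean_sq") {
  P <- as.matrix(P)
  R_hat <- as.matrix(R_hat)
  m <- ncol(P)
  if (m < 3) stop("LOOCV needs at least 3 conditions", call. = FALSE)
  predictions <- matrix(NA_real_, nrow(P), m, dimnames = dimnames(P))
  distances <- matrix(NA_real_, m, length(metrics),
                      dimnames = list(colnames(P), metrics))
  B_sum <- NULL
  for (j in seq_len(m)) {
    fit <- fit_b(P[, -j, drop = FALSE], R_hat[-j, , drop = FALSE], K = K)
    pred <- predict(fit, R_hat[j, seq_len(K)])
    predictions[, j] <- pred
    for (d in metrics) {
      distances[j, d] <- distance_measure(P[, j], pred, d)
    }
    B_sum <- if (is.null(B_sum)) fit$B else B_sum + fit$B
  }
  structure(list(predictions = predictions,
                 distances = distances,
                 overall = colSums(distances),
                 B_average = B_sum / m,
                 K = as.integer(K),
                 condition_ids = colnames(P)),
            class = "loocv_report")
}

#' Permutation test of the overall cross-validation error
#'
#' Compares the observed overall error `sum_j dist(p_j, p^est_j)` with the
#' errors of randomly permuted condition assignments
#' `sum_j dist(p_j, p^est_sigma(j))`. Permutations are drawn uniformly
#' (the identity included); the p-value uses the add-one convention
#' `p = (1 + #{permuted error <= observed}) / (1 + n_perm)`.
#'
#' @param P proteins x conditions measured profiles.
#' @param predictions proteins x conditions predicted profiles (e.g. from
#'   [loocv()]).
#' @param metric a [distance_measure()] metric.
#' @param n_perm number of random permutations (>= 1).
#' @param seed optional seed.
#' @return list with `p_value`, `observed`, `null_errors`, `n_perm`.
#' @export
permutation_test <- function(P, predictions, metric = "euclidean_sq",
                             n_perm = 1e5, seed = NULL) {
  P <- as.matrix(P)
  predictions <- as.matrix(predictions)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  m <- ncol(P)
  # m x m table of dist(p_j, pred_k): permutation errors are index lookups
  dmat <- matrix(NA_real_, m, m)
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      dmat[j, k] <- distance_measure(P[, j], predictions[, k], metric)
    }
  }
  observed <- sum(diag(dmat))
  null_errors <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sigma <- sample.int(m)
      sum(dmat[cbind(seq_len(m), sigma)])
    }, numeric(1))
  })
  p <- (1 + sum(null_errors <= observed)) / (1 + n_perm)
  list(p_value = p, observed = observed, null_errors = null_errors,
       n_perm = as.integer(n_perm))
}

# accept either a correspondence_model, a loocv_report, or a raw B matrix
as_b_matrix <- function(model) {
  if (inherits(model, "correspondence_model")) return(model$B)
  if (inherits(model, "loocv_report")) return(model$B_average)
  as.matrix(model)
}

#' Intercept-normalized coefficients (the regression-based proteome space)
#'
#' Assigns each protein the coordinate `beta_ik = b_ik / b_i0`. Proteins
#' that perfectly conserve mutual stoichiometry share a single point in
#' this space. Proteins whose intercept magnitude falls below
#' `tolerance * median(|b_0|)` are excluded rather than producing unstable
#' ratios.
#'
#' @param model a `correspondence_model`, a `loocv_report` (its averaged
#'   B is used), or an n x (K+1) coefficient matrix.
#' @param tolerance relative intercept exclusion tolerance.
#' @return list with `omega_b` (kept proteins x K coordinate matrix) and
#'   `excluded_proteins` (character).
#' @export
normalized_coefficients <- function(model, tolerance = 1e-8) {
  B <- as_b_matrix(model)
  b0 <- B[, 1]
  keep <- abs(b0) >= tolerance * median(abs(b0)) & abs(b0) > 0
  if (!any(keep)) stop("all proteins excluded: intercepts are degenerate",
                       call. = FALSE)
  omega <- B[keep, -1, drop = FALSE] / b0[keep]
  colnames(omega) <- paste0("beta", seq_len(ncol(omega)))
  list(omega_b = omega,
       excluded_proteins = rownames(B)[!keep] %||% which(!keep))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Proportionality of axis coefficients to the intercept within a group
#'
#' For a stoichiometry-conserving group, each axis coefficient column is
#' proportional to the intercept column. Fits, per axis, the least-squares
#' slope through the origin of `b_k` against `b_0` restricted to the group,
#' with the coefficient of determination computed about the origin.
#'
#' @param model as in [normalized_coefficients()].
#' @param group_ids protein ids (or integer row indices) of the group,
#'   >= 3 members.
#' @return list with `axes` (data.frame: `axis`, `slope`, `r_squared`) and
#'   `overall_r_squared`, the pooled fit quality over all axes. The pooled
#'   value measures how close the group's coefficient matrix is to rank
#'   one (columns proportional to the intercept); per-axis values are
#'   uninformative for axes whose true slope is near zero.
#' @export
coefficient_proportionality <- function(model, group_ids) {
  B <- as_b_matrix(model)
  rows <- if (is.character(group_ids)) match(group_ids, rownames(B))
          else as.integer(group_ids)
  if (anyNA(rows)) stop("unknown protein ids in group", call. = FALSE)
  if (length(rows) < 3) stop("group needs >= 3 members", call. = FALSE)
  Bg <- B[rows, , drop = FALSE]
  b0 <- Bg[, 1]
  if (all(Bg == 0)) stop("degenerate all-zero group", call. = FALSE)
  res <- lapply(seq_len(ncol(Bg) - 1L), function(k) {
    bk <- Bg[, k + 1L]
    slope <- sum(b0 * bk) / sum(b0^2)
    ss_tot <- sum(bk^2)
    r2 <- if (ss_tot == 0) 1 else 1 - sum((bk - slope * b0)^2) / ss_tot
    data.frame(axis = k, slope = slope, r_squared = r2)
  })
  axes <- do.call(rbind, res)
  Bk <- Bg[, -1, drop = FALSE]
  ss_tot <- sum(Bk^2)
  overall <- if (ss_tot == 0) 1 else
    1 - sum((Bk - outer(b0, axes$slope))^2) / ss_tot
  list(axes = axes, overall_r_squared = overall)
}
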