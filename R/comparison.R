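#' Haar-distributed random orthogonal matrix
#'
#' QR decomposition of an i.i.d. standard-normal matrix with the sign of
#' the R diagonal folded into Q, which makes Q Haar-distributed on the
#' orthogonal group.
#'
#' @param m matrix dimension (>= 2).
#' @param seed optional seed.
#' @return m x m orthogonal matrix.
#' @export
haar_orthogonal <- function(m, seed = NULL) {
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  with_seed(seed, {
    qrz <- qr(matrix(rnorm(m * m), m, m))
    Q <- qr.Q(qrz)
    s <- sign(diag(qr.R(qrz)))
    s[s == 0] <- 1
    Q %*% diag(s)
  })
}

#' Closeness of an orthogonal matrix to the identity
#'
#' Squares the matrix element-wise (Hadamard square), whose total mass is
#' exactly m for an orthogonal matrix, and treats the result as a weighted
#' two-dimensional histogram over coordinates (i, j). The weighted Pearson
#' correlation of i with j is 1 exactly when all mass sits on the diagonal
#' (the identity, or any sign-flipped diagonal matrix) and decreases as
#' mass moves off-diagonal.
#'
#' @param Q square matrix (m >= 2).
#' @return scalar in [-1, 1].
#' @export
closeness_score <- function(Q) {
  m <- nrow(Q)
  if (is.null(m) || m != ncol(Q)) stop("Q must be square", call. = FALSE)
  if (m < 2) stop("degenerate 1 x 1 case", call. = FALSE)
  W <- Q * Q
  i <- row(W); j <- col(W)
  wsum <- sum(W)
  mi <- sum(W * i) / wsum
  mj <- sum(W * j) / wsum
  covij <- sum(W * (i - mi) * (j - mj))
  vi <- sum(W * (i - mi)^2)
  vj <- sum(W * (j - mj)^2)
  if (vi == 0 || vj == 0) {
    stop("all histogram mass on one coordinate: correlation undefined",
         call. = FALSE)
  }
  covij / sqrt(vi * vj)
}

#' Cumulative off-diagonal mass profile
#'
#' Step t sums the squared entries on the band `|i - j| >= m - t`: the
#' profile starts from the outermost (+/-(m-1)) diagonals and expands
#' inward, the final step adding the main diagonal. For an orthogonal
#' matrix the final value is m.
#'
#' @param Q square matrix.
#' @return numeric vector of length m (non-decreasing).
#' @export
offdiagonal_profile <- function(Q) {
  m <- nrow(Q)
  W <- Q * Q
  band <- abs(row(W) - col(W))
  vapply(seq_len(m), function(t) sum(W[band >= m - t]), numeric(1))
}

#' Cumulative leading-principal-submatrix mass profile
#'
#' The k-th value is the squared Frobenius mass of the k x k leading
#' principal submatrix, k = 1..m; the identity gives the line k, and any
#' orthogonal matrix ends at m.
#'
#' @param Q square matrix.
#' @return numeric vector of length m (non-decreasing).
#' @export
leading_submatrix_profile <- function(Q) {
  m <- nrow(Q)
  W <- Q * Q
  vapply(seq_len(m), function(k) sum(W[seq_len(k), seq_len(k)]), numeric(1))
}

# augmented m-dimensional protein representations: the trivial/constant
# axis prepended to the (m-1)-dimensional coordinates
augment_embedding <- function(embedding) {
  cbind(trivial = embedding$trivial, embedding$coords)
}

augment_omega_b <- function(omega_b) {
  cbind(const = 1, omega_b)
}

#' Orthogonal matrix relating the two proteome structures
#'
#' Solves the least-squares linear map between the augmented m-dimensional
#' embedding coordinates (trivial axis + csLE axes) and the augmented
#' normalized-coefficient coordinates (constant axis + beta axes) over the
#' proteins present in both, and returns the orthogonal polar factor of
#' that map. Per-axis positive rescaling of either representation leaves
#' the result unchanged. When the two structures genuinely correspond axis
#' by axis, the matrix is close to the identity in the sense of
#' [closeness_score()].
#'
#' @param embedding a [csle()] result.
#' @param omega a [normalized_coefficients()] result with
#'   `ncol(omega_b) == ncol(coords)` (use `K = m - 1`).
#' @return list of class `theta_fit`: `theta` (orthogonal m x m), `map`
#'   (the unconstrained least-squares map), `protein_ids`.
#' @export
compute_theta <- function(embedding, omega) {
  X <- augment_embedding(embedding)
  ids_x <- rownames(embedding$coords) %||% as.character(seq_len(nrow(X)))
  Y <- augment_omega_b(omega$omega_b)
  ids_y <- rownames(omega$omega_b) %||% as.character(seq_len(nrow(Y)))
  shared <- intersect(ids_x, ids_y)
  if (length(shared) < ncol(X)) {
    stop("fewer shared proteins than augmented dimensions", call. = FALSE)
  }
  X <- X[match(shared, ids_x), , drop = FALSE]
  Y <- Y[match(shared, ids_y), , drop = FALSE]
  if (ncol(X) != ncol(Y)) {
    stop("coordinate sets have different dimension; fit the coefficient ",
         "model with K = m - 1 axes", call. = FALSE)
  }
  if (qr(X)$rank < ncol(X) || qr(Y)$rank < ncol(Y)) {
    stop("rank-deficient coordinates", call. = FALSE)
  }
  M <- MASS::ginv(X) %*% Y
  sv <- svd(M)
  theta <- sv$u %*% t(sv$v)
  err <- max(abs(crossprod(theta) - diag(ncol(theta))))
  stopifnot(err < 1e-8)
  structure(list(theta = theta, map = M, protein_ids = shared),
            class = "theta_fit")
}

#' Score an orthogonal matrix against a Haar-random null
#'
#' Computes the [closeness_score()] of `theta`, draws `n_null` Haar-random
#' orthogonal matrices of the same size, and reports the percentile of the
#' observed score in the null, together with the off-diagonal and
#' leading-submatrix mass profiles of `theta`, the identity and the null
#' mean.
#'
#' @param theta orthogonal matrix or a `theta_fit`.
#' @param n_null number of Haar draws.
#' @param seed optional seed.
#' @return list of class `theta_report`: `closeness`, `null_scores`,
#'   `percentile` (fraction of null scores below the observed, in
#'   percent), `offdiag_profile`, `leading_submatrix_profile` (each a
#'   list: theta / identity / null_mean).
#' @export
theta_closeness <- function(theta, n_null = 1000L, seed = NULL) {
  if (inherits(theta, "theta_fit")) theta <- theta$theta
  m <- nrow(theta)
  score <- closeness_score(theta)
  with_seed(seed, {
    null_scores <- numeric(n_null)
    off_null <- matrix(0, n_null, m)
    lead_null <- matrix(0, n_null, m)
    for (i in seq_len(n_null)) {
      Q <- haar_orthogonal(m)
      null_scores[i] <- closeness_score(Q)
      off_null[i, ] <- offdiagonal_profile(Q)
      lead_null[i, ] <- leading_submatrix_profile(Q)
    }
    structure(list(
      closeness = score,
      null_scores = null_scores,
      percentile = 100 * mean(null_scores < score),
      offdiag_profile = list(theta = offdiagonal_profile(theta),
                             identity = offdiagonal_profile(diag(m)),
                             null_mean = colMeans(off_null)),
      leading_submatrix_profile = list(
        theta = leading_submatrix_profile(theta),
        identity = leading_submatrix_profile(diag(m)),
        null_mean = colMeans(lead_null))),
      class = "theta_report")
  })
}

#' Proportionality between centrality and expression generality
#'
#' Tests the structural condition that the stoichiometry conservation
#' centrality d is proportional to the expression generality g, with the
#' analytic slope `((sum_j d_j) / m)^(1/2)`. The per-protein residual from
#' that line is related to the growth rate of the condition where the
#' protein is most expressed, quantified here by a Spearman rank
#' correlation.
#'
#' @param scores a [score_table()].
#' @return list: `slope`, `residuals`, `spearman_rho`, `spearman_p`.
#' @export
d_g_proportionality <- function(scores) {
  m <- attr(scores, "m")
  if (is.null(m)) stop("scores must come from score_table()", call. = FALSE)
  slope <- sqrt(sum(scores$centrality) / m)
  residuals <- scores$centrality - slope * scores$generality
  ct <- suppressWarnings(
    cor.test(residuals, scores$growth_rate_argmax, method = "spearman"))
  list(slope = slope, residuals = residuals,
       spearman_rho = unname(ct$estimate), spearman_p = ct$p.value)
}

#' Condition-count subsampling of the structural correspondence
#'
#' For each subset size, draws random condition subsets, reruns the whole
#' correspondence chain on the subset (LDA on the subset's cells, the
#' coefficient fit with K = size - 1 axes, intercept-normalized
#' coordinates, cosine-similarity embedding of the subset proteome) and
#' scores the orthogonal alignment matrix. Because the Haar null of the
#' closeness score concentrates as the matrix grows, raw closeness values
#' are not comparable across subset sizes; the correspondence precision is
#' therefore reported as the closeness standardized against the
#' size-matched Haar null (`z`), alongside the raw score.
#'
#' @param P proteins x conditions abundance matrix.
#' @param spectra preprocessed [spectra_set()] covering the same conditions.
#' @param conditions condition table matching the columns of `P`.
#' @param sizes integer vector of subset sizes, each in [3, m].
#' @param reps subsets drawn per size.
#' @param seed optional seed (fixes the drawn subsets and the null).
#' @param b_estimate `"full"` (single fit on all subset conditions) or
#'   `"loo_average"` (average of the leave-one-out estimates).
#' @param n_null Haar draws per size for the standardization.
#' @return list with `draws` (data.frame size/rep/closeness/z) and
#'   `summary` (per-size mean and sd of both).
#' @export
subsample_conditions <- function(P, spectra, conditions, sizes,
                                 reps = 10L, seed = NULL,
                                 b_estimate = c("full", "loo_average"),
                                 n_null = 200L) {
  b_estimate <- match.arg(b_estimate)
  P <- as.matrix(P)
  m <- ncol(P)
  if (any(sizes < 3) || any(sizes > m)) {
    stop("subset sizes must be in [3, number of conditions]", call. = FALSE)
  }
  with_seed(seed, {
    nulls <- lapply(unique(sizes), function(s) {
      draws <- vapply(seq_len(n_null),
                      function(i) closeness_score(haar_orthogonal(s)),
                      numeric(1))
      c(mean = mean(draws), sd = sd(draws))
    })
    names(nulls) <- as.character(unique(sizes))
    rows <- list()
    for (s in sizes) {
      for (r in seq_len(reps)) {
        sub <- sort(sample.int(m, s))
        cl <- subset_closeness(P, spectra, conditions, sub, b_estimate)
        nl <- nulls[[as.character(s)]]
        rows[[length(rows) + 1L]] <- data.frame(
          size = s, rep = r, closeness = cl,
          z = (cl - nl[["mean"]]) / nl[["sd"]])
      }
    }
    draws <- do.call(rbind, rows)
    summary <- do.call(rbind, lapply(split(draws, draws$size), function(d) {
      data.frame(size = d$size[1], mean_closeness = mean(d$closeness),
                 sd_closeness = sd(d$closeness),
                 mean_z = mean(d$z), sd_z = sd(d$z))
    }))
    rownames(summary) <- NULL
    list(draws = draws, summary = summary)
  })
}

# one subsample evaluation: restrict to the chosen conditions and rerun
# LDA -> B -> normalized coefficients and csLE, then score theta
subset_closeness <- function(P, spectra, conditions, sub, b_estimate) {
  cond_ids <- conditions$condition_id[sub]
  keep_cells <- spectra$condition %in% cond_ids
  X <- spectra$intensities[keep_cells, , drop = FALSE]
  lab <- spectra$condition[keep_cells]
  Psub <- P[, sub, drop = FALSE]
  model <- fit_lda(X, lab)
  K <- length(cond_ids) - 1L
  R_hat <- condition_means(predict(model, X), lab,
                           condition_order = cond_ids)
  B <- if (b_estimate == "full") {
    fit_b(Psub, R_hat, K = K)
  } else {
    loocv(Psub, R_hat, K = K)
  }
  omega <- normalized_coefficients(B)
  emb <- csle(cosine_matrix(Psub))
  fit <- compute_theta(emb, omega)
  closeness_score(fit$theta)
}
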