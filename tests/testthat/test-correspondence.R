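make_linear_proteome <- function(n = 40, m = 10, K = 3, seed = 1) {
  set.seed(seed)
  R <- matrix(rnorm(m * (m - 1)), m)
  B_true <- matrix(rnorm(n * (K + 1)), n)
  P <- B_true %*% t(cbind(1, R[, seq_len(K)]))
  rownames(P) <- sprintf("P%03d", seq_len(n))
  list(P = P, R = R, B_true = B_true, K = K)
}

test_that("an exactly linear proteome is recovered and reproduced", {
  lp <- make_linear_proteome()
  fit <- fit_b(lp$P, lp$R, K = lp$K)
  expect_equal(unname(fit$B), lp$B_true, tolerance = 1e-8)
  for (j in c(1, 5)) {
    expect_equal(predict(fit, lp$R[j, seq_len(lp$K)]),
                 unname(lp$P[, j]), tolerance = 1e-8)
  }
})

test_that("a constant proteome gets intercept-only coefficients", {
  lp <- make_linear_proteome()
  P <- matrix(5, 20, 10)
  fit <- fit_b(P, lp$R, K = 3)
  expect_equal(unname(fit$B[, 1]), rep(5, 20), tolerance = 1e-10)
  expect_equal(max(abs(fit$B[, -1])), 0, tolerance = 1e-10)
})

test_that("underdetermined fits return the minimum-norm solution", {
  lp <- make_linear_proteome(n = 15, m = 10, K = 3)
  # 9 training rows, 10 unknowns: K = m - 1 with one condition held out
  P <- lp$P[, -1]
  R <- lp$R[-1, ]
  fit <- fit_b(P, R, K = 9)
  X <- cbind(1, R)
  # training residuals vanish
  expect_equal(max(abs(X %*% t(fit$B) - t(P))), 0, tolerance = 1e-8)
  # matches the SVD minimum-norm oracle protein by protein
  for (i in c(1, 7)) {
    expect_equal(unname(fit$B[i, ]), as.numeric(pinv_solve(X, P[i, ])),
                 tolerance = 1e-8)
  }
})

test_that("prediction is affine in the spectral coordinates", {
  lp <- make_linear_proteome()
  fit <- fit_b(lp$P, lp$R, K = 3)
  expect_equal(predict(fit, rep(0, 3)), unname(fit$B[, 1]))
  r1 <- c(1, -2, 0.5); r2 <- c(0.3, 1, -1)
  expect_equal(predict(fit, r1) + predict(fit, r2) - predict(fit, rep(0, 3)),
               predict(fit, r1 + r2), tolerance = 1e-10)
  expect_error(predict(fit, c(1, 2)), "wrong length")
})

test_that("distance measures satisfy their contracts", {
  x <- c(1, 0); y <- c(0, 1)
  for (m in c("euclidean_sq", "manhattan", "cosine_dist",
              "one_minus_pearson")) {
    z <- c(1, 3, 2)
    expect_equal(distance_measure(z, z, m), 0, tolerance = 1e-12)
  }
  expect_equal(distance_measure(x, y, "euclidean_sq"), 2)
  expect_equal(distance_measure(x, y, "cosine_dist"), 1)
  expect_equal(distance_measure(x, 2 * y, "cosine_dist"),
               distance_measure(x, y, "cosine_dist"))
  expect_error(distance_measure(x, c(0, 0), "cosine_dist"), "zero vector")
  expect_error(distance_measure(x, y, "no_such"), "arg")
})

test_that("LOOCV is exact on noiseless linear data and order-invariant", {
  lp <- make_linear_proteome(n = 30, m = 12, K = 4)
  cv <- loocv(lp$P, lp$R, K = 4)
  expect_lt(cv$overall["euclidean_sq"], 1e-12 * sum(lp$P^2))
  # permuting the condition loop leaves the overall error unchanged
  perm <- sample(ncol(lp$P))
  cv2 <- loocv(lp$P[, perm], lp$R[perm, ], K = 4)
  expect_equal(unname(cv2$overall), unname(cv$overall), tolerance = 1e-8)
})

test_that("permutation p-values respect their bounds and detect linkage", {
  lp <- make_linear_proteome(n = 30, m = 12, K = 4)
  cv <- loocv(lp$P, lp$R, K = 4)
  pt <- permutation_test(lp$P, cv$predictions, n_perm = 1000, seed = 1)
  expect_gte(pt$p_value, 1 / 1001)
  expect_lte(pt$p_value, 0.01)
  # predictions equal to a permuted copy of the truth: the matching
  # permutation scores 0, so p cannot sit at the minimum
  sigma <- c(2:12, 1)
  pt2 <- permutation_test(lp$P, lp$P[, sigma], n_perm = 500, seed = 2)
  expect_gt(pt2$p_value, 1 / 501)
})

test_that("null permutation p-values are calibrated", {
  set.seed(99)
  hits <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    P <- matrix(rlnorm(50 * 10), 50)
    pred <- matrix(rlnorm(50 * 10), 50)
    p <- permutation_test(P, pred, n_perm = 199)$p_value
    if (p <= 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.01)
  expect_lte(hits / n_rep, 0.12)
})

test_that("intercept-normalized coordinates collapse conserved proteins", {
  B <- rbind(c(2, 4, 6), c(1, 2, 3), c(0, 1, 1), c(3, 0, 0))
  rownames(B) <- paste0("P", 1:4)
  out <- normalized_coefficients(B)
  expect_equal(unname(out$omega_b["P1", ]), c(2, 3))
  expect_equal(unname(out$omega_b["P2", ]), c(2, 3))
  expect_identical(out$excluded_proteins, "P3")
  all_zero_intercepts <- cbind(rep(0, 3), c(1, 2, 3), c(1, 1, 1))
  expect_error(normalized_coefficients(all_zero_intercepts), "excluded")
})

test_that("omega_b is invariant to per-protein abundance rescaling", {
  lp <- make_linear_proteome(n = 25, m = 10, K = 4)
  P2 <- abs(lp$P) + 1          # keep intercepts well away from zero
  s <- runif(25, 0.5, 3)
  f1 <- normalized_coefficients(fit_b(P2, lp$R, K = 4))
  f2 <- normalized_coefficients(fit_b(P2 * s, lp$R, K = 4))
  expect_equal(f1$omega_b, f2$omega_b, tolerance = 1e-8)
})

test_that("coefficient proportionality finds planted slopes and rejects noise", {
  set.seed(8)
  b0 <- rnorm(50)
  B <- cbind(b0, 2 * b0, -0.5 * b0)
  out <- coefficient_proportionality(B, 1:50)
  expect_equal(out$axes$slope, c(2, -0.5), tolerance = 1e-12)
  expect_equal(out$axes$r_squared, c(1, 1), tolerance = 1e-12)
  expect_equal(out$overall_r_squared, 1, tolerance = 1e-12)
  Brand <- cbind(rnorm(50), rnorm(50))
  out2 <- coefficient_proportionality(Brand, 1:50)
  expect_lt(out2$axes$r_squared[1], 0.5)
  expect_lt(out2$overall_r_squared, 0.5)
  expect_error(coefficient_proportionality(B, 1:2), ">= 3")
})

test_that("the planted core is proportional through the full pipeline", {
  r2 <- vapply(1:3, function(s) {
    inp <- small_pipeline_inputs(seed = s)
    cv <- loocv(inp$proteome, inp$R_hat, K = 4)
    core <- inp$truth$protein_id[inp$truth$scg_assignment == "core"]
    coefficient_proportionality(cv, core)$overall_r_squared
  }, numeric(1))
  expect_true(all(r2 >= 0.9))
})

test_that("linked synthetic data give a significant permutation test", {
  inp <- small_pipeline_inputs(seed = 4)
  cv <- loocv(inp$proteome, inp$R_hat, K = 4)
  pt <- permutation_test(inp$proteome, cv$predictions, n_perm = 1000,
                         seed = 3)
  expect_lte(pt$p_value, 0.01)
})
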