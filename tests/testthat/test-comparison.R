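rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
}

test_that("Haar draws are orthogonal with the right first-entry moments", {
  Q <- haar_orthogonal(8, seed = 1)
  expect_lt(max(abs(crossprod(Q) - diag(8))), 1e-10)
  expect_equal(unname(sqrt(colSums(Q^2))), rep(1, 8), tolerance = 1e-10)
  set.seed(2)
  q11 <- vapply(1:2000, function(i) haar_orthogonal(3)[1, 1], numeric(1))
  expect_equal(mean(q11), 0, tolerance = 0.05)
  expect_equal(var(q11), 1 / 3, tolerance = 0.05)
})

test_that("closeness score: identity 1, reversal -1, Haar null near 0", {
  expect_equal(closeness_score(diag(15)), 1, tolerance = 1e-12)
  rev3 <- diag(3)[3:1, ]
  expect_equal(closeness_score(rev3), -1, tolerance = 1e-12)
  set.seed(3)
  scores <- vapply(1:1000, function(i) closeness_score(haar_orthogonal(15)),
                   numeric(1))
  expect_true(all(scores < 1))
  expect_equal(mean(scores), 0, tolerance = 0.02)
  expect_error(closeness_score(matrix(1, 1, 1)), "square|degenerate")
})

test_that("off-diagonal profile expands inward and totals m", {
  m <- 6
  prof_I <- offdiagonal_profile(diag(m))
  expect_equal(prof_I, c(rep(0, m - 1), m))
  Q <- haar_orthogonal(m, seed = 4)
  prof_Q <- offdiagonal_profile(Q)
  expect_false(is.unsorted(prof_Q))
  expect_equal(prof_Q[m], m, tolerance = 1e-10)
  rev4 <- diag(4)[4:1, ]
  expect_equal(offdiagonal_profile(rev4)[1], 2)  # entries (1,4) and (4,1)
})

test_that("leading-submatrix profile is k for the identity, cos^2 for a rotation", {
  m <- 5
  expect_equal(leading_submatrix_profile(diag(m)), as.numeric(1:m))
  th <- 0.7
  Q <- diag(3)
  Q[1:2, 1:2] <- rot2(th)
  expect_equal(leading_submatrix_profile(Q)[1], cos(th)^2, tolerance = 1e-12)
  expect_equal(leading_submatrix_profile(haar_orthogonal(7, seed = 5))[7], 7,
               tolerance = 1e-10)
})

test_that("theta recovers an exact rotation and the identity", {
  set.seed(6)
  X <- cbind(1, matrix(rnorm(50 * 3), 50))
  rownames(X) <- paste0("P", 1:50)
  emb <- list(trivial = X[, 1], coords = X[, -1])
  rownames(emb$coords) <- rownames(X)
  # identical coordinate sets -> identity
  om_same <- list(omega_b = X[, -1])
  fit <- compute_theta(emb, om_same)
  expect_equal(fit$theta, diag(4), tolerance = 1e-8)
  # an orthogonal map between the representations is recovered exactly:
  # build the target so its augmented form is X Q with Q block-diagonal
  # (the augmented constant column must stay fixed)
  Q <- diag(4)
  Q[2:4, 2:4] <- haar_orthogonal(3, seed = 7)
  Y <- X %*% Q
  om_rot <- list(omega_b = Y[, -1] / Y[, 1])
  rownames(om_rot$omega_b) <- rownames(X)
  fit2 <- compute_theta(emb, om_rot)
  expect_equal(fit2$theta, Q, tolerance = 1e-8)
})

test_that("theta closeness report calibrates against the Haar null", {
  rep <- theta_closeness(diag(10), n_null = 200, seed = 8)
  expect_equal(rep$closeness, 1, tolerance = 1e-12)
  expect_equal(rep$percentile, 100)
  expect_true(all(rep$null_scores < 1))
  expect_equal(rep$offdiag_profile$identity, c(rep(0, 9), 10))
  expect_equal(rep$leading_submatrix_profile$identity, as.numeric(1:10))
})

test_that("pipeline theta beats the Haar null on linked synthetic data", {
  ok <- vapply(1:3, function(s) {
    inp <- small_pipeline_inputs(seed = s)
    m <- ncol(inp$proteome)
    omega <- normalized_coefficients(loocv(inp$proteome, inp$R_hat,
                                           K = m - 1))
    emb <- csle(cosine_matrix(inp$proteome))
    fit <- compute_theta(emb, omega)
    rep <- theta_closeness(fit, n_null = 100, seed = s)
    rep$closeness > quantile(rep$null_scores, 0.95)
  }, logical(1))
  expect_true(all(ok))
})

test_that("d-g residuals vanish for a fully conserved uniform proteome", {
  n <- 40; m <- 9
  P <- outer(runif(n, 0.5, 4), rep(2, m))
  rownames(P) <- paste0("P", 1:n)
  conditions <- data.frame(condition_id = paste0("C", 1:m),
                           growth_rate = rep(1, m))
  st <- score_table(P, conditions)
  dg <- d_g_proportionality(st)
  expect_equal(dg$slope, n / sqrt(m), tolerance = 1e-8)
  expect_equal(max(abs(dg$residuals)), 0, tolerance = 1e-6)
})

test_that("growth structure shows up in the d-g residuals", {
  inp <- small_pipeline_inputs(seed = 2)
  st <- score_table(inp$proteome, inp$conditions)
  dg <- d_g_proportionality(st)
  expect_lt(dg$spearman_p, 0.01)
})

test_that("equal-growth-rate data sit near the proportionality line", {
  # chemostat-like generator: one growth rate, no condition-specific
  # programs, only symmetric background variation around the conserved core
  cfg <- generator_config(n_proteins = 300, core_size = 60,
                          specific_group_sizes = integer(0),
                          cells_per_condition = 6, replicates = 2,
                          channel_count = 300, seed = 3)
  conditions <- make_conditions(cfg$m_conditions,
                                growth_rate_range = c(1, 1.0001), seed = 3)
  pr <- make_proteome(cfg, conditions)
  st <- score_table(pr$proteome, conditions)
  dg <- d_g_proportionality(st)
  expect_lt(quantile(abs(dg$residuals), 0.95), 0.05 * median(st$centrality))
})

test_that("condition subsampling is deterministic and size-monotone", {
  inp <- small_pipeline_inputs(seed = 1)
  out1 <- subsample_conditions(inp$proteome, inp$spectra, inp$conditions,
                               sizes = c(6, 12), reps = 5, seed = 9)
  out2 <- subsample_conditions(inp$proteome, inp$spectra, inp$conditions,
                               sizes = c(6, 12), reps = 5, seed = 9)
  expect_identical(out1, out2)
  s <- out1$summary
  expect_gte(s$mean_z[s$size == 12], s$mean_z[s$size == 6])
  expect_error(subsample_conditions(inp$proteome, inp$spectra,
                                    inp$conditions, sizes = 2),
               "\\[3,")
  # full-size subsample equals the full analysis
  full <- subsample_conditions(inp$proteome, inp$spectra, inp$conditions,
                               sizes = 15, reps = 1, seed = 1)
  m <- ncol(inp$proteome)
  omega <- normalized_coefficients(fit_b(inp$proteome, inp$R_hat, K = m - 1))
  emb <- csle(cosine_matrix(inp$proteome))
  ref <- closeness_score(compute_theta(emb, omega)$theta)
  expect_equal(full$draws$closeness, ref, tolerance = 1e-8)
})
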