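test_that("cosine matrix properties: proportional rows, disjoint support, bounds", {
  P <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(0, 0, 5), d = c(4, 0, 0))
  g <- cosine_matrix(P)
  expect_equal(g$A["a", "b"], 1)
  expect_equal(g$A["c", "d"], 0)
  expect_true(all(g$A >= 0 & g$A <= 1))
  expect_equal(diag(g$A), setNames(rep(1, 4), rownames(P)))
  expect_equal(g$A, t(g$A))
  expect_error(cosine_matrix(rbind(c(1, 2), c(0, 0))), "all-zero")
  expect_error(cosine_matrix(rbind(c(1, -2), c(1, 1))), "non-negative")
})

test_that("cosine matrix is invariant to per-protein rescaling", {
  set.seed(1)
  P <- matrix(rlnorm(60), 12)
  s <- runif(12, 0.1, 10)
  expect_equal(cosine_matrix(P)$A, cosine_matrix(P * s)$A,
               tolerance = 1e-12)
})

test_that("a fully proportional proteome is one component with d = n", {
  a <- seq(1, 3, length.out = 50)
  P <- outer(a, c(1, 2, 5))
  g <- cosine_matrix(P)
  expect_equal(unname(g$degree), rep(50, 50), tolerance = 1e-8)
  scg <- extract_scgs(g)
  expect_equal(scg$sizes, 50L, ignore_attr = TRUE)
  # rank-1 similarity: only the trivial eigenvalue remains below 1, so all
  # proteins share the (empty) nontrivial coordinate set
  emb <- csle(g)
  expect_equal(ncol(emb$coords), 0L)
  expect_equal(emb$n_unit_eigenvalues, 49L)
  expect_lt(diff(range(emb$trivial)), 1e-10)
})

test_that("planted noiseless groups are recovered exactly, ordered by size", {
  cfg <- small_config(noise_cv = 0)
  conditions <- make_conditions(cfg$m_conditions, seed = 1)
  pr <- make_proteome(cfg, conditions)
  scg <- extract_scgs(cosine_matrix(pr$proteome), 0.995)
  expect_equal(scg$sizes[1:4], c(60L, 20L, 12L, 8L), ignore_attr = TRUE)
  core_ids <- pr$truth$protein_id[pr$truth$scg_assignment == "core"]
  expect_setequal(scg$components[[1]], core_ids)
})

test_that("lowering the threshold never shrinks the largest component", {
  set.seed(2)
  P <- matrix(rlnorm(80 * 6), 80)
  g <- cosine_matrix(P)
  sizes <- vapply(c(0.999, 0.99, 0.9, 0.7), function(th) {
    s <- extract_scgs(g, th)
    if (length(s$sizes)) max(s$sizes) else 0L
  }, integer(1))
  expect_true(all(diff(sizes) >= 0))
  expect_equal(length(extract_scgs(g, 1)$sizes), 0L)
})

test_that("generality attains its bounds and is scale-invariant", {
  m <- 15
  onehot <- c(3, rep(0, m - 1))
  expect_equal(generality(rbind(onehot)), 1, ignore_attr = TRUE)
  expect_equal(generality(rbind(rep(2, m))), sqrt(m), ignore_attr = TRUE)
  set.seed(3)
  P <- matrix(rlnorm(200 * m), 200)
  g1 <- generality(P)
  expect_equal(g1, generality(P * 7), tolerance = 1e-12)
  expect_true(all(g1 >= 1 & g1 <= sqrt(m)))
})

test_that("csle matches a dense eigen oracle on a small graph", {
  set.seed(4)
  P <- matrix(rlnorm(10 * 4), 10)
  g <- cosine_matrix(P)
  emb <- csle(g)
  # independent oracle: dense eigendecomposition of the symmetric form
  D <- g$degree
  M <- diag(1 / sqrt(D)) %*% g$A %*% diag(1 / sqrt(D))
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lambda_oracle <- sort(1 - ev$values)
  expect_equal(emb$trivial_eigenvalue, lambda_oracle[1], tolerance = 1e-10)
  expect_equal(emb$eigenvalues, lambda_oracle[2:4], tolerance = 1e-10)
  expect_equal(sum(abs(lambda_oracle - 1) < 1e-10), 10 - 4)
  # coordinates agree with the back-transformed oracle eigenvectors
  for (k in 1:3) {
    v <- diag(1 / sqrt(D)) %*% ev$vectors[, k + 1]
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(emb$coords[, k]), as.numeric(v), tolerance = 1e-8)
  }
  # the random-walk Laplacian annihilates the constant vector
  Lrw <- diag(10) - diag(1 / D) %*% g$A
  expect_equal(max(abs(Lrw %*% rep(1, 10))), 0, tolerance = 1e-12)
  expect_lt(diff(range(emb$trivial)), 1e-10)
})

test_that("csle eigenvalue structure follows the proteome rank", {
  inp <- small_pipeline_inputs(seed = 1)
  emb <- csle(cosine_matrix(inp$proteome))
  expect_equal(length(emb$eigenvalues), 14L)
  expect_true(all(emb$eigenvalues > 0 & emb$eigenvalues < 1))
  expect_false(is.unsorted(emb$eigenvalues))
  expect_equal(emb$n_unit_eigenvalues, nrow(inp$proteome) - 15L)
  expect_lt(abs(emb$trivial_eigenvalue), 1e-10)
})

test_that("two noiseless planted groups collapse to two embedding points", {
  pat1 <- c(1, 2, 3, 4)
  pat2 <- c(4, 1, 0.5, 2)
  P <- rbind(outer(runif(5, 0.5, 2), pat1), outer(runif(5, 0.5, 2), pat2))
  emb <- csle(cosine_matrix(P))
  within1 <- apply(emb$coords[1:5, , drop = FALSE], 2, function(v)
    diff(range(v)))
  expect_lt(max(within1), 1e-8)
  expect_gt(max(abs(emb$coords[1, ] - emb$coords[6, ])), 1e-3)
})

test_that("condition-pair similarity enumerates all pairs", {
  inp <- small_pipeline_inputs(seed = 1)
  core <- inp$truth$protein_id[inp$truth$scg_assignment == "core"]
  out <- within_group_condition_similarity(inp$proteome, core, "cosine")
  expect_equal(nrow(out), 105L)
  # a perfectly conserved group scores 1 under cosine for every pair
  P0 <- outer(1:6, c(1, 3, 2, 5))
  rownames(P0) <- paste0("P", 1:6)
  cos0 <- within_group_condition_similarity(P0, rownames(P0), "cosine")
  expect_equal(cos0$similarity, rep(1, 6), tolerance = 1e-12)
  # Pearson is location-invariant
  Pm <- rbind(c(1, 2, 3), c(2, 3, 4), c(5, 6, 7))
  pe <- within_group_condition_similarity(Pm, 1:3, "pearson")
  expect_equal(pe$similarity, rep(1, 3), tolerance = 1e-12)
  expect_error(
    within_group_condition_similarity(rbind(c(0, 1), c(1, 2)), 1:2,
                                      "pearson_log"),
    "positive")
})

test_that("PCA structure is centered and aligns with the csLE subspace", {
  P0 <- outer(1:6, c(1, 3, 2, 5))
  expect_lt(max(abs(pca_structure(P0))), 1e-10)  # identical rows collapse
  inp <- small_pipeline_inputs(seed = 1)
  pca <- pca_structure(inp$proteome)
  expect_equal(unname(colMeans(pca)), rep(0, ncol(pca)), tolerance = 1e-10)
  emb <- csle(cosine_matrix(inp$proteome))
  # largest principal angle between the leading 3-dim subspaces < 30 deg
  qa <- qr.Q(qr(pca[, 1:3]))
  qb <- qr.Q(qr(emb$coords[, 1:3]))
  cosangles <- svd(crossprod(qa, qb))$d
  expect_gt(min(cosangles), cos(30 * pi / 180))
})

test_that("score table asserts the analytic bounds", {
  inp <- small_pipeline_inputs(seed = 1)
  st <- score_table(inp$proteome, inp$conditions)
  n <- nrow(inp$proteome); m <- ncol(inp$proteome)
  expect_true(all(st$centrality >= 1 & st$centrality <= n + 1e-8))
  expect_true(all(st$generality >= 1 & st$generality <= sqrt(m) + 1e-8))
  expect_equal(attr(st, "m"), m)
  # argmax condition carries its growth rate
  i <- which.max(inp$proteome[5, ])
  expect_equal(st$argmax_condition[5], inp$conditions$condition_id[i])
})

test_that("planted partitions are recovered at low noise (ARI >= 0.99)", {
  aris <- vapply(1:10, function(s) {
    cfg <- small_config(seed = s, noise_cv = 0.01)
    conditions <- make_conditions(cfg$m_conditions, seed = s)
    pr <- make_proteome(cfg, conditions)
    scg <- extract_scgs(cosine_matrix(pr$proteome), 0.995)
    planted <- pr$truth$scg_assignment != "background"
    got <- scg$membership[planted]
    got[is.na(got)] <- -seq_len(sum(is.na(got)))  # singletons stay apart
    ari(pr$truth$scg_assignment[planted], got)
  }, numeric(1))
  expect_true(all(aris >= 0.99))
})
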