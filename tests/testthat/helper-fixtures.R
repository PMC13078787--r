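# Small-scale generator settings used across the suite: same structure as
# the full-scale defaults (growth-law core, exponential group, peaked
# groups, random background) at a size where every stage runs in seconds.
small_config <- function(seed = 1L, noise_cv = 0.05, ...) {
  generator_config(n_proteins = 300L, m_conditions = 15L, core_size = 60L,
                   specific_group_sizes = c(20L, 12L, 8L),
                   noise_cv = noise_cv,
                   cells_per_condition = 6L, replicates = 2L,
                   channel_count = 300L,
                   seed = seed, ...)
}

# generator run through preprocessing and LDA condition means
small_pipeline_inputs <- function(seed = 1L, ...) {
  cfg <- small_config(seed = seed, ...)
  conditions <- make_conditions(cfg$m_conditions, seed = seed)
  pr <- make_proteome(cfg, conditions)
  spectra <- make_spectra(pr$proteome, pr$truth, cfg)
  prep <- preprocess_spectra(spectra)
  model <- fit_lda(prep$intensities, prep$condition)
  R_hat <- condition_means(predict(model, prep$intensities),
                           prep$condition, conditions$condition_id)
  list(cfg = cfg, conditions = conditions, proteome = pr$proteome,
       truth = pr$truth, spectra = prep, lda = model, R_hat = R_hat)
}

# minimum-norm least-squares oracle built directly from the SVD,
# independent of the fitting code under test
pinv_solve <- function(X, y, tol = 1e-12) {
  sv <- svd(X)
  keep <- sv$d > tol * max(sv$d)
  sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
}

# exhaustive pairwise oracle for the stochastic superiority probability
superiority_oracle <- function(x, y) {
  s <- 0
  for (xi in x) s <- s + sum(xi > y) + 0.5 * sum(xi == y)
  s / (length(x) * length(y))
}

# adjusted Rand index between two label vectors (closed-form from the
# pair-counting contingency table)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
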