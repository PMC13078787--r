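#' Generate a condition table with growth rates
#'
#' Creates `m` culture conditions with growth rates spread across a range.
#' Rates are stratified-uniform: one draw per equal-width stratum of the
#' range, so the full range is always represented, then sorted decreasingly
#' so that condition 1 is the fastest-growing one.
#'
#' @param m number of conditions (>= 2; discriminant and cosine analyses
#'   need at least two classes).
#' @param growth_rate_range length-2 non-negative range of growth rates,
#'   per hour.
#' @param replicate_count biological replicates per condition.
#' @param seed optional integer seed; the same seed reproduces the table.
#' @return data.frame with columns `condition_id`, `growth_rate`,
#'   `replicate_count`.
#' @export
make_conditions <- function(m, growth_rate_range = c(0.05, 2),
                            replicate_count = 3L, seed = NULL) {
  stop_if_not_scalar(m, "m")
  if (m < 2) stop("at least 2 conditions are required", call. = FALSE)
  if (length(growth_rate_range) != 2L || any(growth_rate_range < 0) ||
      diff(growth_rate_range) < 0) {
    stop("'growth_rate_range' must be a non-negative increasing pair",
         call. = FALSE)
  }
  m <- as.integer(m)
  lo <- growth_rate_range[1]
  hi <- growth_rate_range[2]
  rates <- with_seed(seed, {
    u <- (seq_len(m) - 1L + runif(m)) / m
    sort(lo + u * (hi - lo), decreasing = TRUE)
  })
  data.frame(
    condition_id = sprintf("C%02d", seq_len(m)),
    growth_rate = rates,
    replicate_count = as.integer(replicate_count)
  )
}

#' Configuration for the synthetic omics/spectra generator
#'
#' Defaults mirror the scale of the reference study: 2058 protein species
#' under 15 conditions with a growth-law core of 191 proteins and four
#' condition-specific stoichiometrically conserved groups of 26, 20, 10 and
#' 9 members; 15 cells x 3 replicates per condition; spectra on a 1 cm^-1
#' grid over 632-1862 cm^-1.
#'
#' @param n_proteins number of protein species.
#' @param m_conditions number of culture conditions.
#' @param core_size size of the planted growth-law core (largest group).
#' @param specific_group_sizes integer vector of condition-specific group
#'   sizes; the first such group follows an exponential growth-rate law,
#'   the rest are peaked at single conditions.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   abundance noise (0 = noiseless).
#' @param cells_per_condition,replicates single cells measured per
#'   condition and replicate count.
#' @param channel_count number of spectral channels (>= 8).
#' @param wavenumber_range length-2 range of the wavenumber axis in cm^-1.
#' @param spectral_noise_sd standard deviation of the additive Gaussian
#'   channel noise, on the scale of a unit-standard-deviation clean
#'   spectrum.
#' @param eta_sdlog sdlog of the per-cell lognormal intensity scale factor
#'   (0 fixes the scale to 1).
#' @param amplitude_sdlog sdlog of the per-protein lognormal amplitude.
#' @param core_amplitude_factor multiplicative amplitude boost of the
#'   growth-law core, giving it a dominant mass share of the proteome
#'   (ribosomal and information-processing proteins carry a large share of
#'   cell mass).
#' @param bg_pattern_sdlog sdlog of the independent lognormal
#'   condition patterns of background proteins; kept below the planted
#'   groups' condition responses, which span more than an order of
#'   magnitude.
#' @param seed integer seed giving full determinism of the generator.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_proteins = 2058L, m_conditions = 15L,
                             core_size = 191L,
                             specific_group_sizes = c(26L, 20L, 10L, 9L),
                             noise_cv = 0.05,
                             cells_per_condition = 15L, replicates = 3L,
                             channel_count = 1231L,
                             wavenumber_range = c(632, 1862),
                             spectral_noise_sd = 0.02,
                             eta_sdlog = 0.05,
                             amplitude_sdlog = 1,
                             core_amplitude_factor = 3,
                             bg_pattern_sdlog = 0.5,
                             seed = NULL) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              m_conditions = as.integer(m_conditions),
              core_size = as.integer(core_size),
              specific_group_sizes = as.integer(specific_group_sizes),
              noise_cv = noise_cv,
              cells_per_condition = as.integer(cells_per_condition),
              replicates = as.integer(replicates),
              channel_count = as.integer(channel_count),
              wavenumber_range = as.numeric(wavenumber_range),
              spectral_noise_sd = spectral_noise_sd,
              eta_sdlog = eta_sdlog,
              amplitude_sdlog = amplitude_sdlog,
              core_amplitude_factor = core_amplitude_factor,
              bg_pattern_sdlog = bg_pattern_sdlog,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (any(c(cfg$core_size, cfg$specific_group_sizes) < 0)) {
    stop("group sizes must be non-negative", call. = FALSE)
  }
  if (cfg$core_size + sum(cfg$specific_group_sizes) > cfg$n_proteins) {
    stop("core_size + sum(specific_group_sizes) exceeds n_proteins",
         call. = FALSE)
  }
  if (cfg$noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (cfg$spectral_noise_sd < 0 || cfg$eta_sdlog < 0) {
    stop("spectral noise parameters must be >= 0", call. = FALSE)
  }
  if (cfg$channel_count < 8) {
    stop("channel_count must be >= 8 (smoothing window must fit)",
         call. = FALSE)
  }
  if (diff(cfg$wavenumber_range) <= 0) {
    stop("wavenumber_range must be increasing", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

# lognormal noise factor with mean 1 and coefficient of variation cv
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

# condition patterns (m-vectors) shared by the members of each planted group
planted_patterns <- function(cfg, growth_rates) {
  mu <- growth_rates
  n_spec <- length(cfg$specific_group_sizes)
  patterns <- list(core = mu)
  if (n_spec >= 1) {
    # exponential growth-rate law with ~30-fold dynamic range over the
    # observed growth-rate span
    b <- log(30) / max(diff(range(mu)), .Machine$double.eps)
    patterns$scg2 <- exp(b * (mu - min(mu)))
  }
  if (n_spec >= 2) {
    # remaining groups peak at single conditions spread over the
    # growth-rate ordering
    ord <- order(mu)
    pos <- round(seq(1, length(mu), length.out = n_spec))[-1]
    for (k in seq_len(n_spec - 1)) {
      pat <- rep(0.05, length(mu))
      pat[ord[pos[k]]] <- 1
      patterns[[paste0("scg", k + 2)]] <- pat
    }
  }
  patterns
}

#' Generate a proteome matrix with planted stoichiometry-conserving groups
#'
#' Core proteins follow the growth law `a_i * mu_j` (protein-specific
#' amplitude, shared linear growth-rate dependence); the first
#' condition-specific group follows `a_i * exp(b * mu_j)`; the remaining
#' groups share single-condition-peaked patterns; background proteins get
#' independent random non-negative patterns. All abundances are multiplied
#' by lognormal noise with coefficient of variation `noise_cv`.
#'
#' @param cfg a [generator_config()].
#' @param conditions a condition table from [make_conditions()] with
#'   `m_conditions` rows.
#' @param seed seed; defaults to `cfg$seed`.
#' @return list with `proteome` (n x m non-negative matrix, dimnames set)
#'   and `truth` (data.frame: `protein_id`, `scg_assignment`,
#'   `signature_index`, `centrality_rank` where rank 1 is the most central
#'   protein of the noiseless construction).
#' @export
make_proteome <- function(cfg, conditions, seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  if (nrow(conditions) != cfg$m_conditions) {
    stop("condition table does not match cfg$m_conditions", call. = FALSE)
  }
  n <- cfg$n_proteins
  m <- cfg$m_conditions
  mu <- conditions$growth_rate
  patterns <- planted_patterns(cfg, mu)
  sizes <- c(cfg$core_size, cfg$specific_group_sizes)
  labels <- c("core", names(patterns)[-1])[seq_along(sizes)]
  n_bg <- n - sum(sizes)
  assignment <- c(rep(labels, sizes), rep("background", n_bg))

  with_seed(seed, {
    amps <- rlnorm(n, meanlog = log(100), sdlog = cfg$amplitude_sdlog)
    if (cfg$core_size > 0) {
      amps[seq_len(cfg$core_size)] <-
        amps[seq_len(cfg$core_size)] * cfg$core_amplitude_factor
    }
    clean <- matrix(0, n, m)
    row0 <- 0L
    for (g in seq_along(sizes)) {
      if (sizes[g] == 0) next
      idx <- row0 + seq_len(sizes[g])
      clean[idx, ] <- outer(amps[idx], patterns[[g]])
      row0 <- row0 + sizes[g]
    }
    if (n_bg > 0) {
      idx <- row0 + seq_len(n_bg)
      clean[idx, ] <- amps[idx] *
        matrix(rlnorm(n_bg * m, 0, cfg$bg_pattern_sdlog), n_bg, m)
    }
    noise <- matrix(lnorm_noise(n * m, cfg$noise_cv), n, m)
    proteome <- clean * noise
    dimnames(proteome) <- list(sprintf("P%04d", seq_len(n)),
                               conditions$condition_id)
    # centrality rank of the noiseless construction, for annotation planting
    nm <- clean / sqrt(rowSums(clean^2))
    d <- as.vector(tcrossprod(nm) %*% rep(1, n))
    truth <- data.frame(
      protein_id = rownames(proteome),
      scg_assignment = assignment,
      signature_index = seq_len(n),
      centrality_rank = rank(-d, ties.method = "first")
    )
    list(proteome = proteome, truth = truth)
  })
}

# channels x n non-negative signature matrix: 3-8 Gaussian peaks per
# protein, centers on the fingerprint band, widths 8-25 cm^-1
make_signatures <- function(n, wavenumbers) {
  lo <- max(min(wavenumbers), 700)
  hi <- min(max(wavenumbers), 1800)
  if (lo >= hi) {  # axis does not reach the fingerprint band
    rng <- range(wavenumbers)
    lo <- rng[1] + 0.1 * diff(rng)
    hi <- rng[2] - 0.1 * diff(rng)
  }
  S <- matrix(0, length(wavenumbers), n)
  for (i in seq_len(n)) {
    k <- sample(3:8, 1)
    centers <- runif(k, lo, hi)
    widths <- runif(k, 8, 25)
    heights <- runif(k, 0.2, 1)
    for (p in seq_len(k)) {
      S[, i] <- S[, i] +
        heights[p] * exp(-(wavenumbers - centers[p])^2 / (2 * widths[p]^2))
    }
  }
  S
}

#' Generate paired single-cell spectra under a linear protein-to-spectrum map
#'
#' Each cell's spectrum is `S p_j * eta + eps`: a fixed non-negative
#' signature matrix `S` applied to the condition's proteome column, scaled
#' by a per-cell lognormal factor `eta`, plus i.i.d. Gaussian channel noise.
#' Condition-mean spectra are therefore an exact linear function of the
#' proteome columns when `eta_sdlog = 0` and `spectral_noise_sd = 0`.
#'
#' @inheritParams make_proteome
#' @param proteome n x m abundance matrix (columns = conditions).
#' @param truth ground-truth table from [make_proteome()].
#' @return a [spectra_set()] with `cells_per_condition * replicates` cells
#'   per condition.
#' @export
make_spectra <- function(proteome, truth, cfg,
                         seed = if (is.null(cfg$seed)) NULL else cfg$seed + 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- nrow(proteome)
  m <- ncol(proteome)
  if (n != cfg$n_proteins || m != cfg$m_conditions) {
    stop("proteome dimensions do not match cfg", call. = FALSE)
  }
  wn <- seq(cfg$wavenumber_range[1], cfg$wavenumber_range[2],
            length.out = cfg$channel_count)
  with_seed(seed, {
    S <- make_signatures(n, wn)
    clean <- S %*% proteome                      # channels x m
    scale0 <- median(apply(clean, 2, sd))
    if (scale0 > 0) clean <- clean / scale0      # unit-sd clean spectra
    per_cond <- cfg$cells_per_condition * cfg$replicates
    n_cells <- per_cond * m
    X <- matrix(0, n_cells, cfg$channel_count)
    condition <- character(n_cells)
    replicate <- integer(n_cells)
    row <- 0L
    for (j in seq_len(m)) {
      for (r in seq_len(cfg$replicates)) {
        for (cell in seq_len(cfg$cells_per_condition)) {
          row <- row + 1L
          eta <- if (cfg$eta_sdlog == 0) 1 else
            rlnorm(1, -cfg$eta_sdlog^2 / 2, cfg$eta_sdlog)
          eps <- if (cfg$spectral_noise_sd == 0) 0 else
            rnorm(cfg$channel_count, sd = cfg$spectral_noise_sd)
          X[row, ] <- clean[, j] * eta + eps
          condition[row] <- colnames(proteome)[j]
          replicate[row] <- r
        }
      }
    }
    spectra_set(X, wn, condition, replicate)
  })
}

#' Generate a synthetic gene-annotation table
#'
#' Essentiality, ortholog counts and coding status are planted with a
#' logistic (essential/coding) or log-linear (orthologs) dependence on the
#' centrality rank of the noiseless construction; `enrichment_strength = 0`
#' makes every attribute independent of rank, 1 gives the strongest
#' association.
#'
#' @param truth ground-truth table from [make_proteome()].
#' @param enrichment_strength scalar in `[0, 1]`.
#' @param seed optional seed for reproducibility.
#' @return data.frame: `gene_id`, `essential` (logical),
#'   `ortholog_count` (integer), `coding` (logical).
#' @export
make_annotations <- function(truth, enrichment_strength = 0.5, seed = NULL) {
  if (enrichment_strength < 0 || enrichment_strength > 1) {
    stop("enrichment_strength must be in [0, 1]", call. = FALSE)
  }
  n <- nrow(truth)
  u <- (n - truth$centrality_rank + 0.5) / n   # 1 = most central
  s <- enrichment_strength
  with_seed(seed, {
    p_ess <- plogis(qlogis(0.15) + 8 * s * (u - 0.5))
    p_cod <- plogis(qlogis(0.85) + 6 * s * (u - 0.5))
    lam <- exp(log(20) + 3 * s * (u - 0.5))
    data.frame(
      gene_id = truth$protein_id,
      essential = rbinom(n, 1, p_ess) == 1,
      ortholog_count = rpois(n, lam),
      coding = rbinom(n, 1, p_cod) == 1
    )
  })
}

#' Write all generator outputs to a directory as TSV files
#'
#' Writes `conditions.tsv`, `proteome.tsv`, `spectra.tsv` (+ wavenumber
#' sidecar), `truth.tsv` and `annotations.tsv`.
#'
#' @param dir output directory (created if missing).
#' @param cfg a [generator_config()].
#' @param enrichment_strength passed to [make_annotations()].
#' @return invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(dir, cfg = generator_config(),
                             enrichment_strength = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conditions <- make_conditions(cfg$m_conditions, seed = cfg$seed)
  pr <- make_proteome(cfg, conditions)
  spectra <- make_spectra(pr$proteome, pr$truth, cfg)
  ann <- make_annotations(pr$truth, enrichment_strength,
                          seed = if (is.null(cfg$seed)) NULL else cfg$seed + 2L)
  write_tsv(conditions, file.path(dir, "conditions.tsv"))
  write_proteome_tsv(pr$proteome, file.path(dir, "proteome.tsv"))
  write_spectra_tsv(spectra, file.path(dir, "spectra.tsv"))
  write_tsv(pr$truth, file.path(dir, "truth.tsv"))
  write_tsv(ann, file.path(dir, "annotations.tsv"))
  invisible(list(conditions = conditions, proteome = pr$proteome,
                 truth = pr$truth, spectra = spectra, annotations = ann))
}
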