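#' Configuration for the end-to-end analysis pipeline
#'
#' @param generator a [generator_config()] used when no input paths are
#'   given (simulation mode).
#' @param input_paths optional named list with paths `proteome`, `spectra`,
#'   `conditions` and optionally `annotations` (TSV, formats as written by
#'   [simulate_dataset()]); when given, the generator is ignored.
#' @param K number of discriminant axes for the correspondence fit.
#' @param threshold cosine threshold for SCG extraction.
#' @param n_perm permutations for the cross-validation permutation test.
#' @param n_null Haar draws for the orthogonal-matrix null.
#' @param metrics distance metrics for [loocv()].
#' @param enrichment_strength annotation planting strength (simulation
#'   mode).
#' @param theta_b_estimate coefficient estimate used for the structural
#'   comparison: `"loo_average"` or `"full"`.
#' @param preprocess list of [preprocess_spectra()] arguments.
#' @param n_bins rank classes for the annotation fraction curves.
#' @param seed base seed; per-stage seeds are derived from it and recorded
#'   in the report.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(seed = 1L),
                            input_paths = NULL,
                            K = 4L, threshold = 0.995,
                            n_perm = 10000L, n_null = 1000L,
                            metrics = c("euclidean_sq", "manhattan",
                                        "cosine_dist", "one_minus_pearson"),
                            enrichment_strength = 0.5,
                            theta_b_estimate = c("loo_average", "full"),
                            preprocess = list(),
                            n_bins = 10L,
                            seed = 1L) {
  structure(list(generator = generator, input_paths = input_paths,
                 K = as.integer(K), threshold = threshold,
                 n_perm = as.integer(n_perm), n_null = as.integer(n_null),
                 metrics = metrics,
                 enrichment_strength = enrichment_strength,
                 theta_b_estimate = match.arg(theta_b_estimate),
                 preprocess = preprocess,
                 n_bins = as.integer(n_bins),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value YAML; keys match the arguments of [pipeline_config()]
#' and [generator_config()] (generator keys under `generator:`).
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs",
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  gen <- do.call(generator_config, raw$generator %||% list())
  raw$generator <- gen
  do.call(pipeline_config, raw)
}

#' Validate pipeline inputs
#'
#' Checks matrix shapes, label joins, non-negativity and zero rows, and
#' distinguishes warnings from fatal problems. Reports issues instead of
#' raising errors.
#'
#' @param proteome,spectra,conditions,annotations optional objects to
#'   check (matrix, [spectra_set()], condition table, annotation table).
#' @return data.frame with columns `severity` (`"fatal"`/`"warning"`) and
#'   `message`; zero rows when everything is well-formed.
#' @export
validate_inputs <- function(proteome = NULL, spectra = NULL,
                            conditions = NULL, annotations = NULL) {
  issues <- list()
  add <- function(severity, msg) {
    issues[[length(issues) + 1L]] <<- data.frame(severity = severity,
                                                 message = msg)
  }
  if (!is.null(proteome)) {
    proteome <- as.matrix(proteome)
    neg <- which(proteome < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      add("fatal", sprintf("negative abundance at row %d, column %d",
                           neg[1, 1], neg[1, 2]))
    }
    zero <- which(rowSums(abs(proteome)) == 0)
    if (length(zero)) {
      add("fatal", sprintf("%d all-zero protein rows (first: %s)",
                           length(zero),
                           rownames(proteome)[zero[1]] %||% zero[1]))
    }
    if (!is.null(conditions) && nrow(conditions) != ncol(proteome)) {
      add("fatal", "condition table does not match proteome columns")
    }
  }
  if (!is.null(spectra) && !is.null(conditions)) {
    extra <- setdiff(unique(spectra$condition), conditions$condition_id)
    if (length(extra)) {
      add("fatal", sprintf("spectra conditions missing from the table: %s",
                           paste(extra, collapse = ", ")))
    }
    uncovered <- setdiff(conditions$condition_id, spectra$condition)
    if (length(uncovered)) {
      add("fatal", sprintf("conditions with no cells: %s",
                           paste(uncovered, collapse = ", ")))
    }
  }
  if (!is.null(annotations) && !is.null(proteome)) {
    miss <- sum(!annotations$gene_id %in% rownames(proteome))
    if (miss > 0) {
      add("warning", sprintf("%d annotation ids not in the proteome", miss))
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(severity = character(0), message = character(0))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the dataset, preprocesses spectra, fits the
#' condition classifier, validates the linear spectra-to-proteome
#' correspondence (leave-one-out cross-validation + permutation test),
#' builds the cosine-similarity network (SCGs, centrality, generality,
#' Laplacian-eigenmap embedding), compares the embedding- and
#' regression-based structures via the orthogonal alignment matrix, and
#' runs the annotation rank tests. Writes every intermediate artifact as
#' TSV plus a machine-readable JSON report to `outdir`.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @param quiet suppress per-stage log lines.
#' @return the report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempdir(),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log1 <- function(...) if (!quiet) message(sprintf(...))

  # --- stage 1: inputs ------------------------------------------------
  if (is.null(config$input_paths)) {
    gen <- config$generator
    if (is.null(gen$seed)) gen$seed <- config$seed
    conditions <- make_conditions(gen$m_conditions, seed = gen$seed)
    pr <- make_proteome(gen, conditions)
    proteome <- pr$proteome
    truth <- pr$truth
    spectra <- make_spectra(proteome, truth, gen)
    annotations <- make_annotations(truth, config$enrichment_strength,
                                    seed = gen$seed + 2L)
    write_tsv(truth, file.path(outdir, "truth.tsv"))
  } else {
    p <- config$input_paths
    for (f in c("proteome", "spectra", "conditions")) {
      if (is.null(p[[f]]) || !file.exists(p[[f]])) {
        stop(sprintf("input path '%s' is missing", f), call. = FALSE)
      }
    }
    proteome <- read_proteome_tsv(p$proteome)
    spectra <- read_spectra_tsv(p$spectra)
    conditions <- read_tsv(p$conditions)
    annotations <- if (!is.null(p$annotations)) read_tsv(p$annotations)
    truth <- NULL
  }
  issues <- validate_inputs(proteome, spectra, conditions, annotations)
  if (any(issues$severity == "fatal")) {
    stop("input validation failed: ",
         paste(issues$message[issues$severity == "fatal"], collapse = "; "),
         call. = FALSE)
  }
  for (w in issues$message[issues$severity == "warning"]) warning(w)
  write_tsv(conditions, file.path(outdir, "conditions.tsv"))
  write_proteome_tsv(proteome, file.path(outdir, "proteome.tsv"))
  log1("inputs: proteome %d x %d, %d cells x %d channels",
       nrow(proteome), ncol(proteome),
       nrow(spectra$intensities), ncol(spectra$intensities))

  # --- stage 2: preprocessing -----------------------------------------
  prep <- do.call(preprocess_spectra, c(list(spectra), config$preprocess))
  log1("preprocess: %d channels retained", ncol(prep$intensities))

  # --- stage 3: LDA ----------------------------------------------------
  model <- fit_lda(prep$intensities, prep$condition)
  scores <- predict(model, prep$intensities)
  R_hat <- condition_means(scores, prep$condition,
                           condition_order = conditions$condition_id)
  growth_cor <- growth_rate_correlation(R_hat, conditions$growth_rate)
  write_tsv(data.frame(cell_id = prep$cell_id, condition = prep$condition,
                       scores, check.names = FALSE),
            file.path(outdir, "lda_scores.tsv"))
  write_tsv(data.frame(condition_id = rownames(R_hat), R_hat,
                       check.names = FALSE),
            file.path(outdir, "condition_means.tsv"))
  log1("lda: %d axes, |r|(LDA1, growth) = %.3f", model$n_axes,
       growth_cor$abs_r)

  # --- stage 4: correspondence ----------------------------------------
  cv <- loocv(proteome, R_hat, K = config$K, metrics = config$metrics)
  perm <- permutation_test(proteome, cv$predictions,
                           metric = config$metrics[1],
                           n_perm = config$n_perm,
                           seed = config$seed + 10L)
  omega_k <- normalized_coefficients(cv)
  log1("correspondence: K = %d, permutation p = %.2g", config$K,
       perm$p_value)

  # --- stage 5: network ------------------------------------------------
  graph <- cosine_matrix(proteome)
  scgs <- extract_scgs(graph, config$threshold)
  emb <- csle(graph)
  st <- score_table(proteome, conditions, graph)
  pca <- pca_structure(proteome)
  write_tsv(cbind(st, scg_rank = scgs$membership,
                  as.data.frame(emb$coords)),
            file.path(outdir, "score_table.tsv"))
  log1("network: %d SCGs (sizes %s)", length(scgs$sizes),
       paste(utils::head(scgs$sizes, 5), collapse = ", "))

  # --- stage 6: structural comparison ----------------------------------
  m <- ncol(proteome)
  b_full <- if (config$theta_b_estimate == "full") {
    fit_b(proteome, R_hat, K = m - 1L)
  } else {
    loocv(proteome, R_hat, K = m - 1L)
  }
  omega_full <- normalized_coefficients(b_full)
  theta_fit <- compute_theta(emb, omega_full)
  theta_rep <- theta_closeness(theta_fit, n_null = config$n_null,
                               seed = config$seed + 20L)
  dg <- d_g_proportionality(st)
  write_tsv(data.frame(protein_id = rownames(omega_full$omega_b),
                       omega_full$omega_b, check.names = FALSE),
            file.path(outdir, "omega_b.tsv"))
  log1("comparison: theta closeness %.3f (null percentile %.1f)",
       theta_rep$closeness, theta_rep$percentile)

  # --- stage 7: annotation statistics ----------------------------------
  annotation_report <- NULL
  if (!is.null(annotations)) {
    idx <- match(st$protein_id, annotations$gene_id)
    ann <- annotations[idx, ]
    keep <- !is.na(idx)
    curves <- list()
    tests <- list()
    if (!is.null(ann$essential)) {
      curves$essential <- binned_fraction_curve(st$centrality[keep],
                                                ann$essential[keep],
                                                config$n_bins)
      tests$essential <- quartile_comparison(st$centrality[keep],
                                             as.numeric(ann$essential[keep]))
    }
    if (!is.null(ann$ortholog_count)) {
      tests$ortholog <- quartile_comparison(st$centrality[keep],
                                            ann$ortholog_count[keep])
    }
    if (!is.null(ann$coding)) {
      curves$coding <- binned_fraction_curve(st$centrality[keep],
                                             ann$coding[keep],
                                             config$n_bins)
    }
    annotation_report <- list(
      curves = curves,
      tests = lapply(tests, function(t) list(
        score_split_p = t$score_split$p_value,
        attribute_split_p = t$attribute_split$p_value))
    )
    log1("annotation: %d genes joined", sum(keep))
  }

  report <- list(
    schema_version = "1.0",
    seed = config$seed,
    n_proteins = nrow(proteome),
    n_conditions = m,
    lda = list(n_axes = model$n_axes,
               eigenvalues = model$eigenvalues,
               growth_rate_r = growth_cor$r,
               growth_rate_abs_r = growth_cor$abs_r),
    loocv = list(K = config$K,
                 overall_errors = as.list(cv$overall),
                 permutation_p = perm$p_value,
                 n_perm = perm$n_perm),
    scg = list(count = length(scgs$sizes), sizes = scgs$sizes,
               threshold = config$threshold),
    centrality = list(min = min(st$centrality), max = max(st$centrality),
                      median = median(st$centrality)),
    generality = list(min = min(st$generality), max = max(st$generality),
                      median = median(st$generality)),
    csle = list(eigenvalues = emb$eigenvalues,
                n_unit_eigenvalues = emb$n_unit_eigenvalues),
    theta = list(closeness = theta_rep$closeness,
                 percentile = theta_rep$percentile,
                 n_null = config$n_null,
                 b_estimate = config$theta_b_estimate),
    d_g = list(slope = dg$slope, spearman_rho = dg$spearman_rho,
               spearman_p = dg$spearman_p),
    annotation = annotation_report
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
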