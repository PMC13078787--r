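#' Cosine-similarity graph of expression vectors
#'
#' Builds the n x n matrix `A` whose (i, j) entry is the cosine similarity
#' between the across-condition expression vectors of proteins i and j, the
#' adjacency matrix of a weighted complete graph with unit loops. The
#' weighted degree `d = A 1` is the stoichiometry conservation centrality.
#'
#' @param P proteins x conditions non-negative abundance matrix with no
#'   all-zero rows.
#' @return object of class `similarity_graph`: `A`, `degree`, and the
#'   row-normalized matrix `normalized` used by the low-rank eigensolver.
#' @export
cosine_matrix <- function(P) {
  P <- as.matrix(P)
  if (any(P < 0)) stop("abundances must be non-negative", call. = FALSE)
  norms <- sqrt(rowSums(P^2))
  zero <- norms == 0
  if (any(zero)) {
    ids <- rownames(P)[zero] %||% which(zero)
    stop(sprintf("all-zero expression rows: %s",
                 paste(utils::head(ids, 5), collapse = ", ")), call. = FALSE)
  }
  N <- P / norms
  A <- tcrossprod(N)
  A <- pmin(A, 1)
  diag(A) <- 1
  structure(list(A = A, degree = rowSums(A), normalized = N,
                 protein_ids = rownames(P)),
            class = "similarity_graph")
}

#' Extract stoichiometrically conserved groups (SCGs)
#'
#' Thresholds the cosine-similarity graph (edges where `A_ij >= threshold`,
#' i != j) and returns its connected components with at least 2 members,
#' ordered by decreasing size (ties broken by smallest member index).
#' Singleton proteins are not reported.
#'
#' @param graph a [cosine_matrix()] result.
#' @param threshold cosine threshold in (0, 1]; the study's operating value
#'   is 0.995.
#' @return list with `components` (list of protein-id vectors, SCG 1
#'   first), `sizes`, `membership` (per-protein SCG rank, NA outside any
#'   SCG), `threshold`.
#' @export
extract_scgs <- function(graph, threshold = 0.995) {
  stopifnot(inherits(graph, "similarity_graph"))
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  E <- graph$A >= threshold
  diag(E) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(E, mode = "undirected")
  comp <- igraph::components(g)
  n <- nrow(graph$A)
  ids <- graph$protein_ids %||% as.character(seq_len(n))
  groups <- split(seq_len(n), comp$membership)
  groups <- Filter(function(x) length(x) >= 2, groups)
  if (length(groups)) {
    ord <- order(-vapply(groups, length, integer(1)),
                 vapply(groups, min, integer(1)))
    groups <- groups[ord]
  }
  membership <- rep(NA_integer_, n)
  for (k in seq_along(groups)) membership[groups[[k]]] <- k
  list(components = lapply(groups, function(x) ids[x]),
       sizes = vapply(groups, length, integer(1)),
       membership = membership,
       threshold = threshold)
}

#' Expression generality score
#'
#' Per protein, the ratio of the L1 to the L2 norm of its across-condition
#' expression vector. The score is scale-invariant and bounded: 1 for a
#' completely condition-specific (one-hot) vector, `sqrt(m)` for perfectly
#' uniform expression over m conditions.
#'
#' @param P proteins x conditions non-negative matrix with no all-zero rows.
#' @return numeric vector of generality scores, named by protein.
#' @export
generality <- function(P) {
  P <- as.matrix(P)
  l2 <- sqrt(rowSums(P^2))
  if (any(l2 == 0)) stop("all-zero expression rows present", call. = FALSE)
  g <- rowSums(abs(P)) / l2
  names(g) <- rownames(P)
  g
}

#' Cosine-similarity Laplacian eigenmaps (csLE)
#'
#' Embeds the proteins with eigenvectors of the random-walk normalized
#' Laplacian `L_rw = I - D^-1 A` of the cosine-similarity graph. The
#' computation uses the equivalent symmetric problem on
#' `D^-1/2 A D^-1/2` for stability and exploits `A`'s low rank (at most the
#' number of conditions), so only an m x m eigenproblem is solved. The
#' trivial eigenvalue 0 has a constant eigenvector; there are
#' `min(m, rank) - 1` nontrivial eigenvalues strictly in (0, 1), and all
#' remaining eigenvalues equal 1.
#'
#' Eigenvectors are scaled to unit L2 norm with the largest-magnitude entry
#' positive.
#'
#' @param graph a [cosine_matrix()] result (all degrees are >= 1 by
#'   construction).
#' @param tol relative tolerance separating nontrivial eigenvalues from 0
#'   and 1.
#' @return object of class `csle_embedding`: `eigenvalues` (nontrivial,
#'   ascending), `coords` (n x k matrix, columns csLE1..), `trivial`
#'   (eigenvalue-0 eigenvector), `n_unit_eigenvalues`.
#' @export
csle <- function(graph, tol = 1e-10) {
  stopifnot(inherits(graph, "similarity_graph"))
  d <- graph$degree
  if (any(d <= 0)) stop("zero-degree node in the graph", call. = FALSE)
  FF <- graph$normalized / sqrt(d)         # D^-1/2 N ; M = FF t(FF)
  G <- crossprod(FF)                       # m x m, same nonzero spectrum
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- eg$values > tol * max(eg$values)
  mu <- eg$values[pos]                     # descending, in (0, 1]
  U <- FF %*% eg$vectors[, pos, drop = FALSE]
  U <- sweep(U, 2, sqrt(mu), "/")          # eigenvectors of the sym. form
  Vrw <- U / sqrt(d)                       # back-transform to L_rw space
  # unit norm + sign convention
  Vrw <- vapply(seq_len(ncol(Vrw)), function(j) {
    v <- Vrw[, j]
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) -v else v
  }, numeric(nrow(Vrw)))
  Vrw <- matrix(Vrw, ncol = sum(pos))
  lambda <- 1 - mu                         # ascending; lambda[1] ~ 0 trivial
  n <- nrow(Vrw)
  coords <- Vrw[, -1, drop = FALSE]
  if (ncol(coords) > 0) {
    colnames(coords) <- paste0("csLE", seq_len(ncol(coords)))
  }
  rownames(coords) <- graph$protein_ids
  structure(list(eigenvalues = lambda[-1],
                 coords = coords,
                 trivial = Vrw[, 1],
                 trivial_eigenvalue = lambda[1],
                 n_unit_eigenvalues = n - sum(pos)),
            class = "csle_embedding")
}

#' Condition-pair expression similarity within a protein group
#'
#' For every unordered pair of conditions, the similarity between the two
#' group-restricted condition profiles. With m conditions this yields
#' m(m-1)/2 values.
#'
#' @param P proteins x conditions matrix.
#' @param group_ids protein ids or row indices (>= 2 proteins).
#' @param measure `pearson`, `pearson_log` (natural log; requires strictly
#'   positive abundances), or `cosine`.
#' @return data.frame with columns `condition_i`, `condition_j`,
#'   `similarity`.
#' @export
within_group_condition_similarity <- function(P, group_ids,
                                              measure = c("pearson",
                                                          "pearson_log",
                                                          "cosine")) {
  measure <- match.arg(measure)
  P <- as.matrix(P)
  rows <- if (is.character(group_ids)) match(group_ids, rownames(P))
          else as.integer(group_ids)
  if (anyNA(rows)) stop("unknown protein ids in group", call. = FALSE)
  if (length(rows) < 2) stop("group needs >= 2 proteins", call. = FALSE)
  sub <- P[rows, , drop = FALSE]
  if (measure == "pearson_log") {
    if (any(sub <= 0)) {
      stop("pearson_log requires strictly positive abundances",
           call. = FALSE)
    }
    sub <- log(sub)
  }
  pairs <- combn(ncol(sub), 2)
  sim <- apply(pairs, 2, function(idx) {
    x <- sub[, idx[1]]; y <- sub[, idx[2]]
    if (measure == "cosine") sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
    else cor(x, y)
  })
  conds <- colnames(P) %||% as.character(seq_len(ncol(P)))
  data.frame(condition_i = conds[pairs[1, ]],
             condition_j = conds[pairs[2, ]],
             similarity = sim)
}

#' PCA structure of the L2-normalized expression vectors
#'
#' Principal component analysis of the proteins x conditions matrix after
#' L2 normalization of each row, the normalization under which PCA becomes
#' comparable to the cosine-similarity embedding. Returns per-protein
#' scores on the first `m - 1` components.
#'
#' @param P proteins x conditions matrix, no all-zero rows.
#' @return n x (m-1) score matrix (columns centered by construction).
#' @export
pca_structure <- function(P) {
  P <- as.matrix(P)
  norms <- sqrt(rowSums(P^2))
  if (any(norms == 0)) stop("all-zero expression rows present", call. = FALSE)
  N <- P / norms
  pc <- prcomp(N, center = TRUE, scale. = FALSE)
  k <- min(ncol(P) - 1L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(P)
  scores
}

#' Per-protein centrality/generality score table
#'
#' Combines the stoichiometry conservation centrality `d`, the expression
#' generality `g`, each protein's most-expressed condition and that
#' condition's growth rate. Bounds `1 <= d <= n` and `1 <= g <= sqrt(m)`
#' are asserted on every call.
#'
#' @param P proteins x conditions matrix.
#' @param conditions condition table with `condition_id` and `growth_rate`
#'   matching the columns of `P`.
#' @param graph optional precomputed [cosine_matrix()].
#' @return data.frame: `protein_id`, `centrality`, `generality`,
#'   `argmax_condition`, `growth_rate_argmax`; the number of conditions is
#'   stored in the `m` attribute.
#' @export
score_table <- function(P, conditions, graph = cosine_matrix(P)) {
  P <- as.matrix(P)
  n <- nrow(P)
  m <- ncol(P)
  d <- graph$degree
  g <- generality(P)
  eps <- 1e-8
  stopifnot(all(d >= 1 - eps), all(d <= n + eps),
            all(g >= 1 - eps), all(g <= sqrt(m) + eps))
  amax <- max.col(P, ties.method = "first")
  out <- data.frame(
    protein_id = rownames(P) %||% as.character(seq_len(n)),
    centrality = unname(d),
    generality = unname(g),
    argmax_condition = conditions$condition_id[amax],
    growth_rate_argmax = conditions$growth_rate[amax]
  )
  attr(out, "m") <- m
  out
}
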