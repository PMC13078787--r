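#' Fraction of flagged genes per centrality rank class
#'
#' Orders genes by a score (typically stoichiometry conservation
#' centrality), splits them into `n_bins` rank classes of near-equal size
#' (any remainder spread from the top class down), and reports the fraction
#' of flagged genes in each class, from the highest-score class to the
#' lowest.
#'
#' @param scores per-gene numeric scores.
#' @param flags per-gene logical attribute (e.g. essentiality).
#' @param n_bins number of rank classes (>= 2).
#' @return data.frame: `bin` (1 = top class), `n`, `fraction`.
#' @export
binned_fraction_curve <- function(scores, flags, n_bins = 10L) {
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  n <- length(scores)
  if (length(flags) != n) stop("scores/flags length mismatch", call. = FALSE)
  if (n < n_bins) stop("fewer genes than bins", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bin <- rep(seq_len(n_bins), sizes)
  f <- tapply(as.logical(flags)[ord], bin, mean)
  data.frame(bin = seq_len(n_bins), n = as.integer(sizes),
             fraction = as.numeric(f))
}

#' Brunner-Munzel rank test
#'
#' Nonparametric two-sample test of the stochastic superiority probability
#' `P(X > Y) + 0.5 P(X = Y)` against 1/2, robust to unequal variances.
#' Uses pooled midranks for ties and the t approximation with
#' Satterthwaite-type degrees of freedom of the original formulation.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param alternative `"greater"` tests whether `x` tends to be larger than
#'   `y`; `"less"` and `"two.sided"` as usual.
#' @return list: `statistic`, `df`, `p_value`, `estimate`
#'   (`P(X > Y) + 0.5 P(X = Y)`), `alternative`.
#' @export
brunner_munzel <- function(x, y, alternative = c("greater", "less",
                                                 "two.sided")) {
  alternative <- match.arg(alternative)
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("both samples need >= 2 values", call. = FALSE)
  r <- rank(c(x, y))                        # pooled midranks
  r1 <- r[seq_len(n1)]
  r2 <- r[n1 + seq_len(n2)]
  m1 <- mean(r1)
  m2 <- mean(r2)
  estimate <- (m1 - (n1 + 1) / 2) / n2      # P(X > Y) + 0.5 P(X = Y)
  v1 <- sum((r1 - rank(x) - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - rank(y) - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  pooled <- n1 * v1 + n2 * v2
  if (pooled == 0) {
    if (length(unique(c(x, y))) == 1L) {
      stop("zero variance estimate: all pooled ranks are identical",
           call. = FALSE)
    }
    # complete separation: the statistic diverges
    statistic <- sign(m1 - m2) * Inf
    df <- Inf
  } else {
    statistic <- (m1 - m2) * n1 * n2 / ((n1 + n2) * sqrt(pooled))
    df <- pooled^2 / ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  }
  p <- switch(alternative,
              greater = pt(statistic, df, lower.tail = FALSE),
              less = pt(statistic, df),
              two.sided = 2 * pt(abs(statistic), df, lower.tail = FALSE))
  list(statistic = statistic, df = df, p_value = p, estimate = estimate,
       alternative = alternative)
}

#' Top-quartile vs bottom-quartile attribute comparison
#'
#' Reciprocal rank tests mirroring the centrality-annotation analyses:
#' (i) split genes by `scores` rank and compare the attribute between the
#' top 25% and the bottom 25% (does high centrality go with larger
#' attribute values?), and (ii) split by the attribute rank and compare
#' the scores between its top and bottom quartiles.
#'
#' @param scores per-gene numeric scores (e.g. centrality).
#' @param attribute per-gene numeric attribute (e.g. ortholog count).
#' @param direction alternative passed to [brunner_munzel()]; the default
#'   `"greater"` tests enrichment of large attribute values at high scores.
#' @return list with `score_split` and `attribute_split`, each a
#'   [brunner_munzel()] result.
#' @export
quartile_comparison <- function(scores, attribute, direction = "greater") {
  n <- length(scores)
  if (length(attribute) != n) stop("length mismatch", call. = FALSE)
  if (n < 8) stop("at least 8 genes required", call. = FALSE)
  q <- max(2L, floor(n / 4))
  split_test <- function(by, value) {
    ord <- order(by, decreasing = TRUE)
    top <- value[ord[seq_len(q)]]
    bottom <- value[ord[n + 1 - seq_len(q)]]
    brunner_munzel(top, bottom, alternative = direction)
  }
  list(score_split = split_test(scores, attribute),
       attribute_split = split_test(attribute, scores))
}
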