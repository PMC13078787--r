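#' @importFrom stats rnorm runif rlnorm rpois rbinom plogis qlogis sd var
#'   cor cor.test prcomp predict pt setNames median quantile
#' @importFrom utils read.table write.table combn
NULL

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, ...)
}

#' Write and read a proteome abundance matrix as TSV
#'
#' The on-disk layout is one row per protein: a `protein_id` column followed
#' by one column per condition, matching the condition table's
#' `condition_id` values.
#'
#' @param proteome numeric matrix, proteins x conditions, with dimnames.
#' @param path file path.
#' @return `write_proteome_tsv` returns `path` invisibly;
#'   `read_proteome_tsv` returns the matrix with dimnames restored.
#' @export
write_proteome_tsv <- function(proteome, path) {
  df <- data.frame(protein_id = rownames(proteome), proteome,
                   check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_proteome_tsv
#' @export
read_proteome_tsv <- function(path) {
  df <- read_tsv(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$protein_id
  mat
}
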