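#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Used throughout the test-suite to score recovery of planted clusters.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return A number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Area under the ROC curve for a score vector against binary labels
#'
#' Rank-based (Mann-Whitney) AUROC; higher scores should indicate positives.
#'
#' @param score numeric scores.
#' @param label logical or 0/1 vector, TRUE for positives.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label), any(label), any(!label))
  r <- rank(score)
  n_pos <- sum(label)
  n_neg <- sum(!label)
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# internal: check a probability-like scalar
.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# internal: positive integer-ish scalar
.check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# internal: Newton inversion of trigamma, as used for the empirical-Bayes
# prior degrees of freedom. Monotone decreasing on (0, Inf).
.trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# internal: deterministic lexicographic order of a character matrix's rows
.lex_order <- function(...) do.call(order, list(...))

#' Write a data frame as a tab-separated file
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated file written by [write_tsv()]
#'
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a genes-by-samples matrix as TSV (first column = gene id)
#'
#' @param m matrix with row and column names.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a genes-by-samples matrix written by [write_matrix_tsv()]
#'
#' @param path input path.
#' @return numeric matrix with gene ids as row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
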