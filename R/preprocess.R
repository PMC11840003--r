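#' Counts per million
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @return matrix of the same shape; each column sums to 1e6.
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  libsize <- colSums(counts)
  zero <- libsize == 0
  if (any(zero))
    stop(sprintf("zero library size in sample(s): %s",
                 paste(colnames(counts)[zero], collapse = ", ")))
  sweep(counts, 2, libsize, "/") * 1e6
}

#' Expression filter on the CPM scale
#'
#' A gene is kept iff its CPM exceeds `min_cpm` (strict inequality) in at
#' least `min_samples` samples.
#'
#' @param cpm_matrix genes x samples CPM matrix.
#' @param min_cpm CPM threshold (default 10).
#' @param min_samples minimum number of samples above threshold (default 3).
#' @return character vector of kept gene ids (row indices if unnamed).
#' @export
filter_expressed <- function(cpm_matrix, min_cpm = 10, min_samples = 3) {
  if (min_cpm <= 0 || min_samples <= 0) stop("thresholds must be positive")
  if (nrow(cpm_matrix) == 0) return(character(0))
  keep <- rowSums(cpm_matrix > min_cpm) >= min_samples
  if (is.null(rownames(cpm_matrix))) which(keep) else rownames(cpm_matrix)[keep]
}

#' Smooth quantile normalization
#'
#' Group-aware quantile normalization. Per quantile level q, the normalized
#' value interpolates between the overall mean quantile O_q and the
#' group-mean quantile G_gq with a data-driven weight
#' w_q = SST_within / (SST_within + SST_between) computed over groups at q
#' and smoothed by a running median over a window of `window` of the
#' quantile levels. When all groups share a distribution (between-group
#' variation 0) w = 1 and the procedure reduces to plain quantile
#' normalization; a single group likewise reduces to quantile normalization.
#' Values are mapped back through each sample's rank order; rank ties
#' receive the mean of their tied quantiles.
#'
#' @param mat genes x samples numeric matrix (any monotone scale).
#' @param group_factor factor/character of length ncol(mat): one group per
#'   sample (the treatment label in this pipeline).
#' @param window smoothing window as a fraction of the quantile levels
#'   (default 0.05).
#' @return normalized matrix of the same shape and dimnames.
#' @export
qsmooth_normalize <- function(mat, group_factor, window = 0.05) {
  mat <- as.matrix(mat)
  n_genes <- nrow(mat)
  n_samp <- ncol(mat)
  group_factor <- droplevels(as.factor(group_factor))
  if (length(group_factor) != n_samp)
    stop("group_factor must have one entry per sample")
  groups <- levels(group_factor)
  tab <- table(group_factor)
  # sorted columns: row q = empirical quantile q of each sample
  Q <- apply(mat, 2, sort)
  O <- rowMeans(Q)                                  # overall mean quantile
  G <- vapply(groups, function(g)
    rowMeans(Q[, group_factor == g, drop = FALSE]), numeric(n_genes))
  if (length(groups) == 1) {
    w <- rep(1, n_genes)
  } else {
    ng <- as.numeric(tab[groups])
    sst_between <- as.numeric((G - O)^2 %*% ng)
    sst_total <- rowSums(sweep(Q, 1, O, "-")^2)
    sst_within <- pmax(sst_total - sst_between, 0)
    denom <- sst_within + sst_between
    w <- ifelse(denom > 0, sst_within / denom, 1)
    k <- max(1L, round(window * n_genes))
    if (k %% 2 == 0) k <- k + 1L                    # odd window for runmed
    if (k > 1 && n_genes >= k) w <- stats::runmed(w, k, endrule = "constant")
  }
  target <- w * O + (1 - w) * G                     # one column per group
  out <- mat
  for (j in seq_len(n_samp)) {
    tgt <- target[, as.integer(group_factor[j])]   # sorted target quantiles
    o <- order(mat[, j])
    val <- numeric(n_genes)
    val[o] <- tgt
    # rank ties get the mean of their tied quantiles
    tie_groups <- split(seq_len(n_genes), mat[, j])
    for (gidx in tie_groups)
      if (length(gidx) > 1) val[gidx] <- mean(val[gidx])
    out[, j] <- val
  }
  out
}

#' Log2 counts per million with a prior count
#'
#' @param counts genes x samples count matrix.
#' @param prior_count pseudo-count added on the CPM-equivalent scale
#'   (default 0.5); keeps zeros finite and the transform monotone.
#' @return log2-scale matrix.
#' @export
log_cpm <- function(counts, prior_count = 0.5) {
  if (prior_count <= 0) stop("prior_count must be positive")
  counts <- as.matrix(counts)
  libsize <- colSums(counts)
  # prior scaled per sample so ordering across samples is stable
  pc <- prior_count * libsize / mean(libsize)
  log2(sweep(sweep(counts, 2, pc, "+"), 2, libsize + 2 * pc, "/") * 1e6)
}

#' PCA overview of an expression matrix
#'
#' Centered SVD of the samples; standard exploratory first look at a
#' normalized expression matrix.
#'
#' @param expr genes x samples matrix (log scale).
#' @return list with `scores` (samples x PCs) and `var_explained`
#'   (fractions summing to 1, or all 0 for a constant matrix).
#' @export
pca_overview <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("need >= 2 samples")
  x <- t(expr)
  x <- sweep(x, 2, colMeans(x), "-")
  if (all(abs(x) < 1e-12)) {
    k <- min(dim(x))
    return(list(scores = matrix(0, nrow(x), k,
                                dimnames = list(rownames(x), NULL)),
                var_explained = rep(0, k)))
  }
  s <- svd(x)
  scores <- s$u %*% diag(s$d, length(s$d))
  rownames(scores) <- rownames(x)
  colnames(scores) <- sprintf("PC%d", seq_len(ncol(scores)))
  list(scores = scores, var_explained = s$d^2 / sum(s$d^2))
}
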