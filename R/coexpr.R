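#' Parameters for the signed weighted co-expression network
#'
#' @param beta soft-thresholding power (the study species used 20, 20, 14).
#' @param merge_threshold eigengene dissimilarity below which modules merge.
#' @param min_module_size smallest reported module.
#' @param max_p_outliers maximum fraction of observations treated as
#'   outliers per side in the biweight midcorrelation.
#' @param hub_k number of hub genes reported per module.
#' @return object of class `coexpr_params`.
#' @export
coexpr_params <- function(beta = 20, merge_threshold = 0.20,
                          min_module_size = 30, max_p_outliers = 0.05,
                          hub_k = 20) {
  stopifnot(beta >= 1, merge_threshold > 0, merge_threshold < 1, hub_k >= 1)
  structure(list(beta = beta, merge_threshold = merge_threshold,
                 min_module_size = min_module_size,
                 max_p_outliers = max_p_outliers, hub_k = hub_k),
            class = "coexpr_params")
}

# internal: biweight-midcorrelation normalized deviation vector for one gene
.bicor_prep <- function(x, max_p_outliers) {
  med <- median(x)
  mad_x <- median(abs(x - med))
  if (mad_x == 0) {
    # degenerate spread: fall back to Pearson-style deviations
    d <- x - mean(x)
    nrm <- sqrt(sum(d^2))
    return(list(dev = if (nrm > 0) d / nrm else d, pearson = TRUE))
  }
  u <- (x - med) / (9 * mad_x)
  q <- quantile(abs(u), 1 - max_p_outliers, names = FALSE, type = 7)
  if (q > 1) u <- u / q   # rescale so at most max_p_outliers exceed |u| = 1
  w <- (1 - u^2)^2 * (abs(u) < 1)
  d <- (x - med) * w
  nrm <- sqrt(sum(d^2))
  list(dev = if (nrm > 0) d / nrm else d, pearson = FALSE)
}

#' Biweight midcorrelation matrix
#'
#' Robust correlation with Tukey biweights
#' w_i = (1 - u_i^2)^2 1(|u_i| < 1), u_i = (x_i - med) / (9 mad). To bound
#' the outlier fraction, |u| is rescaled so that at most `max_p_outliers`
#' of the observations per gene fall beyond |u| = 1 (zero weight). Genes
#' with zero median absolute deviation fall back to Pearson deviations
#' (reported via the `pearson_fallback` attribute).
#'
#' @param expr genes x samples matrix (>= 4 samples).
#' @param max_p_outliers maximum outlier fraction per side (default 0.05).
#' @return symmetric genes x genes correlation matrix with unit diagonal.
#' @export
bicor_matrix <- function(expr, max_p_outliers = 0.05) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 4) stop("need >= 4 samples")
  prep <- apply(expr, 1, .bicor_prep, max_p_outliers = max_p_outliers,
                simplify = FALSE)
  dev <- t(vapply(prep, `[[`, numeric(ncol(expr)), "dev"))
  r <- tcrossprod(dev)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(rownames(expr), rownames(expr))
  attr(r, "pearson_fallback") <-
    rownames(expr)[vapply(prep, `[[`, logical(1), "pearson")]
  r
}

#' Signed adjacency from a correlation matrix
#'
#' a_ij = ((1 + cor_ij) / 2)^beta, mapping correlation -1 to 0 and +1 to 1;
#' the diagonal is set to 0 for connectivity computations.
#'
#' @param cor_mat correlation matrix in \[-1, 1\].
#' @param beta soft power >= 1.
#' @return adjacency matrix in \[0, 1\] with zero diagonal.
#' @export
signed_adjacency <- function(cor_mat, beta) {
  stopifnot(beta >= 1, all(cor_mat >= -1 - 1e-12), all(cor_mat <= 1 + 1e-12))
  a <- ((1 + cor_mat) / 2)^beta
  diag(a) <- 0
  a
}

#' Signed scale-free topology fit index
#'
#' Bins the connectivity distribution, regresses log10 p(k) on
#' log10 mean(k) per bin, and returns -sign(slope) * R^2 so that a
#' decreasing power-law-like histogram scores positively.
#'
#' @param k vector of connectivities (>= n_bins positive values).
#' @param n_bins number of equal-width bins (default 10).
#' @return signed R^2 in \[-1, 1\].
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < n_bins) stop("need >= n_bins positive connectivities")
  if (diff(range(k)) == 0)
    stop("constant connectivity: scale-free fit undefined")
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  pk <- as.numeric(table(bin)) / length(k)
  mk <- tapply(k, bin, mean)
  use <- pk > 0 & !is.na(mk) & mk > 0
  if (sum(use) < 3) {
    message("degenerate binning: fewer than 3 usable bins")
    if (sum(use) < 2) stop("scale-free fit under-determined")
  }
  x <- log10(mk[use])
  y <- log10(pk[use])
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  unname(-sign(slope) * r2)
}

#' Scan soft-thresholding powers and pick one
#'
#' For each candidate power, reports mean and median connectivity and the
#' signed scale-free fit; picks, among powers whose fit reaches `r2_min`,
#' the one with mean connectivity closest to `target_mean_k` (ties go to
#' the lower power). If no power reaches `r2_min`, the best-fitting power
#' is returned with a warning.
#'
#' @param expr genes x samples matrix (>= 50 genes).
#' @param powers candidate powers (default 1:50).
#' @param r2_min scale-free fit threshold (default 0.8).
#' @param target_mean_k preferred mean connectivity (default 50).
#' @param max_p_outliers passed to [bicor_matrix()].
#' @return list with `beta` (chosen power) and `diagnostics` (data frame
#'   power, mean_k, median_k, signed_r2).
#' @export
pick_soft_threshold <- function(expr, powers = 1:50, r2_min = 0.8,
                                target_mean_k = 50, max_p_outliers = 0.05) {
  if (nrow(expr) < 50) stop("need >= 50 genes")
  r <- bicor_matrix(expr, max_p_outliers)
  diag_df <- data.frame(power = powers, mean_k = NA_real_,
                        median_k = NA_real_, signed_r2 = NA_real_)
  for (i in seq_along(powers)) {
    a <- signed_adjacency(r, powers[i])
    k <- rowSums(a)
    diag_df$mean_k[i] <- mean(k)
    diag_df$median_k[i] <- median(k)
    diag_df$signed_r2[i] <- tryCatch(scale_free_fit(k), error = function(e) NA)
  }
  ok <- which(!is.na(diag_df$signed_r2) & diag_df$signed_r2 >= r2_min)
  if (length(ok) == 0) {
    warning("no power reaches the scale-free fit threshold; returning best")
    beta <- powers[which.max(diag_df$signed_r2)]
  } else {
    dist50 <- abs(diag_df$mean_k[ok] - target_mean_k)
    beta <- powers[ok][which.min(dist50)]   # which.min takes the first = lowest power on ties
  }
  list(beta = beta, diagnostics = diag_df)
}

#' Signed topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij), with
#' unit diagonal; combines direct adjacency with shared neighborhoods.
#'
#' @param a symmetric adjacency in \[0, 1\] (zero diagonal).
#' @return TOM similarity matrix in \[0, 1\].
#' @export
signed_tom <- function(a) {
  a <- as.matrix(a)
  stopifnot(isTRUE(all.equal(a, t(a), tolerance = 1e-10)),
            all(a >= 0), all(a <= 1))
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect initial modules from a TOM
#'
#' Average-linkage hierarchical clustering on 1 - TOM with a static height
#' cut; clusters smaller than `min_module_size` are collected into
#' "unassigned". Labels ("m01", "m02", ...) are assigned in decreasing
#' size order with deterministic tie-breaking on the smallest member gene
#' id. The default cut ("gap") places the height at the largest gap
#' between consecutive merge heights within the top decile of merges,
#' which adapts to the number of well-separated blocks; "quantile" cuts at
#' a fixed quantile of the merge heights.
#'
#' @param tom TOM similarity matrix with gene dimnames.
#' @param min_module_size minimum module size (default 30).
#' @param cut_method "gap" (default) or "quantile".
#' @param cut_quantile quantile of merge heights for `cut_method =
#'   "quantile"` (default 0.99).
#' @return named character vector gene -> module label.
#' @export
detect_modules <- function(tom, min_module_size = 30,
                           cut_method = c("gap", "quantile"),
                           cut_quantile = 0.99) {
  cut_method <- match.arg(cut_method)
  d <- as.dist(1 - tom)
  tree <- hclust(d, method = "average")
  hh <- sort(tree$height)
  if (cut_method == "quantile" || length(hh) < 3) {
    h <- quantile(tree$height, cut_quantile, names = FALSE)
  } else {
    top <- seq(max(1L, length(hh) - max(2L, ceiling(0.1 * length(hh)))),
               length(hh) - 1L)
    gaps <- hh[top + 1L] - hh[top]
    i <- top[which.max(gaps)]
    h <- (hh[i] + hh[i + 1L]) / 2
  }
  cl <- cutree(tree, h = h)
  names(cl) <- rownames(tom)
  relabel_modules(cl, min_module_size)
}

#' Relabel an integer clustering into size-ordered module labels
#'
#' @param cl named integer vector gene -> cluster.
#' @param min_module_size clusters below this size become "unassigned".
#' @return named character vector gene -> label ("m01", ..., "unassigned").
#' @export
relabel_modules <- function(cl, min_module_size = 30) {
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  out <- rep("unassigned", length(cl))
  names(out) <- names(cl)
  if (length(keep) > 0) {
    first_gene <- vapply(keep, function(k) min(names(cl)[cl == k]),
                         character(1))
    keep <- keep[order(-sizes[keep], first_gene)]
    for (i in seq_along(keep))
      out[cl == keep[i]] <- sprintf("m%02d", i)
  }
  out
}

#' Module eigengene
#'
#' First principal component of the standardized member-gene submatrix,
#' sign-anchored so the mean correlation with the member genes is positive,
#' scaled to unit norm.
#'
#' @param expr genes x samples matrix.
#' @param genes member gene ids (or indices).
#' @return list with `eigengene` (unit-norm vector over samples) and
#'   `var_explained`.
#' @export
module_eigengene <- function(expr, genes) {
  x <- as.matrix(expr[genes, , drop = FALSE])
  if (nrow(x) == 0) stop("empty module")
  sds <- apply(x, 1, sd)
  sds[sds == 0] <- 1
  xs <- (x - rowMeans(x)) / sds
  if (nrow(xs) == 1) {
    v <- xs[1, ]
    nrm <- sqrt(sum(v^2))
    return(list(eigengene = if (nrm > 0) v / nrm else v, var_explained = 1))
  }
  s <- svd(xs)
  v <- s$v[, 1]
  mean_cor <- mean(cor(t(xs), v))
  if (is.finite(mean_cor) && mean_cor < 0) v <- -v
  names(v) <- colnames(expr)
  list(eigengene = v, var_explained = s$d[1]^2 / sum(s$d^2))
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest pair of modules whose eigengene
#' dissimilarity 1 - cor is below `merge_threshold`, recomputing eigengenes
#' after every merge, until no such pair remains. "unassigned" never
#' participates.
#'
#' @param modules named character vector gene -> module label.
#' @param expr genes x samples matrix.
#' @param merge_threshold dissimilarity threshold (default 0.20).
#' @return named character vector with merged, size-reordered labels.
#' @export
merge_close_modules <- function(modules, expr, merge_threshold = 0.20) {
  repeat {
    labs <- setdiff(sort(unique(modules)), "unassigned")
    if (length(labs) < 2) break
    eg <- vapply(labs, function(l)
      module_eigengene(expr, names(modules)[modules == l])$eigengene,
      numeric(ncol(expr)))
    cc <- cor(eg)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (1 - max(cc) >= merge_threshold) break
    from <- labs[max(best)]
    to <- labs[min(best)]
    modules[modules == from] <- to
  }
  # re-rank labels by size, preserving determinism
  cl <- as.integer(factor(modules, levels = unique(modules)))
  names(cl) <- names(modules)
  out <- rep("unassigned", length(modules))
  names(out) <- names(modules)
  assigned <- modules != "unassigned"
  if (any(assigned)) {
    sub <- relabel_modules(cl[assigned], min_module_size = 1)
    out[assigned] <- sub
  }
  out
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with each numeric trait;
#' p-values from t = r sqrt(n - 2) / sqrt(1 - r^2).
#'
#' @param eigengenes samples x modules matrix (columns named by module).
#' @param traits samples x traits numeric matrix (shared rownames).
#' @return list of matrices `r` and `p` (modules x traits); constant traits
#'   give NA.
#' @export
module_trait_cor <- function(eigengenes, traits) {
  shared <- intersect(rownames(eigengenes), rownames(traits))
  if (length(shared) < 3) stop("need >= 3 shared samples")
  e <- as.matrix(eigengenes[shared, , drop = FALSE])
  tr <- as.matrix(traits[shared, , drop = FALSE])
  n <- length(shared)
  r <- suppressWarnings(cor(e, tr))
  const <- apply(tr, 2, function(x) sd(x) == 0)
  r[, const] <- NA
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 1e-300))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[is.na(r)] <- NA
  list(r = r, p = p)
}

#' Top intramodular hub genes
#'
#' Ranks the members of each module by intramodular connectivity
#' kWithin = sum over module members of a_ij and reports the top `hub_k`
#' (deterministic tie-break on gene id).
#'
#' @param adjacency gene adjacency matrix (zero diagonal).
#' @param modules named character vector gene -> module label.
#' @param hub_k hubs per module (default 20).
#' @param include_unassigned count "unassigned" as a module (default FALSE).
#' @return data frame module, gene, k_within; `hub_k` rows per module (or
#'   fewer for small modules).
#' @export
top_hubs <- function(adjacency, modules, hub_k = 20,
                     include_unassigned = FALSE) {
  labs <- setdiff(sort(unique(modules)), if (include_unassigned) NULL else "unassigned")
  out <- list()
  for (l in labs) {
    members <- names(modules)[modules == l]
    kw <- rowSums(adjacency[members, members, drop = FALSE])
    ord <- order(-kw, members)
    take <- head(ord, hub_k)
    out[[l]] <- data.frame(module = l, gene = members[take],
                           k_within = kw[take], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full signed co-expression module detection
#'
#' Chains [bicor_matrix()], [signed_adjacency()], [signed_tom()],
#' [detect_modules()], [merge_close_modules()], [module_eigengene()] and
#' [top_hubs()].
#'
#' @param expr genes x samples matrix.
#' @param params a [coexpr_params()].
#' @return list with modules (gene -> label), eigengenes (samples x
#'   modules), var_explained, hubs, adjacency, tom.
#' @export
coexpr_modules <- function(expr, params = coexpr_params()) {
  r <- bicor_matrix(expr, params$max_p_outliers)
  a <- signed_adjacency(r, params$beta)
  tom <- signed_tom(a)
  mods <- detect_modules(tom, params$min_module_size)
  mods <- merge_close_modules(mods, expr, params$merge_threshold)
  labs <- setdiff(sort(unique(mods)), "unassigned")
  eg <- vapply(labs, function(l)
    module_eigengene(expr, names(mods)[mods == l])$eigengene,
    numeric(ncol(expr)))
  if (length(labs) > 0) {
    eg <- matrix(eg, ncol = length(labs),
                 dimnames = list(colnames(expr), labs))
  } else eg <- matrix(numeric(0), ncol(expr), 0)
  ve <- vapply(labs, function(l)
    module_eigengene(expr, names(mods)[mods == l])$var_explained, numeric(1))
  hubs <- if (length(labs) > 0) top_hubs(a, mods, params$hub_k) else NULL
  list(modules = mods, eigengenes = eg, var_explained = ve, hubs = hubs,
       adjacency = a, tom = tom)
}
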