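#' Enumerate treatment-vs-matched-control contrasts from a design
#'
#' One contrast per (treatment condition, time) pair against the control
#' condition at the same absolute time.
#'
#' @param design design table with columns condition, time_h (one species).
#' @param control label of the control condition (default "control").
#' @param exclude conditions never contrasted (default the initial time
#'   point "t0").
#' @param on_missing "error" (default) stops when a treatment time has no
#'   matched control, naming the time point; "drop" silently skips it.
#' @return data frame with columns condition, time_h, one row per contrast.
#' @export
build_contrasts <- function(design, control = "control", exclude = "t0",
                            on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  trts <- setdiff(unique(design$condition), c(control, exclude))
  ctrl_times <- unique(design$time_h[design$condition == control])
  rows <- list()
  for (cond in trts) {
    for (t in sort(unique(design$time_h[design$condition == cond]))) {
      if (!t %in% ctrl_times) {
        if (on_missing == "error")
          stop(sprintf("no matched control at time %g h for condition '%s'",
                       t, cond))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(condition = cond, time_h = t,
                                              stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(condition = character(0), time_h = numeric(0)))
  do.call(rbind, rows)
}

#' Per-gene group-mean model fits for a set of contrasts
#'
#' Ordinary least squares on the condition-time factor model: every
#' (condition, time) cell is one group; the coefficient of a contrast is the
#' difference of group means, the residual variance s_g^2 is pooled across
#' all groups with d_g = n - #groups degrees of freedom.
#'
#' @param expr genes x samples log-expression matrix.
#' @param design design rows matching the columns of `expr`.
#' @param contrasts contrast table from [build_contrasts()].
#' @param control control condition label.
#' @return list with `coef` (genes x contrasts log2FC matrix), `s2`
#'   (per-gene pooled residual variance), `df` (residual df), `v` (per
#'   contrast, unscaled variance 1/n1 + 1/n2).
#' @export
fit_gene_models <- function(expr, design, contrasts, control = "control") {
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) == nrow(design))
  grp <- interaction(design$condition, design$time_h, drop = TRUE)
  tab <- table(grp)
  if (any(tab < 2))
    stop("need >= 2 replicates per design cell (singular design)")
  # group means and pooled residual variance
  idx <- split(seq_len(ncol(expr)), grp)
  gm <- vapply(idx, function(i) rowMeans(expr[, i, drop = FALSE]),
               numeric(nrow(expr)))
  if (nrow(expr) == 1) gm <- matrix(gm, nrow = 1, dimnames = list(rownames(expr), names(idx)))
  rss <- numeric(nrow(expr))
  for (g in names(idx))
    rss <- rss + rowSums((expr[, idx[[g]], drop = FALSE] - gm[, g])^2)
  df <- ncol(expr) - length(idx)
  s2 <- rss / df
  cname <- function(cond, t) paste(cond, t, sep = ".")
  coef <- matrix(NA_real_, nrow(expr), nrow(contrasts),
                 dimnames = list(rownames(expr),
                                 sprintf("%s_%g", contrasts$condition,
                                         contrasts$time_h)))
  v <- numeric(nrow(contrasts))
  for (k in seq_len(nrow(contrasts))) {
    trt <- cname(contrasts$condition[k], contrasts$time_h[k])
    ctl <- cname(control, contrasts$time_h[k])
    if (!trt %in% names(idx) || !ctl %in% names(idx))
      stop(sprintf("design lacks cell '%s' or '%s'", trt, ctl))
    coef[, k] <- gm[, trt] - gm[, ctl]
    v[k] <- 1 / length(idx[[trt]]) + 1 / length(idx[[ctl]])
  }
  list(coef = coef, s2 = s2, df = df, v = v)
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Moment-matching on log s_g^2 (digamma/trigamma closed forms) estimates a
#' scaled-inverse-chi-square prior (d0, s0^2); posterior variances
#' s~^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g) give moderated t statistics
#' with d0 + d_g degrees of freedom.
#'
#' @param s2 per-gene residual variances.
#' @param df residual degrees of freedom (scalar or per gene).
#' @param coef optional genes x contrasts coefficient matrix.
#' @param v optional per-contrast unscaled variance (1/n1 + 1/n2).
#' @param d0 optional forced prior df (e.g. Inf or 0), skipping estimation.
#' @return list with d0, s0_2, s2_post, and, when `coef`/`v` are supplied,
#'   `t` and `p` matrices.
#' @export
moderate_variance <- function(s2, df, coef = NULL, v = NULL, d0 = NULL) {
  df <- rep(df, length.out = length(s2))
  if (is.null(d0)) {
    ok <- s2 > 0 & df >= 1
    if (sum(ok) < 10) {
      if (all(s2 == 0)) {
        warning("all variances are zero; falling back to ordinary t")
        d0 <- 0
        s0_2 <- 0
      } else stop("need >= 10 genes with positive variance and df >= 1")
    }
    if (is.null(d0)) {
      z <- log(s2[ok])
      e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
      ebar <- mean(e)
      evar <- var(e) * (length(e) - 1) / length(e)
      rhs <- evar - mean(trigamma(df[ok] / 2))
      if (rhs <= 0) {
        d0 <- Inf
        s0_2 <- exp(ebar)
      } else {
        d0 <- 2 * .trigamma_inverse(rhs)
        s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
      }
    }
  } else {
    s0_2 <- if (is.finite(d0) && d0 == 0) 0 else {
      ok <- s2 > 0 & df >= 1
      if (any(ok)) exp(mean(log(s2[ok]))) else 0
    }
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    (d0 * s0_2 + df * s2) / (d0 + df)
  out <- list(d0 = d0, s0_2 = s0_2, s2_post = s2_post)
  if (!is.null(coef)) {
    stopifnot(!is.null(v))
    se <- sqrt(outer(s2_post, v))
    tt <- coef / se
    df_tot <- pmin(d0 + df, .Machine$double.xmax)
    pp <- 2 * pt(abs(tt), df = df_tot, lower.tail = FALSE)
    out$t <- tt
    out$p <- pp
    out$df_total <- df_tot
  }
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in \[0, 1\].
#' @return monotone adjusted p-values capped at 1.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Call differentially expressed genes
#'
#' DEG iff |log2FC| >= `lfc_min` and adjusted p <= `alpha`, both boundaries
#' inclusive.
#'
#' @param results data frame with columns log2fc and adj_p (e.g. from
#'   [de_table()]).
#' @param lfc_min absolute log2 fold-change threshold (default 1).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return the input with a logical `deg` column.
#' @export
call_degs <- function(results, lfc_min = 1, alpha = 0.05) {
  if (nrow(results) == 0) {
    results$deg <- logical(0)
    return(results)
  }
  results$deg <- abs(results$log2fc) >= lfc_min & results$adj_p <= alpha
  results
}

#' Full per-contrast differential-expression table
#'
#' Convenience wrapper chaining [fit_gene_models()], [moderate_variance()],
#' [bh_adjust()] (within each contrast) and [call_degs()].
#'
#' @inheritParams fit_gene_models
#' @inheritParams call_degs
#' @return data frame with gene, contrast (condition, time_h), log2fc, t,
#'   p, adj_p, deg.
#' @export
de_table <- function(expr, design, contrasts, control = "control",
                     lfc_min = 1, alpha = 0.05) {
  fit <- fit_gene_models(expr, design, contrasts, control)
  mod <- moderate_variance(fit$s2, fit$df, coef = fit$coef, v = fit$v)
  out <- list()
  for (k in seq_len(nrow(contrasts))) {
    res <- data.frame(gene = rownames(fit$coef),
                      condition = contrasts$condition[k],
                      time_h = contrasts$time_h[k],
                      log2fc = fit$coef[, k], t = mod$t[, k], p = mod$p[, k],
                      adj_p = bh_adjust(mod$p[, k]),
                      stringsAsFactors = FALSE)
    out[[k]] <- call_degs(res, lfc_min, alpha)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hypergeometric over-representation analysis
#'
#' Per annotation term, the upper-tail hypergeometric probability
#' P(X >= k) of observing k query genes in a term of size K given a query
#' of size n drawn from a background of size N, BH-adjusted across terms.
#'
#' @param query character vector of query gene ids (subset of background).
#' @param annotation data frame (gene_id, term_id), multiple rows per gene.
#' @param background character vector of background gene ids.
#' @param alpha adjusted-p reporting threshold (default 0.05); set to 1 to
#'   report all terms.
#' @return data frame term, k (overlap), K (term size), n (query size),
#'   N (background size), p, adj_p, sorted by p; only terms with
#'   adj_p <= alpha.
#' @export
hypergeom_ora <- function(query, annotation, background, alpha = 0.05) {
  query <- unique(query)
  background <- unique(background)
  if (!all(query %in% background))
    stop("query must be a subset of the background")
  annotation <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  skipped <- character(0)
  N <- length(background)
  n <- length(query)
  terms <- split(unique(annotation[, c("gene_id", "term_id")])$gene_id,
                 unique(annotation[, c("gene_id", "term_id")])$term_id)
  if (length(terms) == 0)
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      adj_p = numeric(0)))
  res <- data.frame(term = names(terms),
                    K = vapply(terms, length, integer(1)),
                    stringsAsFactors = FALSE)
  res$k <- vapply(terms, function(g) sum(query %in% g), integer(1))
  res$n <- n
  res$N <- N
  res$p <- phyper(res$k - 1, res$K, N - res$K, n, lower.tail = FALSE)
  res$adj_p <- bh_adjust(res$p)
  res <- res[res$adj_p <= alpha, c("term", "k", "K", "n", "N", "p", "adj_p")]
  res[order(res$p, res$term), , drop = FALSE]
}
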