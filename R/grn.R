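#' Parameters for sliding-window lagged random-forest network inference
#'
#' @param min_lag,max_lag lag range for the lagged regressors (defaults
#'   0 and 1).
#' @param window_w sliding-window length in time points (default 4, the
#'   value used for the metabolite-rich series; 2 otherwise). Must be at
#'   least max_lag + 1.
#' @param n_trees trees per random-forest ensemble (default 500).
#' @param top_fraction fraction of supported edges retained (default
#'   0.001, i.e. the top 0.1%).
#' @param mtry features sampled per split; default ceiling(p/3).
#' @param min_node minimum node size of the regression trees.
#' @param seed RNG seed for the ensembles.
#' @return object of class `swing_params`.
#' @export
swing_params <- function(min_lag = 0, max_lag = 1, window_w = 4,
                         n_trees = 500, top_fraction = 0.001, mtry = NULL,
                         min_node = 1, seed = 1L) {
  stopifnot(min_lag >= 0, min_lag <= max_lag, window_w >= max_lag + 1,
            top_fraction > 0, top_fraction <= 1, n_trees >= 1)
  structure(list(min_lag = min_lag, max_lag = max_lag, window_w = window_w,
                 n_trees = n_trees, top_fraction = top_fraction,
                 mtry = mtry, min_node = min_node, seed = as.integer(seed)),
            class = "swing_params")
}

#' Z-score each row of a node-by-time matrix
#'
#' Population standard deviation convention (divide by n). Constant rows
#' cannot be standardized and are dropped with a message.
#'
#' @param mat nodes x time points matrix.
#' @return standardized matrix (possibly fewer rows).
#' @export
zscore_series <- function(mat) {
  mat <- as.matrix(mat)
  mu <- rowMeans(mat)
  sdev <- sqrt(rowMeans((mat - mu)^2))
  const <- sdev == 0
  if (any(const))
    message(sprintf("dropping %d constant row(s): %s", sum(const),
                    paste(head(rownames(mat)[const], 5), collapse = ", ")))
  (mat[!const, , drop = FALSE] - mu[!const]) / sdev[!const]
}

#' Enumerate sliding windows
#'
#' All contiguous index runs of length `w` with stride 1 over `n_times`
#' time points: n_times - w + 1 windows.
#'
#' @param n_times number of time points.
#' @param w window length (<= n_times).
#' @return list of integer index vectors.
#' @export
make_windows <- function(n_times, w) {
  if (w > n_times) stop("window length exceeds the number of time points")
  stopifnot(w >= 1)
  lapply(seq_len(n_times - w + 1), function(s) seq(s, s + w - 1))
}

#' Lagged random-forest importances for one window
#'
#' Per target node, fits a seeded regression random forest of the target at
#' time t on every candidate regulator at t - k for each lag
#' k in \[min_lag, max_lag\] (the target itself is excluded at every lag);
#' impurity importances are normalized to sum 1 per target. Replicate
#' series contribute additional training rows.
#'
#' @param window_data array nodes x window-time x replicates (a plain
#'   matrix is treated as one replicate), already z-scored.
#' @param params a [swing_params()].
#' @return array regulators x targets x lags of importances (lags named
#'   "lag0", "lag1", ...).
#' @export
lagged_importance <- function(window_data, params = swing_params()) {
  if (is.matrix(window_data))
    window_data <- array(window_data, c(nrow(window_data),
                                        ncol(window_data), 1),
                         dimnames = c(dimnames(window_data), list(NULL)))
  nodes <- dimnames(window_data)[[1]]
  p <- length(nodes)
  w <- dim(window_data)[2]
  reps <- dim(window_data)[3]
  lags <- seq(params$min_lag, params$max_lag)
  if (w <= params$max_lag) stop("window length must exceed max_lag")
  t_rows <- seq(params$max_lag + 1, w)
  if (length(t_rows) < 2) {
    if (length(t_rows) * reps < 2) {
      message("window skipped: fewer than 2 usable time rows")
      return(array(0, c(p, p, length(lags)),
                   dimnames = list(nodes, nodes, paste0("lag", lags))))
    }
  }
  imp <- array(0, c(p, p, length(lags)),
               dimnames = list(nodes, nodes, paste0("lag", lags)))
  for (tg in seq_len(p)) {
    regs <- setdiff(seq_len(p), tg)
    # design: rows = (time, replicate); columns = (regulator, lag)
    X <- matrix(0, length(t_rows) * reps, length(regs) * length(lags))
    y <- numeric(length(t_rows) * reps)
    row <- 0L
    for (r in seq_len(reps)) {
      for (t in t_rows) {
        row <- row + 1L
        y[row] <- window_data[tg, t, r]
        col <- 0L
        for (k in lags) {
          for (j in regs) {
            col <- col + 1L
            X[row, col] <- window_data[j, t - k, r]
          }
        }
      }
    }
    mtry <- if (is.null(params$mtry)) ceiling(ncol(X) / 3) else params$mtry
    raw <- rf_importance_cpp(X, y, params$n_trees, mtry, params$min_node)
    tot <- sum(raw)
    if (tot > 0) raw <- raw / tot
    col <- 0L
    for (ki in seq_along(lags)) {
      for (j in regs) {
        col <- col + 1L
        imp[j, tg, ki] <- raw[col]
      }
    }
  }
  imp
}

#' Mean-mean rank aggregation across windows and delays
#'
#' Within each window and delay, edges are ranked by decreasing importance
#' (average ranks on ties); per delay the mean rank across windows is
#' taken, and the final score is the mean of the per-delay mean ranks.
#' Final ordering is ascending in score with a deterministic lexicographic
#' (source, target) tie-break.
#'
#' @param importances list of importance arrays from [lagged_importance()]
#'   (one per window, same dimensions).
#' @return data frame source, target, score, rank, support (number of
#'   windows where the edge had non-zero importance at any delay).
#' @export
aggregate_mean_mean <- function(importances) {
  stopifnot(length(importances) >= 1)
  dn <- dimnames(importances[[1]])
  nodes <- dn[[1]]
  lags <- dn[[3]]
  p <- length(nodes)
  off <- which(row(diag(p)) != col(diag(p)))   # source (row) -> target (col)
  src <- nodes[row(diag(p))[off]]
  tgt <- nodes[col(diag(p))[off]]
  n_e <- length(off)
  per_delay <- matrix(0, n_e, length(lags))
  support <- integer(n_e)
  for (ki in seq_along(lags)) {
    ranks <- vapply(importances, function(im) {
      v <- im[, , ki][off]
      rank(-v, ties.method = "average")
    }, numeric(n_e))
    if (n_e == 1) ranks <- matrix(ranks, 1)
    per_delay[, ki] <- rowMeans(ranks)
  }
  nz <- vapply(importances, function(im) {
    any_nz <- rep(FALSE, n_e)
    for (ki in seq_along(lags))
      any_nz <- any_nz | (im[, , ki][off] > 0)
    any_nz
  }, logical(n_e))
  if (n_e == 1) nz <- matrix(nz, 1)
  support <- rowSums(nz)
  score <- rowMeans(per_delay)
  out <- data.frame(source = src, target = tgt, score = score,
                    support = support, stringsAsFactors = FALSE)
  out <- out[order(out$score, out$source, out$target), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("source", "target", "score", "rank", "support")]
}

#' Retain the top-ranked supported edges
#'
#' Drops edges with zero support in all windows, then keeps the
#' ceil(top_fraction x remaining) best-ranked edges.
#'
#' @param ranked data frame from [aggregate_mean_mean()].
#' @param top_fraction fraction kept (default 0.001).
#' @return filtered edge data frame.
#' @export
finalize_edges <- function(ranked, top_fraction = 0.001) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  nz <- ranked[ranked$support > 0, , drop = FALSE]
  if (nrow(nz) == 0) return(nz)
  head(nz[order(nz$rank), , drop = FALSE], ceiling(top_fraction * nrow(nz)))
}

#' Theoretically possible directed edge count
#'
#' n (n - 1) ordered pairs without self-loops.
#'
#' @param n number of nodes (>= 0).
#' @return edge count (double, exact for all printable sizes).
#' @export
theoretical_edge_count <- function(n) {
  stopifnot(n >= 0)
  as.numeric(n) * (as.numeric(n) - 1)
}

#' Sliding-window Granger-causal network inference (SWING-RF style)
#'
#' Z-scores each node over its full series, slides fixed-length windows
#' with stride 1, fits lagged random forests per window and target,
#' aggregates edge ranks mean-mean across windows and delays, and retains
#' the top-ranked supported edges.
#'
#' @param series array nodes x time x replicates (or a matrix for one
#'   replicate); rows named by node (genes and metabolites alike).
#' @param params a [swing_params()].
#' @return list with `ranked` (full aggregated edge list) and `edges`
#'   (top-fraction list from [finalize_edges()]).
#' @export
swing_grn <- function(series, params = swing_params()) {
  if (is.matrix(series))
    series <- array(series, c(nrow(series), ncol(series), 1),
                    dimnames = c(dimnames(series), list(NULL)))
  # z-score each node over all time points and replicates
  nodes <- dimnames(series)[[1]]
  flat <- matrix(series, nrow = dim(series)[1])
  rownames(flat) <- nodes
  z <- suppressMessages(zscore_series(flat))
  keep <- rownames(z)
  series <- series[keep, , , drop = FALSE]
  for (i in seq_along(keep)) {
    v <- series[i, , ]
    series[i, , ] <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  }
  set.seed(params$seed)
  windows <- make_windows(dim(series)[2], params$window_w)
  imps <- lapply(windows, function(wi)
    lagged_importance(series[, wi, , drop = FALSE], params))
  ranked <- aggregate_mean_mean(imps)
  list(ranked = ranked, edges = finalize_edges(ranked, params$top_fraction))
}
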