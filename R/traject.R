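#' Build log2 fold-change trajectories for one treatment
#'
#' Rows are genes significant (adjusted p <= `alpha`) in at least one time
#' point of the treatment; values are the log2 fold changes versus the
#' matched control at every time point of that treatment.
#'
#' @param contrast_results data frame from [de_table()] (gene, condition,
#'   time_h, log2fc, adj_p).
#' @param treatment condition label to extract.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return genes x time matrix of log2FC, columns named by hour.
#' @export
build_trajectories <- function(contrast_results, treatment, alpha = 0.05) {
  sub <- contrast_results[contrast_results$condition == treatment, ,
                          drop = FALSE]
  if (nrow(sub) == 0) {
    warning(sprintf("no contrasts for treatment '%s'", treatment))
    return(matrix(numeric(0), 0, 0))
  }
  times <- sort(unique(sub$time_h))
  genes <- sort(unique(sub$gene))
  fc <- matrix(NA_real_, length(genes), length(times),
               dimnames = list(genes, as.character(times)))
  sig <- matrix(FALSE, length(genes), length(times),
                dimnames = dimnames(fc))
  gi <- match(sub$gene, genes)
  ti <- match(sub$time_h, times)
  fc[cbind(gi, ti)] <- sub$log2fc
  sig[cbind(gi, ti)] <- sub$adj_p <= alpha
  keep <- rowSums(sig) >= 1 & rowSums(is.na(fc)) == 0
  if (!any(keep)) {
    warning(sprintf("no gene significant for treatment '%s'", treatment))
    return(fc[0, , drop = FALSE])
  }
  if (ncol(fc) < 3) stop("need >= 3 time points per trajectory")
  fc[keep, , drop = FALSE]
}

#' Log marginal likelihood of a Gaussian-process regression model
#'
#' log N(y | 0, K + sigma_n^2 I) with squared-exponential kernel
#' K(t, t') = sigma_f^2 exp(-(t - t')^2 / (2 l^2)). A small jitter (1e-8)
#' is added if the covariance is numerically non-positive-definite.
#'
#' @param y observations.
#' @param t inputs (same length as y).
#' @param sigma_f kernel amplitude (> 0 allowed to be 0 only with
#'   sigma_n > 0).
#' @param lengthscale kernel lengthscale (> 0).
#' @param sigma_n observation noise standard deviation.
#' @return scalar log marginal likelihood.
#' @export
gp_log_marginal <- function(y, t, sigma_f, lengthscale, sigma_n) {
  stopifnot(length(y) == length(t), length(y) >= 1, lengthscale > 0,
            sigma_f >= 0, sigma_n >= 0, sigma_f + sigma_n > 0)
  K <- .se_kernel(t, t, sigma_f, lengthscale) + diag(sigma_n^2, length(t))
  L <- tryCatch(chol(K), error = function(e) {
    message("non-PD covariance: adding 1e-8 jitter")
    chol(K + diag(1e-8, length(t)))
  })
  alpha <- backsolve(L, backsolve(L, y, transpose = TRUE))
  -0.5 * sum(y * alpha) - sum(log(diag(L))) - 0.5 * length(y) * log(2 * pi)
}

# internal: log density of y under N(m, C) given chol(C)
.mvn_logdens <- function(y, m, L) {
  d <- y - m
  a <- backsolve(L, backsolve(L, d, transpose = TRUE))
  -0.5 * sum(d * a) - sum(log(diag(L))) - 0.5 * length(y) * log(2 * pi)
}

# internal: hyperparameter grid for standardized trajectories; total
# variance 1 split between signal fraction f and noise 1 - f
.dpgp_grid <- function(t, lengthscale_mult = c(0.5, 1, 2, 4),
                       varfrac = seq(0.1, 0.9, by = 0.2)) {
  spacing <- median(diff(sort(t)))
  grid <- expand.grid(ell = lengthscale_mult * spacing, f = varfrac)
  lapply(seq_len(nrow(grid)), function(i) {
    K0 <- .se_kernel(t, t, 1, grid$ell[i])
    K <- grid$f[i] * K0 + diag(1 - grid$f[i] + 1e-8, length(t))
    list(ell = grid$ell[i], f = grid$f[i], K = K, L = chol(K))
  })
}

# internal: exact joint log marginal of a cluster under the shared-mean GP
# model y_j = mu + eps_j, mu ~ N(0, Ksig), eps ~ N(0, sigma_n^2 I):
#   log N(ybar; 0, Ksig + sigma_n^2/n I) - SS/(2 sigma_n^2)
#   - T(n-1)/2 log(2 pi sigma_n^2) - T/2 log n,
# with SS the within-cluster sum of squared deviations from ybar.
.cluster_joint_ll <- function(Y, g) {
  n <- nrow(Y)
  T_ <- ncol(Y)
  sigma_n2 <- 1 - g$f + 1e-8
  Ksig <- g$K - diag(sigma_n2, T_)
  ybar <- colMeans(Y)
  Cbar <- Ksig + diag(sigma_n2 / n, T_)
  L <- chol(Cbar)
  ll <- .mvn_logdens(ybar, rep(0, T_), L)
  if (n > 1) {
    SS <- sum(sweep(Y, 2, ybar, "-")^2)
    ll <- ll - SS / (2 * sigma_n2) -
      T_ * (n - 1) / 2 * log(2 * pi * sigma_n2)
  }
  ll - T_ / 2 * log(n)
}

# internal: pick grid entry maximizing the exact joint marginal of the
# cluster, and precompute the posterior predictive for a new member
.cluster_model <- function(Y, grid) {
  n <- nrow(Y)
  T_ <- ncol(Y)
  best <- NULL
  best_ll <- -Inf
  for (g in grid) {
    ll <- .cluster_joint_ll(Y, g)
    if (ll > best_ll) { best_ll <- ll; best <- g }
  }
  sigma_n2 <- 1 - best$f + 1e-8
  Ksig <- best$K - diag(sigma_n2, T_)   # signal part of the covariance
  ybar <- colMeans(Y)
  # posterior over the latent cluster mean: Sigma_mu = (Ksig^-1 + n/s2 I)^-1
  A <- solve(solve(Ksig + diag(1e-8, T_)) + diag(n / sigma_n2, T_))
  m <- A %*% (ybar * n / sigma_n2)
  pred_cov <- A + diag(sigma_n2, T_)
  list(hyper = best, mean = as.numeric(m), L = chol(pred_cov),
       ml = best_ll)
}

#' Collapsed Gibbs sampler for Dirichlet-process GP mixture clustering
#'
#' Rows (genes) are z-scored over time, then assigned by a Chinese
#' restaurant process with Gaussian-process cluster likelihoods:
#' P(c_i = k) is proportional to n_(-i,k) f_k(y_i) for existing clusters
#' and alpha f_0(y_i) for a new cluster, where f_k is the cluster's GP
#' posterior predictive and f_0 the prior predictive. GP hyperparameters
#' are refreshed per cluster each sweep by maximizing the marginal
#' likelihood over a small fixed grid.
#'
#' @param ts genes x time matrix (e.g. from [build_trajectories()]).
#' @param alpha DP concentration (default 1).
#' @param n_iter total Gibbs sweeps (default 500).
#' @param burn_in discarded sweeps (default 250; must be < n_iter).
#' @param seed RNG seed.
#' @param likelihood_off if TRUE, the likelihood is constant (prior-only
#'   chain; used to validate the CRP prior).
#' @return object of class `dpgp_chain`: list with `partitions` (list of
#'   post-burn-in assignment vectors), `coclust` (posterior co-clustering
#'   matrix), `times`, `data` (standardized), and sampler settings.
#' @export
dpgp_gibbs <- function(ts, alpha = 1, n_iter = 500, burn_in = 250, seed = 1,
                       likelihood_off = FALSE) {
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  ts <- as.matrix(ts)
  n <- nrow(ts)
  stopifnot(n >= 1)
  t_h <- as.numeric(colnames(ts))
  if (anyNA(t_h)) t_h <- seq_len(ncol(ts))
  # z-score rows over time
  Y <- t(apply(ts, 1, function(x) {
    s <- sd(x)
    if (s == 0) x - mean(x) else (x - mean(x)) / s
  }))
  if (n == 1) Y <- matrix(Y, 1, ncol(ts))
  set.seed(seed)
  grid <- .dpgp_grid(t_h)
  # prior predictive for a new cluster: hyperparameters marginalized over
  # the grid with uniform weights (log-mean-exp of the per-point densities)
  f0 <- function(y) {
    if (likelihood_off) return(0)
    lls <- vapply(grid, function(g)
      .mvn_logdens(y, rep(0, length(y)), g$L), numeric(1))
    m <- max(lls)
    m + log(mean(exp(lls - m)))
  }
  assign <- rep(1L, n)
  partitions <- list()
  coclust <- matrix(0, n, n)
  for (it in seq_len(n_iter)) {
    # refresh per-cluster models once per sweep
    ks <- sort(unique(assign))
    models <- if (likelihood_off) list() else
      setNames(lapply(ks, function(k)
        .cluster_model(Y[assign == k, , drop = FALSE], grid)),
        as.character(ks))
    for (i in seq_len(n)) {
      counts <- table(assign[-i])
      labs <- as.integer(names(counts))
      logp <- numeric(length(labs) + 1)
      for (j in seq_along(labs)) {
        k <- labs[j]
        lk <- if (likelihood_off) 0 else {
          mk <- models[[as.character(k)]]
          if (is.null(mk)) f0(Y[i, ]) else .mvn_logdens(Y[i, ], mk$mean, mk$L)
        }
        logp[j] <- log(as.numeric(counts[j])) + lk
      }
      logp[length(labs) + 1] <- log(alpha) + f0(Y[i, ])
      pr <- exp(logp - max(logp))
      pick <- sample.int(length(pr), 1, prob = pr)
      if (pick > length(labs)) {
        new_k <- max(assign) + 1L
        if (!likelihood_off && sum(assign == assign[i]) == 1 &&
            !(assign[i] %in% labs)) {
          # singleton moving to a fresh cluster: keep its label
          new_k <- assign[i]
        }
        assign[i] <- new_k
      } else assign[i] <- labs[pick]
    }
    # merge move: single-site Gibbs leaves small satellite clusters stuck,
    # so propose merging one random cluster pair per sweep, accepted by the
    # CRP prior ratio times the exact joint-marginal ratio (mode-seeking;
    # skipped in the prior-validation mode)
    if (!likelihood_off) {
      ks2 <- sort(unique(assign))
      if (length(ks2) >= 2) {
        pair <- sample(ks2, 2)
        i1 <- assign == pair[1]
        i2 <- assign == pair[2]
        m12 <- .cluster_model(Y[i1 | i2, , drop = FALSE], grid)
        # likelihood ratio at the merged fit's hyperparameters, so that a
        # singleton cannot defend itself by overfitting its own kernel
        g12 <- m12$hyper
        ll1 <- .cluster_joint_ll(Y[i1, , drop = FALSE], g12)
        ll2 <- .cluster_joint_ll(Y[i2, , drop = FALSE], g12)
        n1 <- sum(i1); n2 <- sum(i2)
        log_ratio <- (lgamma(n1 + n2) - lgamma(n1) - lgamma(n2) -
                        log(alpha)) + (m12$ml - ll1 - ll2)
        if (log(runif(1)) < log_ratio) assign[i2] <- pair[1]
      }
    }
    # canonical relabeling for storage
    if (it > burn_in) {
      part <- as.integer(factor(assign, levels = unique(assign)))
      partitions[[length(partitions) + 1L]] <- part
      coclust <- coclust + outer(part, part, "==")
    }
  }
  coclust <- coclust / length(partitions)
  dimnames(coclust) <- list(rownames(ts), rownames(ts))
  structure(list(partitions = partitions, coclust = coclust, times = t_h,
                 data = Y, alpha = alpha, n_iter = n_iter,
                 burn_in = burn_in, seed = seed), class = "dpgp_chain")
}

#' Least-squares consensus partition of a Gibbs chain
#'
#' Returns the sampled partition minimizing sum (delta_ij - pi_ij)^2
#' against the posterior co-clustering matrix pi (Dahl's method).
#'
#' @param chain a `dpgp_chain` from [dpgp_gibbs()].
#' @return integer assignment vector (named by gene when available).
#' @export
consensus_partition <- function(chain) {
  stopifnot(inherits(chain, "dpgp_chain"), length(chain$partitions) >= 1)
  pi_mat <- chain$coclust
  losses <- vapply(chain$partitions, function(p)
    sum((outer(p, p, "==") - pi_mat)^2), numeric(1))
  best <- chain$partitions[[which.min(losses)]]
  names(best) <- rownames(chain$coclust)
  best
}

#' Summarize a DPGP chain into a result object
#'
#' @param chain a `dpgp_chain`.
#' @return list of class `dpgp_result` with `partition`, `tightness`
#'   (per-gene mean posterior co-clustering with the other members of its
#'   final cluster; singletons have tightness 1), `coclust`, and
#'   `cluster_means` (per-cluster mean standardized trajectory).
#' @export
dpgp_result <- function(chain) {
  part <- consensus_partition(chain)
  pi_mat <- chain$coclust
  n <- length(part)
  tight <- vapply(seq_len(n), function(i) {
    mates <- setdiff(which(part == part[i]), i)
    if (length(mates) == 0) 1 else mean(pi_mat[i, mates])
  }, numeric(1))
  names(tight) <- names(part)
  means <- do.call(rbind, lapply(sort(unique(part)), function(k)
    colMeans(chain$data[part == k, , drop = FALSE])))
  rownames(means) <- sprintf("C%d", sort(unique(part)))
  structure(list(partition = part, tightness = tight, coclust = pi_mat,
                 cluster_means = means, settings = chain[c("alpha", "n_iter",
                                                           "burn_in", "seed")]),
            class = "dpgp_result")
}

#' Filter DPGP clusters to tightly assigned genes
#'
#' Keeps genes whose posterior co-clustering tightness is at least
#' `threshold` (inclusive).
#'
#' @param result a `dpgp_result` from [dpgp_result()].
#' @param threshold tightness threshold (default 0.7).
#' @return named list cluster label -> character vector of tight genes
#'   (empty clusters dropped).
#' @export
tightness_filter <- function(result, threshold = 0.7) {
  stopifnot(inherits(result, "dpgp_result"))
  keep <- result$tightness >= threshold
  part <- result$partition[keep]
  if (length(part) == 0) return(list())
  sets <- split(names(part), sprintf("C%d", part))
  sets[order(names(sets))]
}

#' One-call DPGP clustering with tightness filtering
#'
#' @inheritParams dpgp_gibbs
#' @param threshold tightness threshold for [tightness_filter()].
#' @return list with `result` (a `dpgp_result`) and `tight_sets`.
#' @export
dpgp_cluster <- function(ts, alpha = 1, n_iter = 500, burn_in = 250,
                         seed = 1, threshold = 0.7) {
  chain <- dpgp_gibbs(ts, alpha, n_iter, burn_in, seed)
  res <- dpgp_result(chain)
  list(result = res, tight_sets = tightness_filter(res, threshold))
}
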