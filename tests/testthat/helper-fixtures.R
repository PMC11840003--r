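# Shared fixture builders; everything is generated in code, seeded.

# expression matrix of `n_blocks` perfectly planted co-expression blocks
planted_block_expr <- function(n_blocks = 2, genes_per_block = 40,
                               n_samples = 20, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  bases <- replicate(n_blocks, rnorm(n_samples), simplify = FALSE)
  expr <- do.call(rbind, lapply(bases, function(b)
    t(sapply(seq_len(genes_per_block), function(i) b + rnorm(n_samples,
                                                             sd = noise_sd)))))
  rownames(expr) <- sprintf("g%03d", seq_len(nrow(expr)))
  colnames(expr) <- sprintf("s%02d", seq_len(n_samples))
  attr(expr, "truth") <- rep(seq_len(n_blocks), each = genes_per_block)
  expr
}

# two groups of trajectories with opposite shapes, their curves `sep`
# noise-standard-deviations apart in rms over the time grid
two_group_trajectories <- function(n_per_group = 20, n_times = 8,
                                   sep = 4, noise_sd = 0.2, seed = 1) {
  set.seed(seed)
  tt <- seq(0.5, 8, length.out = n_times)
  shape <- sin(tt / 2)
  amp <- sep * noise_sd / (2 * sqrt(mean(shape^2)))
  Y <- rbind(
    t(sapply(seq_len(n_per_group), function(i)
      shape * amp + rnorm(n_times, sd = noise_sd))),
    t(sapply(seq_len(n_per_group), function(i)
      -shape * amp + rnorm(n_times, sd = noise_sd))))
  rownames(Y) <- sprintf("g%02d", seq_len(2 * n_per_group))
  colnames(Y) <- tt
  attr(Y, "truth") <- rep(1:2, each = n_per_group)
  Y
}

# hand-rolled full quantile normalization (independent oracle)
oracle_quantile_normalize <- function(mat) {
  target <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    o <- order(mat[, j])
    v <- numeric(nrow(mat))
    v[o] <- target
    for (g in split(seq_len(nrow(mat)), mat[, j]))
      if (length(g) > 1) v[g] <- mean(v[g])
    out[, j] <- v
  }
  out
}

# exact hypergeometric upper tail by combinatorial summation (oracle)
oracle_hyper_tail <- function(k, K, N, n) {
  j <- seq(k, min(K, n))
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# brute-force triple-loop signed TOM (oracle)
oracle_tom <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    s <- 0
    for (u in seq_len(n)) s <- s + a[i, u] * a[u, j]
    tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# small config used across tests; any sim_config() field can be overridden
small_config <- function(seed = 1, ...) {
  args <- list(genes_per_species = 120, n_hogs = 80, n_clusters = 4,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
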