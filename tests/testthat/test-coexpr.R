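test_that("biweight midcorrelation behaves like a robust correlation", {
  set.seed(10)
  x <- rnorm(20)
  expr <- rbind(a = x, b = x, c = -x)
  r <- bicor_matrix(expr)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_true(isSymmetric(r))
  expect_true(all(r >= -1 & r <= 1))

  # close to Pearson on clean Gaussian draws
  y <- 0.6 * x + rnorm(20, sd = 0.5)
  rb <- bicor_matrix(rbind(a = x, b = y))["a", "b"]
  expect_lt(abs(rb - cor(x, y)), 0.15)

  # zero-mad gene falls back to Pearson deviations, flagged
  z <- c(rep(1, 18), 5, 9)
  rz <- bicor_matrix(rbind(a = x, z = z))
  expect_true("z" %in% attr(rz, "pearson_fallback"))
})

test_that("signed adjacency maps correlation to [0,1] as specified", {
  cm <- matrix(c(1, 1, 0, -1,
                 1, 1, 0, 0,
                 0, 0, 1, 0,
                 -1, 0, 0, 1), 4, 4)
  a <- signed_adjacency(cm, 2)
  expect_equal(a[1, 2], 1)        # cor 1 -> 1 for any beta
  expect_equal(a[1, 4], 0)        # cor -1 -> 0
  expect_equal(a[1, 3], 0.25)     # cor 0, beta 2 -> 0.25
  expect_equal(unname(diag(a)), rep(0, 4))
})

test_that("scale-free fit index follows its sign convention", {
  # exact power law: counts proportional to 1/k at k = 1..10
  k <- rep(1:10, times = round(2520 / (1:10)))
  expect_equal(scale_free_fit(k), 1, tolerance = 1e-6)

  # increasing p(k): signed R^2 negative
  k_inc <- rep(1:10, times = 1:10 * 10)
  expect_lt(scale_free_fit(k_inc), 0)

  expect_error(scale_free_fit(rep(5, 100)), "constant")
})

test_that("soft-threshold scan reports connectivity diagnostics", {
  set.seed(11)
  # independent noise: mean connectivity strictly decreasing in beta
  noise <- matrix(rnorm(60 * 12), 60, 12,
                  dimnames = list(sprintf("g%02d", 1:60), NULL))
  expect_warning(
    ps <- pick_soft_threshold(noise, powers = c(2, 4, 8, 16), r2_min = 0.999),
    "threshold")
  expect_true(all(diff(ps$diagnostics$mean_k) < 0))

  # perfectly modular blocks: connectivity = block size - 1 at every beta
  base <- rnorm(12)
  blocks <- rbind(matrix(rep(base, 30), 30, byrow = TRUE),
                  matrix(rep(rev(base), 30), 30, byrow = TRUE))
  rownames(blocks) <- sprintf("g%02d", 1:60)
  r <- bicor_matrix(blocks)
  for (beta in c(2, 6)) {
    a <- signed_adjacency(r, beta)
    expect_equal(unname(rowSums(a > 0.999)), rep(29, 60))
  }
})

test_that("signed TOM equals the brute-force oracle", {
  # 3 nodes, all off-diagonal a = 0.5 -> TOM = 0.5
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 0
  expect_equal(unname(signed_tom(a3)[1, 2]), 0.5)

  # isolated pair: TOM = 0
  a0 <- matrix(0, 4, 4)
  expect_equal(unname(signed_tom(a0)[1, 2]), 0)

  # identical full neighborhoods with a_ij = 1 -> TOM = 1
  a1 <- matrix(1, 4, 4); diag(a1) <- 0
  expect_equal(unname(signed_tom(a1)[1, 2]), 1)

  # random instances vs triple-loop oracle
  set.seed(12)
  for (i in 1:5) {
    n <- sample(5:20, 1)
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tom <- signed_tom(a)
    expect_lt(max(abs(tom - oracle_tom(a))), 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_true(isSymmetric(unname(tom)))
  }
})

test_that("module detection recovers planted blocks and obeys the size rule", {
  expr <- planted_block_expr(2, 40, 20, noise_sd = 0.2, seed = 13)
  r <- bicor_matrix(expr)
  tom <- signed_tom(signed_adjacency(r, 6))
  mods <- detect_modules(tom, min_module_size = 30)
  expect_equal(adjusted_rand_index(mods, attr(expr, "truth")), 1)
  expect_equal(sort(as.integer(table(mods))), c(40L, 40L))

  # everything below min size collapses to unassigned
  small <- planted_block_expr(1, 25, 10, seed = 14)
  toms <- signed_tom(signed_adjacency(bicor_matrix(small), 6))
  expect_true(all(detect_modules(toms, min_module_size = 30) == "unassigned"))

  # permuting gene order changes labels only
  perm <- sample(nrow(expr))
  mods_p <- detect_modules(signed_tom(signed_adjacency(
    bicor_matrix(expr[perm, ]), 6)), 30)
  expect_equal(adjusted_rand_index(mods_p, mods[rownames(expr)[perm]]), 1)
})

test_that("module eigengene matches an eigen-decomposition oracle", {
  set.seed(15)
  expr <- matrix(rnorm(300), 30, 10,
                 dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:10)))
  eg <- module_eigengene(expr, rownames(expr))
  expect_equal(sum(eg$eigengene^2), 1, tolerance = 1e-12)
  # oracle: eigenvalues of the standardized gene-gene cross-product
  xs <- t(scale(t(expr)))
  # module_eigengene standardizes with the population-free sample sd, as scale()
  ev <- eigen(crossprod(xs), symmetric = TRUE)$values
  expect_equal(eg$var_explained, ev[1] / sum(ev), tolerance = 1e-8)
  expect_gt(eg$var_explained, 0)
  expect_lte(eg$var_explained, 1)

  # identical member profiles: eigengene proportional to the profile
  prof <- rnorm(10)
  same <- matrix(rep(prof, 5), 5, byrow = TRUE,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:10)))
  egs <- module_eigengene(same, rownames(same))
  expect_equal(egs$var_explained, 1, tolerance = 1e-12)
  expect_gt(abs(cor(egs$eigengene, prof)), 1 - 1e-10)

  # sign anchored toward positive mean member correlation
  flip <- rbind(same, -same)
  rownames(flip) <- sprintf("g%d", 1:10)
  egf <- module_eigengene(flip[c(1:5, 6:9), ], rownames(flip)[c(1:5, 6:9)])
  expect_gt(mean(cor(t(flip[1:5, ]), egf$eigengene)), 0)
})

test_that("eigengene merging applies the dissimilarity rule and is idempotent", {
  set.seed(16)
  base <- rnorm(12)
  near <- base + rnorm(12, sd = 0.15)      # eigengene cor ~ 0.95
  far <- rnorm(12)
  expr <- rbind(
    t(sapply(1:10, function(i) base + rnorm(12, sd = 0.1))),
    t(sapply(1:10, function(i) near + rnorm(12, sd = 0.1))),
    t(sapply(1:10, function(i) far + rnorm(12, sd = 0.1))))
  rownames(expr) <- sprintf("g%02d", 1:30)
  colnames(expr) <- sprintf("s%d", 1:12)
  mods <- setNames(rep(c("m01", "m02", "m03"), each = 10), rownames(expr))
  merged <- merge_close_modules(mods, expr, 0.20)
  expect_equal(length(unique(merged)), 2)          # near pair merged
  expect_equal(length(unique(merged[1:20])), 1)    # the similar two fused
  again <- merge_close_modules(merged, expr, 0.20)
  expect_identical(again, merged)

  single <- setNames(rep("m01", 10), rownames(expr)[1:10])
  expect_identical(unique(merge_close_modules(single, expr[1:10, ], 0.2)),
                   "m01")
})

test_that("module-trait correlation reproduces closed-form p-values", {
  set.seed(17)
  eg <- matrix(rnorm(30), 10, 3,
               dimnames = list(sprintf("s%02d", 1:10), c("m01", "m02", "m03")))
  traits <- cbind(self = eg[, 1], const = rep(2, 10), noise = rnorm(10))
  rownames(traits) <- rownames(eg)
  mt <- module_trait_cor(eg, traits)
  expect_equal(mt$r["m01", "self"], 1)
  expect_true(is.na(mt$r["m01", "const"]))

  # r = 0 with n = 10 -> p = 1; closed form at r = 0.85, n = 60
  p_of <- function(r, n) 2 * pt(abs(r * sqrt(n - 2) / sqrt(1 - r^2)),
                                df = n - 2, lower.tail = FALSE)
  expect_equal(p_of(0, 10), 1)
  expect_lt(p_of(0.85, 60), 1e-15)   # far tail, as the printed magnitudes
  expect_gt(p_of(0.85, 60), 1e-20)
})

test_that("hub ranking uses intramodular connectivity with stable ties", {
  genes <- sprintf("g%02d", 1:10)
  a <- matrix(0.1, 10, 10, dimnames = list(genes, genes))
  a["g05", ] <- a[, "g05"] <- 1
  diag(a) <- 0
  mods <- setNames(rep("m01", 10), genes)
  hubs <- top_hubs(a, mods, hub_k = 3)
  expect_equal(hubs$gene[1], "g05")
  expect_equal(nrow(hubs), 3)

  # module smaller than hub_k: all members reported
  hubs_all <- top_hubs(a, mods, hub_k = 50)
  expect_equal(sort(hubs_all$gene), genes)
})
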