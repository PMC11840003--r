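test_that("design arithmetic matches the closed-form grid x replicate product", {
  d <- make_design(sim_config())
  expect_equal(nrow(d), 270)
  expect_equal(sum(d$species == "sp1"), 90)          # 28 x 3 + 6
  expect_false(anyDuplicated(d$sample_id) > 0)

  d1 <- make_design(sim_config(n_species = 1,
                               time_grid = list(cold = 2), replicates = 3))
  expect_equal(nrow(d1), 3)

  # closed form for an arbitrary grid
  cfg <- sim_config(n_species = 2,
                    time_grid = list(t0 = 0, control = c(1, 2, 3),
                                     heat = c(1, 3)),
                    replicates = 4, t0_replicates = 5)
  expect_equal(nrow(make_design(cfg)), 2 * (5 + 5 * 4))
})

test_that("overlapping condition/time labels are rejected", {
  expect_error(sim_config(time_grid = list(cold = c(1, 1))), "duplicated")
})

test_that("HOG table construction respects duplication and loss settings", {
  cfg <- small_config(n_hogs = 10)
  h <- make_hog_table(cfg)
  per_hog <- table(h$hog_table$hog_id[h$hog_table$hog_id != ""])
  expect_true(all(per_hog == 3))
  expect_equal(nrow(h$ortholog_map), 10)

  h_loss <- make_hog_table(small_config(n_hogs = 10, hog_loss_rate = 1))
  expect_true(all(h_loss$hog_table$hog_id == ""))
  expect_equal(nrow(h_loss$ortholog_map), 0)

  cfg_dup <- small_config(n_hogs = 10, hog_dup_rate = 0.5, seed = 42)
  expect_identical(make_hog_table(cfg_dup), make_hog_table(cfg_dup))
})

test_that("archetypes behave like squared-exponential GP draws", {
  expect_true(all(make_archetypes(small_config(gp_amplitude = 0)) == 0))
  flat <- make_archetypes(small_config(gp_lengthscale_h = 1e6))
  expect_lt(max(apply(flat, 1, function(x) diff(range(x)))), 1e-3)
  cfg <- small_config(seed = 9)
  expect_identical(make_archetypes(cfg), make_archetypes(cfg))
  expect_error(.se_kernel(1:3, 1:3, 1, -1), "positive")
})

test_that("counts follow the negative-binomial archetype model", {
  cfg <- sim_config(n_species = 1, genes_per_species = 600, n_hogs = 10,
                    n_clusters = 1, nb_dispersion = 0.05, libsize_logsd = 0,
                    time_grid = list(t0 = 0, control = c(1, 2), heat = c(1, 2)),
                    replicates = 3, seed = 11)
  design <- make_design(cfg)
  times <- c("1", "2")
  arch <- matrix(1, 1, 2, dimnames = list("arch01", times))  # +1 log2 unit
  truth <- list(archetypes = arch,
                assignment = list(sp1 = setNames(rep(1L, 600),
                                                 sprintf("sp1_g%05d", 1:600))))
  cnt <- simulate_counts(design, truth, cfg)$sp1
  trt <- design$condition == "heat"
  ctl <- design$condition == "control"
  ratio <- mean(cnt[, trt]) / mean(cnt[, ctl])
  expect_equal(ratio, 2, tolerance = 0.05)   # Monte Carlo over 600 x 6 draws

  # dispersion -> 0 with no effect: Poisson-like variance/mean
  cfg0 <- sim_config(n_species = 1, genes_per_species = 2000, n_hogs = 10,
                     n_clusters = 1, nb_dispersion = 0, libsize_logsd = 0,
                     time_grid = list(control = c(1, 2, 3, 4)),
                     replicates = 3, seed = 12)
  d0 <- make_design(cfg0)
  arch0 <- matrix(0, 1, 4, dimnames = list("arch01", c("1", "2", "3", "4")))
  tr0 <- list(archetypes = arch0,
              assignment = list(sp1 = setNames(rep(1L, 2000),
                                               sprintf("sp1_g%05d", 1:2000))))
  c0 <- simulate_counts(d0, tr0, cfg0)$sp1
  vm <- apply(c0, 1, var) / rowMeans(c0)
  expect_equal(mean(vm, na.rm = TRUE), 1, tolerance = 0.1)

  expect_identical(simulate_counts(design, truth, cfg),
                   simulate_counts(design, truth, cfg))
})

test_that("VAR generator plants recoverable lagged structure", {
  cfg <- small_config(n_regulators = 10, n_causal_edges = 0)
  v0 <- simulate_var_series(cfg, n_times = 60, n_reps = 1)
  expect_equal(nrow(v0$edges), 0)

  # one strong edge: lag-1 cross-correlation of the pair dominates
  A <- matrix(0, 10, 10)
  A[2, 1] <- 0.9                       # node 1 drives node 2
  cfg1 <- small_config(n_regulators = 10, n_causal_edges = 5)
  v1 <- simulate_var_series(cfg1, n_times = 60, n_reps = 1, noise_sd = 0.3,
                            A = A)
  x <- v1$series[, , 1]
  cc <- function(i, j) cor(x[j, 1:59], x[i, 2:60])  # j at t-1 vs i at t
  planted <- cc(2, 1)
  others <- vapply(3:10, function(i) abs(cc(i, 1)), numeric(1))
  expect_gt(planted, max(others) + 0.3)

  expect_identical(simulate_var_series(cfg1, n_times = 20),
                   simulate_var_series(cfg1, n_times = 20))

  # a cycle with |coef| > 1 is non-stationary and must be rejected
  Abad <- matrix(0, 10, 10); Abad[1, 2] <- Abad[2, 1] <- 1.1
  expect_error(simulate_var_series(cfg1, A = Abad), "spectral radius")
})

test_that("metabolite channels track their linked archetypes", {
  cfg <- small_config(n_metabolites = 6)
  design <- make_design(cfg)
  design <- design[design$species == "sp1", ]
  arch <- make_archetypes(cfg)
  truth <- list(archetypes = arch)
  m0 <- simulate_metabolites(truth, design, cfg, noise_sd = 0)
  trt <- !(design$condition %in% c("t0", "control"))
  linked <- which(!is.na(m0$links))[1]
  expect_equal(unname(m0$traits[trt, linked]),
               unname(arch[m0$links[linked], as.character(design$time_h[trt])]))

  # an unlinked metabolite stays uncorrelated with every archetype; the
  # empirical bound needs enough samples, so use the full 270-sample design
  full <- make_design(cfg)
  full$sample_id <- sprintf("s%03d", seq_len(nrow(full)))  # unique ids
  m <- simulate_metabolites(truth, full, cfg, noise_sd = 1, p_linked = 0)
  trt_f <- !(full$condition %in% c("t0", "control"))
  for (a in seq_len(nrow(arch))) {
    sig <- numeric(nrow(full))
    sig[trt_f] <- arch[a, as.character(full$time_h[trt_f])]
    expect_lt(abs(cor(m$traits[, 1], sig)), 0.3)
  }
  expect_identical(simulate_metabolites(truth, design, cfg),
                   simulate_metabolites(truth, design, cfg))
})

test_that("whole-dataset generation is byte-deterministic", {
  cfg <- small_config(seed = 77)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
})

test_that("ortholog trajectory conservation is monotone in the dial", {
  mean_pair_cor <- function(p) {
    cfg <- sim_config(genes_per_species = 250, n_hogs = 220, n_clusters = 6,
                      p_ortholog_conserved = p, seed = 5)
    hogs <- make_hog_table(cfg)
    arch <- make_archetypes(cfg)
    set.seed(cfg$seed + 99L)
    asg <- strepnet:::.assign_archetypes(cfg, hogs)
    omap <- hogs$ortholog_map
    cors <- mapply(function(g1, g2)
      cor(arch[asg$sp1[[g1]], ], arch[asg$sp2[[g2]], ]),
      omap$sp1, omap$sp2)
    mean(cors)
  }
  cors <- vapply(c(0, 0.5, 1), mean_pair_cor, numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_equal(cors[3], 1)    # p = 1: all ortholog pairs share an archetype
})

test_that("dataset round-trips through the plain-text writers", {
  cfg <- sim_config(genes_per_species = 40, n_hogs = 20, n_clusters = 3,
                    time_grid = list(t0 = 0, control = c(1, 2), heat = c(1, 2)),
                    seed = 3)
  ds <- simulate_dataset(cfg)
  out <- withr::local_tempdir()
  write_synth_dataset(ds, out)
  expect_equal(read_tsv(file.path(out, "design.tsv"))$sample_id,
               ds$design$sample_id)
  m <- read_matrix_tsv(file.path(out, "counts_sp1.tsv"))
  expect_equal(m, ds$counts$sp1, ignore_attr = FALSE)
})
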