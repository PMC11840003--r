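#' Default condition -> sampling-time grid
#'
#' 29 condition-time combinations per species: the initial time point t0,
#' eight control times, six cold and six heat times (24 h series), five
#' high-light times (6 h exposure) and three recovery times (4 h after the
#' 6 h high-light exposure, sampled on the absolute clock).
#'
#' @return named list mapping condition to a numeric vector of hours.
#' @export
default_time_grid <- function() {
  list(
    t0        = 0,
    control   = c(0.5, 1, 2, 4, 6, 8, 10, 24),
    cold      = c(0.5, 1, 2, 4, 6, 24),
    heat      = c(0.5, 1, 2, 4, 6, 24),
    highlight = c(0.5, 1, 2, 4, 6),
    recovery  = c(7, 8, 10)
  )
}

#' Configuration for the synthetic multi-species stress time-course generator
#'
#' The defaults describe the world the downstream stages assume: three
#' species sharing hierarchical orthogroups (HOGs), 29 condition-time
#' combinations in biological triplicate (sextuplicate at t0; 270 samples in
#' total), negative-binomial counts driven by Gaussian-process-shaped
#' trajectory archetypes that are partially conserved between orthologs,
#' lagged causal edges among a regulator subset, and metabolite channels
#' correlated with selected archetypes.
#'
#' @param n_species number of species.
#' @param genes_per_species genes simulated per species.
#' @param n_hogs number of orthogroups shared across species.
#' @param p_ortholog_conserved probability that orthologs share a trajectory
#'   archetype.
#' @param time_grid named list mapping condition to hours, see
#'   [default_time_grid()]. The t0 entry is sampled at `t0_replicates`.
#' @param replicates biological replicates per non-t0 condition-time.
#' @param t0_replicates replicates at the initial time point.
#' @param n_clusters number of trajectory archetypes.
#' @param gp_lengthscale_h squared-exponential kernel lengthscale in hours.
#' @param gp_amplitude kernel amplitude (sigma_f, log2 fold-change units).
#' @param nb_dispersion negative-binomial dispersion (1/size); 0 = Poisson.
#' @param libsize_logmean,libsize_logsd log-normal library-size parameters.
#' @param n_regulators,n_causal_edges,causal_coef,causal_lag parameters of
#'   the planted vector-autoregressive causal structure.
#' @param n_metabolites number of metabolite channels.
#' @param hog_dup_rate,hog_loss_rate per-(HOG, species) duplication/loss
#'   probabilities applied when building the orthology table.
#' @param seed integer seed; identical config + seed gives identical output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_species = 3, genes_per_species = 1500, n_hogs = 1000,
                       p_ortholog_conserved = 0.8,
                       time_grid = default_time_grid(),
                       replicates = 3, t0_replicates = 6,
                       n_clusters = 8, gp_lengthscale_h = 4, gp_amplitude = 1.5,
                       nb_dispersion = 0.1,
                       libsize_logmean = log(2e6), libsize_logsd = 0.2,
                       n_regulators = 30, n_causal_edges = 20,
                       causal_coef = 0.6, causal_lag = 1,
                       n_metabolites = 24,
                       hog_dup_rate = 0, hog_loss_rate = 0, seed = 1L) {
  .check_count(n_species, "n_species")
  .check_count(genes_per_species, "genes_per_species")
  .check_count(n_hogs, "n_hogs")
  .check_prob(p_ortholog_conserved, "p_ortholog_conserved")
  .check_count(replicates, "replicates")
  .check_count(t0_replicates, "t0_replicates")
  .check_count(n_clusters, "n_clusters")
  .check_count(causal_lag, "causal_lag")
  .check_prob(hog_dup_rate, "hog_dup_rate")
  .check_prob(hog_loss_rate, "hog_loss_rate")
  if (n_hogs > genes_per_species)
    stop("n_hogs must not exceed genes_per_species")
  if (is.null(names(time_grid)) || anyDuplicated(names(time_grid)))
    stop("time_grid conditions must be uniquely named")
  for (cond in names(time_grid)) {
    if (anyDuplicated(time_grid[[cond]]))
      stop(sprintf("duplicated time in condition '%s'", cond))
  }
  structure(list(
    n_species = n_species, genes_per_species = genes_per_species,
    n_hogs = n_hogs, p_ortholog_conserved = p_ortholog_conserved,
    time_grid = time_grid, replicates = replicates,
    t0_replicates = t0_replicates, n_clusters = n_clusters,
    gp_lengthscale_h = gp_lengthscale_h, gp_amplitude = gp_amplitude,
    nb_dispersion = nb_dispersion, libsize_logmean = libsize_logmean,
    libsize_logsd = libsize_logsd, n_regulators = n_regulators,
    n_causal_edges = n_causal_edges, causal_coef = causal_coef,
    causal_lag = causal_lag, n_metabolites = n_metabolites,
    hog_dup_rate = hog_dup_rate, hog_loss_rate = hog_loss_rate,
    seed = as.integer(seed)), class = "sim_config")
}

.species_names <- function(n) sprintf("sp%d", seq_len(n))

#' Build the sample design table for a configuration
#'
#' One sample per (species, condition, time, replicate); the t0 combination
#' is sampled at `t0_replicates`, every other combination at `replicates`.
#' The default configuration yields 270 samples (90 per species).
#'
#' @param config a [sim_config()].
#' @return data frame with columns sample_id, species, condition, time_h,
#'   replicate.
#' @export
make_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- list()
  for (sp in .species_names(config$n_species)) {
    for (cond in names(config$time_grid)) {
      reps <- if (cond == "t0") config$t0_replicates else config$replicates
      for (t in config$time_grid[[cond]]) {
        for (r in seq_len(reps)) {
          rows[[length(rows) + 1L]] <- data.frame(
            species = sp, condition = cond, time_h = t, replicate = r,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  design <- do.call(rbind, rows)
  design$sample_id <- sprintf("%s_%s_t%g_r%d", design$species,
                              design$condition, design$time_h,
                              design$replicate)
  if (anyDuplicated(design$sample_id))
    stop("overlapping condition/time labels produce duplicate sample ids")
  design[, c("sample_id", "species", "condition", "time_h", "replicate")]
}

#' Build a synthetic hierarchical-orthogroup (HOG) table
#'
#' By default every HOG receives exactly one gene in every species. Gene
#' loss removes a species' member from its HOG (the gene becomes
#' species-specific, empty hog_id); duplication adds a second member drawn
#' from the species-specific gene pool.
#'
#' @param config a [sim_config()].
#' @return list with `hog_table` (gene_id, species, hog_id; empty hog_id for
#'   genes without orthology) and `ortholog_map` (hog_id plus one gene column
#'   per species for HOGs with exactly one surviving member per species).
#' @export
make_hog_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  species <- .species_names(config$n_species)
  hog_ids <- sprintf("HOG%05d", seq_len(config$n_hogs))
  tabs <- list()
  for (sp in species) {
    genes <- sprintf("%s_g%05d", sp, seq_len(config$genes_per_species))
    hog <- rep("", config$genes_per_species)
    hog[seq_len(config$n_hogs)] <- hog_ids
    # loss: membership removed per (HOG, species)
    lost <- runif(config$n_hogs) < config$hog_loss_rate
    hog[seq_len(config$n_hogs)][lost] <- ""
    # duplication: species-specific genes recruited into a random HOG
    free <- which(hog == "")
    dup <- runif(config$n_hogs) < config$hog_dup_rate
    n_dup <- min(sum(dup), length(free))
    if (n_dup > 0) {
      take <- free[seq_len(n_dup)]
      hog[take] <- hog_ids[which(dup)[seq_len(n_dup)]]
    }
    tabs[[sp]] <- data.frame(gene_id = genes, species = sp, hog_id = hog,
                             stringsAsFactors = FALSE)
  }
  hog_table <- do.call(rbind, tabs)
  rownames(hog_table) <- NULL
  # ortholog map: HOGs with exactly one member in every species
  keep <- hog_ids
  cols <- list(hog_id = character(0))
  per_sp <- lapply(species, function(sp) {
    tb <- tabs[[sp]]
    split(tb$gene_id[tb$hog_id != ""], tb$hog_id[tb$hog_id != ""])
  })
  names(per_sp) <- species
  ok <- vapply(keep, function(h) {
    all(vapply(per_sp, function(m) length(m[[h]]) == 1L, logical(1)))
  }, logical(1))
  omap <- data.frame(hog_id = keep[ok], stringsAsFactors = FALSE)
  for (sp in species)
    omap[[sp]] <- vapply(omap$hog_id, function(h) per_sp[[sp]][[h]],
                         character(1))
  list(hog_table = hog_table, ortholog_map = omap)
}

# internal: squared-exponential kernel matrix
.se_kernel <- function(t1, t2, sigma_f, lengthscale) {
  if (lengthscale <= 0) stop("lengthscale must be positive")
  d <- outer(t1, t2, "-")
  sigma_f^2 * exp(-d^2 / (2 * lengthscale^2))
}

#' Draw trajectory archetypes from a Gaussian process
#'
#' Each archetype is a zero-mean GP draw with squared-exponential kernel
#' k(t, t') = sigma_f^2 exp(-(t - t')^2 / (2 l^2)) evaluated on the union of
#' all treatment (non-control, non-t0) sampling times, in log2 fold-change
#' units.
#'
#' @param config a [sim_config()].
#' @return matrix n_clusters x time points, columns named by hour.
#' @export
make_archetypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 202L)
  trt <- setdiff(names(config$time_grid), c("t0", "control"))
  times <- sort(unique(unlist(config$time_grid[trt])))
  K <- .se_kernel(times, times, config$gp_amplitude, config$gp_lengthscale_h)
  if (config$gp_amplitude == 0) {
    arch <- matrix(0, config$n_clusters, length(times))
  } else {
    L <- chol(K + diag(1e-10 * max(diag(K), 1), length(times)))
    z <- matrix(rnorm(config$n_clusters * length(times)),
                config$n_clusters, length(times))
    arch <- z %*% L
  }
  dimnames(arch) <- list(sprintf("arch%02d", seq_len(config$n_clusters)),
                         as.character(times))
  arch
}

# internal: assign genes to archetypes, conserving ortholog assignments
# with probability p_ortholog_conserved
.assign_archetypes <- function(config, hogs) {
  species <- .species_names(config$n_species)
  assign <- list()
  base <- sample.int(config$n_clusters, config$n_hogs, replace = TRUE)
  names(base) <- sprintf("HOG%05d", seq_len(config$n_hogs))
  for (sp in species) {
    genes <- hogs$hog_table[hogs$hog_table$species == sp, ]
    cl <- integer(nrow(genes))
    for (i in seq_len(nrow(genes))) {
      h <- genes$hog_id[i]
      if (h != "" && runif(1) < config$p_ortholog_conserved) {
        cl[i] <- base[[h]]
      } else {
        cl[i] <- sample.int(config$n_clusters, 1)
      }
    }
    assign[[sp]] <- setNames(cl, genes$gene_id)
  }
  assign
}

#' Simulate negative-binomial count matrices
#'
#' Counts follow NB(mean = library-size-scaled baseline x 2^effect,
#' dispersion), where the effect is the gene's archetype value at the
#' sample's time under treatment and 0 in control/t0 samples. Baselines are
#' log-normal (heavy-tailed, like real RNA-seq).
#'
#' @param design design table from [make_design()].
#' @param truth planted truth from [simulate_dataset()] internals: list with
#'   `archetypes` (matrix) and `assignment` (per-species named vectors).
#' @param config a [sim_config()].
#' @return named list of genes x samples integer matrices, one per species.
#' @export
simulate_counts <- function(design, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 303L)
  species <- .species_names(config$n_species)
  arch <- truth$archetypes
  out <- list()
  for (sp in species) {
    asg <- truth$assignment[[sp]]
    genes <- names(asg)
    des <- design[design$species == sp, ]
    baseline <- rlnorm(length(genes), meanlog = log(50), sdlog = 1.2)
    libsize <- rlnorm(nrow(des), config$libsize_logmean, config$libsize_logsd)
    lib_scale <- libsize / exp(config$libsize_logmean)
    eff <- matrix(0, length(genes), nrow(des))
    trt <- !(des$condition %in% c("t0", "control"))
    for (j in which(trt)) {
      tc <- as.character(des$time_h[j])
      eff[, j] <- arch[asg, tc]
    }
    mu <- (baseline %o% lib_scale) * 2^eff
    if (config$nb_dispersion <= 0) {
      cnt <- matrix(rpois(length(mu), mu), nrow(mu))
    } else {
      cnt <- matrix(rnbinom(length(mu), mu = mu,
                            size = 1 / config$nb_dispersion), nrow(mu))
    }
    dimnames(cnt) <- list(genes, des$sample_id)
    out[[sp]] <- cnt
  }
  out
}

#' Simulate a vector-autoregressive multivariate time series
#'
#' x_t = A x_(t-lag) + eps, eps ~ N(0, sigma^2); the planted causal edges
#' are the non-zero off-diagonal entries of A. The coefficient matrix is
#' rejected if its spectral radius is >= 1 (non-stationary).
#'
#' @param config a [sim_config()]; uses n_regulators, n_causal_edges,
#'   causal_coef, causal_lag and seed.
#' @param n_times number of time points to simulate (default 20).
#' @param n_reps number of replicate series (default 3).
#' @param noise_sd innovation standard deviation.
#' @param A optional coefficient matrix; when supplied only the noise is
#'   redrawn, so several species can share one planted network.
#' @param seed optional seed overriding the config's (for independent
#'   realizations of a shared network).
#' @return list with `edges` (data frame source, target, coef), `series`
#'   (array nodes x time x replicate), `A` (coefficient matrix).
#' @export
simulate_var_series <- function(config, n_times = 20, n_reps = 3,
                                noise_sd = 1, A = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed + 404L else as.integer(seed))
  p <- config$n_regulators
  nodes <- sprintf("g%03d", seq_len(p))
  if (is.null(A)) {
    A <- matrix(0, p, p, dimnames = list(nodes, nodes))
    off <- which(row(A) != col(A))
    pick <- sample(off, min(config$n_causal_edges, length(off)))
    A[pick] <- config$causal_coef
  } else {
    stopifnot(nrow(A) == p, ncol(A) == p)
    dimnames(A) <- list(nodes, nodes)
  }
  sr <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (sr >= 1)
    stop(sprintf("unstable coefficient matrix: spectral radius %.3f >= 1", sr))
  lag <- config$causal_lag
  series <- array(0, c(p, n_times, n_reps),
                  dimnames = list(nodes, NULL, NULL))
  for (r in seq_len(n_reps)) {
    x <- matrix(rnorm(p * n_times, sd = noise_sd), p, n_times)
    for (t in seq(lag + 1, n_times))
      x[, t] <- A %*% x[, t - lag] + x[, t]
    series[, , r] <- x
  }
  # A[i, j] != 0 means x_i is driven by x_j: edge source j -> target i
  idx <- which(A != 0, arr.ind = TRUE)
  edges <- data.frame(source = nodes[idx[, 2]], target = nodes[idx[, 1]],
                      coef = A[idx], stringsAsFactors = FALSE)
  edges <- edges[.lex_order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, series = series, A = A)
}

#' Simulate metabolite channels linked to trajectory archetypes
#'
#' Each metabolite is linked to one archetype (or to pure noise); its value
#' in a treatment sample is the linked archetype trajectory at that time
#' plus Gaussian noise, and noise alone in control/t0 samples.
#'
#' @param truth list with `archetypes` matrix.
#' @param design design table (any single species' rows, or all).
#' @param config a [sim_config()].
#' @param noise_sd measurement noise standard deviation (default 0.3).
#' @param p_linked probability a metabolite is linked to an archetype.
#' @return list with `traits` (samples x metabolites matrix) and `links`
#'   (metabolite -> archetype index, NA for unlinked).
#' @export
simulate_metabolites <- function(truth, design, config, noise_sd = 0.3,
                                 p_linked = 0.75) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 505L)
  arch <- truth$archetypes
  m <- config$n_metabolites
  links <- ifelse(runif(m) < p_linked,
                  sample.int(nrow(arch), m, replace = TRUE), NA_integer_)
  names(links) <- sprintf("met%02d", seq_len(m))
  traits <- matrix(0, nrow(design), m,
                   dimnames = list(design$sample_id, names(links)))
  trt <- !(design$condition %in% c("t0", "control"))
  for (k in seq_len(m)) {
    sig <- numeric(nrow(design))
    if (!is.na(links[k])) {
      tc <- as.character(design$time_h[trt])
      sig[trt] <- arch[links[k], tc]
    }
    traits[, k] <- sig + rnorm(nrow(design), sd = noise_sd)
  }
  list(traits = traits, links = links)
}

#' Generate a complete seeded synthetic dataset
#'
#' Runs the whole generator: design, orthology, archetypes, archetype
#' assignment (orthologs conserved with probability `p_ortholog_conserved`),
#' counts, planted causal series, and metabolite channels.
#'
#' @param config a [sim_config()].
#' @return list with elements design, hog_table, ortholog_map, truth
#'   (archetypes, assignment, causal edges, metabolite links), counts (per
#'   species), var (planted causal series), metabolites.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  design <- make_design(config)
  hogs <- make_hog_table(config)
  arch <- make_archetypes(config)
  set.seed(config$seed + 99L)
  assignment <- .assign_archetypes(config, hogs)
  truth <- list(archetypes = arch, assignment = assignment)
  counts <- simulate_counts(design, truth, config)
  var_sim <- simulate_var_series(config)
  met <- simulate_metabolites(truth, design[design$species == "sp1", ], config)
  truth$causal_edges <- var_sim$edges
  truth$metabolite_links <- met$links
  list(design = design, hog_table = hogs$hog_table,
       ortholog_map = hogs$ortholog_map, truth = truth, counts = counts,
       var = var_sim, metabolites = met$traits)
}

#' Write a synthetic dataset to an output directory as plain-text tables
#'
#' @param dataset result of [simulate_dataset()].
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_synth_dataset <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(dataset$design, file.path(outdir, "design.tsv"))
  write_tsv(dataset$hog_table, file.path(outdir, "hogs.tsv"))
  for (sp in names(dataset$counts))
    write_matrix_tsv(dataset$counts[[sp]],
                     file.path(outdir, sprintf("counts_%s.tsv", sp)))
  write_matrix_tsv(t(dataset$metabolites), file.path(outdir, "metabolites.tsv"))
  invisible(outdir)
}
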