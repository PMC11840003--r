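#' Preprocess one species' counts
#'
#' CPM filter (> `min_cpm` in >= `min_samples` samples), log2-CPM, then
#' smooth quantile normalization grouped by condition label.
#'
#' @param counts genes x samples count matrix.
#' @param design matching design rows.
#' @param min_cpm,min_samples expression-filter thresholds.
#' @return list with `expr` (filtered, normalized log2 matrix) and
#'   `kept_genes`.
#' @export
preprocess_counts <- function(counts, design, min_cpm = 10, min_samples = 3) {
  stopifnot(all(colnames(counts) %in% design$sample_id))
  design <- design[match(colnames(counts), design$sample_id), ]
  cm <- cpm(counts)
  keep <- filter_expressed(cm, min_cpm, min_samples)
  lg <- log_cpm(counts[keep, , drop = FALSE])
  expr <- qsmooth_normalize(lg, design$condition)
  list(expr = expr, kept_genes = keep)
}

#' Per-replicate log2 fold-change time series for one treatment
#'
#' For every treatment time point with a matched control, each replicate's
#' log2 expression minus the mean control log2 expression at the same time;
#' the replicate axis is preserved so that the network inference can stack
#' replicates as additional training rows.
#'
#' @param expr genes x samples log2 matrix.
#' @param design matching design rows.
#' @param treatment condition label.
#' @param genes optional gene subset.
#' @param control control condition label.
#' @return array genes x time x replicate; time points without a matched
#'   control are skipped.
#' @export
fold_change_series <- function(expr, design, treatment, genes = NULL,
                               control = "control") {
  design <- design[match(colnames(expr), design$sample_id), ]
  if (is.null(genes)) genes <- rownames(expr)
  times <- sort(intersect(design$time_h[design$condition == treatment],
                          design$time_h[design$condition == control]))
  if (length(times) == 0) stop("no matched treatment/control time points")
  reps <- sort(unique(design$replicate[design$condition == treatment]))
  out <- array(NA_real_, c(length(genes), length(times), length(reps)),
               dimnames = list(genes, as.character(times), NULL))
  for (ti in seq_along(times)) {
    ctrl_cols <- design$condition == control & design$time_h == times[ti]
    ctrl_mean <- rowMeans(expr[genes, ctrl_cols, drop = FALSE])
    for (ri in seq_along(reps)) {
      col <- design$condition == treatment & design$time_h == times[ti] &
        design$replicate == reps[ri]
      if (sum(col) != 1) stop("expected exactly one sample per cell")
      out[, ti, ri] <- expr[genes, col] - ctrl_mean
    }
  }
  out
}

#' Desk-scale end-to-end conserved-network pipeline on synthetic data
#'
#' Runs, per species: preprocessing, moderated differential expression,
#' trajectory construction for `treatment`, DPGP clustering with tightness
#' filtering, and sliding-window random-forest network inference on the
#' per-replicate fold-change series of the most responsive genes. Across
#' species: HOG projection of tight DPGP clusters, conserved-cluster
#' identification, HOG-level edge intersection and the DPGP conservation
#' filter, with stage counts recorded for monotonicity checks.
#'
#' @param config a [sim_config()] (keep genes_per_species modest).
#' @param treatment treatment analyzed (default "heat").
#' @param n_grn_genes genes entering network inference per species.
#' @param swing a [swing_params()].
#' @param dpgp_iter,dpgp_burn DPGP sweeps (scaled down by default).
#' @return list with per-species results and the conserved-network stages,
#'   including `stage_counts` (theoretical, nonzero_support, top_fraction,
#'   conserved, dpgp_filtered).
#' @export
run_conserved_pipeline <- function(config, treatment = "heat",
                                   n_grn_genes = 30,
                                   swing = swing_params(window_w = 4,
                                                        n_trees = 100),
                                   dpgp_iter = 100, dpgp_burn = 50) {
  ds <- simulate_dataset(config)
  species <- names(ds$counts)
  per_species <- list()
  edge_lists <- list()
  tight_genes <- list()
  projections <- list()
  min_nonzero <- Inf
  min_top <- Inf
  for (sp in species) {
    des <- ds$design[ds$design$species == sp, ]
    prep <- preprocess_counts(ds$counts[[sp]], des)
    contrasts <- build_contrasts(des, on_missing = "drop")
    de <- de_table(prep$expr, des, contrasts)
    traj <- build_trajectories(de, treatment)
    dp <- dpgp_cluster(traj, n_iter = dpgp_iter, burn_in = dpgp_burn,
                       seed = config$seed + match(sp, species))
    # most responsive genes enter the network inference
    resp <- sort(apply(abs(traj), 1, max), decreasing = TRUE)
    grn_genes <- names(resp)[seq_len(min(n_grn_genes, length(resp)))]
    series <- fold_change_series(prep$expr, des, treatment, grn_genes)
    sw <- swing_grn(series, swing)
    per_species[[sp]] <- list(de = de, trajectories = traj, dpgp = dp,
                              grn = sw)
    edge_lists[[sp]] <- sw$edges
    min_nonzero <- min(min_nonzero, sum(sw$ranked$support > 0))
    min_top <- min(min_top, nrow(sw$edges))
    tight <- dp$tight_sets
    tight_genes[[sp]] <- unlist(tight, use.names = FALSE)
    projections[[sp]] <- lapply(tight, project_to_hogs,
                                hog_table = ds$hog_table)
    names(projections[[sp]]) <- paste0(sp, "_", names(tight))
  }
  conserved_clusters <- conserved_cluster_sets(projections)
  # genes inside conserved tight clusters, per species
  conserved_tight <- lapply(species, function(sp) {
    keep <- conserved_clusters[[sp]]
    unname(unlist(lapply(keep, function(cl) {
      raw <- sub(paste0("^", sp, "_"), "", cl)
      per_species[[sp]]$dpgp$tight_sets[[raw]]
    })))
  })
  names(conserved_tight) <- species
  net <- conserved_network(edge_lists, ds$hog_table, conserved_tight)
  stage_counts <- c(
    theoretical = theoretical_edge_count(n_grn_genes),
    nonzero_support = min_nonzero,
    top_fraction = min_top,
    conserved = nrow(net$conserved),
    dpgp_filtered = nrow(net$filtered))
  list(dataset = ds, per_species = per_species,
       projections = projections, conserved_clusters = conserved_clusters,
       network = net, stage_counts = stage_counts)
}
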