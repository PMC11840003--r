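#' Map gene-level edges to unique HOG-level pairs
#'
#' Edge (g1 -> g2) becomes (HOG(g1) -> HOG(g2)); edges with an unmapped
#' endpoint are dropped (and counted), duplicate HOG pairs are collapsed,
#' and pairs whose endpoints collapse onto one HOG (self-loops) are
#' removed. Nodes that are not genes (e.g. metabolites) map to themselves.
#'
#' @param edges data frame with columns source, target.
#' @param hog_table data frame (gene_id, species, hog_id).
#' @param keep_unmapped_as_self treat nodes absent from the table as their
#'   own cross-species identifiers (default TRUE: metabolite channels are
#'   shared by name); set FALSE to drop them.
#' @return data frame source, target of unique directed HOG pairs;
#'   attributes `n_dropped` (edges lost to unmapped endpoints) and
#'   `n_self` (collapsed self-loops).
#' @export
edges_to_hog_pairs <- function(edges, hog_table, keep_unmapped_as_self = TRUE) {
  map <- function(x) {
    h <- hog_table$hog_id[match(x, hog_table$gene_id)]
    unknown <- is.na(h)
    h[unknown] <- if (keep_unmapped_as_self) x[unknown] else ""
    h[h == ""] <- NA
    h
  }
  src <- map(edges$source)
  tgt <- map(edges$target)
  ok <- !is.na(src) & !is.na(tgt)
  n_dropped <- sum(!ok)
  src <- src[ok]; tgt <- tgt[ok]
  self <- src == tgt
  n_self <- sum(self)
  pairs <- unique(data.frame(source = src[!self], target = tgt[!self],
                             stringsAsFactors = FALSE))
  pairs <- pairs[.lex_order(pairs$source, pairs$target), , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "n_dropped") <- n_dropped
  attr(pairs, "n_self") <- n_self
  pairs
}

# internal: canonical directed-pair keys
.pair_key <- function(pairs) paste(pairs$source, pairs$target, sep = "\r")

#' Intersect directed HOG-pair sets across species
#'
#' A pair is conserved iff it occurs, with matching direction, in every
#' species' set. Commutative and associative in the species order.
#'
#' @param pair_sets list (>= 2) of data frames with columns source, target.
#' @return data frame of conserved directed pairs, lexicographically
#'   ordered.
#' @export
intersect_conserved <- function(pair_sets) {
  stopifnot(length(pair_sets) >= 2)
  keys <- Reduce(intersect, lapply(pair_sets, .pair_key))
  if (length(keys) == 0)
    return(data.frame(source = character(0), target = character(0)))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(source = vapply(parts, `[`, character(1), 1),
                    target = vapply(parts, `[`, character(1), 2),
                    stringsAsFactors = FALSE)
  out <- out[.lex_order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter a conserved network by conserved tight DPGP membership
#'
#' A HOG pair is kept iff both endpoint HOGs contain, in every species, a
#' tight (posterior tightness >= 0.7) member of a cross-species conserved
#' DPGP cluster. Endpoints absent from the HOG table (metabolites) qualify
#' when listed in `extra_nodes`.
#'
#' @param pairs data frame source, target (HOG-level, conserved).
#' @param tight_conserved_genes named list species -> character vector of
#'   genes in conserved tight DPGP clusters.
#' @param hog_table data frame (gene_id, species, hog_id).
#' @param extra_nodes node ids (e.g. metabolites) that always qualify.
#' @return filtered pair data frame.
#' @export
dpgp_conservation_filter <- function(pairs, tight_conserved_genes, hog_table,
                                     extra_nodes = character(0)) {
  species <- names(tight_conserved_genes)
  qualified_hogs <- Reduce(intersect, lapply(species, function(sp) {
    genes <- tight_conserved_genes[[sp]]
    sub <- hog_table[hog_table$species == sp &
                       hog_table$gene_id %in% genes &
                       hog_table$hog_id != "", , drop = FALSE]
    unique(sub$hog_id)
  }))
  ok_node <- function(x) x %in% qualified_hogs | x %in% extra_nodes
  keep <- ok_node(pairs$source) & ok_node(pairs$target)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degree and HITS hub/authority metrics of a directed network
#'
#' Degrees by direct count; hub/authority scores by HITS power iteration
#' (L2-normalized, tolerance 1e-8, at most 1000 iterations). Authorities
#' are nodes receiving edges from good hubs and vice versa.
#'
#' @param edges data frame source, target.
#' @param tol convergence tolerance.
#' @param max_iter iteration cap.
#' @return data frame node, in_degree, out_degree, degree, authority, hub.
#' @export
node_metrics <- function(edges, tol = 1e-8, max_iter = 1000) {
  nodes <- sort(unique(c(edges$source, edges$target)))
  n <- length(nodes)
  if (n == 0 || nrow(edges) == 0) {
    return(data.frame(node = nodes, in_degree = integer(0),
                      out_degree = integer(0), degree = integer(0),
                      authority = numeric(0), hub = numeric(0)))
  }
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  A[cbind(match(edges$source, nodes), match(edges$target, nodes))] <- 1
  indeg <- colSums(A)
  outdeg <- rowSums(A)
  a <- rep(1 / sqrt(n), n)
  h <- a
  for (i in seq_len(max_iter)) {
    a_new <- as.numeric(crossprod(A, h))
    if (sum(a_new^2) > 0) a_new <- a_new / sqrt(sum(a_new^2))
    h_new <- as.numeric(A %*% a_new)
    if (sum(h_new^2) > 0) h_new <- h_new / sqrt(sum(h_new^2))
    if (max(abs(a_new - a)) < tol && max(abs(h_new - h)) < tol) {
      a <- a_new; h <- h_new
      break
    }
    a <- a_new; h <- h_new
  }
  data.frame(node = nodes, in_degree = as.integer(indeg),
             out_degree = as.integer(outdeg),
             degree = as.integer(indeg + outdeg),
             authority = a, hub = h, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Scale-free behavior check of a degree sequence
#'
#' Applies the binned log-log regression of [scale_free_fit()] to the
#' total degree of the network.
#'
#' @param degree vector of node degrees (>= 10 positive values).
#' @param n_bins histogram bins.
#' @return signed R^2.
#' @export
powerlaw_check <- function(degree, n_bins = 10) {
  degree <- degree[degree >= 1]
  if (length(degree) < 10) stop("need >= 10 nodes with degree >= 1")
  scale_free_fit(degree, n_bins)
}

#' Rank stability of hub nodes across network variants
#'
#' Ranks nodes by total connectivity (in + out degree) in each variant and
#' reports, for the top-`k` nodes of the reference variant, their rank in
#' every variant, plus Spearman correlations between the reference ranks
#' and each variant restricted to those nodes.
#'
#' @param variants named list of edge data frames (source, target).
#' @param reference name (or index) of the reference variant.
#' @param k number of top reference nodes tracked (default 50).
#' @return list with `ranks` (data frame node + one rank column per
#'   variant) and `spearman` (named vector vs the reference).
#' @export
rank_stability <- function(variants, reference = 1, k = 50) {
  stopifnot(length(variants) >= 2)
  metr <- lapply(variants, node_metrics)
  rank_of <- function(m) {
    r <- rank(-m$degree, ties.method = "average")
    setNames(r, m$node)
  }
  ranks <- lapply(metr, rank_of)
  ref <- ranks[[reference]]
  shared <- Reduce(intersect, lapply(ranks, names))
  if (length(shared) < 2) stop("fewer than 2 nodes shared across variants")
  top <- names(sort(ref[shared]))[seq_len(min(k, length(shared)))]
  tab <- data.frame(node = top, stringsAsFactors = FALSE)
  for (nm in names(ranks))
    tab[[nm]] <- unname(ranks[[nm]][top])
  rho <- vapply(names(ranks), function(nm)
    suppressWarnings(cor(tab[[if (is.numeric(reference))
      names(ranks)[reference] else reference]], tab[[nm]],
      method = "spearman")), numeric(1))
  list(ranks = tab, spearman = rho)
}

#' Stage-count report with printed-precision percentages
#'
#' Percentages are computed as 100 x count / reference and rounded to
#' `sig_digits` significant digits so that printed-arithmetic claims can
#' be compared byte-for-byte. Theoretical maxima come from n (n - 1).
#'
#' @param counts named numeric vector of stage counts (>= 0).
#' @param reference denominator (> 0), e.g. the theoretical maximum.
#' @param sig_digits significant digits for the percentage (default 7).
#' @return data frame stage, count, reference, percent.
#' @export
report_counts <- function(counts, reference, sig_digits = 7) {
  if (reference <= 0) stop("reference must be positive")
  stopifnot(all(counts >= 0))
  data.frame(stage = if (is.null(names(counts)))
    sprintf("stage%d", seq_along(counts)) else names(counts),
    count = as.numeric(counts), reference = as.numeric(reference),
    percent = signif(100 * as.numeric(counts) / reference, sig_digits),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the conserved HOG-level network across species
#'
#' Maps each species' finalized edges to HOG pairs, intersects the
#' directed pair sets, optionally applies the DPGP conservation filter,
#' and computes node metrics.
#'
#' @param edge_lists named list species -> finalized edge data frame.
#' @param hog_table data frame (gene_id, species, hog_id).
#' @param tight_conserved_genes optional named list for
#'   [dpgp_conservation_filter()].
#' @param extra_nodes nodes (metabolites) exempt from the DPGP filter.
#' @return list with `pairs_per_species`, `conserved`, `filtered` (NULL if
#'   no filter), `metrics` (on the final network), and `counts`
#'   (monotone stage counts).
#' @export
conserved_network <- function(edge_lists, hog_table,
                              tight_conserved_genes = NULL,
                              extra_nodes = character(0)) {
  pairs <- lapply(edge_lists, edges_to_hog_pairs, hog_table = hog_table)
  conserved <- intersect_conserved(pairs)
  filtered <- NULL
  final <- conserved
  if (!is.null(tight_conserved_genes)) {
    filtered <- dpgp_conservation_filter(conserved, tight_conserved_genes,
                                         hog_table, extra_nodes)
    final <- filtered
  }
  metrics <- if (nrow(final) > 0) node_metrics(final) else NULL
  counts <- c(per_species_min = min(vapply(pairs, nrow, integer(1))),
              conserved = nrow(conserved),
              filtered = if (is.null(filtered)) nrow(conserved) else
                nrow(filtered))
  list(pairs_per_species = pairs, conserved = conserved,
       filtered = filtered, metrics = metrics, counts = counts)
}
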