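#' Project a gene cluster to hierarchical-orthogroup (HOG) space
#'
#' @param genes character vector of member gene ids.
#' @param hog_table data frame (gene_id, species, hog_id); empty hog_id
#'   marks genes without orthology.
#' @return character vector of distinct HOG ids; the number of genes
#'   dropped for lack of a HOG is attached as attribute `n_dropped`.
#' @export
project_to_hogs <- function(genes, hog_table) {
  hits <- hog_table$hog_id[match(genes, hog_table$gene_id)]
  hits[is.na(hits)] <- ""
  dropped <- sum(hits == "")
  out <- sort(unique(hits[hits != ""]))
  attr(out, "n_dropped") <- dropped
  out
}

#' Jaccard distance between two sets
#'
#' 1 - |A intersect B| / |A union B|; two empty sets have distance 1 (with
#' a message), so that vacuous clusters never look similar.
#'
#' @param a,b vectors treated as sets.
#' @return distance in \[0, 1\].
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) {
    message("Jaccard distance of two empty sets defined as 1")
    return(1)
  }
  1 - length(intersect(a, b)) / u
}

#' All-pairs Jaccard distance matrix over cluster projections
#'
#' @param projections named list: cluster id -> HOG id set (cluster ids
#'   should carry a species prefix so they are unique across species).
#' @param top_k number of most-similar distinct pairs to report.
#' @param cap display cap for the distance (default 0.9, matching the
#'   heatmap convention); the returned matrix itself is uncapped.
#' @return list with `distance` (symmetric matrix), `display` (capped
#'   copy), and `top_pairs` (data frame cluster_a, cluster_b, distance,
#'   sorted ascending, lexicographic tie-break).
#' @export
similarity_matrix <- function(projections, top_k = 50, cap = 0.9) {
  stopifnot(length(projections) >= 2)
  ids <- names(projections)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- suppressMessages(
        jaccard_distance(projections[[i]], projections[[j]]))
    }
  }
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  tp <- data.frame(cluster_a = ids[pairs[, 1]], cluster_b = ids[pairs[, 2]],
                   distance = d[pairs], stringsAsFactors = FALSE)
  tp <- tp[order(tp$distance, tp$cluster_a, tp$cluster_b), , drop = FALSE]
  tp <- head(tp, top_k)
  rownames(tp) <- NULL
  disp <- pmin(d, cap)
  list(distance = d, display = disp, top_pairs = tp)
}

#' Identify cross-species conserved clusters
#'
#' Default mode "mutual": a cluster is conserved iff, for every other
#' species, its nearest cluster (smallest Jaccard distance on HOGs) has the
#' cluster among its own nearest matches in the original species (a
#' mutual-nearest cross-species tuple). Mode "threshold": conserved iff its
#' distance to some cluster of every other species is <= `theta`.
#'
#' @param projections named list of lists: species -> (cluster id -> HOG
#'   set).
#' @param mode "mutual" (default) or "threshold".
#' @param theta distance threshold for mode "threshold" (default 0.9).
#' @return named list species -> character vector of conserved cluster ids.
#' @export
conserved_cluster_sets <- function(projections, mode = c("mutual", "threshold"),
                                   theta = 0.9) {
  mode <- match.arg(mode)
  species <- names(projections)
  stopifnot(length(species) >= 2)
  jd <- function(a, b) suppressMessages(jaccard_distance(a, b))
  nearest <- function(sp_from, cl, sp_to) {
    # nearest cluster(s) of sp_to to cluster cl of sp_from (ties kept)
    ds <- vapply(projections[[sp_to]], jd, numeric(1),
                 b = projections[[sp_from]][[cl]])
    names(ds)[ds == min(ds)]
  }
  out <- list()
  for (sp in species) {
    keep <- character(0)
    for (cl in names(projections[[sp]])) {
      ok <- TRUE
      for (other in setdiff(species, sp)) {
        if (length(projections[[other]]) == 0) { ok <- FALSE; break }
        if (mode == "threshold") {
          ds <- vapply(projections[[other]], jd, numeric(1),
                       b = projections[[sp]][[cl]])
          if (min(ds) > theta) { ok <- FALSE; break }
        } else {
          best <- nearest(sp, cl, other)
          mutual <- any(vapply(best, function(b)
            cl %in% nearest(other, b, sp), logical(1)))
          # a match against an empty projection is meaningless
          if (!mutual ||
              min(vapply(projections[[other]], jd, numeric(1),
                         b = projections[[sp]][[cl]])) >= 1) {
            ok <- FALSE; break
          }
        }
      }
      if (ok) keep <- c(keep, cl)
    }
    out[[sp]] <- keep
  }
  out
}
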