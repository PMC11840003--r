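hog_tab3 <- data.frame(
  gene_id = c("a1", "a2", "a3", "b1", "b2", "b3", "c1", "c2", "c3"),
  species = rep(c("spA", "spB", "spC"), each = 3),
  hog_id = rep(c("h1", "h2", "h3"), 3))

test_that("gene edges map to unique directed HOG pairs", {
  edges <- data.frame(source = c("a1", "a1", "a2", "a3", "zz"),
                      target = c("a2", "a2", "a1", "a3x", "a1"))
  pairs <- edges_to_hog_pairs(edges, hog_tab3, keep_unmapped_as_self = FALSE)
  expect_equal(pairs, data.frame(source = c("h1", "h2"),
                                 target = c("h2", "h1")),
               ignore_attr = TRUE)
  expect_equal(attr(pairs, "n_dropped"), 2)   # a3x and zz unmapped

  # duplicate gene edges collapse; metabolites map to themselves
  edges_m <- data.frame(source = c("a1", "met01"), target = c("met01", "a2"))
  pm <- edges_to_hog_pairs(edges_m, hog_tab3)
  expect_true(all(c("met01") %in% c(pm$source, pm$target)))

  # same-HOG endpoints collapse to dropped self-loops
  e_self <- data.frame(source = "a1", target = "a1")
  ps <- edges_to_hog_pairs(e_self, hog_tab3)
  expect_equal(nrow(ps), 0)
  expect_equal(attr(ps, "n_self"), 1)
})

test_that("conserved intersection is direction-aware and commutative", {
  s1 <- data.frame(source = c("h1", "h2", "h3"), target = c("h2", "h1", "h1"))
  s2 <- data.frame(source = c("h1", "h3"), target = c("h2", "h1"))
  s3 <- data.frame(source = c("h1", "h2"), target = c("h2", "h1"))
  out <- intersect_conserved(list(s1, s2, s3))
  expect_equal(out, data.frame(source = "h1", target = "h2"),
               ignore_attr = TRUE)   # h2->h1 missing in s2, h3->h1 in s3

  perm <- intersect_conserved(list(s3, s1, s2))
  expect_equal(out, perm)

  expect_equal(nrow(intersect_conserved(list(
    s1, data.frame(source = "x", target = "y")))), 0)
})

test_that("DPGP conservation filter keeps doubly-qualified pairs only", {
  pairs <- data.frame(source = c("h1", "h1", "h2", "h3"),
                      target = c("h2", "h3", "h3", "h2"))
  tight <- list(spA = c("a1", "a2"), spB = c("b1", "b2"), spC = c("c1", "c2"))
  out <- dpgp_conservation_filter(pairs, tight, hog_tab3)
  # h3 qualifies nowhere (a3/b3/c3 never tight)
  expect_equal(out, data.frame(source = "h1", target = "h2"),
               ignore_attr = TRUE)

  # an endpoint missing in one species disqualifies
  tight2 <- list(spA = c("a1", "a2"), spB = "b1", spC = c("c1", "c2"))
  out2 <- dpgp_conservation_filter(pairs, tight2, hog_tab3)
  expect_equal(out2, data.frame(source = character(0), target = character(0)),
               ignore_attr = TRUE)

  # metabolites pass through the extra-node whitelist
  pairs_m <- data.frame(source = "h1", target = "met01")
  expect_equal(nrow(dpgp_conservation_filter(pairs_m, tight, hog_tab3,
                                             extra_nodes = "met01")), 1)
  expect_equal(nrow(dpgp_conservation_filter(pairs_m, tight, hog_tab3)), 0)
})

test_that("HITS authority/hub scores match fixed points and an eigen oracle", {
  # star with all edges into one node
  star <- data.frame(source = c("a", "b", "c"), target = "z")
  m <- node_metrics(star)
  expect_equal(m$authority[m$node == "z"], 1, tolerance = 1e-8)
  expect_equal(sum(m$authority[m$node != "z"]), 0, tolerance = 1e-8)
  expect_equal(m$in_degree[m$node == "z"], 3L)

  # 2-cycle: symmetric scores
  cyc <- data.frame(source = c("a", "b"), target = c("b", "a"))
  mc <- node_metrics(cyc)
  expect_equal(mc$authority[1], mc$authority[2], tolerance = 1e-8)
  expect_equal(mc$hub, mc$authority, tolerance = 1e-8)

  # 4-node toy digraph vs dense eigen-decomposition oracle
  toy <- data.frame(source = c("a", "a", "b", "c", "d"),
                    target = c("b", "c", "c", "d", "b"))
  mt <- node_metrics(toy)
  nodes <- sort(unique(c(toy$source, toy$target)))
  A <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  A[cbind(toy$source, toy$target)] <- 1
  ev_a <- eigen(t(A) %*% A, symmetric = TRUE)$vectors[, 1]
  ev_a <- abs(ev_a) / sqrt(sum(ev_a^2))
  expect_equal(mt$authority, unname(ev_a), tolerance = 1e-6)
  ev_h <- eigen(A %*% t(A), symmetric = TRUE)$vectors[, 1]
  expect_equal(mt$hub, abs(ev_h) / sqrt(sum(ev_h^2)), tolerance = 1e-6)

  # relabeling invariance
  relab <- data.frame(source = c("n1", "n1", "n2", "n3", "n4"),
                      target = c("n2", "n3", "n3", "n4", "n2"))
  expect_equal(node_metrics(relab)$authority, mt$authority, tolerance = 1e-8)
})

test_that("power-law check flags scale-free-like degree sequences", {
  k <- rep(1:10, times = round(1000 / (1:10)^2))   # p(k) ~ k^-2
  expect_gt(powerlaw_check(k), 0.95)
  expect_error(powerlaw_check(rep(3, 50)), "constant")
  expect_error(powerlaw_check(c(5, 1, 1, 1)), ">= 10")
})

test_that("rank stability reports Spearman agreement across variants", {
  # total degrees: a = 3, b = 2, c = 2, d = 1
  net <- data.frame(source = c("a", "a", "a", "b"),
                    target = c("b", "c", "d", "c"))
  rs <- rank_stability(list(v1 = net, v2 = net), reference = "v1", k = 4)
  expect_equal(unname(rs$spearman["v2"]), 1)

  # reversing edge direction leaves total degree, hence the ranks, intact
  rev_net <- data.frame(source = net$target, target = net$source)
  rs2 <- rank_stability(list(v1 = net, v2 = rev_net), k = 4)
  expect_equal(unname(rs2$spearman["v2"]), 1)

  # a variant concentrating degree on the former last-rank node drops rho
  alt <- data.frame(source = c("d", "d", "d", "c"),
                    target = c("a", "b", "c", "a"))
  rs3 <- rank_stability(list(v1 = net, v2 = alt), k = 4)
  # hand Spearman: v1 ranks (a,b,c,d) = (1, 2.5, 2.5, 4),
  #                v2 ranks (a,b,c,d) = (2.5, 4, 2.5, 1)
  expect_equal(unname(rs3$spearman["v2"]),
               cor(c(1, 2.5, 2.5, 4), c(2.5, 4, 2.5, 1)))
  expect_lt(unname(rs3$spearman["v2"]), 1)

  expect_error(rank_stability(list(
    v1 = net, v2 = data.frame(source = "x", target = "y"))), "shared")
})

test_that("count reports reproduce printed-precision percentages", {
  rep1 <- report_counts(c(nonzero = 383984), theoretical_edge_count(5552))
  expect_equal(rep1$percent, 1.245927)
  rep2 <- report_counts(c(final = 923), theoretical_edge_count(923))
  expect_equal(rep2$percent, 0.1084599)
  expect_equal(report_counts(c(x = 0), 100)$percent, 0)
  expect_error(report_counts(c(x = 1), 0), "positive")
})
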