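test_that("prevalence filter applies the >= min_samples rule", {
  set.seed(1)
  counts <- matrix(1L, 30, 27,
                   dimnames = list(sprintf("o%02d", 1:30),
                                   sprintf("s%02d", 1:27)))
  counts[1, sample(27, 7)] <- 0L   # present in 20 of 27
  counts[2, sample(27, 6)] <- 0L   # present in 21 of 27
  tb <- otu_table(counts)
  kept <- prevalence_filter(tb, 21)
  expect_false("o01" %in% otu_ids(kept))
  expect_true("o02" %in% otu_ids(kept))
  expect_identical(otu_ids(prevalence_filter(tb, 1)), otu_ids(tb))
  few <- otu_table(counts[1:3, ])
  expect_error(prevalence_filter(few, 27), "meaningless")
})

test_that("the prevalence cut is the smallest integer above 75%", {
  expect_identical(prevalence_cut(27), 21L)
  expect_identical(prevalence_cut(28), 22L)
  expect_identical(prevalence_cut(24), 19L)
})

test_that("spearman matrix matches rank-based brute force, ties included", {
  x <- c(1, 2, 2, 4); y <- c(3, 1, 1, 2)
  counts <- rbind(o1 = x, o2 = y, o3 = c(5, 1, 7, 2))
  colnames(counts) <- paste0("s", 1:4)
  cm <- spearman_matrix(otu_table(counts))
  expect_equal(cm$r["o1", "o2"], oracle_spearman(x, y), tolerance = 1e-12)
  expect_equal(diag(cm$r), stats::setNames(rep(1, 3), rownames(counts)))
  expect_equal(cm$r, t(cm$r))
  # strictly co-monotone pair
  counts2 <- rbind(o1 = c(1, 5, 9, 20), o2 = c(2, 40, 60, 61),
                   o3 = c(4, 2, 8, 1))
  colnames(counts2) <- paste0("s", 1:4)
  cm2 <- spearman_matrix(otu_table(counts2))
  expect_equal(cm2$r["o1", "o2"], 1)
  expect_equal(cm2$p["o1", "o2"], 0)
})

test_that("constant OTUs are recorded as r = 0, p = 1 with a warning", {
  counts <- rbind(o1 = c(3L, 3L, 3L, 3L, 3L), o2 = c(1L, 2L, 3L, 4L, 5L),
                  o3 = c(5L, 4L, 3L, 2L, 1L))
  colnames(counts) <- paste0("s", 1:5)
  expect_warning(cm <- spearman_matrix(otu_table(counts)), "constant")
  expect_equal(cm$r["o1", "o2"], 0)
  expect_equal(cm$p["o1", "o2"], 1)
})

test_that("edge rule: |r| >= r_min inclusive, p < p_max strict, signs kept", {
  ids <- c("a", "b", "c", "d")
  r <- diag(4); dimnames(r) <- list(ids, ids)
  p <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(p) <- 0
  r["a", "b"] <- r["b", "a"] <- 0.820; p["a", "b"] <- p["b", "a"] <- 1e-4
  r["a", "c"] <- r["c", "a"] <- 0.90;  p["a", "c"] <- p["c", "a"] <- 0.01
  r["b", "d"] <- r["d", "b"] <- -0.85; p["b", "d"] <- p["d", "b"] <- 1e-5
  cm <- structure(list(otu_ids = ids, r = r, p = p, n_samples = 27),
                  class = "cor_matrix_pair")
  net <- build_network(cm)
  edges <- igraph::as_data_frame(net)
  expect_identical(nrow(edges), 2L)
  expect_true(any(edges$from == "a" & edges$to == "b"))   # boundary r kept
  expect_false(any(edges$from == "a" & edges$to == "c"))  # p fails
  neg <- edges[edges$sign == "-", ]
  expect_identical(nrow(neg), 1L)
  expect_equal(neg$weight, 0.85)
  expect_false("c" %in% igraph::V(net)$name)              # isolated dropped

  p["a", "b"] <- p["b", "a"] <- 0.5; p["b", "d"] <- p["d", "b"] <- 0.5
  cm$p <- p
  expect_error(build_network(cm), "no edges")
})

test_that("network construction is invariant to OTU row order", {
  cm <- planted_cor_pair(2, n_blocks = 2, block_size = 10)
  net1 <- build_network(cm, r_min = 0.8, p_max = 0.01)
  set.seed(10)
  perm <- sample(length(cm$otu_ids))
  cm2 <- structure(list(otu_ids = cm$otu_ids[perm],
                        r = cm$r[perm, perm], p = cm$p[perm, perm],
                        n_samples = cm$n_samples),
                   class = "cor_matrix_pair")
  net2 <- build_network(cm2, r_min = 0.8, p_max = 0.01)
  e1 <- igraph::as_data_frame(net1)
  e2 <- igraph::as_data_frame(net2)
  key <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  expect_identical(key(e1), key(e2))
})

test_that("raising the threshold never adds edges", {
  cm <- planted_cor_pair(3, n_blocks = 3, block_size = 10, between_sd = 0.2)
  thresholds <- seq(0.3, 0.9, by = 0.1)
  counts <- vapply(thresholds, function(t) {
    tryCatch(igraph::ecount(build_network(cm, r_min = t, p_max = 0.05)),
             error = function(e) 0L)
  }, 0)
  expect_true(all(diff(counts) <= 0))
  expect_true(counts[1] > counts[length(counts)])
})

test_that("topology metrics match closed forms on toy graphs", {
  k4 <- as_coocnet(igraph::make_full_graph(4))
  tm <- topology_metrics(k4)
  expect_equal(tm$average_connectivity, 3)
  expect_equal(tm$average_path_distance, 1)
  expect_equal(tm$average_clustering_coefficient, 1)
  expect_equal(tm$pct_negative_edges, 0)

  path3 <- as_coocnet(igraph::make_graph(~ A - B - C))
  tp <- topology_metrics(path3)
  expect_equal(tp$average_connectivity, 4 / 3)
  expect_equal(tp$average_path_distance, 4 / 3)
  expect_equal(tp$average_clustering_coefficient, 0)

  two_k3 <- as_coocnet(igraph::disjoint_union(igraph::make_full_graph(3),
                                              igraph::make_full_graph(3)))
  expect_equal(topology_metrics(two_k3)$average_path_distance, 1)
})

test_that("scale-free fit is exact on power laws, NA when degenerate", {
  # frequencies proportional to k^-2 over k in {1, 2, 4, 8}
  degrees <- rep(c(1L, 2L, 4L, 8L), times = c(64L, 16L, 4L, 1L))
  expect_equal(scale_free_fit(degrees), 1)
  expect_true(is.na(scale_free_fit(rep(3L, 10))))
  # preferential attachment beats a comparable uniform random graph
  deltas <- vapply(1:10, function(s) {
    ba <- sample_scale_free_network(200, 2, seed = s)
    set.seed(s)
    er <- igraph::sample_gnm(200, igraph::ecount(ba))
    scale_free_fit(igraph::degree(ba)) - scale_free_fit(igraph::degree(er))
  }, 0)
  expect_gt(stats::median(deltas), 0)
})

test_that("module detection recovers planted structure and maximises Q", {
  two_cliques <- igraph::disjoint_union(igraph::make_full_graph(4),
                                        igraph::make_full_graph(4))
  two_cliques <- igraph::add_edges(two_cliques, c(1, 5))
  net <- as_coocnet(two_cliques)
  mods <- detect_modules(net)
  expect_identical(mods$n_modules, 2L)
  expect_identical(unname(mods$membership[1:4]),
                   rep(mods$membership[[1]], 4))
  # Q verified by direct evaluation of the definitional formula
  ends <- igraph::ends(net, igraph::E(net), names = FALSE)
  q_direct <- oracle_modularity(ends, rep(1, nrow(ends)),
                                unname(mods$membership))
  expect_equal(mods$q, q_direct, tolerance = 1e-12)
  expect_equal(mods$q, igraph::modularity(net, mods$membership),
               tolerance = 1e-12)
  # detected partition is at least as good as the trivial one
  expect_gte(mods$q, modularity_q(net, rep(1L, igraph::vcount(net))))

  clique <- as_coocnet(igraph::make_full_graph(4))
  m1 <- detect_modules(clique)
  expect_equal(m1$q, 0, tolerance = 1e-12)

  cm <- planted_cor_pair(5, n_blocks = 2, block_size = 12)
  pnet <- build_network(cm, r_min = 0.8, p_max = 0.01)
  pm <- detect_modules(pnet)
  truth <- rep(1:2, each = 12)
  names(truth) <- cm$otu_ids
  expect_gt(adjusted_rand_index(pm$membership[igraph::V(pnet)$name],
                                truth[igraph::V(pnet)$name]), 0.9)
})

test_that("adjusted Rand agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(4)
  for (i in 1:5) {
    a <- sample(3, 40, replace = TRUE)
    b <- ifelse(stats::runif(40) < 0.3, sample(3, 40, replace = TRUE), a)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})
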