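## Co-occurrence network construction: prevalence filtering, Spearman
## correlation with t-approximation p-values, thresholded graph building,
## topology metrics, scale-free fit, and greedy modularity modules.

#' Prevalence filter
#'
#' Keeps OTUs detected (count > 0) in at least `min_samples` samples —
#' correlations estimated from taxa seen in only a handful of samples are
#' unreliable, so networks are built from prevalent taxa only.
#'
#' @param table an [otu_table].
#' @param min_samples minimum number of samples with a nonzero count.
#' @return filtered [otu_table]; fewer than 3 surviving OTUs is an error.
#' @export
prevalence_filter <- function(table, min_samples) {
  n <- ncol(table$counts)
  if (min_samples < 1 || min_samples > n)
    stop("min_samples must be in [1, ", n, "]", call. = FALSE)
  keep <- rowSums(table$counts > 0) >= min_samples
  if (sum(keep) < 3)
    stop("fewer than 3 OTUs pass the prevalence filter (", sum(keep),
         "); a network would be meaningless", call. = FALSE)
  subset_table(table, otus = keep)
}

#' Prevalence cut-off for a group of n samples
#'
#' The smallest integer strictly greater than `fraction * n`; with the
#' default 75% rule, 27 samples give 21.
#'
#' @param n group sample count.
#' @param fraction prevalence fraction (default 0.75).
#' @export
prevalence_cut <- function(n, fraction = 0.75) as.integer(floor(fraction * n) + 1)

#' Pairwise Spearman correlations with p-values
#'
#' Spearman rank correlation (average ranks on ties) between every pair of
#' OTUs across samples, with two-sided p-values from the t approximation.
#' Correlation is computed on the counts as given; once samples are
#' rarefied to even depth this coincides with correlating per-sample
#' relative abundances, because a common per-sample divisor does not
#' change an OTU's ranking across samples. OTUs with zero variance get
#' r = 0, p = 1 against everything (with a warning).
#'
#' @param table an [otu_table] with >= 4 samples.
#' @return list of class `cor_matrix_pair`: `otu_ids`, `r`, `p`,
#'   `n_samples`.
#' @export
spearman_matrix <- function(table) {
  counts <- table$counts
  n <- ncol(counts)
  if (n < 4) stop("need >= 4 samples for correlation", call. = FALSE)
  ranks <- t(apply(counts, 1, rank))  # average ranks on ties
  constant <- apply(ranks, 1, stats::sd) == 0
  r <- suppressWarnings(stats::cor(t(ranks)))
  if (any(constant)) {
    warning(sum(constant), " constant OTU(s) assigned r = 0, p = 1: ",
            paste(utils::head(rownames(counts)[constant], 5), collapse = ", "))
    r[constant, ] <- 0
    r[, constant] <- 0
  }
  diag(r) <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  diag(p) <- 0
  p[constant, ] <- 1; p[, constant] <- 1; diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(rownames(counts), rownames(counts))
  structure(list(otu_ids = rownames(counts), r = r, p = p, n_samples = n),
            class = "cor_matrix_pair")
}

#' Build a co-occurrence network from a correlation matrix pair
#'
#' An undirected edge joins OTUs i and j when `|r_ij| >= r_min` (inclusive)
#' and `p_ij < p_max` (strict). Edge weight is `|r|`; the sign of r is kept
#' as an edge attribute so negative associations stay in the network.
#' Nodes left without any edge are dropped.
#'
#' @param cm a `cor_matrix_pair` from [spearman_matrix].
#' @param r_min correlation magnitude threshold, inclusive (default 0.820).
#' @param p_max p-value threshold, strict (default 0.001).
#' @param taxonomy optional named lineage vector attached to nodes.
#' @return an igraph graph of class `cooccur_network` with edge attributes
#'   `weight` (|r|), `r`, `sign` ("+"/"-") and graph attributes recording
#'   the thresholds and sample count.
#' @export
build_network <- function(cm, r_min = 0.820, p_max = 0.001, taxonomy = NULL) {
  stopifnot(inherits(cm, "cor_matrix_pair"))
  if (r_min <= 0 || r_min >= 1 || p_max <= 0 || p_max >= 1)
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  r <- cm$r; p <- cm$p
  sel <- which(upper.tri(r) & abs(r) >= r_min & p < p_max, arr.ind = TRUE)
  if (nrow(sel) == 0)
    stop("no edges satisfy |r| >= ", r_min, " and p < ", p_max,
         "; consider a threshold scan (rmt_threshold_scan) or relaxing ",
         "the cut-offs", call. = FALSE)
  ids <- cm$otu_ids
  edges <- data.frame(
    from = ids[sel[, 1]], to = ids[sel[, 2]],
    r = r[sel], weight = abs(r[sel]),
    sign = ifelse(r[sel] >= 0, "+", "-"),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::set_graph_attr(g, "r_threshold", r_min)
  g <- igraph::set_graph_attr(g, "p_threshold", p_max)
  g <- igraph::set_graph_attr(g, "n_samples", cm$n_samples)
  if (!is.null(taxonomy)) {
    igraph::V(g)$taxonomy <-
      unname(taxonomy[match(igraph::V(g)$name, names(taxonomy))])
  }
  class(g) <- c("cooccur_network", class(g))
  g
}

#' @export
print.cooccur_network <- function(x, ...) {
  cat("Co-occurrence network:", igraph::vcount(x), "nodes,",
      igraph::ecount(x), "edges\n")
  cat("  thresholds: |r| >=", igraph::graph_attr(x, "r_threshold"),
      ", p <", igraph::graph_attr(x, "p_threshold"),
      "(", igraph::graph_attr(x, "n_samples"), "samples )\n")
  neg <- mean(igraph::E(x)$sign == "-") * 100
  cat("  negative edges:", fmt_num(neg, 3), "%\n")
  invisible(x)
}

#' Greedy modularity module detection
#'
#' Fast-greedy agglomerative modularity maximisation on the unsigned
#' weighted graph (weights = |r|). The algorithm is deterministic; the
#' seed argument exists for interface symmetry with the stochastic stages
#' and is recorded, not consumed.
#'
#' @param net a `cooccur_network` (or any undirected igraph).
#' @param seed recorded seed (unused by the deterministic algorithm).
#' @return list: `membership` (named integer vector), `q` (modularity of
#'   the partition), `n_modules`.
#' @export
detect_modules <- function(net, seed = 1L) {
  comm <- igraph::cluster_fast_greedy(
    net, weights = igraph::E(net)$weight %||% rep(1, igraph::ecount(net)))
  membership <- igraph::membership(comm)
  q <- modularity_q(net, membership)
  # the greedy cut can land below the trivial partition on tiny graphs
  trivial <- stats::setNames(rep(1L, igraph::vcount(net)),
                             igraph::V(net)$name)
  q_trivial <- modularity_q(net, trivial)
  if (q_trivial > q + 1e-12) {
    membership <- trivial
    q <- q_trivial
  }
  list(membership = membership, q = q,
       n_modules = as.integer(max(membership)), seed = seed)
}

#' Modularity Q of a partition
#'
#' \eqn{Q = \sum_m (e_m / E - (d_m / 2E)^2)} with edge weights: e_m is the
#' within-module weight, E the total weight, d_m the module's weighted
#' degree sum.
#'
#' @param net undirected igraph.
#' @param membership module id per node (named or in vertex order).
#' @export
modularity_q <- function(net, membership) {
  w <- igraph::E(net)$weight %||% rep(1, igraph::ecount(net))
  ends <- igraph::ends(net, igraph::E(net), names = FALSE)
  if (!is.null(names(membership)))
    membership <- membership[igraph::V(net)$name]
  m <- as.integer(membership)
  total <- sum(w)
  within <- tapply(w[m[ends[, 1]] == m[ends[, 2]]],
                   m[ends[, 1]][m[ends[, 1]] == m[ends[, 2]]], sum)
  strength <- tapply(rep(w, 2), c(m[ends[, 1]], m[ends[, 2]]), sum)
  e_m <- rep(0, max(m)); e_m[as.integer(names(within))] <- within
  d_m <- rep(0, max(m)); d_m[as.integer(names(strength))] <- strength
  sum(e_m / total - (d_m / (2 * total))^2)
}

#' Goodness of a power-law degree distribution
#'
#' OLS of log10 P(k) on log10 k over the observed (unbinned) nonzero
#' degree frequencies; the returned R-squared is the conventional
#' scale-free index. Needs >= 3 distinct positive degrees, otherwise NA.
#'
#' @param degrees integer degree sequence.
#' @return R-squared in \[0, 1\], or NA if undefined.
#' @export
scale_free_fit <- function(degrees) {
  degrees <- degrees[degrees >= 1]
  tab <- table(degrees)
  if (length(tab) < 3) return(NA_real_)
  k <- as.numeric(names(tab))
  pk <- as.numeric(tab) / sum(tab)
  fit <- stats::lm(log10(pk) ~ log10(k))
  suppressWarnings(summary(fit)$r.squared)
}

#' Topology metrics of a co-occurrence network
#'
#' @param net a `cooccur_network`.
#' @param modules optional result of [detect_modules] (computed if absent).
#' @return list of class `topology_metrics`: `n_nodes`, `n_links`,
#'   `average_connectivity` (2L/N), `average_path_distance` (mean shortest
#'   path over the largest connected component, unweighted),
#'   `average_clustering_coefficient` (mean local clustering, nodes of
#'   degree < 2 contributing 0), `modularity` (Q of the detected
#'   partition), `n_modules`, `scale_free_r2`, `pct_negative_edges`.
#' @export
topology_metrics <- function(net, modules = NULL) {
  if (igraph::ecount(net) < 1) stop("network has no edges", call. = FALSE)
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  comp <- igraph::components(net)
  giant <- igraph::induced_subgraph(net, which(comp$membership ==
                                                 which.max(comp$csize)))
  apd <- igraph::mean_distance(giant, weights = NA)
  cc <- igraph::transitivity(net, type = "localundirected", isolates = "zero")
  cc[is.na(cc)] <- 0
  modules <- modules %||% detect_modules(net)
  sign <- igraph::E(net)$sign %||% rep("+", e)
  structure(list(
    n_nodes = n,
    n_links = e,
    average_connectivity = 2 * e / n,
    average_path_distance = apd,
    average_clustering_coefficient = mean(cc),
    modularity = modules$q,
    n_modules = modules$n_modules,
    scale_free_r2 = scale_free_fit(igraph::degree(net)),
    pct_negative_edges = 100 * mean(sign == "-")
  ), class = "topology_metrics")
}

#' @export
print.topology_metrics <- function(x, ...) {
  cat("Network topology\n")
  for (f in names(x))
    cat("  ", format(f, width = 30), fmt_num(x[[f]], 5), "\n")
  invisible(x)
}
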