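# Programmatic fixtures shared across test files.

random_table <- function(n_otus = 12, n_samples = 10, lambda = 20, seed = 1) {
  set.seed(seed)
  counts <- matrix(stats::rpois(n_otus * n_samples, lambda), nrow = n_otus,
                   dimnames = list(sprintf("o%02d", seq_len(n_otus)),
                                   sprintf("s%02d", seq_len(n_samples))))
  otu_table(counts)
}

# dress an igraph up as a cooccur_network (unit weights, "+" signs)
as_coocnet <- function(g, weights = NULL, signs = NULL) {
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  igraph::E(g)$weight <- weights %||% rep(1, igraph::ecount(g))
  igraph::E(g)$sign <- signs %||% rep("+", igraph::ecount(g))
  g <- igraph::set_graph_attr(g, "r_threshold", NA_real_)
  g <- igraph::set_graph_attr(g, "p_threshold", NA_real_)
  g <- igraph::set_graph_attr(g, "n_samples", NA_integer_)
  class(g) <- c("cooccur_network", class(g))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# directly planted block correlation matrix: within-block correlation
# `within` (jittered), between-block entries N(0, between_sd), clipped
planted_cor_pair <- function(seed, n_blocks = 4, block_size = 15,
                             within = 0.9, between_sd = 0.06,
                             n_samples = 27) {
  set.seed(seed)
  n <- n_blocks * block_size
  r <- matrix(stats::rnorm(n * n, 0, between_sd), n, n)
  r <- (r + t(r)) / 2
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1) * block_size + 1):(b * block_size)
    jit <- matrix(stats::rnorm(block_size^2, 0, 0.02), block_size)
    r[idx, idx] <- within + (jit + t(jit)) / 2
  }
  r <- pmin(pmax(r, -0.98), 0.98)
  diag(r) <- 1
  ids <- sprintf("o%03d", seq_len(n))
  dimnames(r) <- list(ids, ids)
  tstat <- r * sqrt((n_samples - 2) / pmax(1 - r^2, 1e-12))
  p <- 2 * stats::pt(-abs(tstat), df = n_samples - 2)
  diag(p) <- 0
  structure(list(otu_ids = ids, r = r, p = p, n_samples = n_samples),
            class = "cor_matrix_pair")
}

# metadata for a single-site single-treatment 27-sample design
simple_metadata <- function(ids, dates, plots) {
  sample_metadata(data.frame(
    sample_id = ids, site = "siteA", treatment = "control",
    time_point = dates, plot = plots, stringsAsFactors = FALSE))
}
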