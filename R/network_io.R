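#' Export a co-occurrence network
#'
#' GraphML (loadable by Gephi and other graph tools) or an undirected
#' edge-list CSV with each edge written once, endpoints in lexicographic
#' order. Nodes carry OTU id, taxonomy (when present), degree, and module
#' and role when supplied; edges carry weight = |r|, the signed r and the
#' sign.
#'
#' @param net a `cooccur_network` with >= 1 edge.
#' @param path output file.
#' @param format "graphml" or "edgelist".
#' @param membership optional module id per node (from [detect_modules]).
#' @param roles optional role table (from [classify_roles]).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist"),
                          membership = NULL, roles = NULL) {
  format <- match.arg(format)
  if (igraph::ecount(net) == 0)
    stop("network has no edges; relax the correlation/p thresholds",
         call. = FALSE)
  g <- net
  igraph::V(g)$degree <- igraph::degree(g)
  if (!is.null(membership)) {
    mm <- if (!is.null(names(membership))) membership[igraph::V(g)$name]
          else membership
    igraph::V(g)$module <- as.integer(mm)
  }
  if (!is.null(roles)) {
    idx <- match(igraph::V(g)$name, roles$otu_id)
    igraph::V(g)$role <- as.character(roles$role)[idx]
  }
  if (format == "graphml") {
    # graphml writers dislike NA attribute values
    for (a in igraph::vertex_attr_names(g)) {
      v <- igraph::vertex_attr(g, a)
      if (is.character(v)) igraph::vertex_attr(g, a) <- ifelse(is.na(v), "", v)
    }
    for (a in igraph::graph_attr_names(g)) {
      if (is.na(igraph::graph_attr(g, a))) g <- igraph::delete_graph_attr(g, a)
    }
    cls <- class(g); class(g) <- "igraph"
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ends <- igraph::ends(g, igraph::E(g))
    swap <- ends[, 1] > ends[, 2]
    df <- data.frame(
      from = ifelse(swap, ends[, 2], ends[, 1]),
      to = ifelse(swap, ends[, 1], ends[, 2]),
      weight = igraph::E(g)$weight,
      sign = igraph::E(g)$sign %||% rep("+", igraph::ecount(g)),
      r = igraph::E(g)$r %||% igraph::E(g)$weight,
      stringsAsFactors = FALSE
    )
    df <- df[order(df$from, df$to), , drop = FALSE]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a network back from GraphML
#'
#' @param path GraphML file written by [write_network].
#' @return a `cooccur_network`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  class(g) <- c("cooccur_network", class(g))
  g
}
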