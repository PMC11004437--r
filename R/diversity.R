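## Rarefaction, alpha diversity, and beta-diversity distance matrices.

#' Rarefy an OTU table to even depth
#'
#' Each sample is subsampled uniformly without replacement to exactly
#' `depth` reads. Samples whose library size is below `depth` are dropped
#' with a message; rarefying every sample away is an error. A sample whose
#' total equals `depth` is returned unchanged.
#'
#' @param table an [otu_table].
#' @param depth target reads per sample (> 0).
#' @param seed RNG seed for the subsampling.
#' @return a rarefied [otu_table] (possibly with fewer samples).
#' @export
rarefy_table <- function(table, depth, seed = 1L) {
  stopifnot(depth > 0)
  totals <- colSums(table$counts)
  keep <- totals >= depth
  if (!any(keep))
    stop("all samples have fewer than ", depth, " reads", call. = FALSE)
  if (any(!keep))
    message("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(names(totals)[!keep], collapse = ", "))
  counts <- table$counts[, keep, drop = FALSE]
  # rrarefy's "observed counts" advisory is redundant with our own checks
  rar <- with_seed(seed,
                   t(suppressWarnings(vegan::rrarefy(t(counts), depth))))
  storage.mode(rar) <- "integer"
  otu_table(rar, table$taxonomy)
}

#' Shannon diversity index (natural log)
#'
#' \eqn{H = -\sum p_i \ln p_i} over the positive proportions of a count
#' vector.
#'
#' @param counts numeric vector of non-negative counts with at least one
#'   positive entry.
#' @return Shannon index in nats.
#' @export
shannon <- function(counts) {
  if (all(counts == 0)) stop("all counts are zero", call. = FALSE)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Per-sample alpha diversity
#'
#' @param table an [otu_table].
#' @return data.frame with `sample_id`, observed `richness` and `shannon`
#'   (nats).
#' @export
alpha_diversity <- function(table) {
  counts <- table$counts
  data.frame(
    sample_id = colnames(counts),
    richness = as.integer(colSums(counts > 0)),
    shannon = apply(counts, 2, shannon),
    row.names = NULL
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = 1 - 2\sum_i \min(x_i, y_i) / (\sum x + \sum y)} between
#' every pair of samples.
#'
#' @param table an [otu_table] with >= 2 samples, none empty.
#' @return square symmetric matrix (samples x samples) in \[0, 1\].
#' @export
bray_curtis <- function(table) {
  counts <- table$counts
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  empty <- colSums(counts) == 0
  if (any(empty))
    stop("sample(s) with zero total: ",
         paste(colnames(counts)[empty], collapse = ", "), call. = FALSE)
  d <- as.matrix(vegan::vegdist(t(counts), method = "bray"))
  diag(d) <- 0
  d
}

#' Unweighted UniFrac distance matrix
#'
#' For each pair of samples, the fraction of tree branch length leading to
#' leaves present in exactly one of the two communities, out of the branch
#' length leading to leaves present in either. Presence means count >= 1.
#' Every OTU with a nonzero count must be a leaf of the tree; branches with
#' no observed leaf below them are ignored.
#'
#' @param table an [otu_table].
#' @param tree a rooted [ape::phylo] with branch lengths.
#' @return square symmetric matrix (samples x samples) in \[0, 1\].
#' @export
unweighted_unifrac <- function(table, tree) {
  tree <- validate_tree(tree)
  counts <- table$counts
  present_otus <- rownames(counts)[rowSums(counts) > 0]
  missing <- setdiff(present_otus, tree$tip.label)
  if (length(missing))
    stop("OTU(s) absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ntip <- length(tree$tip.label)
  # edge x leaf incidence: which leaves descend from each edge's child node
  desc <- edge_descendant_leaves(tree)
  inc <- matrix(FALSE, nrow(tree$edge), ntip)
  for (e in seq_len(nrow(tree$edge))) inc[e, desc[[e]]] <- TRUE
  # leaf presence per sample, in tree tip order
  pres <- matrix(0L, ntip, ncol(counts),
                 dimnames = list(tree$tip.label, colnames(counts)))
  hit <- intersect(tree$tip.label, rownames(counts))
  pres[hit, ] <- (counts[hit, , drop = FALSE] > 0) + 0L
  # branch length below which each sample has at least one leaf
  edge_has <- (inc %*% pres) > 0   # edges x samples
  len <- tree$edge.length
  n <- ncol(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- edge_has[, i]; b <- edge_has[, j]
    either <- sum(len[a | b])
    uniq <- sum(len[xor(a, b)])
    d[i, j] <- d[j, i] <- if (either == 0) 0 else uniq / either
  }
  d
}

# list: for each edge (row of tree$edge), the tip indices below it
edge_descendant_leaves <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  below <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  # postorder: children resolved before parents
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1L]; child <- edges[e, 2L]
    below[[parent]] <- c(below[[parent]], below[[child]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) below[[tree$edge[e, 2L]]])
}
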