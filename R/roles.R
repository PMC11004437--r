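## Zi-Pi node roles and keystone identification. Within-module degree
## z-score (Zi) and among-module connectivity / participation coefficient
## (Pi) jointly classify nodes; any non-peripheral node is a keystone.

#' Within- and among-module connectivity per node
#'
#' Zi is the z-score of a node's within-module degree relative to the
#' other nodes of its module; Pi = 1 - sum_s (k_is / k_i)^2 over modules
#' s. Degrees are unweighted edge counts. If every node of a module has
#' the same within-module degree (sd 0), Zi is 0 for those nodes.
#'
#' @param net a `cooccur_network`.
#' @param membership module id per node (named vector, e.g. from
#'   [detect_modules]).
#' @return data.frame: `otu_id`, `module`, `degree`, `zi`, `pi`.
#' @export
zipi <- function(net, membership) {
  nodes <- igraph::V(net)$name
  if (!is.null(names(membership))) {
    miss <- setdiff(nodes, names(membership))
    if (length(miss))
      stop("nodes without module assignment: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    membership <- membership[nodes]
  }
  m <- as.integer(membership)
  deg <- igraph::degree(net)
  if (any(deg == 0))
    stop("network contains degree-0 nodes; rebuild it first", call. = FALSE)
  ends <- igraph::ends(net, igraph::E(net), names = FALSE)
  nmod <- max(m)
  # k_is: links from node i into module s
  k_is <- matrix(0L, length(nodes), nmod)
  for (e in seq_len(nrow(ends))) {
    a <- ends[e, 1L]; b <- ends[e, 2L]
    k_is[a, m[b]] <- k_is[a, m[b]] + 1L
    k_is[b, m[a]] <- k_is[b, m[a]] + 1L
  }
  k_own <- k_is[cbind(seq_along(m), m)]
  zi <- numeric(length(m))
  for (s in seq_len(nmod)) {
    idx <- which(m == s)
    mu <- mean(k_own[idx])
    sdv <- stats::sd(k_own[idx])
    zi[idx] <- if (length(idx) < 2 || is.na(sdv) || sdv == 0) 0
               else (k_own[idx] - mu) / sdv
  }
  pi_val <- 1 - rowSums((k_is / deg)^2)
  data.frame(otu_id = nodes, module = m, degree = as.integer(deg),
             zi = zi, pi = pi_val, row.names = NULL)
}

#' Classify node roles from Zi and Pi
#'
#' Thresholds follow the molecular-ecological-network convention:
#' module hubs have Zi > `zi_threshold`, connectors Pi > `pi_threshold`,
#' network hubs both, peripherals neither. Keystones are all
#' non-peripheral nodes.
#'
#' @param records data.frame from [zipi].
#' @param zi_threshold within-module degree z-score cut (default 2.5).
#' @param pi_threshold participation coefficient cut (default 0.62).
#' @return `records` with a `role` factor column.
#' @export
classify_roles <- function(records, zi_threshold = 2.5, pi_threshold = 0.62) {
  hi_z <- records$zi > zi_threshold
  hi_p <- records$pi > pi_threshold
  role <- ifelse(hi_z & hi_p, "network_hub",
          ifelse(hi_z, "module_hub",
          ifelse(hi_p, "connector", "peripheral")))
  records$role <- factor(role, levels = c("peripheral", "module_hub",
                                          "connector", "network_hub"))
  records
}

#' Keystone nodes of a role table
#'
#' @param records output of [classify_roles].
#' @return character vector of non-peripheral OTU ids.
#' @export
keystones <- function(records) {
  if (is.null(records$role)) stop("run classify_roles first", call. = FALSE)
  records$otu_id[records$role != "peripheral"]
}

#' Percentage overlap between two keystone sets
#'
#' 100 * |A intersect B| / |A union B| (Jaccard, as a percentage). NA when
#' both sets are empty.
#'
#' @param roles_a,roles_b role tables from [classify_roles].
#' @export
keystone_overlap <- function(roles_a, roles_b) {
  a <- keystones(roles_a); b <- keystones(roles_b)
  u <- union(a, b)
  if (!length(u)) return(NA_real_)
  100 * length(intersect(a, b)) / length(u)
}
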