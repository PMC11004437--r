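#' Principal coordinate analysis
#'
#' Classical metric scaling: the distance matrix is squared, multiplied by
#' -1/2 and double-centred (Gower), then eigendecomposed. Coordinates are
#' eigenvectors scaled by the square root of their (positive) eigenvalues;
#' axes with non-positive eigenvalues are reported but carry no
#' coordinates. Proportion explained is computed over the positive
#' eigenvalues.
#'
#' @param d square symmetric distance matrix (sample ids as dimnames).
#' @param k number of axes to return (>= 1, at most n - 1).
#' @return object of class `pcoa_result` with `coordinates`
#'   (samples x <= k), `eigenvalues` (all, descending) and
#'   `proportion_explained` per returned axis.
#' @export
pcoa <- function(d, k = 2) {
  d <- check_distance_matrix(d)
  n <- nrow(d)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > n - 1) stop("k must be <= n - 1", call. = FALSE)
  a <- -0.5 * d^2
  centred <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  eig <- eigen(centred, symmetric = TRUE)
  values <- eig$values
  pos <- values > max(values[1], 0) * 1e-12 & values > 0
  npos <- sum(pos)
  kk <- min(k, npos)
  coords <- if (kk >= 1) {
    sweep(eig$vectors[, seq_len(kk), drop = FALSE], 2,
          sqrt(values[seq_len(kk)]), `*`)
  } else {
    matrix(0, n, 0)
  }
  rownames(coords) <- rownames(d)
  if (ncol(coords)) colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  prop <- if (npos) values[seq_len(kk)] / sum(values[pos]) else numeric(0)
  structure(list(coordinates = coords, eigenvalues = values,
                 proportion_explained = prop, n_negative = sum(values < 0)),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "samples,", ncol(x$coordinates),
      "axes returned\n")
  if (length(x$proportion_explained))
    cat("  proportion explained:",
        paste(fmt_num(100 * x$proportion_explained, 3), collapse = "%, "),
        "%\n")
  if (x$n_negative)
    cat("  negative eigenvalues:", x$n_negative, "\n")
  invisible(x)
}
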