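## Random-matrix-theory threshold selection. The similarity matrix is
## hard-thresholded over a grid of candidate cut-offs; at each cut-off the
## eigenvalue nearest-neighbour spacing distribution (NNSD) of the
## thresholded matrix is compared against Poisson (uncorrelated spectrum,
## the signature of modular/block structure) and GOE (Wigner surmise, the
## signature of a noise-dominated spectrum). The chosen threshold is the
## smallest cut-off whose NNSD is consistent with Poisson and inconsistent
## with GOE: below it, random correlations knit the matrix together and
## level repulsion appears; above it, only genuine block structure remains.

# spacings of the unfolded spectrum: the cumulative spectral function is
# approximated by a smoothing spline through (sorted eigenvalue, rank),
# and spacings are the increments of that smooth function between
# consecutive distinct eigenvalues (mean-normalised to 1)
unfold_spacings <- function(values, dedup_tol = 1e-8) {
  values <- sort(values)
  values <- values[c(TRUE, diff(values) > dedup_tol)]
  n <- length(values)
  if (n < 6) return(numeric(0))
  df <- max(4, min(15, floor(n / 4)))
  fit <- stats::smooth.spline(values, seq_len(n), df = df)
  cum <- stats::predict(fit, values)$y
  s <- diff(cum)
  s <- s[s > 0]
  if (!length(s)) return(numeric(0))
  s / mean(s)
}

# chi-squared GOF p-value of spacings against a null CDF, using
# equal-probability bins under the null
nnsd_gof <- function(s, cdf) {
  n <- length(s)
  k <- max(5, min(12, floor(n / 5)))
  probs <- seq(0, 1, length.out = k + 1)
  # invert the null CDF on a fine grid to get equal-probability breaks
  grid <- seq(0, max(max(s), 10), length.out = 4096)
  cg <- cdf(grid)
  breaks <- c(0, stats::approx(cg, grid, xout = probs[-c(1, k + 1)],
                               ties = "ordered")$y, Inf)
  obs <- table(cut(s, breaks = breaks, include.lowest = TRUE))
  expected <- n / k
  stat <- sum((as.numeric(obs) - expected)^2 / expected)
  stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
}

poisson_cdf <- function(s) 1 - exp(-s)
goe_cdf <- function(s) 1 - exp(-pi * s^2 / 4)   # Wigner surmise

#' RMT-based correlation threshold scan
#'
#' Scans candidate cut-offs; at each, entries of the correlation matrix
#' with |r| below the cut-off are zeroed (diagonal kept at 1), rows/columns
#' left with no off-diagonal entry are dropped, and the nearest-neighbour
#' spacing distribution of the unfolded eigenvalue spectrum is tested by
#' chi-squared GOF against the Poisson and GOE (Wigner) laws. The chosen
#' threshold is the smallest cut-off where Poisson is not rejected and GOE
#' is rejected at `alpha`.
#'
#' @param cm a `cor_matrix_pair` from [spearman_matrix] with >= 20 OTUs.
#' @param grid candidate thresholds (default 0.30 to 0.95 by 0.01).
#' @param alpha GOF significance level (default 0.05).
#' @param min_spacings minimum number of usable eigenvalue spacings for a
#'   candidate to be judged (default 20).
#' @return list of class `rmt_scan`: `threshold` (NA if no candidate
#'   satisfies the rule — fall back to a fixed threshold) and `scan`, a
#'   data.frame with per-candidate node/eigenvalue counts and GOF p-values.
#' @export
rmt_threshold_scan <- function(cm, grid = seq(0.30, 0.95, by = 0.01),
                               alpha = 0.05, min_spacings = 20) {
  stopifnot(inherits(cm, "cor_matrix_pair"))
  r <- cm$r
  if (nrow(r) < 20)
    stop("need >= 20 OTUs for a meaningful spectrum", call. = FALSE)
  rows <- lapply(grid, function(t) {
    m <- r
    m[abs(m) < t] <- 0
    diag(m) <- 1
    connected <- rowSums(abs(m) > 0) > 1   # beyond the diagonal
    m <- m[connected, connected, drop = FALSE]
    if (nrow(m) < 6)
      return(data.frame(threshold = t, n_nodes = nrow(m), n_spacings = 0,
                        poisson_p = NA_real_, goe_p = NA_real_,
                        passes = FALSE))
    s <- unfold_spacings(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    if (length(s) < min_spacings)
      return(data.frame(threshold = t, n_nodes = nrow(m),
                        n_spacings = length(s),
                        poisson_p = NA_real_, goe_p = NA_real_,
                        passes = FALSE))
    pp <- nnsd_gof(s, poisson_cdf)
    gp <- nnsd_gof(s, goe_cdf)
    data.frame(threshold = t, n_nodes = nrow(m), n_spacings = length(s),
               poisson_p = pp, goe_p = gp,
               passes = pp > alpha && gp <= alpha)
  })
  scan <- do.call(rbind, rows)
  chosen <- scan$threshold[scan$passes]
  structure(list(threshold = if (length(chosen)) min(chosen) else NA_real_,
                 scan = scan, alpha = alpha),
            class = "rmt_scan")
}

#' @export
print.rmt_scan <- function(x, ...) {
  if (is.na(x$threshold)) {
    cat("RMT scan: no threshold satisfied the Poisson/GOE rule;",
        "fall back to a fixed threshold\n")
  } else {
    cat("RMT scan: chosen threshold", x$threshold, "\n")
  }
  cat("  candidates evaluated:", nrow(x$scan), "\n")
  invisible(x)
}
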