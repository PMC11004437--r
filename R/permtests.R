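## Seeded permutation tests on distance matrices. All p-values follow the
## add-one rule p = (1 + #{perm stat >= observed}) / (1 + n_perm), one-sided
## towards group separation / positive association, and are exactly
## reproducible given the seed.

perm_test_result <- function(statistic_name, statistic, n_perm, p, seed,
                             extra = list()) {
  structure(c(list(statistic_name = statistic_name, statistic = statistic,
                   n_permutations = n_perm, p_value = p, seed = seed), extra),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(x$statistic_name, "=", fmt_num(x$statistic),
      " p =", fmt_num(x$p_value),
      " (", x$n_permutations, "permutations )\n")
  if (!is.null(x$R2)) cat("  R2 =", fmt_num(x$R2), "\n")
  invisible(x)
}

check_groups <- function(groups, n) {
  groups <- as.factor(groups)
  if (length(groups) != n)
    stop("groups length must match the distance matrix", call. = FALSE)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2))
    stop("group(s) of size 1: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  groups
}

# within-group sum of squares from squared distances: sum over groups of
# (sum of within-group d^2) / (2 * n_g); block sums via rowsum twice.
permanova_ssw <- function(d2, groups) {
  block <- rowsum(t(rowsum(d2, groups)), groups)
  sizes <- table(groups)
  sum(diag(block) / (2 * as.numeric(sizes[rownames(block)])))
}

#' One-factor PERMANOVA (Adonis)
#'
#' Partitions the total sum of squared distances into between- and
#' within-group components and tests the pseudo-F statistic by permuting
#' group labels.
#'
#' @param d square symmetric distance matrix.
#' @param groups factor-like group labels, one per sample; >= 2 groups of
#'   >= 2.
#' @param n_perm number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return a `perm_test` with pseudo-F statistic, `R2` and permutation p.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- check_distance_matrix(d)
  n <- nrow(d)
  groups <- check_groups(groups, n)
  a <- nlevels(groups)
  d2 <- d^2
  ss_total <- sum(d2) / (2 * n)
  ssw <- permanova_ssw(d2, groups)
  ssb <- ss_total - ssw
  f_obs <- (ssb / (a - 1)) / (ssw / (n - a))
  perm_f <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    g <- groups[sample.int(n)]
    w <- permanova_ssw(d2, g)
    ((ss_total - w) / (a - 1)) / (w / (n - a))
  }, 0))
  p <- (1 + sum(perm_f >= f_obs)) / (1 + n_perm)
  perm_test_result("pseudo-F", f_obs, n_perm, p, seed,
                   extra = list(R2 = ssb / ss_total, method = "PERMANOVA"))
}

anosim_stat <- function(rank_mat, within) {
  n <- nrow(rank_mat)
  r <- rank_mat[upper.tri(rank_mat)]
  w <- within[upper.tri(within)]
  (mean(r[!w]) - mean(r[w])) / (n * (n - 1) / 4)
}

#' ANOSIM
#'
#' Tests whether between-group distances are larger in rank than
#' within-group distances: R = (mean rank between - mean rank within) /
#' (N(N-1)/4), permuting group labels.
#'
#' @inheritParams permanova
#' @return a `perm_test` with the R statistic.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- check_distance_matrix(d)
  n <- nrow(d)
  groups <- check_groups(groups, n)
  rank_mat <- d
  rank_mat[upper.tri(d)] <- rank(d[upper.tri(d)])
  rank_mat[lower.tri(d)] <- t(rank_mat)[lower.tri(d)]
  same <- outer(groups, groups, `==`)
  r_obs <- anosim_stat(rank_mat, same)
  perm_r <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    g <- groups[sample.int(n)]
    anosim_stat(rank_mat, outer(g, g, `==`))
  }, 0))
  p <- (1 + sum(perm_r >= r_obs)) / (1 + n_perm)
  perm_test_result("ANOSIM R", r_obs, n_perm, p, seed,
                   extra = list(method = "ANOSIM"))
}

#' Mantel test
#'
#' Correlation between the upper triangles of two distance matrices over
#' the same samples, tested by simultaneous row/column permutation of the
#' second matrix.
#'
#' @param d1,d2 square symmetric distance matrices with identical ids in
#'   identical order.
#' @param method "pearson" or "spearman".
#' @inheritParams permanova
#' @return a `perm_test` with the Mantel r statistic.
#' @export
mantel <- function(d1, d2, method = c("pearson", "spearman"),
                   n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  d1 <- check_distance_matrix(d1, "d1")
  d2 <- check_distance_matrix(d2, "d2")
  if (!identical(rownames(d1), rownames(d2)))
    stop("d1 and d2 must share identical sample ids in identical order",
         call. = FALSE)
  n <- nrow(d1)
  if (method == "spearman") {
    # rank-transform each matrix's pairwise values once; a row/column
    # permutation of the matrix permutes those values bijectively, so
    # Pearson on the rank matrices is Spearman for every permutation
    rank_tri <- function(m) {
      m[upper.tri(m)] <- rank(m[upper.tri(m)])
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    }
    d1 <- rank_tri(d1); d2 <- rank_tri(d2)
  }
  ut <- upper.tri(d1)
  r_obs <- stats::cor(d1[ut], d2[ut])
  perm_r <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(d1[ut], d2[p, p][ut])
  }, 0))
  p <- (1 + sum(perm_r >= r_obs)) / (1 + n_perm)
  perm_test_result(paste0("Mantel r (", method, ")"), r_obs, n_perm, p, seed,
                   extra = list(method = "Mantel"))
}

#' Pearson / Spearman correlation with two-sided p
#'
#' Coefficient plus a two-sided p-value from the t approximation with
#' n - 2 degrees of freedom (applied to the rank correlation in the
#' Spearman case).
#'
#' @param x,y numeric vectors of equal length >= 3, finite, non-constant.
#' @param method "pearson" or "spearman".
#' @return list with `r` and `p`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need >= 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- stats::cor(x, y)
  list(r = r, p = cor_t_pvalue(r, length(x)))
}

# two-sided p for a correlation coefficient via the t approximation
cor_t_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}
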