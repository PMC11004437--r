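#' @keywords internal
"_PACKAGE"

## Seed handling ---------------------------------------------------------

#' Expand one master seed into independent stream seeds
#'
#' A single integer seed is expanded into `n` sub-seeds by seeding R's RNG
#' once with the master seed and drawing `n` integers uniformly from
#' \[1, 2^31 - 2\]. Every stochastic stage of the package draws its own
#' stream seed this way, so stages can be re-run independently without
#' disturbing each other's randomness.
#'
#' @param seed master seed (single integer).
#' @param n number of stream seeds to derive.
#' @return integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed), n >= 1L)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Run an expression with a local RNG seed
#'
#' Seeds the RNG, evaluates `expr`, and restores the previous RNG state so
#' package internals never perturb the caller's random stream.
#'
#' @param seed integer seed, or NULL to leave the RNG alone.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Misc helpers ----------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

upper_tri_values <- function(m) m[upper.tri(m)]

#' Adjusted Rand index between two partitions
#'
#' Measures agreement between two labelings of the same items, corrected
#' for chance; 1 means identical partitions, ~0 means no better than random.
#' Used to score recovery of planted correlation modules by community
#' detection.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

## Distance-matrix validation -------------------------------------------

#' Validate a square symmetric distance matrix
#'
#' @param d numeric matrix with identical row/column names, zero diagonal.
#' @param name label used in error messages.
#' @return `d`, invisibly checked.
#' @keywords internal
check_distance_matrix <- function(d, name = "distance matrix") {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d))
    stop(name, " must be a numeric matrix", call. = FALSE)
  if (nrow(d) != ncol(d))
    stop(name, " must be square", call. = FALSE)
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    stop(name, " must carry identical row and column sample ids", call. = FALSE)
  if (anyDuplicated(rownames(d)))
    stop(name, " has duplicate sample ids", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop(name, " is not symmetric", call. = FALSE)
  if (max(abs(diag(d))) > 1e-8)
    stop(name, " must have a zero diagonal", call. = FALSE)
  d
}

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
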