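named_dist <- function(pts, ids = NULL) {
  d <- as.matrix(stats::dist(pts))
  ids <- ids %||% sprintf("s%02d", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  d
}

test_that("pcoa reconstructs euclidean configurations exactly", {
  set.seed(1)
  pts <- matrix(rnorm(8), 4, 2)
  d <- named_dist(pts)
  res <- pcoa(d, 2)
  expect_lt(max(abs(as.matrix(stats::dist(res$coordinates)) - d)), 1e-9)
  # eigenvalue sum equals the trace of the centred Gower matrix
  a <- -0.5 * d^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  expect_equal(sum(res$eigenvalues), sum(diag(g)))
  # agreement with the classical-scaling reference
  ref <- stats::cmdscale(d, k = 2, eig = TRUE)
  expect_equal(abs(res$coordinates), abs(ref$points), ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("pcoa handles degenerate and non-euclidean inputs", {
  d <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  res <- pcoa(d, 2)
  expect_equal(unname(res$coordinates), matrix(0, 3, 0))
  expect_true(all(res$eigenvalues == 0))
  expect_error(pcoa(named_dist(matrix(rnorm(8), 4)), 0), "k must be")
  expect_error(pcoa(named_dist(matrix(rnorm(8), 4)), 4), "k must be")
})

test_that("permanova p from sampling matches exhaustive enumeration", {
  set.seed(2)
  pts <- matrix(rnorm(12), 6, 2)
  pts[1:3, ] <- pts[1:3, ] + 1          # moderate separation
  d <- named_dist(pts)
  groups <- rep(c("a", "b"), each = 3)
  obs <- oracle_permanova(d, groups)
  # exhaustive: every distinct split of 6 samples into two 3s
  splits <- all_balanced_splits(6)
  fs <- vapply(splits, function(idx) {
    g <- rep("b", 6); g[idx] <- "a"
    oracle_permanova(d, g)$f
  }, 0)
  p_exact <- mean(fs >= obs$f - 1e-12)
  res <- permanova(d, groups, n_perm = 999, seed = 7)
  expect_equal(res$statistic, obs$f, tolerance = 1e-12)
  expect_equal(res$R2, obs$r2, tolerance = 1e-12)
  expect_lt(abs(res$p_value - p_exact), 0.05)
})

test_that("anosim matches direct rank arithmetic and enumeration", {
  set.seed(3)
  pts <- matrix(rnorm(12), 6, 2)
  pts[4:6, ] <- pts[4:6, ] + 1.5
  d <- named_dist(pts)
  groups <- rep(c("a", "b"), each = 3)
  r_obs <- oracle_anosim_r(d, groups)
  splits <- all_balanced_splits(6)
  rs <- vapply(splits, function(idx) {
    g <- rep("b", 6); g[idx] <- "a"
    oracle_anosim_r(d, g)
  }, 0)
  p_exact <- mean(rs >= r_obs - 1e-12)
  res <- anosim(d, groups, n_perm = 999, seed = 5)
  expect_equal(res$statistic, r_obs, tolerance = 1e-12)
  expect_lt(abs(res$p_value - p_exact), 0.05)

  # hand-sized n = 4 case against the same direct arithmetic
  d4 <- named_dist(matrix(c(0, 0, 1, 0, 0, 3, 1, 3.2), 4, 2))
  g4 <- c("a", "a", "b", "b")
  expect_equal(anosim(d4, g4, n_perm = 99, seed = 1)$statistic,
               oracle_anosim_r(d4, g4), tolerance = 1e-12)
})

test_that("clearly separated groups reach the minimal attainable p", {
  set.seed(4)
  pts <- rbind(matrix(rnorm(20, 0, 0.05), 10), matrix(rnorm(20, 50, 0.05), 10))
  d <- named_dist(pts)
  groups <- rep(c("a", "b"), each = 10)
  expect_equal(permanova(d, groups, n_perm = 199, seed = 1)$p_value, 1 / 200)
  expect_equal(anosim(d, groups, n_perm = 199, seed = 1)$statistic, 1)
})

test_that("permutation engines agree with the vegan reference", {
  skip_if_not_installed("vegan")
  tb <- random_table(12, 10, seed = 9)
  d <- bray_curtis(tb)
  groups <- factor(rep(c("a", "b"), each = 5))
  pm <- permanova(d, groups, n_perm = 99, seed = 1)
  ad <- vegan::adonis2(stats::as.dist(d) ~ groups, permutations = 99)
  expect_equal(pm$statistic, ad$F[1], tolerance = 1e-10)
  expect_equal(pm$R2, ad$R2[1], tolerance = 1e-10)
  an <- anosim(d, groups, n_perm = 99, seed = 1)
  va <- vegan::anosim(stats::as.dist(d), groups, permutations = 99)
  expect_equal(an$statistic, unname(va$statistic), tolerance = 1e-10)
})

test_that("mantel detects identical, affine and independent structure", {
  set.seed(5)
  d1 <- named_dist(matrix(rnorm(20), 10, 2))
  expect_equal(mantel(d1, d1, n_perm = 99, seed = 1)$statistic, 1)
  aff <- 0.2 + 3 * d1; diag(aff) <- 0
  expect_equal(mantel(d1, aff, n_perm = 99, seed = 1)$statistic, 1)
  d2 <- named_dist(matrix(rnorm(20), 10, 2))
  expect_error(mantel(d1, named_dist(matrix(rnorm(16), 8, 2))), "ids")
  skip_if_not_installed("vegan")
  mm <- mantel(d1, d2, method = "spearman", n_perm = 99, seed = 2)
  vm <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                      method = "spearman", permutations = 99)
  expect_equal(mm$statistic, unname(vm$statistic), tolerance = 1e-10)
})

test_that("permuted null statistics are centred at zero for anosim", {
  set.seed(6)
  d <- named_dist(matrix(rnorm(24), 12, 2))
  groups <- rep(c("a", "b"), each = 6)
  rs <- vapply(1:200, function(i) {
    g <- sample(groups)
    oracle_anosim_r(d, g)
  }, 0)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("correlate returns coefficients with t-approximation p-values", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlate(x, 2 * x)$r, 1)
  expect_equal(correlate(x, x^3, method = "spearman")$r, 1)
  res <- correlate(c(1, 2, 3, 4), c(2, 1, 4, 3), method = "spearman")
  expect_equal(res$r, oracle_spearman(c(1, 2, 3, 4), c(2, 1, 4, 3)),
               tolerance = 1e-12)
  ct <- stats::cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3), method = "spearman")
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(correlate(1:2, 1:2), ">= 3")
})

test_that("tdr recovers exact linear decay and flat similarity", {
  dates <- as.Date("2018-05-15") + c(0, 100, 200, 300, 450, 600)
  ids <- paste0("s", seq_along(dates))
  meta <- simple_metadata(ids, dates, rep("p1", length(dates)))
  dt <- abs(outer(as.numeric(dates), as.numeric(dates), `-`))
  sim <- 0.8 - 0.001 * dt
  d <- 1 - sim; diag(d) <- 0; dimnames(d) <- list(ids, ids)
  fit <- tdr_fit(d, meta)
  expect_equal(fit$v, 0.001, tolerance = 1e-12)
  expect_equal(fit$slope, -0.001, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  flat <- matrix(0.3, length(ids), length(ids), dimnames = list(ids, ids))
  diag(flat) <- 0
  ffit <- tdr_fit(flat, meta)
  # constant similarity except the self-pairs: slope and R2 collapse
  expect_lt(ffit$v, 1e-12)
  expect_equal(ffit$r_squared, 0)

  one_date <- simple_metadata(ids, rep(dates[1], 6), rep("p1", 6))
  expect_error(tdr_fit(d, one_date), "positive time interval")
})

test_that("tdr pairing scopes select the intended pairs", {
  dates <- rep(as.Date("2018-05-15") + c(0, 100, 200), each = 2)
  ids <- paste0("s", 1:6)
  meta <- simple_metadata(ids, dates, rep(c("p1", "p2"), 3))
  set.seed(8)
  d <- named_dist(matrix(rnorm(12), 6, 2), ids)
  fp <- tdr_fit(d, meta, pairing_scope = "plot")
  fg <- tdr_fit(d, meta, pairing_scope = "group")
  expect_identical(fp$n_pairs, 6L)   # per plot: C(3,2) pairs x 2 plots
  expect_identical(fg$n_pairs, 12L)  # all cross-time pairs
})
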