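test_that("rarefaction subsamples exactly and drops shallow samples", {
  tb <- random_table(8, 6, lambda = 40, seed = 2)
  depth <- min(colSums(tb$counts))
  rar <- rarefy_table(tb, depth, seed = 1)
  expect_true(all(colSums(rar$counts) == depth))
  expect_true(all(rar$counts <= tb$counts))     # never creates counts
  # the sample sitting exactly at depth is untouched
  at_depth <- which(colSums(tb$counts) == depth)
  expect_identical(rar$counts[, at_depth], tb$counts[, at_depth])

  counts <- cbind(deep = c(50L, 50L), shallow = c(2L, 1L))
  rownames(counts) <- c("o1", "o2")
  tb2 <- otu_table(counts)
  expect_message(r2 <- rarefy_table(tb2, 10, seed = 1), "shallow")
  expect_identical(sample_ids(r2), "deep")
  expect_error(rarefy_table(tb2, 1000), "fewer than")
})

test_that("rarefied richness matches the hypergeometric expectation", {
  counts <- matrix(c(5L, 5L, 10L), ncol = 1,
                   dimnames = list(c("a", "b", "c"), "s"))
  tb <- otu_table(counts)
  rich <- vapply(1:1000, function(s) {
    sum(rarefy_table(tb, 10, seed = s)$counts > 0)
  }, 0)
  expected <- oracle_rarefied_richness(c(5, 5, 10), 10)
  mc_se <- stats::sd(rich) / sqrt(length(rich))
  expect_lt(abs(mean(rich) - expected), 3 * mc_se)
})

test_that("shannon evaluates the entropy formula in nats", {
  expect_equal(shannon(c(10, 10, 10, 10)), log(4))
  expect_equal(shannon(42), 0)
  expect_equal(round(shannon(c(1, 2, 3)), 4), 1.0114)
  expect_equal(shannon(c(1, 2, 3)), oracle_shannon(c(1, 2, 3)))
  # invariant to integer scaling of counts
  expect_equal(shannon(c(3, 7, 1) * 13L), shannon(c(3, 7, 1)))
  expect_error(shannon(c(0, 0)), "zero")
})

test_that("alpha diversity respects the Shannon/richness bound", {
  tb <- random_table(15, 8, lambda = 3, seed = 7)
  a <- alpha_diversity(tb)
  expect_true(all(a$shannon >= 0))
  expect_true(all(a$shannon <= log(pmax(a$richness, 1)) + 1e-12))
})

test_that("bray-curtis matches its formula on hand cases", {
  counts <- cbind(x = c(2L, 0L), y = c(1L, 1L), z = c(2L, 0L))
  rownames(counts) <- c("o1", "o2")
  d <- bray_curtis(otu_table(counts))
  expect_equal(d["x", "y"], 0.5)
  expect_equal(d["x", "z"], 0)              # identical samples
  disj <- cbind(a = c(3L, 0L), b = c(0L, 4L))
  rownames(disj) <- c("o1", "o2")
  expect_equal(bray_curtis(otu_table(disj))["a", "b"], 1)

  zero <- cbind(a = c(1L, 0L), b = c(0L, 0L))
  rownames(zero) <- c("o1", "o2")
  expect_error(bray_curtis(otu_table(zero)), "zero total")
})

test_that("distance matrices are symmetric with zero diagonal and in [0,1]", {
  for (seed in 1:3) {
    tb <- random_table(10, 7, lambda = 5, seed = seed)
    d <- bray_curtis(tb)
    expect_equal(d, t(d))
    expect_equal(diag(d), stats::setNames(rep(0, 7), sample_ids(tb)))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d["s01", "s02"],
                 oracle_bray(tb$counts[, 1], tb$counts[, 2]))

    tree <- ape::rtree(10, tip.label = otu_ids(tb))
    u <- unweighted_unifrac(tb, tree)
    expect_equal(u, t(u))
    expect_true(all(diag(u) == 0) && all(u >= 0 & u <= 1))
  }
})

test_that("unweighted unifrac classifies branches correctly", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2):0;")
  counts <- matrix(c(1, 1, 0, 1, 0, 1), nrow = 3,
                   dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  u <- unweighted_unifrac(otu_table(counts), tree)
  # edges unique to one community: B (1) and C (2); either-community
  # branch length: A + B + C + the (A,B) stem = 5
  expect_equal(u["s1", "s2"], 3 / 5)

  # identical presence sets are at distance zero
  same <- matrix(c(1, 1, 0, 2, 5, 0), nrow = 3,
                 dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  expect_equal(unweighted_unifrac(otu_table(same), tree)["s1", "s2"], 0)

  # star tree, disjoint singleton communities -> 1
  star <- ape::read.tree(text = "(A:1,B:1,C:1):0;")
  disj <- matrix(c(1, 0, 0, 0, 1, 0), nrow = 3,
                 dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  expect_equal(unweighted_unifrac(otu_table(disj), star)["s1", "s2"], 1)

  bad <- matrix(c(1, 1), nrow = 2, dimnames = list(c("A", "zzz"), "s1"))
  bad <- cbind(bad, s2 = c(1, 0))
  expect_error(unweighted_unifrac(otu_table(bad), tree), "zzz")
})

test_that("unifrac agrees with the independent picante implementation", {
  skip_if_not_installed("picante")
  tb <- random_table(12, 6, lambda = 2, seed = 5)
  set.seed(6)
  tree <- ape::rtree(12, tip.label = otu_ids(tb))
  mine <- unweighted_unifrac(tb, tree)
  ref <- as.matrix(picante::unifrac(t((tb$counts > 0) + 0), tree))
  expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-12)
})
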