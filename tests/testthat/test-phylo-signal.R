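# literal transcription of the K formula with explicit matrix algebra,
# independent of the package's vectorised path
oracle_blomberg_k <- function(tree, x) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  n <- length(x)
  one <- matrix(1, n, 1)
  Ci <- solve(C)
  a <- as.numeric(solve(t(one) %*% Ci %*% one) %*% t(one) %*% Ci %*% x)
  mse0 <- as.numeric(t(x - a * one) %*% (x - a * one)) / (n - 1)
  mse <- as.numeric(t(x - a * one) %*% Ci %*% (x - a * one)) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(Ci)) / (n - 1)
  (mse0 / mse) / expected
}

test_that("Blomberg's K matches the formula transcription on small fixtures", {
  tree <- read_tree("((A:1,B:1):1.5,(C:2,D:0.5):0.5);")
  x <- c(A = 1.2, B = 0.7, C = -0.4, D = 2.2)
  expect_equal(blomberg_k(tree, x, n_perm = 9, seed = 1)$statistic,
               oracle_blomberg_k(tree, x), tolerance = 1e-10)
  for (s in 1:5) {
    tr <- generate_tree(5, seed = s)
    y <- setNames(rnorm(5), tr$tip.label)
    expect_equal(blomberg_k(tr, y, n_perm = 9, seed = 1)$statistic,
                 oracle_blomberg_k(tr, y), tolerance = 1e-8)
  }
  expect_error(blomberg_k(tree, c(A = 1, B = 1, C = 1, D = 1), 9, 1),
               "zero variance")
})

test_that("Kmult reduces exactly to Blomberg's K for one trait", {
  tree <- generate_tree(20, seed = 3)
  x <- setNames(rnorm(20), tree$tip.label)
  k1 <- blomberg_k(tree, x, n_perm = 99, seed = 7)
  k2 <- kmult(tree, matrix(x, ncol = 1, dimnames = list(names(x), "t")),
              n_perm = 99, seed = 7)
  expect_equal(k1$statistic, k2$statistic, tolerance = 1e-10)
  expect_equal(k1$p_value, k2$p_value)
})

test_that("K and Kmult average near 1 under Brownian motion", {
  # BM expectation: K = 1. 500 simulations on a 100-tip tree.
  tree <- generate_tree(100, seed = 10)
  C <- ape::vcv(tree)
  U <- chol(C)
  set.seed(77)
  ks <- replicate(500, {
    x <- setNames(as.numeric(t(U) %*% rnorm(100)), tree$tip.label)
    blomberg_k(tree, x, n_perm = 0, seed = 1)$statistic
  })
  expect_gt(mean(ks), 0.9)
  expect_lt(mean(ks), 1.1)
  kms <- replicate(100, {
    Y <- t(U) %*% matrix(rnorm(300), 100, 3)
    rownames(Y) <- tree$tip.label
    kmult(tree, Y, n_perm = 0, seed = 1)$statistic
  })
  expect_gt(mean(kms), 0.9)
  expect_lt(mean(kms), 1.1)
})

test_that("tree-free noise gives K below 1 nearly always", {
  tree <- generate_tree(64, seed = 2)
  set.seed(12)
  ks <- replicate(200, {
    x <- setNames(rnorm(64), tree$tip.label)
    blomberg_k(tree, x, n_perm = 0, seed = 1)$statistic
  })
  expect_gte(mean(ks < 1), 0.95)
})

test_that("Abouheif proximity matrix matches the hand-computed 4-tip case", {
  tree <- read_tree("((A:1,B:1):1,(C:1,D:1):1);")
  W <- abouheif_proximity(tree)
  expected <- rbind(c(0, 1/2, 1/8, 1/8),
                    c(1/2, 0, 1/8, 1/8),
                    c(1/8, 1/8, 0, 1/2),
                    c(1/8, 1/8, 1/2, 0))
  dimnames(expected) <- list(c("A","B","C","D"), c("A","B","C","D"))
  expect_equal(W, expected)
})

test_that("Cmean detects clade structure and its null p-values are uniform", {
  tree <- read_tree("(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);")
  x <- c(A = 5, B = 5.2, C = 4.8, D = 5.1, E = -5, F = -5.2, G = -4.9, H = -5.1)
  res <- abouheif_cmean(tree, x, n_perm = 999, seed = 1)
  expect_gt(res$statistic, 0)
  expect_lte(res$p_value, 0.05)

  big <- generate_tree(32, seed = 4)
  set.seed(21)
  ps <- replicate(400, {
    y <- setNames(rnorm(32), big$tip.label)
    abouheif_cmean(big, y, n_perm = 99, seed = sample.int(1e6, 1))$p_value
  })
  expect_lt(mean(ps <= 0.05), 0.09)
  expect_gt(mean(ps <= 0.05), 0.015)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("signal statistics are invariant to tip-order permutation", {
  tree <- generate_tree(16, seed = 6)
  x <- setNames(rnorm(16), tree$tip.label)
  shuf <- sample(x)
  expect_equal(blomberg_k(tree, x, 9, 1)$statistic,
               blomberg_k(tree, shuf, 9, 1)$statistic)
  expect_equal(abouheif_cmean(tree, x, 9, 1)$statistic,
               abouheif_cmean(tree, shuf, 9, 1)$statistic)
})

test_that("permutation p-values use the (count+1)/(n+1) estimator", {
  tree <- generate_tree(12, seed = 8)
  x <- setNames(rnorm(12), tree$tip.label)
  r <- blomberg_k(tree, x, n_perm = 99, seed = 3)
  expect_true(r$p_value > 0 && r$p_value <= 1)
  expect_equal(r$p_value * 100, round(r$p_value * 100))
  tab <- signal_table(tree, matrix(x, ncol = 1, dimnames = list(names(x), "N")),
                      n_perm = 49, seed = 1)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$parameter, c("N", "(multivariate)"))
})
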