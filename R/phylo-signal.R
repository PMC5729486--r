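#' Phylogenetic signal statistics
#'
#' Three permutation-based tests of phylogenetic signal on the species-by-
#' parameter matrix: Blomberg's K (univariate, expectation 1 under Brownian
#' motion on the given tree), its multivariate generalisation Kmult, and
#' Abouheif's Cmean (a Moran-type autocorrelation using a tree-derived
#' proximity matrix). All permutation p-values use the
#' \eqn{(\#\{\ge obs\}+1)/(n_{perm}+1)} estimator, so \eqn{p \in (0, 1]}.
#'
#' @name phylo-signal
NULL

# align a named vector / matrix of tip values with the tree tip order
align_tips <- function(tree, x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      if (nrow(x) != length(tree$tip.label)) abort("trait rows do not match tips")
      rownames(x) <- tree$tip.label
    }
    miss <- setdiff(tree$tip.label, rownames(x))
    if (length(miss) > 0) abort(sprintf("traits missing for tips: %s",
                                        paste(head(miss, 5), collapse = ", ")))
    x <- x[tree$tip.label, , drop = FALSE]
    if (anyNA(x)) abort("missing trait values")
    x
  } else {
    if (is.null(names(x))) {
      if (length(x) != length(tree$tip.label)) abort("trait length does not match tips")
      names(x) <- tree$tip.label
    }
    miss <- setdiff(tree$tip.label, names(x))
    if (length(miss) > 0) abort(sprintf("traits missing for tips: %s",
                                        paste(head(miss, 5), collapse = ", ")))
    x <- x[tree$tip.label]
    if (anyNA(x)) abort("missing trait values")
    x
  }
}

with_seed_restore <- function(seed, code) {
  force(seed)   # callers may pass seed = sample.int(...); draw it before saving
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# (observed MSE0/MSE) / (expected MSE0/MSE under BM), shared by K and Kmult.
# Y: n x p matrix aligned to the rows of C.
k_stat <- function(Y, Cinv, one_Cinv_one, trC, n) {
  a <- colSums(Cinv %*% Y) / one_Cinv_one       # phylogenetic mean
  R <- sweep(Y, 2, a)
  mse0 <- sum(R * R)
  mse <- sum(R * (Cinv %*% R))
  expected <- (trC - n / one_Cinv_one) / (n - 1)
  (mse0 / mse) / expected
}

#' @describeIn phylo-signal Blomberg's K for one trait, with tip-shuffling
#'   randomization p-value (one-sided, more signal than random).
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param x Named numeric vector of tip values (univariate), or a
#'   species-by-trait matrix for [kmult()].
#' @param n_perm Number of randomizations.
#' @param seed Integer seed.
#' @return A list of class `phylo_signal` with `statistic`, `p_value`,
#'   `n_perm`, `method`.
#' @export
blomberg_k <- function(tree, x, n_perm = 999, seed = 1) {
  x <- align_tips(tree, x)
  if (var(x) == 0) abort("trait has zero variance")
  kmult_impl(tree, matrix(x, ncol = 1, dimnames = list(names(x), "x")),
             n_perm, seed, method = "Blomberg's K")
}

#' @describeIn phylo-signal Multivariate Kmult over a trait block; reduces
#'   exactly to Blomberg's K for a single column.
#' @param scale Standardize columns to unit variance first? The default FALSE
#'   keeps the traits on their measured scales.
#' @export
kmult <- function(tree, x, n_perm = 999, seed = 1, scale = FALSE) {
  Y <- align_tips(tree, x)
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1, dimnames = list(names(Y), "x"))
  if (scale) Y <- base::scale(Y)
  if (qr(sweep(Y, 2, colMeans(Y)))$rank < min(dim(Y))) {
    warn("trait block is rank deficient")
  }
  kmult_impl(tree, Y, n_perm, seed, method = "Kmult")
}

kmult_impl <- function(tree, Y, n_perm, seed, method) {
  C <- ape::vcv(tree)
  C <- C[rownames(Y), rownames(Y)]
  Cinv <- solve(C)
  oco <- sum(Cinv)
  trC <- sum(diag(C))
  n <- nrow(Y)
  obs <- k_stat(Y, Cinv, oco, trC, n)
  perm <- with_seed_restore(seed, {
    vapply(seq_len(n_perm), function(i) {
      k_stat(Y[sample.int(n), , drop = FALSE], Cinv, oco, trC, n)
    }, numeric(1))
  })
  structure(list(statistic = obs,
                 p_value = (sum(perm >= obs) + 1) / (n_perm + 1),
                 n_perm = n_perm, permuted = perm, method = method),
            class = "phylo_signal")
}

#' Abouheif phylogenetic proximity matrix
#'
#' For tips i and j, the proximity is the product of \eqn{1/dd_k} over the
#' interior nodes k on the path connecting i and j through their most recent
#' common ancestor, where \eqn{dd_k} is the number of direct descendants
#' (children) of node k. The diagonal is zero. Branch lengths play no role.
#'
#' @param tree An `ape::phylo` tree.
#' @return A symmetric matrix with tip names as dimnames.
#' @export
abouheif_proximity <- function(tree) {
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  parent <- rep(NA_integer_, n + nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  nchild <- tabulate(tree$edge[, 1], n + nnode)
  # ancestor paths per tip, root last
  paths <- lapply(seq_len(n), function(i) {
    anc <- integer(0)
    p <- parent[i]
    while (!is.na(p)) {
      anc <- c(anc, p)
      p <- parent[p]
    }
    anc
  })
  A <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      pi <- paths[[i]]; pj <- paths[[j]]
      mrca <- pi[pi %in% pj][1]
      nodes <- c(pi[seq_len(match(mrca, pi))], pj[seq_len(match(mrca, pj) - 1)])
      A[i, j] <- A[j, i] <- prod(1 / nchild[nodes])
    }
  }
  A
}

#' @describeIn phylo-signal Abouheif's Cmean: Moran autocorrelation of the
#'   trait under the Abouheif proximity matrix, with permutation p-value.
#' @export
abouheif_cmean <- function(tree, x, n_perm = 999, seed = 1) {
  x <- align_tips(tree, x)
  if (var(x) == 0) abort("trait has zero variance")
  W <- abouheif_proximity(tree)
  if (diff(range(W[upper.tri(W)])) < 1e-12) {
    warn("all proximities equal (star-like tree); Cmean is degenerate")
  }
  n <- length(x)
  s0 <- sum(W)
  moran <- function(z) {
    zc <- z - mean(z)
    (n / s0) * sum(zc * (W %*% zc)) / sum(zc^2)
  }
  obs <- moran(x)
  perm <- with_seed_restore(seed, {
    vapply(seq_len(n_perm), function(i) moran(x[sample.int(n)]), numeric(1))
  })
  structure(list(statistic = obs,
                 p_value = (sum(perm >= obs) + 1) / (n_perm + 1),
                 n_perm = n_perm, permuted = perm,
                 method = "Abouheif's Cmean"),
            class = "phylo_signal")
}

signif_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ""))
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf("%s = %.3f%s (p = %.4g, %d permutations)\n", x$method,
              x$statistic, signif_stars(x$p_value), x$p_value, x$n_perm))
  invisible(x)
}

#' @describeIn phylo-signal One-row tibble (`method`, `statistic`, `p_value`,
#'   `stars`, `n_perm`).
#' @param ... Unused.
#' @method tidy phylo_signal
#' @export
tidy.phylo_signal <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p_value = x$p_value,
         stars = signif_stars(x$p_value), n_perm = x$n_perm)
}

#' Phylogenetic signal table for every parameter column
#'
#' Runs [abouheif_cmean()] and [blomberg_k()] on each column of the trait
#' matrix and [kmult()] on the whole block, mirroring the usual reporting
#' layout (statistic plus significance stars per parameter).
#'
#' @param tree An `ape::phylo` tree.
#' @param data Species-by-parameter data (tibble with `species` column, or a
#'   named matrix).
#' @param n_perm Permutations per test.
#' @param seed Integer seed.
#' @return A tibble with one row per parameter and the Kmult row labelled
#'   `"(multivariate)"`.
#' @export
signal_table <- function(tree, data, n_perm = 999, seed = 1) {
  X <- if (is.matrix(x <- data)) x else trait_matrix(data)
  rows <- map(colnames(X), function(v) {
    ab <- abouheif_cmean(tree, X[, v], n_perm = n_perm, seed = seed)
    bk <- blomberg_k(tree, X[, v], n_perm = n_perm, seed = seed)
    tibble(parameter = v,
           cmean = ab$statistic, cmean_p = ab$p_value,
           blomberg_k = bk$statistic, blomberg_k_p = bk$p_value)
  })
  km <- kmult(tree, X, n_perm = n_perm, seed = seed)
  bind_rows(bind_rows(rows),
            tibble(parameter = "(multivariate)", cmean = NA, cmean_p = NA,
                   blomberg_k = km$statistic, blomberg_k_p = km$p_value))
}
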