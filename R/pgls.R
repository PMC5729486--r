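#' Phylogenetic generalized least squares
#'
#' GLS regression under a Brownian-motion correlation structure: the residual
#' covariance is proportional to the tree's shared-branch-length matrix. The
#' predictor is tested with an F-test against the intercept-only model, both
#' evaluated in the GLS metric. On a star tree with equal branch lengths the
#' fit coincides with ordinary least squares.
#'
#' @param formula Model formula; variables are looked up in `data`.
#' @param data Data frame with one row per species and a `species` column
#'   matching the tree tips (or row names).
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param species_col Name of the species column.
#' @return A list of class `pgls_fit` with `coefficients`, `F`, `df`,
#'   `p_value`, `r_squared`, `sigma2` and the aligned model frame.
#' @examples
#' tree <- generate_tree(24, seed = 1)
#' d <- simulate_traits(tree, "BM", seed = 2, n_traits = 2)
#' names(d) <- c("species", "y", "x")
#' pgls(y ~ x, d, tree)
#' @export
pgls <- function(formula, data, tree, species_col = "species") {
  data <- as.data.frame(data)
  rn <- if (species_col %in% names(data)) as.character(data[[species_col]]) else
    rownames(data)
  mf <- stats::model.frame(formula, data)
  rownames(mf) <- rn
  miss <- setdiff(tree$tip.label, rn)
  if (length(miss) > 0) abort(sprintf("data missing for tips: %s",
                                      paste(head(miss, 5), collapse = ", ")))
  mf <- mf[tree$tip.label, , drop = FALSE]
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) abort("singular design matrix")
  C <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
  U <- chol(C)                                  # C = U'U
  ty <- backsolve(U, y, transpose = TRUE)
  tX <- backsolve(U, X, transpose = TRUE)
  fit <- lm.fit(tX, ty)
  n <- length(y); k <- ncol(X)
  rss1 <- sum(fit$residuals^2)
  t1 <- backsolve(U, rep(1, n), transpose = TRUE)
  fit0 <- lm.fit(matrix(t1, ncol = 1), ty)
  rss0 <- sum(fit0$residuals^2)
  q <- k - 1
  Fstat <- if (q == 0) NA_real_ else ((rss0 - rss1) / q) / (rss1 / (n - k))
  structure(list(
    coefficients = fit$coefficients,
    F = Fstat, df = c(q, n - k),
    p_value = if (q == 0) NA_real_ else pf(Fstat, q, n - k, lower.tail = FALSE),
    r_squared = 1 - rss1 / rss0,
    sigma2 = rss1 / (n - k),
    formula = formula, n = n
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS:", deparse(x$formula), "\n")
  print(x$coefficients)
  cat(sprintf("F(%d, %d) = %.3f, p = %.4g, R^2 = %.3f\n",
              x$df[1], x$df[2], x$F, x$p_value, x$r_squared))
  invisible(x)
}

#' @describeIn pgls Coefficient tibble.
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @method tidy pgls_fit
#' @export
tidy.pgls_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @describeIn pgls One-row model summary.
#' @method glance pgls_fit
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble(statistic = x$F, df1 = x$df[1], df2 = x$df[2], p_value = x$p_value,
         r_squared = x$r_squared, n = x$n)
}

#' Distance-based phylogenetic GLS with residual permutation
#'
#' Multivariate test of a grouping factor on a trait block under Brownian-
#' motion phylogenetic covariance. The data and design are premultiplied by
#' the inverse square root of the tree covariance matrix; the F statistic
#' comes from sums of squares of the transformed fit, and its significance
#' from permutation of the reduced-model residuals (RRPP), with the
#' \eqn{(count+1)/(n_{perm}+1)} estimator. With one trait and a star tree
#' this is the classical one-way ANOVA F.
#'
#' @param tree An `ape::phylo` tree.
#' @param x Species-by-trait matrix (or data frame with `species` column).
#' @param group Factor over species (named, or ordered as the rows of `x`);
#'   must have at least two levels.
#' @param n_perm Number of residual permutations.
#' @param seed Integer seed.
#' @return A list of class `dpgls_fit` with `F`, `df`, `p_value`, `n_perm`.
#' @export
dpgls <- function(tree, x, group, n_perm = 999, seed = 1) {
  Y <- align_tips(tree, if (is.matrix(x)) x else trait_matrix(x))
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1)
  if (!is.null(names(group))) group <- group[rownames(Y)]
  group <- factor(group)
  if (nlevels(group) < 2) abort("grouping factor needs at least two levels")
  n <- nrow(Y)
  C <- ape::vcv(tree)[rownames(Y), rownames(Y)]
  ei <- eigen(C, symmetric = TRUE)
  P <- ei$vectors %*% diag(1 / sqrt(ei$values)) %*% t(ei$vectors)
  tY <- P %*% Y
  X1 <- stats::model.matrix(~ group)
  X0 <- matrix(1, n, 1)
  tX1 <- P %*% X1
  tX0 <- P %*% X0
  rss <- function(X, Y) {
    f <- lm.fit(X, Y)
    sum(f$residuals^2)
  }
  hat_fit <- function(X, Y) {
    f <- lm.fit(X, Y)
    list(fitted = as.matrix(f$fitted.values), resid = as.matrix(f$residuals))
  }
  df1 <- ncol(X1) - 1
  df2 <- n - ncol(X1)
  rss1 <- rss(tX1, tY)
  red <- hat_fit(tX0, tY)
  rss0 <- sum(red$resid^2)
  Fobs <- ((rss0 - rss1) / df1) / (rss1 / df2)
  count <- with_seed_restore(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      Yp <- red$fitted + red$resid[sample.int(n), , drop = FALSE]
      r1 <- rss(tX1, Yp)
      r0 <- rss(tX0, Yp)
      Fp <- ((r0 - r1) / df1) / (r1 / df2)
      if (Fp >= Fobs) cnt <- cnt + 1L
    }
    cnt
  })
  structure(list(F = Fobs, df = c(df1, df2),
                 p_value = (count + 1) / (n_perm + 1), n_perm = n_perm,
                 levels = levels(group)),
            class = "dpgls_fit")
}

#' @export
print.dpgls_fit <- function(x, ...) {
  cat(sprintf("D-PGLS (%s): F(%d, %d) = %.3f, p = %.4g (%d permutations)\n",
              paste(x$levels, collapse = " vs "), x$df[1], x$df[2], x$F,
              x$p_value, x$n_perm))
  invisible(x)
}

#' @describeIn dpgls One-row tibble of the test.
#' @param x A `dpgls_fit`.
#' @param ... Unused.
#' @method glance dpgls_fit
#' @export
glance.dpgls_fit <- function(x, ...) {
  tibble(statistic = x$F, df1 = x$df[1], df2 = x$df[2], p_value = x$p_value,
         n_perm = x$n_perm)
}
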