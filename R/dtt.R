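#' Mean subclade disparity through time
#'
#' Disparity of a set of tips is the average squared pairwise Euclidean
#' distance between their trait vectors. Walking from the root towards the
#' present through the internal nodes in order of their age, the curve value
#' at each node time is the mean, over all lineages alive at that time, of
#' the disparity of the clade descending from the lineage relative to the
#' disparity of the full tip set. The first value (at the root) is 1 by
#' construction; single-tip lineages contribute 0, so the curve ends at 0 at
#' the present. Values near 1 late in the curve mean variance lies within
#' subclades; values near 0 mean variance lies among subclades.
#'
#' @param tree An ultrametric `ape::phylo` tree (within `tol` relative
#'   deviation).
#' @param x Species-by-trait matrix (e.g. PC scores) or data frame with
#'   `species` column.
#' @param tol Ultrametricity tolerance.
#' @return A tibble with columns `time` (relative, 0 = root, 1 = present) and
#'   `disparity`, including the terminal point (1, 0).
#' @export
subclade_disparity <- function(tree, x, tol = 1e-6) {
  X <- align_tips(tree, if (is.matrix(x)) x else trait_matrix(x))
  if (!is.matrix(X)) X <- matrix(X, ncol = 1, dimnames = list(names(X), "x"))
  if (!is_ultrametric_tol(tree, tol)) {
    abort("tree is not ultrametric within tolerance")
  }
  total <- avg_sq_dist(X)
  if (total == 0) {
    warn("traits identical at all tips; disparity curve set to zero")
  }
  dtt_curve(tree, X, total)
}

# average squared pairwise Euclidean distance; 0 for fewer than 2 rows
avg_sq_dist <- function(X) {
  n <- nrow(X)
  if (n < 2) return(0)
  d2 <- as.matrix(stats::dist(X))^2
  sum(d2[upper.tri(d2)]) / (n * (n - 1) / 2)
}

dtt_curve <- function(tree, X, total) {
  tree <- stats::reorder(tree, "cladewise")   # preorder edges for traversal
  n <- length(tree$tip.label)
  heights <- ape::node.depth.edgelength(tree)
  depth <- max(heights[seq_len(n)])
  internal <- seq(n + 1, n + tree$Nnode)
  ord <- internal[order(heights[internal])]
  times <- heights[ord] / depth
  # tips below each node
  tips_below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) tips_below[[i]] <- i
  for (e in rev(seq_len(nrow(tree$edge)))) {       # edges are in preorder
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    tips_below[[p]] <- c(tips_below[[p]], tips_below[[ch]])
  }
  rel_disp <- vapply(seq_along(tips_below), function(node) {
    idx <- tips_below[[node]]
    if (total == 0) 0 else
      avg_sq_dist(X[tree$tip.label[idx], , drop = FALSE]) / total
  }, numeric(1))
  h_parent <- heights[tree$edge[, 1]] / depth
  h_child <- heights[tree$edge[, 2]] / depth
  vals <- vapply(seq_along(ord), function(i) {
    t <- times[i]
    if (i == 1) return(if (total == 0) 0 else 1)
    # lineages alive just before the i-th divergence: a clade about to split
    # still counts as one subclade at its own divergence time
    alive <- which(h_parent < t - 1e-12 & h_child >= t - 1e-12)
    mean(rel_disp[tree$edge[alive, 2]])
  }, numeric(1))
  tibble(time = c(times, 1), disparity = c(vals, 0))
}

#' Disparity through time with a Brownian-motion null
#'
#' Computes the observed mean-subclade disparity curve of the (PC scores of
#' the) trait matrix, simulates `n_sim` Brownian-motion datasets on the same
#' tree with the rate matrix estimated from the data, and summarises the
#' simulations by their median curve and pointwise 95% envelope. The
#' morphological disparity index (MDI) is the signed area between the
#' observed curve and the simulated median (trapezoid rule over the node
#' times); positive MDI means more within-subclade disparity than the BM
#' expectation. `p` is the fraction of simulations whose own MDI (against
#' the same median) is at least the observed one, with the
#' \eqn{(count+1)/(n_{sim}+1)} estimator.
#'
#' @inheritParams subclade_disparity
#' @param n_sim Number of BM simulations (values below 100 warn: unstable
#'   envelope).
#' @param seed Integer seed.
#' @param use_pca Recompute standardized PC scores inside (default TRUE, so
#'   the module is self-contained and invariant to trait-column scaling).
#' @param level Envelope coverage.
#' @param interval Optional relative-time window `c(from, to)` over which the
#'   MDI integral is restricted (default: full range).
#' @return A list of class `dtt_result`: `observed` (tibble time/disparity),
#'   `median`, `lower`, `upper`, `mdi`, `p_value`, `n_sim`.
#' @examples
#' tree <- generate_tree(24, seed = 1)
#' d <- simulate_traits(tree, "BM", seed = 2, n_traits = 3)
#' r <- dtt_bm(tree, d, n_sim = 200, seed = 3)
#' r$mdi
#' @export
dtt_bm <- function(tree, x, n_sim = 10000, seed = 1, use_pca = TRUE,
                   level = 0.95, tol = 1e-6, interval = NULL) {
  X <- align_tips(tree, if (is.matrix(x)) x else trait_matrix(x))
  if (!is.matrix(X)) X <- matrix(X, ncol = 1, dimnames = list(names(X), "x"))
  if (n_sim < 100) warn("fewer than 100 simulations gives an unstable envelope")
  if (use_pca) {
    pca <- prcomp(X, center = TRUE, scale. = TRUE)
    X <- pca$x
  }
  obs <- subclade_disparity(tree, X, tol = tol)
  # BM rate matrix (ML) from the scores
  C <- ape::vcv(tree)[rownames(X), rownames(X)]
  Cinv <- solve(C)
  mu <- colSums(Cinv %*% X) / sum(Cinv)
  R0 <- sweep(X, 2, mu)
  Rate <- crossprod(R0, Cinv %*% R0) / nrow(X)
  cholC <- chol(C)
  cholR <- tryCatch(chol(Rate), error = function(e) {
    ei <- eigen(Rate, symmetric = TRUE)
    ei$vectors %*% diag(sqrt(pmax(ei$values, 0))) %*% t(ei$vectors)
  })
  n <- nrow(X); p <- ncol(X)
  total_obs <- NULL
  sims <- with_seed_restore(seed, {
    lapply(seq_len(n_sim), function(s) {
      Z <- matrix(rnorm(n * p), n, p)
      Y <- t(cholC) %*% Z %*% cholR
      rownames(Y) <- rownames(X)
      dtt_curve(tree, Y, avg_sq_dist(Y))$disparity
    })
  })
  simmat <- do.call(cbind, sims)
  med <- apply(simmat, 1, median)
  alpha <- (1 - level) / 2
  lower <- apply(simmat, 1, quantile, probs = alpha)
  upper <- apply(simmat, 1, quantile, probs = 1 - alpha)
  times <- obs$time
  win <- if (is.null(interval)) rep(TRUE, length(times)) else
    times >= interval[1] & times <= interval[2]
  mdi_obs <- trapezoid(times[win], (obs$disparity - med)[win])
  mdi_sim <- vapply(seq_len(n_sim), function(s) {
    trapezoid(times[win], (simmat[, s] - med)[win])
  }, numeric(1))
  structure(list(
    observed = obs,
    median = med, lower = lower, upper = upper,
    mdi = mdi_obs,
    p_value = (sum(mdi_sim >= mdi_obs) + 1) / (n_sim + 1),
    mdi_sim = mdi_sim, n_sim = n_sim, seed = seed
  ), class = "dtt_result")
}

trapezoid <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @export
print.dtt_result <- function(x, ...) {
  cat(sprintf("<dtt_result> MDI = %.4f, p = %.3g (%d BM simulations)\n",
              x$mdi, x$p_value, x$n_sim))
  invisible(x)
}

#' @describeIn dtt_bm Curve tibble: time, observed, median and envelope.
#' @param x A `dtt_result`.
#' @param ... Unused.
#' @method tidy dtt_result
#' @export
tidy.dtt_result <- function(x, ...) {
  tibble(time = x$observed$time, observed = x$observed$disparity,
         median = x$median, lower = x$lower, upper = x$upper)
}

#' @describeIn dtt_bm One-row summary with the MDI and its p-value.
#' @method glance dtt_result
#' @export
glance.dtt_result <- function(x, ...) {
  tibble(mdi = x$mdi, p_value = x$p_value, n_sim = x$n_sim)
}

#' @describeIn dtt_bm Observed curve over the BM median and envelope.
#' @param object A `dtt_result`.
#' @method autoplot dtt_result
#' @export
autoplot.dtt_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed)) +
    ggplot2::labs(x = "relative time", y = "mean subclade disparity") +
    ggplot2::theme_minimal()
}
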