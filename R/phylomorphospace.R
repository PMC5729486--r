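#' Ancestral states under Brownian motion
#'
#' Maximum-likelihood (equivalently BLUP) estimates of internal-node states
#' under Brownian motion: the GLS root estimate plus the conditional
#' expectation given the tips, using shared path lengths between each
#' internal node and each tip. Estimates do not depend on the BM rate.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param x Species-by-trait matrix (columns = traits) or named vector.
#' @return Matrix of internal-node states (rows ordered as node numbers
#'   `n+1 ... n+Nnode`).
#' @export
bm_ancestral_states <- function(tree, x) {
  X <- align_tips(tree, x)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1, dimnames = list(names(X), "x"))
  n <- length(tree$tip.label)
  heights <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  C <- ape::vcv(tree)[rownames(X), rownames(X)]
  Cinv <- solve(C)
  mu <- colSums(Cinv %*% X) / sum(Cinv)
  internal <- seq(n + 1, n + tree$Nnode)
  tip_idx <- match(rownames(X), tree$tip.label)
  S <- matrix(heights[M[internal, tip_idx]], nrow = tree$Nnode)
  R <- sweep(X, 2, mu)
  A <- sweep(S %*% (Cinv %*% R), 2, mu, "+")
  rownames(A) <- as.character(internal)
  colnames(A) <- colnames(X)
  A
}

#' Phylomorphospace of the network parameters
#'
#' Principal component analysis of the species-by-parameter matrix
#' (correlation-matrix PCA by default, since the parameters differ by orders
#' of magnitude), with the phylogeny projected into PC space through
#' Brownian-motion ancestral-state estimates, so branches can be drawn
#' between species points.
#'
#' @param tree An `ape::phylo` tree.
#' @param x Species-by-trait data (tibble with `species` column or named
#'   matrix).
#' @param scale. Use the correlation matrix (`TRUE`, default) or the raw
#'   covariance matrix.
#' @return A list of class `phylomorphospace` with `scores` (tip PC scores),
#'   `anc_scores` (internal nodes), `percent_var`, `rotation` and the tree.
#' @examples
#' tree <- generate_tree(12, seed = 1)
#' d <- simulate_traits(tree, "BM", seed = 1, n_traits = 4)
#' pm <- phylomorphospace(tree, d)
#' round(pm$percent_var, 1)
#' @export
phylomorphospace <- function(tree, x, scale. = TRUE) {
  X <- align_tips(tree, if (is.matrix(x)) x else trait_matrix(x))
  if (any(apply(X, 2, var) == 0)) abort("constant trait column")
  pca <- prcomp(X, center = TRUE, scale. = scale.)
  pct <- 100 * pca$sdev^2 / sum(pca$sdev^2)
  anc <- bm_ancestral_states(tree, X)
  anc_sc <- scale(anc, center = pca$center,
                  scale = if (isTRUE(scale.)) pca$scale else FALSE) %*%
    pca$rotation
  structure(list(scores = pca$x, anc_scores = anc_sc,
                 percent_var = setNames(pct, colnames(pca$x)),
                 rotation = pca$rotation, tree = tree),
            class = "phylomorphospace")
}

#' @export
print.phylomorphospace <- function(x, ...) {
  cat(sprintf("<phylomorphospace> %d species, PC1 = %.0f%%, PC2 = %.0f%%\n",
              nrow(x$scores), x$percent_var[1],
              if (length(x$percent_var) > 1) x$percent_var[2] else NA))
  invisible(x)
}

#' @describeIn phylomorphospace Tip scores as a tibble with percent variance
#'   attached as an attribute.
#' @param x A `phylomorphospace`.
#' @param ... Unused.
#' @method tidy phylomorphospace
#' @export
tidy.phylomorphospace <- function(x, ...) {
  out <- as_tibble(x$scores, rownames = "species")
  attr(out, "percent_var") <- x$percent_var
  out
}

#' @describeIn phylomorphospace Scatter of PC1/PC2 with the phylogeny's
#'   branches drawn through ancestral projections.
#' @param object A `phylomorphospace`.
#' @method autoplot phylomorphospace
#' @export
autoplot.phylomorphospace <- function(object, ...) {
  tree <- object$tree
  n <- length(tree$tip.label)
  coords <- rbind(object$scores[tree$tip.label, 1:2, drop = FALSE],
                  object$anc_scores[, 1:2, drop = FALSE])
  rownames(coords) <- c(tree$tip.label, rownames(object$anc_scores))
  node_xy <- function(i) {
    if (i <= n) coords[tree$tip.label[i], ] else coords[as.character(i), ]
  }
  segm <- t(apply(tree$edge, 1, function(e) c(node_xy(e[1]), node_xy(e[2]))))
  colnames(segm) <- c("x", "y", "xend", "yend")
  seg <- as_tibble(segm)
  tips <- as_tibble(object$scores[, 1:2, drop = FALSE], rownames = "species")
  names(tips)[2:3] <- c("PC1", "PC2")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(data = tips,
                        ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", object$percent_var[1]),
      y = sprintf("PC2 (%.0f%%)", object$percent_var[2])) +
    ggplot2::theme_minimal()
}
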