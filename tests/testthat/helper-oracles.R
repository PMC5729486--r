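# Brute-force oracles and small fixtures, independent of the package's
# implementation paths.

# mean local clustering by explicit triangle enumeration on the adjacency matrix
oracle_clustering <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) { vals[i] <- 0; next }
    tri <- 0
    for (a in seq_along(nb)) for (b in seq_len(a - 1)) {
      if (A[nb[a], nb[b]] == 1) tri <- tri + 1
    }
    vals[i] <- tri / (k * (k - 1) / 2)
  }
  mean(vals)
}

# mean shortest path over unordered pairs by hand-rolled BFS
oracle_path_length <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  total <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(A[v, ] == 1)) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    stopifnot(!anyNA(dist))
    total <- total + sum(dist)
  }
  total / (n * (n - 1))
}

oracle_heterogeneity <- function(g, population = TRUE) {
  k <- igraph::degree(g)
  n <- length(k)
  v <- sum((k - mean(k))^2) / (if (population) n else n - 1)
  sqrt(v) / mean(k)
}

# direct evaluation of Newman-Girvan Q from the edge list
oracle_q <- function(g, memb) {
  el <- igraph::as_edgelist(g, names = FALSE)
  K <- nrow(el)
  deg <- igraph::degree(g)
  mods <- unique(memb)
  q <- 0
  for (m in mods) {
    within <- sum(memb[el[, 1]] == m & memb[el[, 2]] == m)
    dm <- sum(deg[memb == m])
    q <- q + within / K - (dm / (2 * K))^2
  }
  q
}

# all set partitions of 1..n as restricted-growth strings
enumerate_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1)) grow(c(prefix, v), max(maxv, v))
  }
  grow(integer(0), 0L)
  out
}

exhaustive_best_q <- function(g) {
  parts <- enumerate_partitions(igraph::vcount(g))
  qs <- vapply(parts, function(p) oracle_q(g, p), numeric(1))
  i <- which.max(qs)
  list(q = qs[i], membership = parts[[i]])
}

# connected Erdos-Renyi graph (resamples until connected)
random_connected_graph <- function(n, p) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) >= 1) {
      igraph::V(g)$name <- paste0("v", seq_len(n))
      return(g)
    }
  }
}

named_graph <- function(g) {
  if (is.null(igraph::V(g)$name)) igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  g
}

two_cliques_bridge <- function(k = 3) {
  g <- igraph::make_full_graph(k) + igraph::make_full_graph(k)
  g <- igraph::add_edges(g, c(1, k + 1))
  named_graph(g)
}

clique_ring <- function(n_cliques = 4, size = 5) {
  g <- igraph::make_full_graph(size)
  for (i in seq_len(n_cliques - 1)) g <- g + igraph::make_full_graph(size)
  for (i in seq_len(n_cliques)) {
    a <- (i - 1) * size + 1
    b <- (i %% n_cliques) * size + 2
    g <- igraph::add_edges(g, c(a, b))
  }
  named_graph(g)
}

# tiny vocabulary so toy networks do not warn about unknown labels
toy_vocab <- function(ids) data.frame(token = ids, tissue = "bone")

toy_network <- function(ids, from, to, species = "toy") {
  anatomical_network(species, ids, data.frame(from = from, to = to),
                     vocabulary = toy_vocab(ids))
}

fixture_params <- function() mammal_neck_parameters()
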