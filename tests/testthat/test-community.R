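test_that("modularity Q matches hand evaluation and the direct oracle", {
  g <- two_cliques_bridge(3)
  memb <- setNames(rep(1:2, each = 3), igraph::V(g)$name)
  expect_equal(modularity_q(g, memb), 6 / 7 - 1 / 2)
  # single module telescopes to zero
  expect_equal(modularity_q(g, setNames(rep(1, 6), igraph::V(g)$name)), 0)
  # independent transcription of the formula, plus igraph cross-check
  expect_equal(modularity_q(g, memb), oracle_q(g, unname(memb[igraph::V(g)$name])))
  expect_equal(modularity_q(g, memb),
               igraph::modularity(g, unname(memb[igraph::V(g)$name])))
  # invariant under module relabeling
  expect_equal(modularity_q(g, setNames(c(9, 9, 9, 4, 4, 4), igraph::V(g)$name)),
               modularity_q(g, memb))
})

test_that("random partitions of a random graph score near zero on average", {
  set.seed(7)
  g <- random_connected_graph(30, 0.2)
  qs <- replicate(100, {
    memb <- sample(1:4, 30, replace = TRUE)
    modularity_q(g, memb)
  })
  expect_lt(mean(abs(qs)), 0.1)
})

test_that("annealing recovers planted partitions", {
  g <- two_cliques_bridge(4)
  part <- detect_modules(g, seed = 1)
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(length(unique(part$membership[1:4])), 1)
  expect_equal(length(unique(part$membership[5:8])), 1)

  ring <- clique_ring(4, 5)
  part2 <- detect_modules(ring, seed = 3)
  expect_equal(length(unique(part2$membership)), 4)
  for (i in 0:3) {
    expect_equal(length(unique(part2$membership[i * 5 + 1:5])), 1)
  }
})

test_that("annealing attains the exhaustive optimum on small graphs (best of 10 seeds)", {
  # exhaustive search over all set partitions; graphs scaled to n <= 8 so the
  # enumeration (Bell(8) = 4140 partitions per graph) stays fast in plain R
  set.seed(99)
  graphs <- list(two_cliques_bridge(3),
                 named_graph(igraph::make_ring(7)),
                 random_connected_graph(7, 0.4),
                 random_connected_graph(8, 0.35),
                 named_graph(igraph::make_star(6, mode = "undirected")))
  for (g in graphs) {
    best <- exhaustive_best_q(g)
    qs <- vapply(1:10, function(s) detect_modules(g, seed = s,
                                                  with_stats = FALSE)$Q,
                 numeric(1))
    expect_equal(max(qs), best$q, tolerance = 1e-10)
  }
})

test_that("detected Q dominates the trivial and random partitions", {
  fixtures <- list(two_cliques_bridge(4), clique_ring(3, 4),
                   as_igraph(generate_network(neck_template(), seed = 5)))
  set.seed(11)
  for (g in fixtures) {
    part <- detect_modules(g, seed = 2, with_stats = FALSE)
    expect_gte(part$Q, 0)                                     # single module
    n <- igraph::vcount(g)
    rand_q <- replicate(100, modularity_q(g, sample(1:5, n, replace = TRUE)))
    expect_true(all(part$Q >= rand_q))
    expect_true(part$Q >= -0.5 && part$Q < 1)
  }
})

test_that("detection is deterministic given seed and schedule", {
  g <- as_igraph(generate_network(neck_template(), seed = 8))
  a <- detect_modules(g, seed = 4, with_stats = FALSE)
  b <- detect_modules(g, seed = 4, with_stats = FALSE)
  expect_identical(a$membership, b$membership)
  expect_identical(a$Q, b$Q)
})

test_that("jackknife error matches brute-force leave-one-link-out recomputation", {
  g <- two_cliques_bridge(3)
  memb <- setNames(rep(1:2, each = 3), igraph::V(g)$name)
  # brute force: delete each edge in turn and recompute Q from scratch
  el <- igraph::as_edgelist(g, names = FALSE)
  q_loo <- vapply(seq_len(nrow(el)), function(e) {
    h <- igraph::delete_edges(g, e)
    oracle_q(h, unname(memb[igraph::V(g)$name]))
  }, numeric(1))
  K <- nrow(el)
  expected <- sqrt((K - 1) / K * sum((q_loo - mean(q_loo))^2))
  expect_equal(jackknife_q_error(g, memb), expected, tolerance = 1e-12)

  # edge-transitive graph with a symmetric partition: orbits give a closed form
  ring <- named_graph(igraph::make_ring(6))
  memb_r <- setNames(c(1, 1, 1, 2, 2, 2), igraph::V(ring)$name)
  q_loo_r <- vapply(1:6, function(e) {
    oracle_q(igraph::delete_edges(ring, e), unname(memb_r))
  }, numeric(1))
  expect_equal(jackknife_q_error(ring, memb_r),
               sqrt(5 / 6 * sum((q_loo_r - mean(q_loo_r))^2)), tolerance = 1e-12)

  # single-module partition: all leave-one-out Q are zero
  expect_equal(jackknife_q_error(g, setNames(rep(1, 6), igraph::V(g)$name)), 0)
})

test_that("strong-modularity threshold is a strict inequality on Q - error", {
  expect_true(is_strongly_modular(0.5, 0.05))
  expect_false(is_strongly_modular(0.31, 0.02))
  expect_false(is_strongly_modular(0.3, 0.0))
})

test_that("module significance is the one-sided rank-sum on internal vs external links", {
  # planted 4-clique with no external links: complete separation, p = 1/C(8,4)
  g <- two_cliques_bridge(4)
  memb <- setNames(rep(1:2, each = 4), igraph::V(g)$name)
  stats <- module_significance(g, memb)
  expect_equal(nrow(stats), 2)
  # module 2 of the bridge fixture: nodes have internal 3,3,3,3, external 0,0,0,1
  expect_lt(stats$p_value[2], 0.05)
  # identical internal and external counts: null symmetric, p >= 0.5
  ring <- named_graph(igraph::make_ring(8))
  memb_r <- setNames(rep(1:4, each = 2), igraph::V(ring)$name)  # pairs: 1 in, 1 out... per node
  st <- module_significance(ring, memb_r)
  expect_true(all(st$p_value >= 0.5))
  # perfectly separated clique: exact minimal one-sided p
  cl <- named_graph(igraph::make_full_graph(4))
  stc <- module_significance(cl, setNames(rep(1, 4), igraph::V(cl)$name))
  expect_equal(stc$p_value, 1 / choose(8, 4))
  expect_equal(stc$internal_links, 6)
  expect_equal(stc$external_links, 0)
})

test_that("rank-sum p-values are roughly uniform under random partitions", {
  set.seed(5)
  g <- random_connected_graph(40, 0.25)
  ps <- replicate(300, {
    memb <- sample(rep(1:2, each = 20))
    st <- module_significance(g, memb)
    st$p_value[1]
  })
  # the rank-sum p is discrete, so check calibration rather than exact
  # uniformity: no inflation of small p-values, centre near 1/2
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("consensus over seeds returns the best partition and coassignment", {
  g <- two_cliques_bridge(4)
  cons <- consensus_modules(g, seeds = 1:5)
  expect_equal(nrow(cons$runs), 5)
  expect_equal(cons$Q, max(cons$runs$Q))
  co <- cons$coassignment
  expect_true(all(diag(co) == 1))
  expect_true(all(co >= 0 & co <= 1))
  # clique mates always co-assigned
  expect_equal(co[1, 2], 1)
})

test_that("module stats counts are consistent with the edge set", {
  g <- as_igraph(generate_network(neck_template(), seed = 13))
  part <- detect_modules(g, seed = 1)
  st <- part$module_stats
  expect_equal(sum(st$n_nodes), igraph::vcount(g))
  # every edge is either internal to one module or external to exactly two
  expect_equal(sum(st$internal_links) + sum(st$external_links) / 2,
               igraph::ecount(g))
  expect_equal(net_parcellation(part), glance(part)$parcellation)
})
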