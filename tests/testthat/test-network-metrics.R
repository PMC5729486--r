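triangle <- function() named_graph(igraph::make_full_graph(3))
path3 <- function() named_graph(igraph::make_graph(~ a - b - c))
star4 <- function() named_graph(igraph::make_star(4, mode = "undirected"))

test_that("density matches its closed form", {
  expect_equal(net_density(triangle()), 1)
  expect_equal(net_density(star4()), 0.5)
  expect_error(net_density(named_graph(igraph::make_empty_graph(1, directed = FALSE))),
               "2 nodes")
})

test_that("clustering handles low-degree nodes by the stated conventions", {
  expect_equal(net_clustering(triangle()), 1)
  expect_equal(net_clustering(path3()), 0)
  # 4-cycle plus one diagonal: hand enumeration gives 5/6
  g <- named_graph(igraph::make_graph(~ a - b, b - c, c - d, d - a, a - c))
  expect_equal(net_clustering(g), 5 / 6)
  expect_equal(net_clustering(g), oracle_clustering(g))
  # triangle plus pendant: locals are {1, 1, 1/3, NaN}
  h <- named_graph(igraph::make_graph(~ a - b, b - c, c - a, c - d))
  expect_equal(net_clustering(h, low_degree = "zero"), 7 / 12)
  expect_equal(net_clustering(h, low_degree = "zero"), oracle_clustering(h))
  expect_equal(net_clustering(h, low_degree = "drop"), 7 / 9)
})

test_that("path length matches the BFS oracle and both conventions", {
  expect_equal(net_path_length(triangle()), 1)
  expect_equal(net_path_length(path3()), 4 / 3)
  expect_equal(net_path_length(star4()), 1.5)
  expect_equal(net_path_length(path3(), convention = "printed_sum"), 4 / 2)
  g <- named_graph(igraph::make_graph(~ a - b, c - d))
  expect_error(net_path_length(g), "disconnected")
})

test_that("heterogeneity follows the chosen SD convention", {
  expect_equal(net_heterogeneity(triangle()), 0)
  expect_equal(net_heterogeneity(named_graph(igraph::make_ring(6))), 0)
  expect_equal(round(net_heterogeneity(star4(), sd_type = "population"), 3), 0.577)
  expect_equal(round(net_heterogeneity(star4(), sd_type = "sample"), 3), 0.667)
})

test_that("parcellation evaluates module-size fractions", {
  expect_equal(net_parcellation(10), 0)
  expect_equal(net_parcellation(c(5, 5)), 0.5)
  expect_equal(net_parcellation(c(4, 3, 3)), 0.66)
  # invariant under module and node relabeling
  memb <- setNames(c(1, 1, 2, 2, 3), letters[1:5])
  perm <- setNames(c(7, 7, 1, 1, 4), letters[c(3, 4, 1, 2, 5)])
  expect_equal(net_parcellation(memb), net_parcellation(perm))
})

test_that("C, L, H agree with brute-force oracles on random graphs", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    g <- random_connected_graph(n, runif(1, 0.15, 0.5))
    expect_equal(net_clustering(g), oracle_clustering(g), tolerance = 1e-12)
    expect_equal(net_path_length(g), oracle_path_length(g), tolerance = 1e-12)
    expect_equal(net_heterogeneity(g), oracle_heterogeneity(g), tolerance = 1e-12)
    # structural invariants
    expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
    expect_gte(net_path_length(g), 1)
    d <- net_density(g)
    expect_true(d > 0 && d <= 1)
  }
})

test_that("L equals 1 exactly on complete graphs", {
  g <- named_graph(igraph::make_full_graph(7))
  expect_equal(net_path_length(g), 1)
})

test_that("compute_all assembles the full parameter vector", {
  out <- network_parameters(triangle(), partition = c(a = 1, b = 1, c = 1))
  expect_equal(unlist(out[c("N", "K", "D", "C", "L", "H", "P")]),
               c(N = 3, K = 3, D = 1, C = 1, L = 1, H = 0, P = 0))
  # P is absent without a partition
  expect_true(is.na(network_parameters(triangle())$P))
  # dual-implementation check on a synthetic network
  syn <- generate_network(neck_template(), seed = 11)
  g <- as_igraph(syn)
  row <- network_parameters(syn)
  expect_equal(row$N, igraph::vcount(g))
  expect_equal(row$K, igraph::ecount(g))
  expect_equal(row$D, 2 * row$K / (row$N * (row$N - 1)))
  expect_equal(row$C, oracle_clustering(g), tolerance = 1e-12)
  expect_equal(row$L, oracle_path_length(g), tolerance = 1e-12)
  expect_equal(row$H, oracle_heterogeneity(g), tolerance = 1e-12)
})

test_that("parameter table stacks species rows", {
  nets <- list(a = generate_network(neck_template(), seed = 1, species = "a"),
               b = generate_network(neck_template(), seed = 2, species = "b"))
  tab <- network_parameter_table(nets)
  expect_equal(tab$species, c("a", "b"))
  expect_equal(ncol(tab), 8)
})
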