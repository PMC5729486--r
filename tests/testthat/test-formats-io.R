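test_that("a labelled 0/1 matrix reads into the expected network", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",cr,C1,rmi", "cr,0,1,1", "C1,1,0,1", "rmi,1,1,0"), f)
  net <- read_adjacency_matrix(f, species = "toy")
  expect_s3_class(net, "anatomical_network")
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 3)
  expect_setequal(net$nodes$tissue[match(c("cr", "C1", "rmi"), net$nodes$id)],
                  c("bone", "bone", "muscle"))
})

test_that("malformed matrices are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",a,b,c", "a,0,1,0", "b,1,0,1"), f)      # not square
  expect_error(read_adjacency_matrix(f, "x"), "square")
  writeLines(c(",a,a", "a,0,1", "a,1,0"), f)            # duplicate labels
  expect_error(read_adjacency_matrix(f, "x"), "unique")
  writeLines(c(",a,b", "a,0,2", "b,2,0"), f)            # non-binary
  expect_error(read_adjacency_matrix(f, "x"), "0 or 1")
  writeLines(c(",a,b", "b,0,1", "a,1,0"), f)            # label order mismatch
  expect_error(read_adjacency_matrix(f, "x"), "labels")
})

test_that("asymmetric cells are OR-symmetrized with a warning, idempotently", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",cr,C1,C2", "cr,0,1,0", "C1,1,0,1", "C2,1,1,0"), f)
  expect_warning(net <- read_adjacency_matrix(f, "asym"), "symmetrized")
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",cr,C1,C2", "cr,0,1,1", "C1,1,0,1", "C2,1,1,0"), g)
  ref <- read_adjacency_matrix(g, "asym")
  expect_equal(net$edges, ref$edges)
  # symmetrization is idempotent: re-writing and re-reading changes nothing
  h <- withr::local_tempfile(fileext = ".csv")
  write_adjacency_matrix(net, h)
  expect_equal(read_adjacency_matrix(h, "asym")$edges, net$edges)
})

test_that("nonzero diagonal entries are dropped with a warning", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",cr,C1", "cr,1,1", "C1,1,0"), f)
  expect_warning(net <- read_adjacency_matrix(f, "loopy"), "diagonal")
  expect_equal(nrow(net$edges), 1)
})

test_that("read-write round trip is the identity, including on synthetic networks", {
  f <- withr::local_tempfile(fileext = ".csv")
  net <- suppressWarnings(toy_network(c("a", "b"), character(0), character(0)))
  write_adjacency_matrix(net, f)
  mat <- as.matrix(readr::read_csv(f, show_col_types = FALSE,
                                   name_repair = "minimal")[, -1])
  expect_true(all(mat == 0))

  for (seed in 1:3) {
    syn <- generate_network(neck_template(), seed = seed)
    write_adjacency_matrix(syn, f)
    back <- read_adjacency_matrix(f, species = syn$species)
    expect_equal(back$edges, syn$edges)
    expect_equal(back$nodes, syn$nodes)
    # degree multisets survive the round trip
    expect_equal(sort(igraph::degree(as_igraph(back))),
                 sort(igraph::degree(as_igraph(syn))))
  }
})

test_that("tissue and side are inferred from the label vocabulary", {
  meta <- infer_node_metadata(c("trr", "scl", "cl", "ln", "C3", "ty", "col"))
  expect_equal(meta$tissue,
               c("muscle", "bone", "bone", "ligament", "bone",
                 "cartilage/other", "muscle"))
  expect_equal(meta$side,
               c("right", "left", "midline", "midline", "midline", "midline",
                 "midline"))
  expect_warning(meta2 <- infer_node_metadata("mysterymuscle"), "unknown")
  expect_equal(meta2$tissue, "muscle")
})

test_that("disconnected input is a warning, not an error", {
  expect_warning(
    toy_network(c("a", "b", "c", "d"), c("a", "c"), c("b", "d")),
    "not connected")
})

test_that("Newick trees are read and cross-checked against species", {
  tree <- read_tree("((A:1,B:1):1,C:2);")
  expect_equal(length(tree$tip.label), 3)
  expect_true(is_ultrametric_tol(tree))
  expect_equal(max(ape::node.depth.edgelength(tree)), 2)
  expect_error(read_tree("((A,B),C);"), "branch lengths")

  mism <- check_tree_tips(tree, c("A", "B"))
  expect_equal(mism$name, "C")
  expect_equal(mism$status, "tip_only")
  expect_equal(nrow(check_tree_tips(tree, c("A", "B", "C"))), 0)

  big <- generate_tree(48, seed = 7)
  expect_equal(length(big$tip.label), 48)
  expect_true(is_ultrametric_tol(big, 1e-9))
})

test_that("covariate files are validated", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,body_mass_kg,neck_length,predatory",
               "A,10,0.3,1", "B,5,0.2,0"), f)
  cov <- read_covariates(f, network_species = c("A", "B", "C"))
  expect_identical(cov$predatory, c(TRUE, FALSE))
  expect_error(read_covariates(f, network_species = "A"), "not in the network")
  writeLines("species,body_mass_kg\nA,1", f)
  expect_error(read_covariates(f), "misses columns")
})
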