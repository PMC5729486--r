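#' Read an adjacency matrix into an anatomical network
#'
#' Reads a labelled, square 0/1 adjacency matrix from a delimited text file
#' (CSV/TSV with node labels both as header and as first column) or from one
#' sheet of a multi-sheet workbook in which each sheet holds one species
#' (`sheet` selects it; requires the readxl package). The upper triangle
#' defines the link set. An asymmetric matrix is symmetrized by logical OR
#' with a warning; nonzero diagonal entries are ignored with a warning.
#'
#' @param source Path to the file.
#' @param species Species name attached to the network; defaults to the file
#'   base name (or the sheet name for workbooks).
#' @param sheet Sheet name or index for workbook input; `NULL` for delimited
#'   text.
#' @param vocabulary Label vocabulary for tissue/side inference, see
#'   [neck_element_vocabulary()].
#' @return An [anatomical_network()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(",cr,C1,rmi", "cr,0,1,1", "C1,1,0,1", "rmi,1,1,0"), f)
#' read_adjacency_matrix(f, species = "toy")
#' @export
read_adjacency_matrix <- function(source, species = NULL, sheet = NULL,
                                  vocabulary = neck_element_vocabulary()) {
  if (!is.null(sheet) || grepl("\\.(xls|xlsx)$", source, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("reading workbooks requires the 'readxl' package")
    }
    if (is.null(sheet)) sheet <- 1L
    raw <- readxl::read_excel(source, sheet = sheet, col_names = TRUE)
    if (is.null(species)) {
      species <- if (is.character(sheet)) sheet else
        readxl::excel_sheets(source)[sheet]
    }
  } else {
    delim <- if (grepl("\\.tsv$", source, ignore.case = TRUE)) "\t" else ","
    raw <- readr::read_delim(source, delim = delim, col_names = TRUE,
                             show_col_types = FALSE,
                             name_repair = "minimal")
    if (is.null(species)) {
      species <- sub("\\.[^.]+$", "", basename(source))
    }
  }
  labels_row <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  labels_col <- colnames(mat)
  if (nrow(mat) != ncol(mat)) {
    abort(sprintf("adjacency matrix must be square, got %d x %d",
                  nrow(mat), ncol(mat)))
  }
  if (!identical(labels_row, labels_col)) {
    abort("row labels and column labels differ (same order required)")
  }
  if (anyDuplicated(labels_row)) abort("node labels are not unique")
  storage.mode(mat) <- "numeric"
  if (anyNA(mat) || !all(mat %in% c(0, 1))) {
    abort("adjacency matrix cells must all be 0 or 1")
  }
  dimnames(mat) <- list(labels_row, labels_row)
  adjacency_to_network(mat, species, vocabulary)
}

# shared core: validated numeric 0/1 matrix -> network
adjacency_to_network <- function(mat, species, vocabulary = neck_element_vocabulary()) {
  if (any(diag(mat) != 0)) {
    warn(sprintf("%d nonzero diagonal entries ignored", sum(diag(mat) != 0)))
    diag(mat) <- 0
  }
  if (!isTRUE(all.equal(mat, t(mat)))) {
    warn("asymmetric adjacency matrix symmetrized by logical OR")
    mat <- 1 * ((mat + t(mat)) > 0)
  }
  idx <- which(upper.tri(mat) & mat == 1, arr.ind = TRUE)
  labels <- rownames(mat)
  edges <- tibble(from = labels[idx[, 1]], to = labels[idx[, 2]])
  anatomical_network(species, labels, edges, vocabulary = vocabulary)
}

#' Write an anatomical network as a labelled adjacency matrix
#'
#' The inverse of [read_adjacency_matrix()]: reading the written file yields
#' a network with the same node set, edge set and inferred metadata.
#'
#' @param net An [anatomical_network()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_adjacency_matrix <- function(net, path) {
  stopifnot(inherits(net, "anatomical_network"))
  ids <- net$nodes$id
  mat <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$edges) > 0) {
    i <- match(net$edges$from, ids)
    j <- match(net$edges$to, ids)
    mat[cbind(i, j)] <- 1L
    mat[cbind(j, i)] <- 1L
  }
  df <- as.data.frame(mat)
  df <- cbind(tibble(` ` = ids), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a time-calibrated phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contract the
#' comparative analyses need: named tips and branch lengths. Use
#' [check_tree_tips()] to cross-check tip names against a species table.
#'
#' @param source Path to a Newick file, or a Newick string.
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(source) {
  tree <- if (file.exists(source)) ape::read.tree(source) else
    ape::read.tree(text = source)
  if (is.null(tree)) abort("could not parse Newick input")
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths; comparative analyses require them")
  }
  if (anyDuplicated(tree$tip.label)) abort("tip names are not unique")
  tree
}

#' Cross-check tree tips against dataset species
#'
#' @param tree An `ape::phylo` tree.
#' @param species Character vector of species names in the dataset.
#' @return A tibble with columns `name` and `status` (`"tip_only"` for tips
#'   absent from the dataset, `"species_only"` for species absent from the
#'   tree); zero rows when the two sets agree.
#' @export
check_tree_tips <- function(tree, species) {
  tip_only <- setdiff(tree$tip.label, species)
  sp_only <- setdiff(species, tree$tip.label)
  tibble(name = c(tip_only, sp_only),
         status = c(rep("tip_only", length(tip_only)),
                    rep("species_only", length(sp_only))))
}

#' Is a tree ultrametric within a relative tolerance?
#'
#' @param tree An `ape::phylo` tree.
#' @param tol Maximum allowed relative deviation of tip depths.
#' @return Logical scalar.
#' @export
is_ultrametric_tol <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  diff(range(depths)) <= tol * max(depths)
}

#' Read per-species covariates
#'
#' Expects a CSV with columns `species`, `body_mass_kg`, `neck_length` and
#' `predatory` (0/1 or logical). Species must be a subset of the network
#' species when a dataset is given.
#'
#' @param path CSV path.
#' @param network_species Optional character vector to validate against.
#' @return A tibble.
#' @export
read_covariates <- function(path, network_species = NULL) {
  cov <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("species", "body_mass_kg", "neck_length", "predatory")
  miss <- setdiff(needed, names(cov))
  if (length(miss) > 0) {
    abort(sprintf("covariate file misses columns: %s",
                  paste(miss, collapse = ", ")))
  }
  cov$predatory <- as.logical(cov$predatory)
  if (!is.null(network_species)) {
    extra <- setdiff(cov$species, network_species)
    if (length(extra) > 0) {
      abort(sprintf("covariate species not in the network set: %s",
                    paste(extra, collapse = ", ")))
    }
  }
  cov
}
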