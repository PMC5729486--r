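#' Network parameters of an anatomical network
#'
#' The seven descriptors used throughout the package to summarise the
#' topology of a musculoskeletal network:
#' \describe{
#'   \item{N}{number of nodes (anatomical elements).}
#'   \item{K}{number of links (articulations and attachments); interpreted as
#'     the amount of anatomical dependences, i.e. burden or constraint.}
#'   \item{D}{density of connections, \eqn{D = 2K / (N(N-1))}; a proxy of
#'     morphological complexity.}
#'   \item{C}{mean local clustering coefficient (relative amount of 3-node
#'     loops); integration by co-dependency.}
#'   \item{L}{mean shortest path length; integration by effective proximity.}
#'   \item{H}{degree heterogeneity \eqn{\sigma_k/\mu_k}; anisomerism, the
#'     unevenness of connections across elements.}
#'   \item{P}{parcellation \eqn{1 - \sum_m (N_m/N)^2} over connectivity
#'     modules; degree of modularity (requires a partition).}
#' }
#'
#' @name network-metrics
NULL

#' @describeIn network-metrics Density of connections \eqn{2K/(N(N-1))}.
#' @param net An [anatomical_network()] or igraph graph.
#' @export
net_density <- function(net) {
  g <- as_neck_graph(net)
  n <- igraph::vcount(g)
  if (n < 2) abort("density needs at least 2 nodes")
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' @describeIn network-metrics Mean local clustering coefficient. Nodes of
#'   degree < 2 contribute 0 by default (`low_degree = "zero"`); set
#'   `low_degree = "drop"` to exclude them from the average instead.
#' @param low_degree How nodes of degree < 2 enter the average.
#' @export
net_clustering <- function(net, low_degree = c("zero", "drop")) {
  low_degree <- match.arg(low_degree)
  g <- as_neck_graph(net)
  local <- igraph::transitivity(g, type = "local", isolates = "NaN")
  if (low_degree == "zero") local[is.nan(local)] <- 0 else
    local <- local[!is.nan(local)]
  if (length(local) == 0) return(0)
  mean(local)
}

#' @describeIn network-metrics Mean shortest path length. The default
#'   (`convention = "pair_mean"`) averages the geodesic distance over all
#'   unordered node pairs; `convention = "printed_sum"` divides the summed
#'   distance over unordered pairs by \eqn{N-1} instead (the non-normalised
#'   form some sources print, kept switchable for sensitivity checks).
#'   Disconnected graphs are a hard error naming the components.
#' @param convention Normalisation of the path-length sum.
#' @export
net_path_length <- function(net, convention = c("pair_mean", "printed_sum")) {
  convention <- match.arg(convention)
  g <- as_neck_graph(net)
  n <- igraph::vcount(g)
  if (n < 2) abort("path length needs at least 2 nodes")
  if (!igraph::is_connected(g)) {
    comp <- igraph::components(g)$membership
    sizes <- table(comp)
    abort(sprintf("graph is disconnected (%d components of sizes %s); L is undefined",
                  length(sizes), paste(sizes, collapse = ", ")))
  }
  d <- igraph::distances(g)
  total <- sum(d[upper.tri(d)])
  switch(convention,
         pair_mean = total / (n * (n - 1) / 2),
         printed_sum = total / (n - 1))
}

#' @describeIn network-metrics Degree heterogeneity \eqn{\sigma_k / \mu_k}.
#'   `sd_type = "population"` (default) uses the \eqn{1/N} variance;
#'   `"sample"` uses \eqn{1/(N-1)}.
#' @param sd_type Standard-deviation convention for the degree spread.
#' @export
net_heterogeneity <- function(net, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  g <- as_neck_graph(net)
  deg <- igraph::degree(g)
  if (length(deg) < 2) abort("heterogeneity needs at least 2 nodes")
  mu <- mean(deg)
  if (mu == 0) abort("heterogeneity undefined on a graph with no links")
  s <- sd(deg)
  if (sd_type == "population") s <- s * sqrt((length(deg) - 1) / length(deg))
  s / mu
}

#' @describeIn network-metrics Parcellation \eqn{1 - \sum_m (N_m/N)^2} of a
#'   module partition: 0 when all nodes share one module, approaching 1 for
#'   many evenly sized modules. `partition` may be a [detect_modules()]
#'   result, a named membership vector, or a vector of module sizes.
#' @param partition Module partition (see Details).
#' @export
net_parcellation <- function(partition) {
  sizes <- if (inherits(partition, "module_partition")) {
    as.numeric(table(partition$membership))
  } else if (length(partition) > 0 && !is.null(names(partition))) {
    as.numeric(table(partition))
  } else {
    as.numeric(partition)
  }
  if (any(is.na(sizes)) || any(sizes <= 0)) abort("invalid module sizes")
  n <- sum(sizes)
  1 - sum((sizes / n)^2)
}

#' Compute all network parameters for one network
#'
#' @param net An [anatomical_network()] or igraph graph.
#' @param partition Optional module partition for `P`; when missing, `P` is
#'   `NA`.
#' @param convention,sd_type,low_degree Conventions passed to the individual
#'   metrics (see [network-metrics]).
#' @return A one-row tibble with columns `species`, `N`, `K`, `D`, `C`, `L`,
#'   `H`, `P`.
#' @examples
#' tri <- anatomical_network("triangle", c("a", "b", "c"),
#'                           data.frame(from = c("a", "a", "b"),
#'                                      to = c("b", "c", "c")),
#'                           vocabulary = data.frame(token = c("a","b","c"),
#'                                                   tissue = "bone"))
#' network_parameters(tri)
#' @export
network_parameters <- function(net, partition = NULL,
                               convention = "pair_mean",
                               sd_type = "population",
                               low_degree = "zero") {
  g <- as_neck_graph(net)
  species <- if (inherits(net, "anatomical_network")) net$species else NA_character_
  tibble(
    species = species,
    N = igraph::vcount(g),
    K = igraph::ecount(g),
    D = net_density(g),
    C = net_clustering(g, low_degree = low_degree),
    L = net_path_length(g, convention = convention),
    H = net_heterogeneity(g, sd_type = sd_type),
    P = if (is.null(partition)) NA_real_ else net_parcellation(partition)
  )
}

#' Network parameter table for a set of species networks
#'
#' @param networks A (named) list of [anatomical_network()] objects.
#' @param partitions Optional list of partitions, matched by position or name.
#' @param ... Convention flags passed to [network_parameters()].
#' @return A tibble with one row per network, ready for the comparative
#'   analyses ([blomberg_k()], [cv_report()], [dtt_bm()], ...).
#' @export
network_parameter_table <- function(networks, partitions = NULL, ...) {
  rows <- imap(networks, function(net, nm) {
    part <- if (is.null(partitions)) NULL else partitions[[nm]]
    row <- network_parameters(net, partition = part, ...)
    if (is.na(row$species) && is.character(nm)) row$species <- nm
    row
  })
  bind_rows(rows)
}

#' Species-by-trait matrix from a parameter table
#'
#' Utility to turn a tidy parameter table (one species column plus numeric
#' trait columns) into the named matrix the comparative functions consume.
#'
#' @param data A data frame with a species identifier column.
#' @param species_col Name of that column.
#' @param traits Which columns to keep (default: all numeric columns).
#' @return A numeric matrix with species as row names.
#' @export
trait_matrix <- function(data, species_col = "species", traits = NULL) {
  data <- as.data.frame(data)
  if (!species_col %in% names(data)) {
    abort(sprintf("no column '%s' in data", species_col))
  }
  rn <- as.character(data[[species_col]])
  keep <- if (is.null(traits)) {
    names(data)[vapply(data, is.numeric, logical(1))]
  } else traits
  m <- as.matrix(data[, keep, drop = FALSE])
  rownames(m) <- rn
  m
}
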