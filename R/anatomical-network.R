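#' Build an anatomical network
#'
#' An anatomical network is a simple undirected graph whose nodes are the
#' bones, muscles and other passive elements (ligaments, cartilage) of a
#' musculoskeletal system and whose links are their physical contacts:
#' articulations between bones and fleshy or tendinous attachments of muscles
#' onto bones. Nodes carry a tissue type and a side label; bilateral elements
#' are split into left and right nodes with an `"l"`/`"r"` suffix.
#'
#' @param species Species (or other unit) name.
#' @param nodes A data frame with columns `id` and optionally `tissue` and
#'   `side`; missing metadata is inferred from the label vocabulary with
#'   [infer_node_metadata()]. A character vector of ids is also accepted.
#' @param edges A two-column data frame (`from`, `to`) of undirected links, or
#'   a two-column character matrix.
#' @param vocabulary Vocabulary tibble used to infer tissue/side, see
#'   [neck_element_vocabulary()].
#' @param validate Check the structural invariants (no self loops, no
#'   duplicate links, endpoints exist)? Connectivity violations are reported
#'   as warnings, not errors, because disconnected inputs are readable even
#'   though the mean path length is undefined on them.
#' @return An object of class `anatomical_network`: a list with elements
#'   `species`, `nodes` (tibble `id`, `tissue`, `side`) and `edges` (tibble
#'   `from`, `to`).
#' @examples
#' net <- anatomical_network("toy", c("cr", "C1", "rmi"),
#'                           data.frame(from = c("cr", "cr", "C1"),
#'                                      to   = c("C1", "rmi", "rmi")))
#' net
#' @export
anatomical_network <- function(species, nodes, edges,
                               vocabulary = neck_element_vocabulary(),
                               validate = TRUE) {
  if (is.character(nodes)) nodes <- tibble(id = nodes)
  nodes <- as_tibble(nodes)
  if (!"id" %in% names(nodes)) abort("`nodes` needs an `id` column")
  nodes$id <- as.character(nodes$id)
  if (!all(c("tissue", "side") %in% names(nodes))) {
    meta <- infer_node_metadata(nodes$id, vocabulary)
    if (!"tissue" %in% names(nodes)) nodes$tissue <- meta$tissue
    if (!"side" %in% names(nodes)) nodes$side <- meta$side
  }
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  edges <- as_tibble(edges)
  names(edges)[1:2] <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  # canonical order so that each undirected link is stored once
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- dplyr::distinct(dplyr::arrange(edges, .data$from, .data$to))
  net <- structure(
    list(species = species, nodes = nodes[c("id", "tissue", "side")],
         edges = edges[c("from", "to")]),
    class = "anatomical_network"
  )
  if (validate) validate_network(net)
  net
}

#' Infer tissue type and side from node labels
#'
#' Labels are looked up in the vocabulary as-is first (so `"cl"`, the
#' clavicle, is not mistaken for a left-side element); if that fails, a
#' trailing `"l"` or `"r"` is stripped and the remainder looked up, with the
#' suffix setting the side. Unknown labels default to tissue `"muscle"` with
#' a warning, since species differ in which muscles exist and muscle labels
#' dominate the vocabulary.
#'
#' @param ids Character vector of node labels.
#' @param vocabulary See [neck_element_vocabulary()].
#' @return Tibble with columns `id`, `tissue`, `side`.
#' @export
infer_node_metadata <- function(ids, vocabulary = neck_element_vocabulary()) {
  tissue <- character(length(ids))
  side <- rep("midline", length(ids))
  unknown <- character(0)
  for (i in seq_along(ids)) {
    id <- ids[i]
    hit <- match(id, vocabulary$token)
    if (is.na(hit)) {
      suffix <- substring(id, nchar(id))
      stem <- substring(id, 1, nchar(id) - 1)
      hit2 <- if (suffix %in% c("l", "r")) match(stem, vocabulary$token) else NA
      if (!is.na(hit2)) {
        tissue[i] <- vocabulary$tissue[hit2]
        side[i] <- if (suffix == "l") "left" else "right"
      } else {
        tissue[i] <- "muscle"
        unknown <- c(unknown, id)
      }
    } else {
      tissue[i] <- vocabulary$tissue[hit]
    }
  }
  if (length(unknown) > 0) {
    warn(sprintf("unknown labels defaulted to tissue 'muscle': %s",
                 paste(unique(unknown), collapse = ", ")))
  }
  tibble(id = ids, tissue = tissue, side = side)
}

validate_network <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  if (anyDuplicated(nodes$id)) abort("duplicate node ids")
  if (any(edges$from == edges$to)) abort("self loops are not allowed")
  missing <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(missing) > 0) {
    abort(sprintf("edge endpoints not in node set: %s",
                  paste(missing, collapse = ", ")))
  }
  key <- paste(edges$from, edges$to)
  if (anyDuplicated(key)) abort("duplicate edges")
  g <- as_igraph(net)
  if (igraph::vcount(g) > 0 && !igraph::is_connected(g)) {
    warn(sprintf("network '%s' is not connected (%d components); mean path length will be undefined",
                 net$species, igraph::count_components(g)))
  }
  invisible(net)
}

#' Convert an anatomical network to an igraph object
#'
#' @param net An `anatomical_network` (igraph objects pass through).
#' @return An undirected simple `igraph` graph with vertex attributes
#'   `tissue` and `side`.
#' @export
as_igraph <- function(net) {
  if (inherits(net, "igraph")) return(net)
  stopifnot(inherits(net, "anatomical_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  g
}

# accept either representation in the metric/modularity layer
as_neck_graph <- function(net) {
  if (inherits(net, "igraph")) net else as_igraph(net)
}

#' @export
print.anatomical_network <- function(x, ...) {
  cat(sprintf("<anatomical_network> %s: %d nodes, %d links\n",
              x$species, nrow(x$nodes), nrow(x$edges)))
  tab <- table(x$nodes$tissue)
  cat("  tissues:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
format.anatomical_network <- function(x, ...) {
  sprintf("<anatomical_network> %s (%d nodes, %d links)", x$species,
          nrow(x$nodes), nrow(x$edges))
}
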