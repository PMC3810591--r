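.checkNodes <- function(net, v) {
  missing <- setdiff(v, igraph::V(net@graph)$name %||% character())
  if (length(missing) > 0)
    stop("missing node(s): ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Shortest-path distance between two genes
#'
#' The minimal number of consecutive interaction steps between two genes in
#' the background network: 1 means directly connected, 2 means separated by
#' one intermediate gene. Unreachable pairs yield \code{Inf} (an explicit
#' sentinel, never an arbitrary large number).
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param a,b gene symbols present in the network.
#' @return non-negative numeric distance, \code{Inf} if unreachable; 0 iff
#'   \code{a == b}.
#' @export
shortestDistance <- function(net, a, b) {
  .checkNodes(net, c(a, b))
  as.numeric(igraph::distances(net@graph, v = a, to = b)[1, 1])
}

#' All-pairs seed distances
#'
#' Distance matrix among a set of genes (used to find qualifying seed pairs).
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param genes gene symbols present in the network.
#' @return numeric matrix of shortest-path distances (\code{Inf} =
#'   unreachable).
#' @export
seedDistances <- function(net, genes) {
  .checkNodes(net, genes)
  if (length(genes) == 0)
    return(matrix(numeric(), 0, 0))
  d <- igraph::distances(net@graph, v = genes, to = genes)
  d[genes, genes, drop = FALSE]
}

#' Intermediate genes on length-2 shortest paths
#'
#' The common neighbors of \code{a} and \code{b} — every node lying on some
#' shortest path when the two genes are at distance exactly 2. Returns an
#' empty set whenever the distance differs from 2 (in particular for directly
#' connected pairs).
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param a,b distinct gene symbols present in the network.
#' @return sorted character vector of intermediate gene symbols.
#' @export
length2Intermediates <- function(net, a, b) {
  if (a == b) stop("a and b must be distinct")
  .checkNodes(net, c(a, b))
  g <- net@graph
  if (igraph::are_adjacent(g, a, b)) return(character())
  common <- intersect(igraph::neighbors(g, a)$name,
                      igraph::neighbors(g, b)$name)
  sort(common)
}

#' Induced subgraph on a node subset
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param keep gene symbols to retain (must all be nodes of \code{net}).
#' @return an \linkS4class{InteractionNetwork} with exactly the kept nodes
#'   and every edge of \code{net} whose two endpoints were kept (edge
#'   \code{kind} labels preserved).
#' @export
inducedSubgraph <- function(net, keep) {
  .checkNodes(net, keep)
  g <- igraph::induced_subgraph(net@graph, vids = sort(unique(keep)))
  new("InteractionNetwork", graph = g, provenance = net@provenance)
}

#' Direct neighbors of a gene
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param v a gene symbol present in the network.
#' @return sorted character vector of neighbor symbols (never includes
#'   \code{v} itself).
#' @export
nodeNeighbors <- function(net, v) {
  .checkNodes(net, v)
  sort(setdiff(igraph::neighbors(net@graph, v)$name, v))
}

#' Degree (number of direct interacting neighbors) of a gene
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param v a gene symbol present in the network.
#' @return non-negative integer degree.
#' @export
nodeDegree <- function(net, v) {
  .checkNodes(net, v)
  as.integer(igraph::degree(net@graph, v))
}
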