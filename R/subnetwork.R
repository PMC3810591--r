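#' Map seed genes onto a background network
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param seeds character vector of seed gene symbols (normalized on entry).
#' @param quiet suppress the mapping message.
#' @return list with elements \code{mapped} and \code{unmapped} (sorted
#'   character vectors). Unmapped seeds are a normal outcome, not an error.
#' @export
mapSeeds <- function(net, seeds, quiet = FALSE) {
  seeds <- unique(normalizeSymbol(seeds))
  nodes <- igraph::V(net@graph)$name %||% character()
  mapped <- sort(intersect(seeds, nodes))
  unmapped <- sort(setdiff(seeds, nodes))
  if (!quiet)
    message(length(mapped), " of ", length(seeds),
            " seed(s) mapped onto the background network")
  list(mapped = mapped, unmapped = unmapped)
}

.emptySubnetwork <- function(unmapped, backgroundId) {
  new("SubNetwork", graph = igraph::make_empty_graph(0, directed = FALSE),
      seedNodes = character(), intermediateNodes = character(),
      qualifyingPairs = data.frame(seed_a = character(), seed_b = character(),
                                   distance = integer(),
                                   stringsAsFactors = FALSE),
      unmappedSeeds = unmapped, backgroundId = backgroundId)
}

#' Extract the seed-gene sub-network
#'
#' The core inference step: the seed genes are mapped onto the background
#' network and every unordered pair of mapped seeds at shortest-path distance
#' below 3 (i.e. 1 or 2, or more generally \code{<= maxDistance}) qualifies.
#' The sub-network consists of all seeds belonging to at least one qualifying
#' pair, plus, for every qualifying pair at distance 2, all of its
#' intermediate genes (common neighbors in the background), plus the edges
#' induced among the selected nodes. A seed gene that also lies between two
#' other seeds stays classified as a seed. Seeds with no qualifying partner
#' are excluded (not kept as isolates). The result is deterministic for a
#' given input.
#'
#' @param net the background \linkS4class{InteractionNetwork}.
#' @param seeds character vector of seed gene symbols.
#' @param maxDistance largest qualifying seed-pair distance (default 2,
#'   the "distance less than 3" rule). Intermediate genes are collected from
#'   distance-2 pairs.
#' @param backgroundId identifier recorded in the result (defaults to the
#'   network provenance).
#' @param quiet suppress the mapping message.
#' @return a \linkS4class{SubNetwork}; an empty sub-network is a valid
#'   result.
#' @examples
#' net <- interactionNetwork(data.frame(from = c("A", "B"), to = c("B", "C")))
#' sn <- extractSubnetwork(net, c("A", "C"), quiet = TRUE)
#' seedNodes(sn)          # "A" "C"
#' intermediateNodes(sn)  # "B"
#' @export
extractSubnetwork <- function(net, seeds, maxDistance = 2,
                              backgroundId = net@provenance, quiet = FALSE) {
  stopifnot(maxDistance >= 1)
  m <- mapSeeds(net, seeds, quiet = quiet)
  if (length(m$mapped) < 2)
    return(.emptySubnetwork(m$unmapped, backgroundId))
  g <- net@graph
  D <- igraph::distances(g, v = m$mapped, to = m$mapped)
  qp <- which(upper.tri(D) & D >= 1 & D <= maxDistance, arr.ind = TRUE)
  if (nrow(qp) == 0)
    return(.emptySubnetwork(m$unmapped, backgroundId))
  pa <- m$mapped[qp[, 1]]; pb <- m$mapped[qp[, 2]]
  sw <- pa > pb
  tmp <- pa[sw]; pa[sw] <- pb[sw]; pb[sw] <- tmp
  pd <- as.integer(D[qp])
  ord <- order(pa, pb)
  pairs <- data.frame(seed_a = pa[ord], seed_b = pb[ord], distance = pd[ord],
                      stringsAsFactors = FALSE)
  seedNodes <- sort(unique(c(pairs$seed_a, pairs$seed_b)))
  # intermediates: common background neighbors of each distance-2 pair
  adj <- igraph::adjacent_vertices(g, seedNodes)
  adj <- lapply(adj, function(v) v$name)
  names(adj) <- seedNodes
  inter <- character()
  d2 <- pairs[pairs$distance == 2L, , drop = FALSE]
  if (nrow(d2) > 0) {
    inter <- unique(unlist(lapply(seq_len(nrow(d2)), function(i)
      intersect(adj[[d2$seed_a[i]]], adj[[d2$seed_b[i]]])), use.names = FALSE))
    inter <- sort(setdiff(inter, m$mapped))
  }
  keep <- sort(c(seedNodes, inter))
  sub <- igraph::induced_subgraph(g, vids = keep)
  new("SubNetwork", graph = sub, seedNodes = seedNodes,
      intermediateNodes = inter, qualifyingPairs = pairs,
      unmappedSeeds = m$unmapped, backgroundId = backgroundId)
}

#' Merge sub-networks from several backgrounds or tissues
#'
#' Node and edge union of the parts. A gene that is a seed in any part is a
#' seed in the merge; qualifying pairs are unioned with their background of
#' origin retained in a \code{background_id} column; a seed counts as
#' unmapped only if it is absent from every merged graph.
#'
#' @param parts non-empty list of \linkS4class{SubNetwork} objects.
#' @param backgroundId identifier for the merge (default: the part ids
#'   joined with "+").
#' @return a \linkS4class{SubNetwork}.
#' @export
mergeSubnetworks <- function(parts, backgroundId = NULL) {
  stopifnot(length(parts) > 0)
  if (!is.list(parts)) parts <- list(parts)
  if (is.null(backgroundId))
    backgroundId <- paste(unique(vapply(parts, function(p) p@backgroundId, "")),
                          collapse = "+")
  ed <- do.call(rbind, lapply(parts, function(p) {
    e <- .edgeDF(p@graph)
    if (!"kind" %in% names(e)) e$kind <- rep("undefined", nrow(e))
    e[, c("from", "to", "kind")]
  }))
  seedsAll <- sort(unique(unlist(lapply(parts, seedNodes))))
  nodesAll <- sort(unique(unlist(lapply(parts, networkNodes))))
  inter <- setdiff(nodesAll, seedsAll)
  qp <- do.call(rbind, lapply(parts, function(p) {
    q <- p@qualifyingPairs
    if (nrow(q) == 0)
      return(data.frame(seed_a = character(), seed_b = character(),
                        distance = integer(), background_id = character(),
                        stringsAsFactors = FALSE))
    q$background_id <- p@backgroundId
    q
  }))
  qp <- qp[!duplicated(qp[, c("seed_a", "seed_b", "distance", "background_id")]), ,
           drop = FALSE]
  qp <- qp[order(qp$seed_a, qp$seed_b, qp$distance, qp$background_id), ,
           drop = FALSE]
  rownames(qp) <- NULL
  unmapped <- sort(setdiff(unique(unlist(lapply(parts, unmappedSeeds))),
                           nodesAll))
  net <- interactionNetwork(ed, nodes = nodesAll, quiet = TRUE)
  new("SubNetwork", graph = net@graph, seedNodes = seedsAll,
      intermediateNodes = inter, qualifyingPairs = qp,
      unmappedSeeds = unmapped, backgroundId = backgroundId)
}

#' Over-representation of a disease gene list in a sub-network
#'
#' One-sided Fisher exact (hypergeometric upper-tail) test of the 2x2 table
#' (gene in sub-network) x (gene in disease list) over a stated gene
#' universe — typically the background network's node set. Sub-network genes
#' outside the universe are dropped with a warning.
#'
#' @param subnet a \linkS4class{SubNetwork} (or a plain character vector of
#'   genes).
#' @param diseaseGenes character vector of disease-associated gene symbols.
#' @param universe character vector defining the gene universe (non-empty).
#' @return list with \code{subnet_size}, \code{overlap},
#'   \code{disease_size_in_universe}, \code{universe_size},
#'   \code{overlap_genes} and \code{p_value}.
#' @export
diseaseOverlapTest <- function(subnet, diseaseGenes, universe) {
  genes <- if (is(subnet, "SubNetwork")) networkNodes(subnet)
           else unique(normalizeSymbol(subnet))
  diseaseGenes <- unique(normalizeSymbol(diseaseGenes))
  universe <- unique(normalizeSymbol(universe))
  if (length(universe) == 0) stop("usage error: empty universe")
  out <- setdiff(genes, universe)
  if (length(out) > 0)
    warning(length(out), " sub-network gene(s) outside the universe dropped")
  genes <- intersect(genes, universe)
  disease <- intersect(diseaseGenes, universe)
  ov <- intersect(genes, disease)
  p <- fisherOverrep(length(ov), length(genes), length(disease),
                     length(universe))
  list(subnet_size = length(genes), overlap = length(ov),
       disease_size_in_universe = length(disease),
       universe_size = length(universe),
       overlap_genes = sort(ov), p_value = p)
}
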