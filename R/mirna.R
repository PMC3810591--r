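#' Build the miRNA-gene bipartite network over sub-network genes
#'
#' One vertex part is the sub-network genes that are validated targets of at
#' least one miRNA; the other part is the miRNAs targeting them. Edges are
#' the (miRNA, gene) target relations restricted to those genes; there are
#' never gene-gene or miRNA-miRNA edges.
#'
#' @param subnetGenes character vector of sub-network gene symbols (or a
#'   \linkS4class{SubNetwork}).
#' @param tmap a \linkS4class{MiRNATargetMap}.
#' @return a \linkS4class{BipartiteNetwork}.
#' @export
buildBipartite <- function(subnetGenes, tmap) {
  if (is(subnetGenes, "SubNetwork")) subnetGenes <- networkNodes(subnetGenes)
  subnetGenes <- unique(normalizeSymbol(subnetGenes))
  allTargets <- unique(unlist(tmap@targets, use.names = FALSE))
  geneNodes <- sort(intersect(subnetGenes, allTargets))
  edges <- do.call(rbind, lapply(names(tmap@targets), function(m) {
    g <- intersect(tmap@targets[[m]], geneNodes)
    if (length(g) == 0) return(NULL)
    data.frame(mirna = m, gene = sort(g), stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(mirna = character(), gene = character(),
                        stringsAsFactors = FALSE)
  edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  new("BipartiteNetwork", mirnaNodes = sort(unique(edges$mirna)),
      geneNodes = geneNodes, edges = edges)
}

#' Rank miRNAs by target over-representation in the sub-network
#'
#' For every miRNA of the target map, tests whether its validated targets
#' are over-represented among the bipartite network's gene part (the
#' sub-network genes) relative to a gene universe, by the one-sided
#' hypergeometric upper tail: k = |targets in query|, K = |targets in
#' universe|, n = |query in universe|, N = |universe|. Results are sorted by
#' ascending p with ties broken by miRNA id, and ranked 1..M.
#'
#' @param bip a \linkS4class{BipartiteNetwork} built on the sub-network
#'   genes.
#' @param tmap the \linkS4class{MiRNATargetMap}.
#' @param universe gene universe; default: the union of all target sets in
#'   \code{tmap} (a self-contained choice; pass a genome-wide list to widen
#'   it). Targets outside the universe are ignored by the counts.
#' @return data.frame with columns \code{mirna}, \code{k}, \code{n},
#'   \code{K}, \code{N}, \code{p_value}, \code{rank}.
#' @export
enrichMiRNAs <- function(bip, tmap, universe = NULL) {
  allTargets <- sort(unique(unlist(tmap@targets, use.names = FALSE)))
  if (is.null(universe)) universe <- allTargets
  universe <- unique(normalizeSymbol(universe))
  if (length(universe) == 0) stop("usage error: empty universe")
  query <- intersect(bip@geneNodes, universe)
  n <- length(query); N <- length(universe)
  mir <- names(tmap@targets)
  rows <- lapply(mir, function(m) {
    tg <- tmap@targets[[m]]
    K <- length(intersect(tg, universe))
    k <- length(intersect(tg, query))
    data.frame(mirna = m, k = k, n = n, K = K, N = N,
               p_value = fisherOverrep(k, n, K, N), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(mirna = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  res <- res[order(res$p_value, res$mirna), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Top-k miRNAs by rank
#'
#' @param results data.frame from [enrichMiRNAs()].
#' @param k how many to keep (default 10); fewer are returned if fewer
#'   exist.
#' @return the first \code{k} rows by rank.
#' @export
topK <- function(results, k = 10) {
  stopifnot(k >= 1)
  head(results[order(results$rank), , drop = FALSE], k)
}

#' Export the bipartite network as GraphML
#'
#' Nodes carry a \code{part} attribute ("mirna" or "gene").
#'
#' @param bip a \linkS4class{BipartiteNetwork}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeBipartite <- function(bip, path) {
  nodes <- c(bip@mirnaNodes, bip@geneNodes)
  part <- c(rep("mirna", length(bip@mirnaNodes)),
            rep("gene", length(bip@geneNodes)))
  g <- igraph::graph_from_data_frame(
    bip@edges, directed = FALSE,
    vertices = data.frame(name = nodes, part = part, stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
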