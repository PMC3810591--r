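#' Accessors for seednet classes
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{networkNodes}/\code{networkEdges} return the node symbols and the
#' edge table of any graph-bearing object, \code{degRecords} the rows of a
#' \linkS4class{DEGTable}, \code{seedNodes}/\code{intermediateNodes}/
#' \code{qualifyingPairs}/\code{unmappedSeeds}/\code{backgroundId} the parts
#' of a \linkS4class{SubNetwork}, \code{hubGene}/\code{moduleMembers} those
#' of a \linkS4class{HubModule}, \code{geneSetIds}/\code{geneSetMembers}/
#' \code{geneSetDescriptions} those of a \linkS4class{GeneSetList}, and
#' \code{mirnaTargets}/\code{pairCount} those of a
#' \linkS4class{MiRNATargetMap}. \code{bundleTruth} returns the
#' \linkS4class{SyntheticTruth} of a \linkS4class{SyntheticBundle}.
#'
#' @param x the object.
#' @return the requested component (character vector, data.frame, list or
#'   count as appropriate).
#' @name accessors
#' @aliases networkNodes networkEdges degRecords seedNodes intermediateNodes
#'   qualifyingPairs unmappedSeeds backgroundId hubGene moduleMembers
#'   geneSetIds geneSetMembers geneSetDescriptions mirnaTargets pairCount
#'   bundleTruth
NULL

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("degRecords", function(x) standardGeneric("degRecords"))
#' @rdname accessors
#' @export
setGeneric("seedNodes", function(x) standardGeneric("seedNodes"))
#' @rdname accessors
#' @export
setGeneric("intermediateNodes", function(x) standardGeneric("intermediateNodes"))
#' @rdname accessors
#' @export
setGeneric("qualifyingPairs", function(x) standardGeneric("qualifyingPairs"))
#' @rdname accessors
#' @export
setGeneric("unmappedSeeds", function(x) standardGeneric("unmappedSeeds"))
#' @rdname accessors
#' @export
setGeneric("backgroundId", function(x) standardGeneric("backgroundId"))
#' @rdname accessors
#' @export
setGeneric("hubGene", function(x) standardGeneric("hubGene"))
#' @rdname accessors
#' @export
setGeneric("moduleMembers", function(x) standardGeneric("moduleMembers"))
#' @rdname accessors
#' @export
setGeneric("geneSetIds", function(x) standardGeneric("geneSetIds"))
#' @rdname accessors
#' @export
setGeneric("geneSetMembers", function(x) standardGeneric("geneSetMembers"))
#' @rdname accessors
#' @export
setGeneric("geneSetDescriptions", function(x) standardGeneric("geneSetDescriptions"))
#' @rdname accessors
#' @export
setGeneric("mirnaTargets", function(x) standardGeneric("mirnaTargets"))
#' @rdname accessors
#' @export
setGeneric("pairCount", function(x) standardGeneric("pairCount"))
#' @rdname accessors
#' @export
setGeneric("bundleTruth", function(x) standardGeneric("bundleTruth"))

.edgeDF <- function(g) {
  if (igraph::ecount(g) == 0)
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  e <- igraph::as_data_frame(g, what = "edges")
  # canonical unordered representation: endpoint-sorted, then row-sorted
  a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
  e$from <- a; e$to <- b
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' @rdname accessors
setMethod("networkNodes", "InteractionNetwork",
          function(x) sort(igraph::V(x@graph)$name %||% character()))
#' @rdname accessors
setMethod("networkEdges", "InteractionNetwork", function(x) .edgeDF(x@graph))
#' @rdname accessors
setMethod("networkNodes", "SubNetwork",
          function(x) sort(igraph::V(x@graph)$name %||% character()))
#' @rdname accessors
setMethod("networkEdges", "SubNetwork", function(x) .edgeDF(x@graph))
#' @rdname accessors
setMethod("networkNodes", "HubModule",
          function(x) sort(igraph::V(x@graph)$name %||% character()))
#' @rdname accessors
setMethod("networkEdges", "HubModule", function(x) .edgeDF(x@graph))

#' @rdname accessors
setMethod("degRecords", "DEGTable", function(x) x@records)
#' @rdname accessors
setMethod("seedNodes", "SubNetwork", function(x) x@seedNodes)
#' @rdname accessors
setMethod("intermediateNodes", "SubNetwork", function(x) x@intermediateNodes)
#' @rdname accessors
setMethod("qualifyingPairs", "SubNetwork", function(x) x@qualifyingPairs)
#' @rdname accessors
setMethod("unmappedSeeds", "SubNetwork", function(x) x@unmappedSeeds)
#' @rdname accessors
setMethod("backgroundId", "SubNetwork", function(x) x@backgroundId)
#' @rdname accessors
setMethod("hubGene", "HubModule", function(x) x@hub)
#' @rdname accessors
setMethod("moduleMembers", "HubModule", function(x) x@members)
#' @rdname accessors
setMethod("backgroundId", "HubModule", function(x) x@sourceId)
#' @rdname accessors
setMethod("geneSetIds", "GeneSetList", function(x) x@ids)
#' @rdname accessors
setMethod("geneSetMembers", "GeneSetList", function(x) setNames(x@members, x@ids))
#' @rdname accessors
setMethod("geneSetDescriptions", "GeneSetList", function(x) setNames(x@descriptions, x@ids))
#' @rdname accessors
setMethod("mirnaTargets", "MiRNATargetMap", function(x) x@targets)
#' @rdname accessors
setMethod("pairCount", "MiRNATargetMap",
          function(x) sum(vapply(x@targets, length, 1L)))
#' @rdname accessors
setMethod("bundleTruth", "SyntheticBundle", function(x) x@truth)

setMethod("show", "DEGTable", function(object) {
  r <- object@records
  cat(sprintf("DEGTable with %d record(s) [%s]\n", nrow(r),
              object@provenance))
  if (nrow(r) > 0) {
    tab <- table(r$tissue, r$age_months)
    for (ti in rownames(tab)) for (ag in colnames(tab))
      if (tab[ti, ag] > 0)
        cat(sprintf("  %s, %s mo: %d\n", ti, ag, tab[ti, ag]))
  }
})

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf("InteractionNetwork: %d nodes, %d edges [%s]\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph),
              object@provenance))
})

setMethod("show", "SubNetwork", function(object) {
  cat(sprintf(
    "SubNetwork [%s]: %d nodes (%d seed, %d intermediate), %d edges\n",
    object@backgroundId, igraph::vcount(object@graph),
    length(object@seedNodes), length(object@intermediateNodes),
    igraph::ecount(object@graph)))
  cat(sprintf("  qualifying seed pairs: %d; unmapped seeds: %d\n",
              nrow(object@qualifyingPairs), length(object@unmappedSeeds)))
})

setMethod("show", "HubModule", function(object) {
  cat(sprintf("HubModule hub=%s [%s]: %d members, %d edges\n",
              object@hub, object@sourceId, length(object@members),
              igraph::ecount(object@graph)))
})

setMethod("show", "GeneSetList", function(object) {
  cat(sprintf("GeneSetList with %d set(s)\n", length(object@ids)))
})

setMethod("show", "MiRNATargetMap", function(object) {
  cat(sprintf("MiRNATargetMap: %d miRNA(s), %d distinct pairs\n",
              length(object@targets), pairCount(object)))
})

setMethod("show", "BipartiteNetwork", function(object) {
  cat(sprintf("BipartiteNetwork: %d miRNA(s) x %d gene(s), %d edges\n",
              length(object@mirnaNodes), length(object@geneNodes),
              nrow(object@edges)))
})

setMethod("show", "SyntheticBundle", function(object) {
  cat(sprintf(
    "SyntheticBundle (seed %d): background %d nodes / %d edges, %d seeds\n",
    object@rngSeed, igraph::vcount(object@background@graph),
    igraph::ecount(object@background@graph), length(object@seeds)))
  cat(sprintf("  planted: cluster %d, bridges %d, decoys %d, hub %s\n",
              length(object@truth@plantedCluster),
              length(object@truth@plantedBridges),
              length(object@truth@decoySeeds),
              if (length(object@truth@plantedHub)) object@truth@plantedHub else "<none>"))
})
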