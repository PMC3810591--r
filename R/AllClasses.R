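#' @import methods
#' @importFrom stats cor setNames
#' @importFrom utils read.delim write.table head
NULL

setOldClass("igraph")

.emptyGraph <- function() igraph::make_empty_graph(0, directed = FALSE)

#' DEGTable: a table of differentially expressed genes
#'
#' One row per differentially expressed gene, carrying the signed linear
#' fold-change ratio (magnitude >= 1; the sign encodes direction, "-" =
#' down-regulated), the tissue of origin and the age in months. No two rows
#' may share the same (gene, tissue, age_months) key.
#'
#' @slot records data.frame with columns \code{gene}, \code{ratio},
#'   \code{tissue}, \code{age_months}.
#' @slot provenance free-text description of where the table came from.
#' @export
setClass("DEGTable",
  representation(records = "data.frame", provenance = "character"),
  prototype(records = data.frame(gene = character(), ratio = numeric(),
                                 tissue = character(), age_months = integer(),
                                 stringsAsFactors = FALSE),
            provenance = ""))

setValidity("DEGTable", function(object) {
  r <- object@records
  need <- c("gene", "ratio", "tissue", "age_months")
  if (!all(need %in% names(r)))
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  if (nrow(r) == 0L) return(TRUE)
  if (any(is.na(r$ratio)) || any(r$ratio == 0))
    return("ratio must be non-missing and non-zero")
  if (any(abs(r$ratio) < 1))
    return("fold-change convention requires |ratio| >= 1")
  if (!all(r$tissue %in% c("hippocampus", "cortex", "other")))
    return("tissue must be one of hippocampus, cortex, other")
  if (any(is.na(r$age_months)) || any(r$age_months <= 0))
    return("age_months must be a positive integer")
  key <- paste(r$gene, r$tissue, r$age_months, sep = "\r")
  if (anyDuplicated(key))
    return("duplicate (gene, tissue, age_months) records")
  TRUE
})

#' InteractionNetwork: an undirected simple background graph
#'
#' Nodes are normalized gene symbols; edges are undirected interactions
#' (physical binding, curated regulation, or thresholded co-expression).
#' Self-loops and duplicate edges are forbidden. An optional per-edge
#' \code{kind} attribute (e.g. activation/inhibition) is retained for export
#' but ignored by all distance computations.
#'
#' @slot graph an \pkg{igraph} undirected simple graph with a vertex
#'   \code{name} attribute.
#' @slot provenance free-text origin of the network.
#' @export
setClass("InteractionNetwork",
  representation(graph = "igraph", provenance = "character"),
  prototype(provenance = ""))

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
    return("vertices must be named by gene symbol")
  if (igraph::any_loop(g)) return("self-loops are not allowed")
  if (igraph::any_multiple(g)) return("duplicate edges are not allowed")
  TRUE
})

#' SubNetwork: the extracted seed/intermediate sub-network
#'
#' The result of mapping a seed-gene list onto a background
#' \linkS4class{InteractionNetwork} and keeping seed pairs at shortest-path
#' distance 1 or 2 together with the intermediate genes (common neighbors)
#' that connect distance-2 pairs, and the induced edges.
#'
#' @slot graph induced \pkg{igraph} subgraph over seed + intermediate nodes.
#' @slot seedNodes seeds that belong to at least one qualifying pair.
#' @slot intermediateNodes non-seed common neighbors of distance-2 pairs.
#' @slot qualifyingPairs data.frame (seed_a, seed_b, distance) of the
#'   unordered seed pairs that justified inclusion.
#' @slot unmappedSeeds input seeds absent from the background network.
#' @slot backgroundId identifier of the background network(s).
#' @export
setClass("SubNetwork",
  representation(graph = "igraph", seedNodes = "character",
                 intermediateNodes = "character",
                 qualifyingPairs = "data.frame",
                 unmappedSeeds = "character", backgroundId = "character"),
  prototype(seedNodes = character(), intermediateNodes = character(),
            qualifyingPairs = data.frame(seed_a = character(),
                                         seed_b = character(),
                                         distance = integer(),
                                         stringsAsFactors = FALSE),
            unmappedSeeds = character(), backgroundId = ""))

setValidity("SubNetwork", function(object) {
  if (length(intersect(object@seedNodes, object@intermediateNodes)) > 0)
    return("seed and intermediate node sets must be disjoint")
  nodes <- sort(igraph::V(object@graph)$name %||% character())
  if (!identical(nodes, sort(c(object@seedNodes, object@intermediateNodes))))
    return("graph nodes must be exactly the seed + intermediate nodes")
  qp <- object@qualifyingPairs
  if (nrow(qp) > 0) {
    if (!all(qp$distance %in% c(1L, 2L)))
      return("qualifying distances must be 1 or 2")
    inpair <- unique(c(qp$seed_a, qp$seed_b))
    if (!all(object@seedNodes %in% inpair))
      return("every seed node must appear in a qualifying pair")
  } else if (length(object@seedNodes) > 0) {
    return("seed nodes present but no qualifying pairs")
  }
  TRUE
})

#' HubModule: a hub seed gene and its ego network
#'
#' A hub seed gene (strictly more than a threshold number of direct neighbors
#' within a sub-network) together with those neighbors and the induced edges
#' among them.
#'
#' @slot hub the hub seed gene symbol.
#' @slot members hub plus its direct neighbors in the source sub-network.
#' @slot graph induced subgraph of the source sub-network on the members.
#' @slot sourceId identifier of the source sub-network.
#' @export
setClass("HubModule",
  representation(hub = "character", members = "character",
                 graph = "igraph", sourceId = "character"))

setValidity("HubModule", function(object) {
  if (length(object@hub) != 1L) return("exactly one hub")
  if (!object@hub %in% object@members) return("hub must be a member")
  nodes <- igraph::V(object@graph)$name %||% character()
  if (!setequal(nodes, object@members))
    return("module graph nodes must equal members")
  others <- setdiff(object@members, object@hub)
  if (length(others) > 0) {
    nb <- igraph::neighbors(object@graph, object@hub)$name
    if (!all(others %in% nb))
      return("every non-hub member must be adjacent to the hub")
  }
  TRUE
})

#' GeneSetList: a collection of flat gene sets (GMT records)
#'
#' @slot ids set identifiers, unique, in file order.
#' @slot descriptions one description per set.
#' @slot members list of character vectors of normalized member symbols.
#' @export
setClass("GeneSetList",
  representation(ids = "character", descriptions = "character",
                 members = "list"),
  prototype(ids = character(), descriptions = character(), members = list()))

setValidity("GeneSetList", function(object) {
  if (length(object@ids) != length(object@members) ||
      length(object@ids) != length(object@descriptions))
    return("ids, descriptions and members must have equal length")
  if (anyDuplicated(object@ids)) return("set ids must be unique")
  if (any(vapply(object@members, length, 1L) == 0L))
    return("empty gene sets are not allowed")
  TRUE
})

#' MiRNATargetMap: validated miRNA -> target-gene map
#'
#' @slot targets named list: miRNA id -> character vector of normalized
#'   target gene symbols (non-empty, deduplicated).
#' @export
setClass("MiRNATargetMap",
  representation(targets = "list"), prototype(targets = structure(list(), names = character())))

setValidity("MiRNATargetMap", function(object) {
  t <- object@targets
  if (length(t) == 0) return(TRUE)
  if (is.null(names(t)) || any(names(t) == "") || anyDuplicated(names(t)))
    return("targets must be a uniquely named list")
  if (any(vapply(t, length, 1L) == 0L)) return("empty target sets not allowed")
  if (any(vapply(t, anyDuplicated, 1L) > 0L)) return("duplicate targets within a miRNA")
  TRUE
})

#' BipartiteNetwork: miRNA-gene bipartite graph
#'
#' @slot mirnaNodes miRNAs with at least one edge.
#' @slot geneNodes sub-network genes that are targets of some miRNA.
#' @slot edges data.frame (mirna, gene) of target relations.
#' @export
setClass("BipartiteNetwork",
  representation(mirnaNodes = "character", geneNodes = "character",
                 edges = "data.frame"),
  prototype(mirnaNodes = character(), geneNodes = character(),
            edges = data.frame(mirna = character(), gene = character(),
                               stringsAsFactors = FALSE)))

setValidity("BipartiteNetwork", function(object) {
  e <- object@edges
  if (!all(c("mirna", "gene") %in% names(e))) return("edges need mirna, gene columns")
  if (nrow(e) > 0) {
    if (!all(e$mirna %in% object@mirnaNodes)) return("edge miRNA not in mirnaNodes")
    if (!all(e$gene %in% object@geneNodes)) return("edge gene not in geneNodes")
  }
  if (length(intersect(object@mirnaNodes, object@geneNodes)) > 0)
    return("the two vertex parts must be disjoint")
  TRUE
})

#' SyntheticTruth: ground truth planted into a synthetic bundle
#'
#' @slot plantedCluster seed genes pairwise within distance 2.
#' @slot plantedBridges intermediate genes bridging the cluster.
#' @slot decoySeeds seeds at distance >= 3 from every other seed.
#' @slot plantedHub the cluster seed wired to exceed the hub degree threshold
#'   (or empty).
#' @slot plantedTerm id of the planted over-represented gene set (or empty).
#' @slot plantedMiRNA id of the planted enriched miRNA (or empty).
#' @export
setClass("SyntheticTruth",
  representation(plantedCluster = "character", plantedBridges = "character",
                 decoySeeds = "character", plantedHub = "character",
                 plantedTerm = "character", plantedMiRNA = "character"),
  prototype(plantedCluster = character(), plantedBridges = character(),
            decoySeeds = character(), plantedHub = character(),
            plantedTerm = character(), plantedMiRNA = character()))

#' SyntheticBundle: a complete synthetic input set with ground truth
#'
#' @slot background synthetic interaction network (seed structure planted).
#' @slot coexprPairs data.frame (gene_a, gene_b, r) of co-expression pairs.
#' @slot seeds the seed gene symbols (planted cluster + decoys).
#' @slot degTable DEG table stamping the seeds with fold changes.
#' @slot geneSets gene sets including the planted term.
#' @slot mirnaMap miRNA target map including the planted miRNA.
#' @slot diseaseGenes synthetic disease gene list.
#' @slot truth \linkS4class{SyntheticTruth}.
#' @slot rngSeed the integer seed the whole bundle derives from.
#' @export
setClass("SyntheticBundle",
  representation(background = "InteractionNetwork", coexprPairs = "data.frame",
                 seeds = "character", degTable = "DEGTable",
                 geneSets = "GeneSetList", mirnaMap = "MiRNATargetMap",
                 diseaseGenes = "character", truth = "SyntheticTruth",
                 rngSeed = "integer"))

`%||%` <- function(a, b) if (is.null(a)) b else a
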