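#' Find hub seed genes of a sub-network
#'
#' Seed genes with strictly more than \code{minNeighbors} direct interacting
#' neighbors within the sub-network ("more than 14" is a strict inequality:
#' a seed with exactly 14 neighbors is not a hub). Intermediate genes never
#' qualify, whatever their degree. Degree is counted within the extracted
#' sub-network; set \code{where = "background"} (with the background network
#' in \code{net}) to count it in the raw background instead.
#'
#' @param subnet a \linkS4class{SubNetwork}.
#' @param minNeighbors degree threshold (default 14).
#' @param where \code{"subnetwork"} (default) or \code{"background"}.
#' @param net the background \linkS4class{InteractionNetwork}, required when
#'   \code{where = "background"}.
#' @return sorted character vector of hub seed gene symbols.
#' @export
findHubSeeds <- function(subnet, minNeighbors = 14,
                         where = c("subnetwork", "background"), net = NULL) {
  where <- match.arg(where)
  stopifnot(minNeighbors >= 0)
  seeds <- subnet@seedNodes
  if (length(seeds) == 0) return(character())
  g <- if (where == "subnetwork") subnet@graph else {
    if (is.null(net)) stop("usage error: background network required")
    net@graph
  }
  deg <- igraph::degree(g, seeds)
  sort(seeds[deg > minNeighbors])
}

#' Extract the ego-network module of a hub seed gene
#'
#' The module is the hub seed gene together with its direct neighbors in the
#' sub-network and the induced edges among them (neighbor-neighbor edges
#' included).
#'
#' @param subnet a \linkS4class{SubNetwork}.
#' @param hub a seed gene of \code{subnet}.
#' @return a \linkS4class{HubModule}.
#' @export
extractModule <- function(subnet, hub) {
  hub <- normalizeSymbol(hub)
  if (!hub %in% subnet@seedNodes)
    stop("usage error: '", hub, "' is not a seed node of the sub-network")
  members <- sort(unique(c(hub, igraph::neighbors(subnet@graph, hub)$name)))
  g <- igraph::induced_subgraph(subnet@graph, vids = members)
  new("HubModule", hub = hub, members = members, graph = g,
      sourceId = subnet@backgroundId)
}

#' Hub modules across several sub-networks
#'
#' Finds hub seed genes in each sub-network and extracts their modules,
#' ordered by descending hub degree with lexicographic tie-break on the hub
#' symbol. The same hub found in two backgrounds yields two distinct modules
#' with their own provenance.
#'
#' @param subnets list of \linkS4class{SubNetwork} objects.
#' @param minNeighbors degree threshold (default 14).
#' @return list of \linkS4class{HubModule} objects (possibly empty).
#' @export
modulesReport <- function(subnets, minNeighbors = 14) {
  if (is(subnets, "SubNetwork")) subnets <- list(subnets)
  mods <- list()
  for (sn in subnets) {
    hubs <- findHubSeeds(sn, minNeighbors = minNeighbors)
    for (h in hubs) mods[[length(mods) + 1L]] <- extractModule(sn, h)
  }
  if (length(mods) == 0) return(mods)
  deg <- vapply(mods, function(m) length(m@members) - 1L, 1L)
  hub <- vapply(mods, hubGene, "")
  src <- vapply(mods, backgroundId, "")
  mods[order(-deg, hub, src)]
}

#' Tabular summary of hub modules
#'
#' @param modules list of \linkS4class{HubModule} objects (as returned by
#'   [modulesReport()]).
#' @return data.frame with columns hub, background_id, degree, n_members,
#'   n_edges.
#' @export
moduleSummary <- function(modules) {
  data.frame(
    hub = vapply(modules, hubGene, ""),
    background_id = vapply(modules, backgroundId, ""),
    degree = vapply(modules, function(m) length(m@members) - 1L, 1L),
    n_members = vapply(modules, function(m) length(m@members), 1L),
    n_edges = vapply(modules, function(m) as.integer(igraph::ecount(m@graph)), 1L),
    stringsAsFactors = FALSE)
}
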