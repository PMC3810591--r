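#' Construct an interaction network from an edge table
#'
#' Builds an undirected simple \linkS4class{InteractionNetwork}. Self-loops
#' are dropped and duplicate edges collapsed (their count is reported via
#' \code{message}), since shortest-path distances and degrees presume a
#' simple graph. An optional \code{kind} column is kept as an edge attribute
#' for export only.
#'
#' @param edges data.frame with columns \code{from}, \code{to} and optional
#'   \code{kind}; symbols are assumed normalized.
#' @param nodes optional extra (isolated) node symbols.
#' @param provenance free-text origin.
#' @param quiet suppress the dropped/collapsed messages.
#' @return an \linkS4class{InteractionNetwork}.
#' @export
interactionNetwork <- function(edges = NULL, nodes = character(),
                               provenance = "", quiet = FALSE) {
  if (is.null(edges) || nrow(edges) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    if (length(nodes) > 0) g <- igraph::add_vertices(g, length(nodes),
                                                     name = unique(sort(nodes)))
    return(new("InteractionNetwork", graph = g, provenance = provenance))
  }
  loops <- edges$from == edges$to
  if (any(loops) && !quiet)
    message(sum(loops), " self-loop(s) dropped")
  edges <- edges[!loops, , drop = FALSE]
  a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup) && !quiet)
    message(sum(dup), " duplicate edge(s) collapsed")
  ed <- data.frame(from = a[!dup], to = b[!dup], stringsAsFactors = FALSE)
  if ("kind" %in% names(edges)) ed$kind <- edges$kind[!dup]
  allnodes <- sort(unique(c(ed$from, ed$to, nodes)))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = allnodes)
  new("InteractionNetwork", graph = g, provenance = provenance)
}

#' Read a background network from an edge-list file
#'
#' Supports two dialects: \code{"pair-tsv"} (rows
#' \code{geneA<TAB>geneB[<TAB>attr]}; a third column is kept as the edge
#' \code{kind}) and \code{"sif"} (rows
#' \code{geneA<TAB>relation<TAB>geneB[<TAB>geneC...]}, fanning one source out
#' to several targets; the relation token is kept as \code{kind} but ignored
#' for topology). Directed curated-interaction inputs are symmetrized: the
#' graph is always undirected. Symbols are normalized; self-loops are dropped
#' and duplicate edges collapsed with a message.
#'
#' @param path path to the file.
#' @param dialect \code{"pair-tsv"} or \code{"sif"}.
#' @param aliases optional alias map passed to [normalizeSymbol()].
#' @param provenance free-text origin (defaults to the path).
#' @return an \linkS4class{InteractionNetwork}.
#' @export
readNetwork <- function(path, dialect = c("pair-tsv", "sif"), aliases = NULL,
                        provenance = path) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(interactionNetwork(NULL, provenance = provenance))
  toks <- strsplit(lines, "\t", fixed = TRUE)
  from <- character(); to <- character(); kind <- character()
  for (i in seq_along(toks)) {
    tk <- trimws(toks[[i]])
    tk <- tk[nzchar(tk)]
    if (dialect == "pair-tsv") {
      if (length(tk) < 2)
        stop(sprintf("parse error: fewer than 2 gene tokens at row %d of %s",
                     i, path))
      from <- c(from, tk[1]); to <- c(to, tk[2])
      kind <- c(kind, if (length(tk) >= 3) tk[3] else "undefined")
    } else {
      if (length(tk) < 3)
        stop(sprintf("parse error: fewer than 2 gene tokens at row %d of %s",
                     i, path))
      tg <- tk[3:length(tk)]
      from <- c(from, rep(tk[1], length(tg))); to <- c(to, tg)
      kind <- c(kind, rep(tk[2], length(tg)))
    }
  }
  interactionNetwork(
    data.frame(from = normalizeSymbol(from, aliases),
               to = normalizeSymbol(to, aliases),
               kind = kind, stringsAsFactors = FALSE),
    provenance = provenance)
}

#' Write a network to an edge-list file
#'
#' Writes the canonical (endpoint- and row-sorted) edge list, so repeated
#' exports of the same network are byte-identical.
#'
#' @param net an \linkS4class{InteractionNetwork} (or
#'   \linkS4class{SubNetwork}).
#' @param path output path.
#' @param format \code{"tsv"} (2 columns) or \code{"sif"}
#'   (source, relation, target).
#' @return invisibly, the path.
#' @export
writeNetwork <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  g <- net@graph
  e <- .edgeDF(g)
  kind <- if (nrow(e) > 0 && "kind" %in% names(e)) e$kind else
    rep("pp", nrow(e))
  kind[is.na(kind) | !nzchar(kind)] <- "pp"
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(e) > 0) {
    out <- if (format == "sif") paste(e$from, kind, e$to, sep = "\t")
           else paste(e$from, e$to, sep = "\t")
    writeLines(out, con)
  }
  invisible(path)
}

#' Export a sub-network with node roles
#'
#' Serializes a \linkS4class{SubNetwork}. For \code{"sif"} and \code{"tsv"}
#' the edges go to \code{path} and the node attributes (role seed/intermediate
#' and provenance) to a sidecar table \code{<path>.nodes.tsv}; such exports
#' round-trip through [readNetwork()]. \code{"graphml"} writes a single file
#' with \code{role} and \code{provenance} node attributes.
#'
#' @param subnet a \linkS4class{SubNetwork}.
#' @param path output path.
#' @param format one of \code{"sif"}, \code{"tsv"}, \code{"graphml"}.
#' @return invisibly, the main output path.
#' @export
writeSubnetwork <- function(subnet, path, format = c("sif", "tsv", "graphml")) {
  if (!is(subnet, "SubNetwork")) stop("usage error: not a SubNetwork")
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("usage error: unknown format"))
  nodes <- networkNodes(subnet)
  role <- ifelse(nodes %in% subnet@seedNodes, "seed", "intermediate")
  if (format == "graphml") {
    g <- subnet@graph
    if (igraph::vcount(g) > 0) {
      ord <- match(igraph::V(g)$name, nodes)
      igraph::V(g)$role <- role[ord]
      igraph::V(g)$provenance <- subnet@backgroundId
    }
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  writeNetwork(subnet, path, format = format)
  nt <- data.frame(node = nodes, role = role,
                   provenance = rep(subnet@backgroundId, length(nodes)),
                   stringsAsFactors = FALSE)
  write.table(nt, paste0(path, ".nodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
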