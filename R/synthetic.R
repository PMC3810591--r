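#' Generate a synthetic background interaction network
#'
#' Emulates the scale and topology of curated interaction databases: a
#' preferential-attachment (Barabasi-Albert) graph gives the heavy-tailed
#' degree distribution typical of protein-protein interaction networks
#' (about 1e4 proteins and 4e4 interactions at the default bundle scale);
#' a uniform random graph (G(n, p)) is available as a null alternative.
#' Deterministic for a given \code{rngSeed}.
#'
#' @param nNodes number of genes (>= 2).
#' @param model \code{"preferential_attachment"} (param = edges attached per
#'   new node) or \code{"uniform_random"} (param = edge probability).
#' @param param model parameter, see above.
#' @param rngSeed integer seed.
#' @return an \linkS4class{InteractionNetwork} with nodes named
#'   \code{G00001...}.
#' @export
generateBackground <- function(nNodes,
                               model = c("preferential_attachment",
                                         "uniform_random"),
                               param = 4, rngSeed = 1L) {
  model <- match.arg(model)
  if (nNodes < 2) stop("usage error: nNodes must be >= 2")
  set.seed(rngSeed)
  g <- if (model == "preferential_attachment") {
    if (param < 1) stop("usage error: attachment count must be >= 1")
    igraph::sample_pa(nNodes, m = param, directed = FALSE)
  } else {
    if (param < 0 || param > 1) stop("usage error: edge probability in [0,1]")
    igraph::sample_gnp(nNodes, p = param, directed = FALSE)
  }
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("G%05d", seq_len(nNodes))
  new("InteractionNetwork", graph = g,
      provenance = sprintf("synthetic-%s(n=%d, param=%g, seed=%d)",
                           model, nNodes, param, rngSeed))
}

#' Plant a recoverable seed structure into a background network
#'
#' Augments the network with ground-truth structure for validating
#' sub-network extraction: a cluster of new seed genes made pairwise
#' reachable within distance 2 through dedicated bridge (intermediate)
#' nodes, optionally one cluster seed wired as a hub (directly adjacent to
#' every other cluster seed), and decoy seeds attached to the original graph
#' through a stalk node so that they sit at distance >= 3 from every other
#' seed. Both defining properties are asserted at generation time by direct
#' shortest-path computation; infeasible requests fail loudly.
#'
#' @param net background \linkS4class{InteractionNetwork}.
#' @param nCluster number of cluster seeds (>= 0; pairs require >= 2).
#' @param nDecoys number of decoy seeds (needs that many distinct attachment
#'   nodes in \code{net}).
#' @param nBridges number of bridge intermediates (>= 1 when a cluster of
#'   >= 2 seeds is requested without a hub).
#' @param hub wire the first cluster seed as a hub (degree
#'   \code{nCluster - 1 + nBridges} in the recovered sub-network)?
#' @param rngSeed integer seed.
#' @return list with \code{net} (augmented network), \code{seeds} (cluster +
#'   decoy symbols) and \code{truth} (a \linkS4class{SyntheticTruth}).
#' @export
plantSeedStructure <- function(net, nCluster, nDecoys, nBridges = 2,
                               hub = FALSE, rngSeed = 1L) {
  stopifnot(nCluster >= 0, nDecoys >= 0, nBridges >= 0)
  if (nCluster >= 2 && nBridges < 1 && !hub)
    stop("generation error: a cluster needs bridges (or a hub) to connect it")
  if (hub && nCluster < 2)
    stop("generation error: a hub needs at least 2 cluster seeds")
  set.seed(rngSeed)
  nodes0 <- networkNodes(net)
  if (nDecoys > length(nodes0))
    stop("generation error: network too small to host ", nDecoys, " decoys")
  cluster <- if (nCluster > 0) sprintf("CLUST%03d", seq_len(nCluster)) else character()
  bridges <- if (nCluster >= 2 && nBridges > 0) sprintf("BRIDGE%02d", seq_len(nBridges)) else character()
  decoys <- if (nDecoys > 0) sprintf("DECOY%03d", seq_len(nDecoys)) else character()
  stalks <- if (nDecoys > 0) sprintf("STALK%03d", seq_len(nDecoys)) else character()
  newNodes <- c(cluster, bridges, decoys, stalks)
  if (any(newNodes %in% nodes0))
    stop("generation error: planted node names collide with the background")
  from <- character(); to <- character()
  for (b in bridges) { from <- c(from, rep(b, nCluster)); to <- c(to, cluster) }
  hubGene <- character()
  if (hub) {
    hubGene <- cluster[1]
    from <- c(from, rep(hubGene, nCluster - 1)); to <- c(to, cluster[-1])
  }
  attach <- sort(sample(nodes0, nDecoys))
  if (nDecoys > 0) {
    from <- c(from, decoys, stalks)
    to <- c(to, stalks, attach)
  }
  g <- igraph::add_vertices(net@graph, length(newNodes), name = newNodes)
  if (length(from) > 0)
    g <- igraph::add_edges(g, rbind(from, to))
  aug <- new("InteractionNetwork", graph = g,
             provenance = paste0(net@provenance, "+planted"))
  seeds <- c(cluster, decoys)
  # generation-time assertions: the planted properties must hold exactly
  if (length(seeds) > 1) {
    D <- seedDistances(aug, seeds)
    if (length(cluster) >= 2) {
      dc <- D[cluster, cluster]
      if (any(dc[upper.tri(dc)] > 2))
        stop("generation error: cluster seeds not pairwise within distance 2")
    }
    for (d in decoys) {
      dd <- D[d, setdiff(seeds, d)]
      if (length(dd) > 0 && any(dd < 3))
        stop("generation error: decoy ", d, " within distance 2 of a seed")
    }
  }
  truth <- new("SyntheticTruth", plantedCluster = cluster,
               plantedBridges = bridges, decoySeeds = decoys,
               plantedHub = hubGene, plantedTerm = character(),
               plantedMiRNA = character())
  list(net = aug, seeds = seeds, truth = truth)
}

#' Generate gene sets with one planted over-represented term
#'
#' Random flat gene sets drawn from the universe, plus one planted term that
#' contains the whole planted query (padded with a few random extra genes),
#' so the planted term is by construction maximally over-represented for
#' that query.
#'
#' @param universe character vector of gene symbols (superset of
#'   \code{plantedQuery}).
#' @param nTerms number of random terms (>= 0).
#' @param sizeRange integer 2-vector, uniform size range of random terms.
#' @param plantedQuery the gene set the planted term must cover.
#' @param rngSeed integer seed.
#' @param padding number of extra random genes added to the planted term.
#' @return list with \code{sets} (a \linkS4class{GeneSetList}, random terms
#'   in order then the planted term) and \code{plantedId}.
#' @export
generateGeneSets <- function(universe, nTerms = 50, sizeRange = c(10, 40),
                             plantedQuery, rngSeed = 1L, padding = 2) {
  universe <- unique(normalizeSymbol(universe))
  plantedQuery <- unique(normalizeSymbol(plantedQuery))
  if (!all(plantedQuery %in% universe))
    stop("usage error: universe must contain the planted query")
  if (sizeRange[1] < 1 || sizeRange[2] > length(universe) ||
      sizeRange[1] > sizeRange[2])
    stop("usage error: infeasible size range")
  set.seed(rngSeed)
  ids <- character(); desc <- character(); members <- list()
  if (nTerms > 0) {
    for (i in seq_len(nTerms)) {
      sz <- sample(seq(sizeRange[1], sizeRange[2]), 1)
      ids <- c(ids, sprintf("TERM%03d", i))
      desc <- c(desc, sprintf("synthetic random term %d", i))
      members <- c(members, list(sort(sample(universe, sz))))
    }
  }
  pad <- sample(setdiff(universe, plantedQuery),
                min(padding, length(universe) - length(plantedQuery)))
  ids <- c(ids, "TERM_PLANTED")
  desc <- c(desc, "synthetic planted over-represented term")
  members <- c(members, list(sort(unique(c(plantedQuery, pad)))))
  list(sets = new("GeneSetList", ids = ids, descriptions = desc,
                  members = members),
       plantedId = "TERM_PLANTED")
}

#' Generate a miRNA target map with one planted enriched miRNA
#'
#' Random miRNAs with targets drawn uniformly from the universe, plus one
#' planted miRNA targeting most of the planted query (a random 80% subset,
#' at least one gene), so it is by construction the most enriched miRNA for
#' that query.
#'
#' @param universe character vector of gene symbols.
#' @param nMirnas number of random miRNAs.
#' @param targetsRange integer 2-vector, uniform target-count range.
#' @param plantedQuery gene set the planted miRNA targets.
#' @param rngSeed integer seed.
#' @param plantedFrac fraction of the planted query targeted (default 0.8).
#' @return list with \code{map} (a \linkS4class{MiRNATargetMap}) and
#'   \code{plantedId}.
#' @export
generateMiRNAMap <- function(universe, nMirnas = 50, targetsRange = c(1, 8),
                             plantedQuery, rngSeed = 1L, plantedFrac = 0.8) {
  universe <- unique(normalizeSymbol(universe))
  plantedQuery <- unique(normalizeSymbol(plantedQuery))
  if (length(plantedQuery) == 0)
    stop("usage error: planted query must be non-empty")
  if (!all(plantedQuery %in% universe))
    stop("usage error: universe must contain the planted query")
  if (targetsRange[1] < 1 || targetsRange[2] > length(universe) ||
      targetsRange[1] > targetsRange[2])
    stop("usage error: infeasible target-count range")
  set.seed(rngSeed)
  targets <- list()
  if (nMirnas > 0) {
    for (i in seq_len(nMirnas)) {
      sz <- sample(seq(targetsRange[1], targetsRange[2]), 1)
      targets[[sprintf("mir-syn-%03d", i)]] <- sort(sample(universe, sz))
    }
  }
  nPl <- max(1L, ceiling(plantedFrac * length(plantedQuery)))
  targets[["mir-syn-planted"]] <- sort(sample(plantedQuery, nPl))
  targets <- targets[order(names(targets))]
  list(map = new("MiRNATargetMap", targets = targets),
       plantedId = "mir-syn-planted")
}

#' Generate a synthetic DEG table
#'
#' Each gene receives a fold-change magnitude uniform in \code{foldRange}
#' and an up-regulation sign with probability \code{fracUp} (negative =
#' down-regulated), stamped with the given tissue and age.
#'
#' @param genes gene symbols.
#' @param fracUp probability of up-regulation in [0, 1].
#' @param foldRange numeric 2-vector, \code{1 <= low <= high}.
#' @param tissue,age_months stamped onto every record.
#' @param rngSeed integer seed.
#' @return a \linkS4class{DEGTable}.
#' @export
generateDEGTable <- function(genes, fracUp = 0.5, foldRange = c(1.7, 3.0),
                             tissue = "other", age_months = 6L, rngSeed = 1L) {
  stopifnot(fracUp >= 0, fracUp <= 1, foldRange[1] >= 1,
            foldRange[1] <= foldRange[2])
  genes <- unique(normalizeSymbol(genes))
  set.seed(rngSeed)
  mag <- round(stats::runif(length(genes), foldRange[1], foldRange[2]), 4)
  mag <- pmax(mag, foldRange[1])
  sign <- ifelse(stats::runif(length(genes)) < fracUp, 1, -1)
  DEGTable(data.frame(gene = genes, ratio = sign * mag,
                      stringsAsFactors = FALSE),
           provenance = sprintf("synthetic-deg(seed=%d)", rngSeed),
           tissue = tissue, age_months = age_months)
}

.bundleProfiles <- list(
  default = list(nNodes = 10000L, model = "preferential_attachment",
                 param = 4, nCluster = 60L, nDecoys = 20L, nBridges = 2L,
                 hub = TRUE, nTerms = 50L, setSize = c(10L, 40L),
                 nMirnas = 137L, targetsRange = c(10L, 45L),
                 nCoexprPairs = 5000L, nDisease = 40L,
                 foldRange = c(1.7, 3.0)),
  tiny = list(nNodes = 60L, model = "preferential_attachment", param = 2,
              nCluster = 5L, nDecoys = 2L, nBridges = 2L, hub = FALSE,
              nTerms = 10L, setSize = c(3L, 8L), nMirnas = 12L,
              targetsRange = c(2L, 5L), nCoexprPairs = 100L, nDisease = 8L,
              foldRange = c(1.7, 3.0)))

#' Generate a complete synthetic input bundle
#'
#' Produces every input the pipeline needs, with ground truth: a scale-free
#' background with a planted seed cluster, bridges, hub and decoys; a random
#' co-expression pair list; a DEG table over the seeds (fold range above the
#' 1.6 filter); gene sets with a planted over-represented term; a miRNA map
#' with a planted enriched miRNA; and a disease gene list enriched in the
#' planted sub-network. All randomness flows from the single \code{rngSeed};
#' two bundles with the same seed are identical (and, when written, their
#' files byte-identical).
#'
#' The \code{"default"} profile approximates the scale of curated human
#' interaction resources (1e4-node scale-free background with ~4e4 edges, 80
#' seeds, ~4e3 miRNA-target pairs); \code{"tiny"} (60 nodes) exercises the
#' full pipeline in milliseconds.
#'
#' @param profile \code{"default"}, \code{"tiny"}, or a named list
#'   overriding any profile field.
#' @param rngSeed integer seed.
#' @param dir optional directory: when given, the bundle is also written out
#'   via [writeBundle()].
#' @return a \linkS4class{SyntheticBundle}.
#' @export
makeBundle <- function(profile = "default", rngSeed = 1L, dir = NULL) {
  p <- if (is.character(profile)) {
    if (!profile %in% names(.bundleProfiles))
      stop("usage error: unknown profile '", profile, "'")
    .bundleProfiles[[profile]]
  } else utils::modifyList(.bundleProfiles$default, profile)
  rngSeed <- as.integer(rngSeed)
  set.seed(rngSeed)
  s <- sample.int(.Machine$integer.max - 1L, 8)
  bg0 <- generateBackground(p$nNodes, p$model, p$param, s[1])
  pl <- plantSeedStructure(bg0, p$nCluster, p$nDecoys, p$nBridges,
                           hub = p$hub, rngSeed = s[2])
  query <- sort(c(pl$truth@plantedCluster, pl$truth@plantedBridges))
  if (length(query) == 0) query <- pl$seeds
  nodes <- networkNodes(pl$net)
  sets <- generateGeneSets(nodes, p$nTerms, p$setSize, query, rngSeed = s[3])
  mir <- generateMiRNAMap(nodes, p$nMirnas, p$targetsRange, query,
                          rngSeed = s[4])
  set.seed(s[5])
  bgNodes <- networkNodes(bg0)
  ca <- sample(bgNodes, p$nCoexprPairs, replace = TRUE)
  cb <- sample(bgNodes, p$nCoexprPairs, replace = TRUE)
  ok <- ca != cb
  coex <- data.frame(gene_a = pmin(ca[ok], cb[ok]),
                     gene_b = pmax(ca[ok], cb[ok]),
                     r = round(stats::runif(sum(ok), -1, 1), 6),
                     stringsAsFactors = FALSE)
  coex <- coex[!duplicated(coex[, c("gene_a", "gene_b")]), , drop = FALSE]
  coex <- coex[order(coex$gene_a, coex$gene_b), , drop = FALSE]
  rownames(coex) <- NULL
  set.seed(s[6])
  nFromSubnet <- min(length(query), ceiling(p$nDisease / 2))
  disease <- sort(unique(c(sample(query, nFromSubnet),
                           sample(setdiff(nodes, query),
                                  p$nDisease - nFromSubnet))))
  half <- ceiling(length(pl$seeds) / 2)
  degH <- generateDEGTable(pl$seeds[seq_len(half)], foldRange = p$foldRange,
                           tissue = "hippocampus", age_months = 6L,
                           rngSeed = s[7])
  degC <- if (half < length(pl$seeds))
    generateDEGTable(pl$seeds[(half + 1):length(pl$seeds)],
                     foldRange = p$foldRange, tissue = "cortex",
                     age_months = 6L, rngSeed = s[8])@records
  else NULL
  deg <- new("DEGTable", records = rbind(degH@records, degC),
             provenance = sprintf("synthetic-bundle(seed=%d)", rngSeed))
  truth <- pl$truth
  truth@plantedTerm <- sets$plantedId
  truth@plantedMiRNA <- mir$plantedId
  bundle <- new("SyntheticBundle", background = pl$net, coexprPairs = coex,
                seeds = sort(pl$seeds), degTable = deg, geneSets = sets$sets,
                mirnaMap = mir$map, diseaseGenes = disease, truth = truth,
                rngSeed = rngSeed)
  if (!is.null(dir)) writeBundle(bundle, dir)
  bundle
}

#' Write a synthetic bundle to a directory in the standard file formats
#'
#' Emits background.tsv (pair-tsv edge list), coexpr_pairs.tsv,
#' deg_table.tsv, gene_sets.gmt, mirna_targets.tsv, disease_genes.txt,
#' truth.json and a ready-to-run pipeline config.yaml. All files are plain
#' text and parse back losslessly through the package readers.
#'
#' @param bundle a \linkS4class{SyntheticBundle}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  writeNetwork(bundle@background, fp("background.tsv"), format = "tsv")
  write.table(bundle@coexprPairs, fp("coexpr_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  write.table(bundle@degTable@records, fp("deg_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  writeGMT(bundle@geneSets, fp("gene_sets.gmt"))
  writeMiRNATargets(bundle@mirnaMap, fp("mirna_targets.tsv"))
  writeLines(bundle@diseaseGenes, fp("disease_genes.txt"))
  tr <- bundle@truth
  jsonlite::write_json(
    list(planted_cluster = tr@plantedCluster,
         planted_bridges = tr@plantedBridges,
         decoy_seeds = tr@decoySeeds, planted_hub = tr@plantedHub,
         planted_term = tr@plantedTerm, planted_mirna = tr@plantedMiRNA,
         rng_seed = bundle@rngSeed),
    fp("truth.json"), pretty = TRUE)
  cfg <- list(
    deg_inputs = list(list(path = "deg_table.tsv")),
    fold_threshold = 1.6,
    backgrounds = list(list(path = "background.tsv", dialect = "pair-tsv",
                            id = "ppi")),
    coexpr = list(path = "coexpr_pairs.tsv", r_min = 0.5, mode = "signed",
                  id = "coexpr"),
    max_distance = 2L, hub_min_neighbors = 14L,
    gene_sets = list("gene_sets.gmt"), universe_policy = "background",
    p_max = 1e-3, q_max = 0.01, mirna_targets = "mirna_targets.tsv",
    disease_genes = "disease_genes.txt", top_k_mirnas = 10L,
    rng_seed = bundle@rngSeed, output_dir = "out")
  writeLines(yaml::as.yaml(cfg), fp("config.yaml"))
  invisible(dir)
}

#' Re-verify the planted ground truth of a bundle
#'
#' Recomputes, from the bundle contents alone, whether each planted property
#' holds: cluster seeds pairwise within distance 2, decoys at distance >= 3
#' from all other seeds, sub-network extraction recovering exactly cluster +
#' bridges, the planted hub exceeding the degree threshold, and the planted
#' term and miRNA ranking first under enrichment of the recovered
#' sub-network.
#'
#' @param bundle a \linkS4class{SyntheticBundle}.
#' @param hubThreshold hub degree threshold (default 14).
#' @return named logical vector.
#' @export
verifyTruth <- function(bundle, hubThreshold = 14) {
  tr <- bundle@truth
  sn <- extractSubnetwork(bundle@background, bundle@seeds, quiet = TRUE)
  expect <- sort(c(tr@plantedCluster, tr@plantedBridges))
  res <- c(
    cluster_within_2 = length(tr@plantedCluster) < 2 || {
      D <- seedDistances(bundle@background, tr@plantedCluster)
      all(D[upper.tri(D)] <= 2)
    },
    decoys_beyond_2 = length(tr@decoySeeds) == 0 || {
      D <- seedDistances(bundle@background, bundle@seeds)
      all(vapply(tr@decoySeeds, function(d)
        all(D[d, setdiff(bundle@seeds, d)] >= 3), TRUE))
    },
    subnetwork_exact = identical(networkNodes(sn), expect),
    hub_detected = length(tr@plantedHub) == 0 ||
      identical(findHubSeeds(sn, hubThreshold), tr@plantedHub))
  enr <- enrichGeneSets(networkNodes(sn), bundle@geneSets,
                        universe = networkNodes(bundle@background))
  res["term_rank1"] <- nrow(enr) > 0 && enr$term_id[1] == tr@plantedTerm
  bip <- buildBipartite(networkNodes(sn), bundle@mirnaMap)
  mr <- enrichMiRNAs(bip, bundle@mirnaMap)
  res["mirna_rank1"] <- nrow(mr) > 0 && mr$mirna[1] == tr@plantedMiRNA
  res
}
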