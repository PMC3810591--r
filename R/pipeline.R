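.cfgDefaults <- list(
  fold_threshold = 1.6, max_distance = 2L, hub_min_neighbors = 14L,
  universe_policy = "background", p_max = 1e-3, q_max = 0.01,
  top_k_mirnas = 10L, gene_sets = list(), coexpr = NULL,
  disease_genes = NULL, rng_seed = NULL, output_dir = NULL,
  enrichment_method = "ease")

#' Load and validate a pipeline configuration
#'
#' The configuration mirrors the analysis parameters: DEG inputs and the
#' fold-change threshold (default 1.6, strict), background networks, an
#' optional co-expression input with its correlation threshold (default 0.5,
#' inclusive), the seed-pair distance cutoff (default 2, i.e. "less than
#' 3"), the hub degree threshold (default 14, strict), enrichment thresholds
#' (p < 1e-3, FDR < 0.01, strict) and the number of top miRNAs (default 10).
#' Relative paths are resolved against the config file's directory.
#'
#' @param config a named list or the path to a YAML file.
#' @return validated config list (class \code{seednet_config}).
#' @export
pipelineConfig <- function(config) {
  base <- "."
  if (is.character(config)) {
    base <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(.cfgDefaults, config)
  if (is.null(cfg$deg_inputs) || length(cfg$deg_inputs) == 0)
    stop("config error: at least one DEG input is required")
  if (is.null(cfg$backgrounds) || length(cfg$backgrounds) == 0)
    stop("config error: at least one background network is required")
  stopifnot(cfg$fold_threshold >= 1, cfg$max_distance >= 1,
            cfg$hub_min_neighbors >= 0, cfg$p_max > 0, cfg$p_max <= 1,
            cfg$q_max > 0, cfg$q_max <= 1, cfg$top_k_mirnas >= 1)
  resolve <- function(p) if (is.null(p) || grepl("^/", p)) p else file.path(base, p)
  cfg$deg_inputs <- lapply(cfg$deg_inputs, function(d) {
    if (is.character(d)) d <- list(path = d)
    d$path <- resolve(d$path); d
  })
  cfg$backgrounds <- lapply(cfg$backgrounds, function(b) {
    if (is.character(b)) b <- list(path = b)
    if (is.null(b$dialect)) b$dialect <- "pair-tsv"
    if (is.null(b$id)) b$id <- basename(b$path)
    b$path <- resolve(b$path); b
  })
  if (!is.null(cfg$coexpr)) {
    if (is.null(cfg$coexpr$r_min)) cfg$coexpr$r_min <- 0.5
    if (is.null(cfg$coexpr$mode)) cfg$coexpr$mode <- "signed"
    if (is.null(cfg$coexpr$id)) cfg$coexpr$id <- "coexpr"
    cfg$coexpr$path <- resolve(cfg$coexpr$path)
  }
  cfg$gene_sets <- lapply(cfg$gene_sets, resolve)
  if (!is.null(cfg$mirna_targets)) cfg$mirna_targets <- resolve(cfg$mirna_targets)
  if (!is.null(cfg$disease_genes)) cfg$disease_genes <- resolve(cfg$disease_genes)
  if (!is.null(cfg$output_dir) && !grepl("^/", cfg$output_dir))
    cfg$output_dir <- file.path(base, cfg$output_dir)
  class(cfg) <- c("seednet_config", "list")
  cfg
}

.stage <- function(name, quiet, expr) {
  if (!quiet) message("[seednet] stage: ", name)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
}

.configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full sub-network inference pipeline
#'
#' Executes the stages in order: parse and fold-change-filter the DEG tables;
#' form seed lists per tissue and pooled; extract a sub-network per
#' background network (including the thresholded co-expression background,
#' if configured); merge them; find hub seed genes and their modules;
#' gene-set enrichment of the merged sub-network and of each module; build
#' the miRNA-gene bipartite network and rank miRNAs; optionally test the
#' disease-gene overlap. All tables and exports are written under the output
#' directory with deterministic ordering, so a rerun with the same inputs is
#' artifact-for-artifact identical.
#'
#' @param config a config list or YAML path (see [pipelineConfig()]).
#' @param outputDir overrides the config's output directory.
#' @param quiet suppress stage log messages.
#' @return the pipeline report: a list (class \code{seednet_report}) whose
#'   every number is recomputable from the emitted artifacts.
#' @export
runPipeline <- function(config, outputDir = NULL, quiet = FALSE) {
  cfg <- if (inherits(config, "seednet_config")) config else pipelineConfig(config)
  outDir <- outputDir %||% cfg$output_dir
  if (is.null(outDir)) stop("config error: no output directory given")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  deg <- .stage("parse-deg", quiet, {
    tabs <- lapply(cfg$deg_inputs, function(d)
      readDEGTable(d$path, tissue = d$tissue %||% "other",
                   age_months = d$age_months %||% 1L)@records)
    new("DEGTable", records = do.call(rbind, tabs), provenance = "pipeline")
  })
  degF <- .stage("filter-deg", quiet,
                 filterDEG(deg, minFold = cfg$fold_threshold, strict = TRUE))

  tissues <- sort(unique(degF@records$tissue))
  seedSets <- c(setNames(lapply(tissues, function(t) degSeeds(degF, tissue = t)),
                         tissues),
                list(pooled = degSeeds(degF)))

  backgrounds <- .stage("read-backgrounds", quiet, {
    bgs <- lapply(cfg$backgrounds, function(b) {
      net <- suppressMessages(readNetwork(b$path, dialect = b$dialect))
      net@provenance <- b$id
      net
    })
    names(bgs) <- vapply(cfg$backgrounds, `[[`, "", "id")
    if (!is.null(cfg$coexpr)) {
      pairs <- readCoexpressionPairs(cfg$coexpr$path)
      cnet <- coexpressionFromPairs(pairs, rMin = cfg$coexpr$r_min,
                                    mode = cfg$coexpr$mode,
                                    provenance = cfg$coexpr$id)
      bgs[[cfg$coexpr$id]] <- cnet
    }
    bgs
  })

  subnets <- .stage("extract-subnetworks", quiet, {
    out <- list()
    for (bid in names(backgrounds)) {
      for (sid in names(seedSets)) {
        sn <- extractSubnetwork(backgrounds[[bid]], seedSets[[sid]],
                                maxDistance = cfg$max_distance,
                                backgroundId = paste(bid, sid, sep = ":"),
                                quiet = TRUE)
        out[[paste(bid, sid, sep = ":")]] <- sn
        writeSubnetwork(sn, file.path(outDir,
                                      sprintf("subnetwork_%s_%s.sif", bid, sid)),
                        format = "sif")
      }
    }
    out
  })
  pooled <- subnets[grepl(":pooled$", names(subnets))]
  merged <- .stage("merge-subnetworks", quiet, {
    m <- mergeSubnetworks(pooled, backgroundId = "merged")
    writeSubnetwork(m, file.path(outDir, "subnetwork_merged.sif"),
                    format = "sif")
    m
  })

  modules <- .stage("hubs-modules", quiet, {
    mods <- modulesReport(pooled, minNeighbors = cfg$hub_min_neighbors)
    .writeTSV(moduleSummary(mods), file.path(outDir, "modules.tsv"))
    for (m in mods)
      writeNetwork(m, file.path(outDir,
                                sprintf("module_%s_%s.sif", hubGene(m),
                                        gsub("[^A-Za-z0-9_.-]", "_",
                                             backgroundId(m)))),
                   format = "sif")
    mods
  })

  universe <- if (cfg$universe_policy == "background")
    sort(unique(unlist(lapply(backgrounds, networkNodes)))) else NULL

  enrich <- .stage("enrichment", quiet, {
    if (length(cfg$gene_sets) == 0) {
      if (!quiet) message("[seednet]   no gene sets configured; stage skipped")
      NULL
    } else {
      res <- list()
      for (gmt in cfg$gene_sets) {
        sets <- suppressWarnings(readGMT(gmt))
        uni <- universe %||% sort(unique(unlist(sets@members)))
        tag <- sub("\\.gmt$", "", basename(gmt))
        er <- enrichGeneSets(networkNodes(merged), sets, uni,
                             method = cfg$enrichment_method)
        .writeTSV(er, file.path(outDir,
                                sprintf("enrichment_merged_%s.tsv", tag)))
        .writeTSV(filterSignificant(er, cfg$p_max, cfg$q_max),
                  file.path(outDir,
                            sprintf("enrichment_merged_%s_significant.tsv", tag)))
        res[[tag]] <- list(merged = er)
        for (m in modules) {
          em <- enrichGeneSets(moduleMembers(m), sets, uni,
                               method = cfg$enrichment_method)
          .writeTSV(em, file.path(outDir,
                                  sprintf("enrichment_module_%s_%s.tsv",
                                          hubGene(m), tag)))
          res[[tag]][[paste0("module_", hubGene(m))]] <- em
        }
      }
      res
    }
  })

  mirna <- .stage("mirna-bipartite", quiet, {
    if (is.null(cfg$mirna_targets)) NULL else {
      tmap <- suppressMessages(readMiRNATargets(cfg$mirna_targets))
      bip <- buildBipartite(merged, tmap)
      er <- enrichMiRNAs(bip, tmap)
      .writeTSV(er, file.path(outDir, "mirna_enrichment.tsv"))
      .writeTSV(topK(er, cfg$top_k_mirnas),
                file.path(outDir, "mirna_top.tsv"))
      writeBipartite(bip, file.path(outDir, "mirna_bipartite.graphml"))
      list(bipartite = bip, results = er,
           top = topK(er, cfg$top_k_mirnas))
    }
  })

  disease <- .stage("disease-overlap", quiet, {
    if (is.null(cfg$disease_genes)) NULL else {
      dg <- readGeneList(cfg$disease_genes)
      uni <- universe %||% sort(unique(unlist(lapply(backgrounds, networkNodes))))
      ot <- suppressWarnings(diseaseOverlapTest(merged, dg, uni))
      .writeTSV(data.frame(subnet_size = ot$subnet_size, overlap = ot$overlap,
                           disease_size_in_universe = ot$disease_size_in_universe,
                           universe_size = ot$universe_size,
                           p_value = ot$p_value),
                file.path(outDir, "disease_overlap.tsv"))
      ot
    }
  })

  report <- .stage("report", quiet, {
    snSummary <- lapply(subnets, function(s) list(
      background_id = backgroundId(s),
      n_nodes = length(networkNodes(s)),
      n_edges = nrow(networkEdges(s)),
      n_seed = length(seedNodes(s)),
      n_intermediate = length(intermediateNodes(s)),
      n_qualifying_pairs = nrow(qualifyingPairs(s)),
      n_unmapped_seeds = length(unmappedSeeds(s))))
    rep <- list(
      config_hash = .configHash(cfg),
      rng_seed = cfg$rng_seed,
      package_version = as.character(utils::packageVersion("seednet")),
      n_deg_records = nrow(deg@records),
      n_deg_after_filter = nrow(degF@records),
      seed_counts = lapply(seedSets, length),
      subnetworks = snSummary,
      merged = list(n_nodes = length(networkNodes(merged)),
                    n_edges = nrow(networkEdges(merged)),
                    n_seed = length(seedNodes(merged)),
                    n_intermediate = length(intermediateNodes(merged))),
      hubs = lapply(modules, function(m) list(
        hub = hubGene(m), background_id = backgroundId(m),
        degree = length(moduleMembers(m)) - 1L)),
      enrichment_skipped = is.null(enrich),
      n_significant_terms = if (is.null(enrich)) NULL else
        vapply(enrich, function(e)
          nrow(filterSignificant(e$merged, cfg$p_max, cfg$q_max)), 1L),
      mirna_top = if (is.null(mirna)) NULL else
        mirna$top[, c("mirna", "k", "p_value", "rank")],
      disease_overlap = disease)
    jsonlite::write_json(rep, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    txt <- c(
      "seednet pipeline report",
      sprintf("config hash: %s", rep$config_hash),
      sprintf("DEG records: %d (after |fold| > %g filter: %d)",
              rep$n_deg_records, cfg$fold_threshold, rep$n_deg_after_filter),
      sprintf("merged sub-network: %d nodes (%d seed, %d intermediate), %d edges",
              rep$merged$n_nodes, rep$merged$n_seed,
              rep$merged$n_intermediate, rep$merged$n_edges),
      sprintf("hub modules: %d", length(modules)))
    writeLines(txt, file.path(outDir, "report.txt"))
    writeLines(yaml::as.yaml(unclass(cfg)), file.path(outDir, "config_used.yaml"))
    rep
  })

  out <- list(config = cfg, report = report, subnetworks = subnets,
              merged = merged, modules = modules, enrichment = enrich,
              mirna = mirna, disease = disease, output_dir = outDir)
  class(out) <- c("seednet_report", "list")
  invisible(out)
}

#' @export
print.seednet_report <- function(x, ...) {
  cat("seednet pipeline run ->", x$output_dir, "\n")
  cat(sprintf("  merged sub-network: %d nodes, %d hub module(s)\n",
              x$report$merged$n_nodes, length(x$modules)))
  invisible(x)
}
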