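test_that("background generation honors its model contracts", {
  # preferential attachment with m = 1 yields a tree (n - 1 edges)
  tree <- generateBackground(40, "preferential_attachment", 1, rngSeed = 3)
  expect_equal(nrow(networkEdges(tree)), 39L)
  # p = 0 yields no edges
  none <- generateBackground(10, "uniform_random", 0, rngSeed = 3)
  expect_equal(nrow(networkEdges(none)), 0L)
  # determinism: same seed, identical edge set; different seed differs
  a <- generateBackground(100, "preferential_attachment", 3, rngSeed = 5)
  b <- generateBackground(100, "preferential_attachment", 3, rngSeed = 5)
  c <- generateBackground(100, "preferential_attachment", 3, rngSeed = 6)
  expect_equal(networkEdges(a), networkEdges(b))
  expect_false(identical(networkEdges(a), networkEdges(c)))
  # heavy-tailed degrees: the max degree well exceeds the mean
  deg <- igraph::degree(a@graph)
  expect_gt(max(deg), 3 * mean(deg))
  expect_error(generateBackground(1), "usage error")
})

test_that("planted seed structures satisfy their defining distance properties", {
  bg <- generateBackground(100, "preferential_attachment", 2, rngSeed = 11)
  pl <- plantSeedStructure(bg, nCluster = 5, nDecoys = 3, nBridges = 2,
                           rngSeed = 12)
  tr <- pl$truth
  expect_equal(length(tr@plantedCluster), 5L)
  expect_equal(length(tr@decoySeeds), 3L)
  D <- seedDistances(pl$net, pl$seeds)
  dc <- D[tr@plantedCluster, tr@plantedCluster]
  expect_true(all(dc[upper.tri(dc)] <= 2))
  for (d in tr@decoySeeds)
    expect_true(all(D[d, setdiff(pl$seeds, d)] >= 3))
  # extraction recovers exactly cluster + bridges; decoys are absent
  sn <- extractSubnetwork(pl$net, pl$seeds, quiet = TRUE)
  expect_identical(networkNodes(sn),
                   sort(c(tr@plantedCluster, tr@plantedBridges)))
  expect_identical(sort(unmappedSeeds(sn)), character())
  # n_cluster = 0 -> extraction yields an empty sub-network
  pl0 <- plantSeedStructure(bg, nCluster = 0, nDecoys = 2, rngSeed = 13)
  sn0 <- extractSubnetwork(pl0$net, pl0$seeds, quiet = TRUE)
  expect_equal(length(networkNodes(sn0)), 0L)
  # infeasible requests fail loudly
  expect_error(plantSeedStructure(bg, nCluster = 3, nDecoys = 0, nBridges = 0),
               "generation error")
  tiny <- generateBackground(2, "uniform_random", 0, rngSeed = 1)
  expect_error(plantSeedStructure(tiny, 2, nDecoys = 5), "generation error")
})

test_that("a planted hub exceeds the degree threshold within the recovered sub-network", {
  bg <- generateBackground(100, "preferential_attachment", 2, rngSeed = 21)
  pl <- plantSeedStructure(bg, nCluster = 20, nDecoys = 2, nBridges = 2,
                           hub = TRUE, rngSeed = 22)
  sn <- extractSubnetwork(pl$net, pl$seeds, quiet = TRUE)
  expect_identical(findHubSeeds(sn, 14), pl$truth@plantedHub)
  expect_gte(igraph::degree(sn@graph, pl$truth@plantedHub), 20L)
})

test_that("synthetic DEG tables follow the sign and fold-range conventions", {
  genes <- sprintf("G%03d", 1:30)
  tab <- generateDEGTable(genes, fracUp = 1, foldRange = c(1.6, 1.6),
                          tissue = "hippocampus", age_months = 6, rngSeed = 4)
  rec <- degRecords(tab)
  expect_true(all(rec$ratio == 1.6))          # fixed range, all up
  tabMix <- generateDEGTable(genes, fracUp = 0.5, foldRange = c(1.7, 3),
                             rngSeed = 5)
  r <- degRecords(tabMix)$ratio
  expect_true(all(abs(r) >= 1.7 & abs(r) <= 3))
  # above-threshold ranges survive the strict 1.6 filter untouched
  expect_equal(nrow(degRecords(filterDEG(tabMix, 1.6))), 30L)
})

test_that("gene-set and miRNA generators plant a top-ranked object", {
  universe <- sprintf("G%04d", 1:500)
  query <- sprintf("G%04d", 1:12)
  gs <- generateGeneSets(universe, nTerms = 0, sizeRange = c(5, 10),
                         plantedQuery = query, rngSeed = 31)
  expect_equal(length(geneSetIds(gs$sets)), 1L)  # only the planted term
  expect_true(all(query %in% geneSetMembers(gs$sets)[[gs$plantedId]]))
  mm <- generateMiRNAMap(universe, nMirnas = 10, targetsRange = c(1, 1),
                         plantedQuery = query, rngSeed = 32)
  # pair count arithmetic: n random single-target miRNAs + planted size
  planted_n <- length(mirnaTargets(mm$map)[[mm$plantedId]])
  expect_equal(pairCount(mm$map), 10L + planted_n)
  mm2 <- generateMiRNAMap(universe, nMirnas = 10, targetsRange = c(1, 1),
                          plantedQuery = query, rngSeed = 32)
  expect_identical(mirnaTargets(mm$map), mirnaTargets(mm2$map))
  expect_error(generateGeneSets(universe, 5, c(5, 10), "NOT_IN_UNIVERSE"),
               "usage error")
})

test_that("bundles are reproducible from their seed and verify their own truth", {
  b1 <- makeBundle("tiny", rngSeed = 42)
  b2 <- makeBundle("tiny", rngSeed = 42)
  expect_equal(networkEdges(b1@background), networkEdges(b2@background))
  expect_identical(b1@seeds, b2@seeds)
  expect_identical(mirnaTargets(b1@mirnaMap), mirnaTargets(b2@mirnaMap))
  expect_true(all(verifyTruth(b1, hubThreshold = 3)[
    c("cluster_within_2", "decoys_beyond_2", "subnetwork_exact")]))
  # written twice with the same seed -> byte-identical files
  d1 <- tempfile(); d2 <- tempfile()
  writeBundle(b1, d1); writeBundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("bundle files parse back losslessly through the package readers", {
  d <- tempfile()
  b <- makeBundle("tiny", rngSeed = 9, dir = d)
  net <- suppressMessages(readNetwork(file.path(d, "background.tsv"), "pair-tsv"))
  expect_equal(networkEdges(net)[, c("from", "to")],
               networkEdges(b@background)[, c("from", "to")])
  expect_identical(networkNodes(net)[networkNodes(net) %in% b@seeds],
                   b@seeds[b@seeds %in% networkNodes(net)])
  deg <- readDEGTable(file.path(d, "deg_table.tsv"))
  expect_equal(degRecords(deg), degRecords(b@degTable))
  sets <- readGMT(file.path(d, "gene_sets.gmt"))
  expect_identical(geneSetMembers(sets), geneSetMembers(b@geneSets))
  map <- readMiRNATargets(file.path(d, "mirna_targets.tsv"), quiet = TRUE)
  expect_identical(mirnaTargets(map), mirnaTargets(b@mirnaMap))
  expect_identical(readGeneList(file.path(d, "disease_genes.txt")),
                   b@diseaseGenes)
  tr <- jsonlite::read_json(file.path(d, "truth.json"), simplifyVector = TRUE)
  expect_identical(sort(tr$planted_cluster), b@truth@plantedCluster)
})
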