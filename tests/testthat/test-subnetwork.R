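test_that("seed mapping splits mapped and unmapped without error", {
  net <- interactionNetwork(data.frame(from = "A", to = "B"))
  m <- mapSeeds(net, c("A", "C"), quiet = TRUE)
  expect_identical(m$mapped, "A")
  expect_identical(m$unmapped, "C")
  expect_identical(mapSeeds(net, c("A", "B"), quiet = TRUE)$unmapped,
                   character())
  m0 <- mapSeeds(net, c("X", "Y"), quiet = TRUE)
  expect_identical(m0$mapped, character())
})

test_that("extraction keeps seed pairs below distance 3 with their intermediates", {
  net <- interactionNetwork(data.frame(from = c("A", "B"), to = c("B", "C")))
  sn <- extractSubnetwork(net, c("A", "C"), quiet = TRUE)
  expect_identical(seedNodes(sn), c("A", "C"))
  expect_identical(intermediateNodes(sn), "B")
  expect_equal(nrow(networkEdges(sn)), 2L)
  qp <- qualifyingPairs(sn)
  expect_equal(nrow(qp), 1L)
  expect_equal(qp$distance, 2L)

  # distance-3 seeds are excluded ("less than 3")
  p4 <- interactionNetwork(data.frame(from = c("A", "B", "C"),
                                      to = c("B", "C", "D")))
  empty <- extractSubnetwork(p4, c("A", "D"), quiet = TRUE)
  expect_equal(length(networkNodes(empty)), 0L)

  # all common neighbors of a distance-2 pair are included
  net2 <- interactionNetwork(data.frame(from = c("A", "B", "A", "X"),
                                        to = c("B", "C", "X", "C")))
  sn2 <- extractSubnetwork(net2, c("A", "C"), quiet = TRUE)
  expect_identical(intermediateNodes(sn2), c("B", "X"))
  expect_equal(length(networkNodes(sn2)), 4L)
  expect_equal(nrow(networkEdges(sn2)), 4L)
})

test_that("a seed lying between two other seeds stays classified as seed", {
  net <- interactionNetwork(data.frame(from = c("A", "B"), to = c("B", "C")))
  sn <- extractSubnetwork(net, c("A", "B", "C"), quiet = TRUE)
  expect_identical(seedNodes(sn), c("A", "B", "C"))
  expect_identical(intermediateNodes(sn), character())
})

test_that("seeds with no qualifying partner are excluded, not kept as isolates", {
  # Q3 is two steps away from every other seed's component
  net <- interactionNetwork(data.frame(from = c("A", "Q1", "Q2"),
                                       to = c("B", "Q2", "Q3")))
  sn <- extractSubnetwork(net, c("A", "B", "Q3"), quiet = TRUE)
  expect_identical(seedNodes(sn), c("A", "B"))
  expect_false("Q3" %in% networkNodes(sn))
})

test_that("extraction node sets equal the brute-force length<=2 path oracle", {
  set.seed(404)
  for (rep in 1:500) {
    fx <- random_graph_fixture(sample(4:10, 1), stats::runif(1, 0.1, 0.7))
    net <- interactionNetwork(fx$edges, nodes = fx$nodes, quiet = TRUE)
    seeds <- sample(fx$nodes, sample(2:length(fx$nodes), 1))
    sn <- extractSubnetwork(net, seeds, quiet = TRUE)
    A <- oracle_adjacency(fx$nodes, fx$edges)
    expect_identical(networkNodes(sn), oracle_subnetwork_nodes(A, seeds))
  }
})

test_that("extraction is monotone in maxDistance and deterministic", {
  set.seed(505)
  for (rep in 1:50) {
    fx <- random_graph_fixture(sample(5:9, 1), stats::runif(1, 0.15, 0.5))
    net <- interactionNetwork(fx$edges, nodes = fx$nodes, quiet = TRUE)
    seeds <- sample(fx$nodes, 3)
    sn1 <- extractSubnetwork(net, seeds, maxDistance = 1, quiet = TRUE)
    sn2 <- extractSubnetwork(net, seeds, maxDistance = 2, quiet = TRUE)
    expect_true(all(networkNodes(sn1) %in% networkNodes(sn2)))
    again <- extractSubnetwork(net, seeds, maxDistance = 2, quiet = TRUE)
    expect_identical(networkNodes(sn2), networkNodes(again))
    expect_identical(qualifyingPairs(sn2), qualifyingPairs(again))
    # every intermediate is a common background neighbor of a distance-2 pair
    for (w in intermediateNodes(sn2)) {
      qp <- qualifyingPairs(sn2)
      qp <- qp[qp$distance == 2L, , drop = FALSE]
      ok <- any(vapply(seq_len(nrow(qp)), function(i)
        w %in% length2Intermediates(net, qp$seed_a[i], qp$seed_b[i]), TRUE))
      expect_true(ok)
    }
  }
})

test_that("merging unions nodes and edges with seed role precedence", {
  netX <- interactionNetwork(data.frame(from = c("A", "B"), to = c("B", "C")))
  netY <- interactionNetwork(data.frame(from = c("D", "E"), to = c("E", "F")))
  s1 <- extractSubnetwork(netX, c("A", "C"), backgroundId = "x", quiet = TRUE)
  s2 <- extractSubnetwork(netY, c("D", "F"), backgroundId = "y", quiet = TRUE)
  mg <- mergeSubnetworks(list(s1, s2))
  expect_equal(length(networkNodes(mg)),
               length(networkNodes(s1)) + length(networkNodes(s2)))
  expect_equal(nrow(networkEdges(mg)),
               nrow(networkEdges(s1)) + nrow(networkEdges(s2)))
  # idempotent on identical parts
  mg2 <- mergeSubnetworks(list(s1, s1), backgroundId = "x")
  expect_identical(networkNodes(mg2), networkNodes(s1))
  expect_equal(networkEdges(mg2)[, c("from", "to")],
               networkEdges(s1)[, c("from", "to")])
  # a gene seed in one part, intermediate in another, is seed in the merge
  netZ <- interactionNetwork(data.frame(from = c("B", "H"), to = c("H", "Q")))
  s3 <- extractSubnetwork(netZ, c("B", "Q"), backgroundId = "z", quiet = TRUE)
  # in s1, B is intermediate; in s3, B is seed
  expect_true("B" %in% intermediateNodes(s1))
  expect_true("B" %in% seedNodes(s3))
  mg3 <- mergeSubnetworks(list(s1, s3))
  expect_true("B" %in% seedNodes(mg3))
  expect_false("B" %in% intermediateNodes(mg3))
})

test_that("disease overlap matches subset-enumeration probabilities", {
  net <- interactionNetwork(data.frame(from = c("A", "C"), to = c("B", "D")))
  sn <- extractSubnetwork(net, c("A", "B"), quiet = TRUE)
  # subnet {A,B}, disease {A,B}, universe of 4: p = 1/C(4,2) = 1/6
  ot <- diseaseOverlapTest(sn, c("A", "B"), c("A", "B", "C", "D"))
  expect_equal(ot$p_value, 1 / choose(4, 2))
  expect_equal(ot$overlap, 2L)
  # zero overlap and subnet == universe both give p = 1
  expect_equal(diseaseOverlapTest(c("A", "B"), c("C", "D"),
                                  c("A", "B", "C", "D"))$p_value, 1)
  expect_equal(diseaseOverlapTest(c("A", "B", "C", "D"), c("A", "B"),
                                  c("A", "B", "C", "D"))$p_value, 1)
  expect_error(diseaseOverlapTest(sn, "A", character()), "empty universe")
  expect_warning(diseaseOverlapTest(c("A", "ZZ"), "A", c("A", "B")),
                 "outside the universe")
})
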