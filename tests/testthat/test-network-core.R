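test_that("shortest distances match the paper's path semantics on small cases", {
  path <- interactionNetwork(data.frame(from = c("A", "B"), to = c("B", "C")))
  expect_equal(shortestDistance(path, "A", "B"), 1)  # directly connected
  expect_equal(shortestDistance(path, "A", "C"), 2)  # one intermediate
  expect_equal(shortestDistance(path, "A", "A"), 0)
  disj <- interactionNetwork(data.frame(from = c("A", "C"), to = c("B", "D")))
  expect_identical(shortestDistance(disj, "A", "C"), Inf)
  expect_error(shortestDistance(path, "A", "Z"), "missing node")
})

test_that("shortest distances agree with exhaustive path enumeration on random graphs", {
  set.seed(101)
  for (rep in 1:500) {
    fx <- random_graph_fixture(sample(2:8, 1), stats::runif(1, 0.1, 0.9))
    net <- interactionNetwork(fx$edges, nodes = fx$nodes, quiet = TRUE)
    A <- oracle_adjacency(fx$nodes, fx$edges)
    ab <- sample(fx$nodes, 2)
    expect_equal(shortestDistance(net, ab[1], ab[2]),
                 oracle_shortest_distance(A, ab[1], ab[2]))
    expect_equal(shortestDistance(net, ab[1], ab[2]),
                 shortestDistance(net, ab[2], ab[1]))  # symmetry
  }
})

test_that("triangle inequality holds for finite distances", {
  set.seed(202)
  for (rep in 1:50) {
    fx <- random_graph_fixture(6, 0.4)
    net <- interactionNetwork(fx$edges, nodes = fx$nodes, quiet = TRUE)
    D <- seedDistances(net, fx$nodes)
    for (a in 1:6) for (b in 1:6) for (c in 1:6) {
      if (is.finite(D[a, b]) && is.finite(D[b, c]))
        expect_lte(D[a, c], D[a, b] + D[b, c])
    }
  }
})

test_that("length-2 intermediates are exactly the common neighbors of distance-2 pairs", {
  net <- interactionNetwork(data.frame(from = c("A", "B"), to = c("B", "C")))
  expect_identical(length2Intermediates(net, "A", "C"), "B")
  net2 <- interactionNetwork(data.frame(from = c("A", "B", "A", "X"),
                                        to = c("B", "C", "X", "C")))
  expect_identical(length2Intermediates(net2, "A", "C"), c("B", "X"))
  # adjacent pair: distance 1, no intermediates even with common neighbors
  tri <- interactionNetwork(data.frame(from = c("A", "B", "A"),
                                       to = c("B", "C", "C")))
  expect_identical(length2Intermediates(tri, "A", "C"), character())
  expect_error(length2Intermediates(net, "A", "A"), "distinct")
  expect_error(length2Intermediates(net, "A", "Z"), "missing node")
})

test_that("intermediates are nonempty iff distance is exactly 2 (random graphs)", {
  set.seed(303)
  for (rep in 1:100) {
    fx <- random_graph_fixture(sample(3:8, 1), stats::runif(1, 0.2, 0.8))
    net <- interactionNetwork(fx$edges, nodes = fx$nodes, quiet = TRUE)
    ab <- sample(fx$nodes, 2)
    d <- shortestDistance(net, ab[1], ab[2])
    ints <- length2Intermediates(net, ab[1], ab[2])
    expect_equal(length(ints) > 0, d == 2)
  }
})

test_that("induced subgraphs keep exactly the kept nodes and their edges", {
  tri <- interactionNetwork(data.frame(from = c("A", "B", "A"),
                                       to = c("B", "C", "C")))
  sub <- inducedSubgraph(tri, c("A", "B"))
  expect_identical(networkNodes(sub), c("A", "B"))
  expect_equal(nrow(networkEdges(sub)), 1L)
  expect_equal(length(networkNodes(inducedSubgraph(tri, character()))), 0L)
  full <- inducedSubgraph(tri, c("A", "B", "C"))
  expect_identical(networkNodes(full), networkNodes(tri))
  expect_equal(networkEdges(full), networkEdges(tri))
  expect_error(inducedSubgraph(tri, "Z"), "missing node")
})

test_that("degree and neighbors behave on stars, triangles and isolates", {
  star <- interactionNetwork(data.frame(from = rep("HUB", 15),
                                        to = sprintf("L%02d", 1:15)))
  expect_equal(nodeDegree(star, "HUB"), 15L)
  expect_identical(nodeNeighbors(star, "HUB"), sort(sprintf("L%02d", 1:15)))
  iso <- interactionNetwork(NULL, nodes = "ALONE")
  expect_equal(nodeDegree(iso, "ALONE"), 0L)
  tri <- interactionNetwork(data.frame(from = c("A", "B", "A"),
                                       to = c("B", "C", "C")))
  expect_equal(nodeDegree(tri, "B"), 2L)
  expect_false("B" %in% nodeNeighbors(tri, "B"))
})
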