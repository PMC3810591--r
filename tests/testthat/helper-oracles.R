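# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and igraph) so they can stand as ground truth.

# adjacency matrix from an edge data.frame over given node names
oracle_adjacency <- function(nodes, edges) {
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      A[edges$from[i], edges$to[i]] <- TRUE
      A[edges$to[i], edges$from[i]] <- TRUE
    }
  }
  diag(A) <- FALSE
  A
}

# exhaustive simple-path search: shortest distance by enumerating all simple
# paths (only feasible on tiny graphs)
oracle_shortest_distance <- function(A, a, b) {
  if (a == b) return(0)
  nodes <- rownames(A)
  best <- Inf
  recurse <- function(cur, visited, len) {
    if (len >= best) return()
    for (nxt in nodes[A[cur, ]]) {
      if (nxt == b) { best <<- min(best, len + 1); next }
      if (!(nxt %in% visited)) recurse(nxt, c(visited, nxt), len + 1)
    }
  }
  recurse(a, a, 0)
  best
}

# brute-force sub-network node set: every seed pair connected by a direct
# edge or by some length-2 path; intermediates are the non-seed middles of
# length-2 paths between non-adjacent seed pairs
oracle_subnetwork_nodes <- function(A, seeds) {
  nodes <- rownames(A)
  seeds <- intersect(seeds, nodes)
  keep_seeds <- character(); inter <- character()
  if (length(seeds) >= 2) {
    for (i in seq_len(length(seeds) - 1)) for (j in (i + 1):length(seeds)) {
      a <- seeds[i]; b <- seeds[j]
      if (A[a, b]) {
        keep_seeds <- c(keep_seeds, a, b)
      } else {
        mids <- nodes[A[a, ] & A[b, ]]
        if (length(mids) > 0) {
          keep_seeds <- c(keep_seeds, a, b)
          inter <- c(inter, setdiff(mids, seeds))
        }
      }
    }
  }
  sort(unique(c(keep_seeds, inter)))
}

# exhaustive hypergeometric upper tail: enumerate every n-subset of a
# universe whose first K elements are annotated and count overlaps >= k
oracle_fisher_tail <- function(k, n, K, N) {
  if (k == 0) return(1)
  if (n == 0) return(if (k == 0) 1 else 0)
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= K)
  mean(overlap >= k)
}

# uniform random simple graph over named nodes, plus its edge data.frame
random_graph_fixture <- function(n_nodes, p_edge) {
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}

fixture_path <- function(f) system.file("extdata", f, package = "seednet")

tsv_lines <- function(...) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(...), tf)
  tf
}
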