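.checkCounts <- function(k, n, K, N) {
  if (any(is.na(c(k, n, K, N))))
    stop("validation error: missing contingency counts")
  if (k < 0 || n < 0 || K < 0 || N < 1 || k > min(n, K) || n > N || K > N)
    stop(sprintf(
      "validation error: invalid contingency counts k=%d n=%d K=%d N=%d",
      k, n, K, N))
  invisible(TRUE)
}

#' One-sided Fisher exact over-representation p-value
#'
#' Upper-tail hypergeometric probability P(X >= k) of drawing at least
#' \code{k} annotated genes when \code{n} genes are sampled without
#' replacement from a universe of \code{N} genes of which \code{K} carry the
#' annotation. Computed exactly in log space (log-binomial terms combined by
#' a max-shifted log-sum-exp), so it stays accurate for universes of 1e5
#' genes and beyond; no chi-square approximation is involved.
#'
#' @param k overlap count (query AND term).
#' @param n query size within the universe.
#' @param K term size within the universe.
#' @param N universe size.
#' @return p-value in (0, 1]; exactly 1 when \code{k = 0}.
#' @export
fisherOverrep <- function(k, n, K, N) {
  .checkCounts(k, n, K, N)
  if (k == 0) return(1)
  i <- k:min(n, K)
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lp)
  p <- exp(m + log(sum(exp(lp - m))))
  min(p, 1)
}

#' EASE-score over-representation p-value
#'
#' The conservative "jackknife" variant of the one-sided Fisher exact test
#' used by the EASE/DAVID tools: one gene is removed from the overlap
#' (\code{k' = max(k - 1, 0)}) before computing the upper tail, so
#' single-gene overlaps are nulled (p = 1) and the score is always at least
#' the plain Fisher p-value.
#'
#' @inheritParams fisherOverrep
#' @return p-value in (0, 1].
#' @export
easeScore <- function(k, n, K, N) {
  .checkCounts(k, n, K, N)
  fisherOverrep(max(k - 1L, 0L), n, K, N)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjusted values \code{q_(i) = min_(j >= i) p_(j) * m / j}, capped
#' at 1 and returned in the input order. Invariant to permutations of the
#' input (up to the same reordering).
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same length and order.
#' @export
bhFDR <- function(pvals) {
  if (length(pvals) == 0) return(numeric())
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("validation error: p-values must lie in [0, 1]")
  m <- length(pvals)
  ord <- order(pvals)
  q <- pvals[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(ord)]
}

#' Gene-set over-representation analysis
#'
#' Tests every gene set for over-representation of a query gene list within
#' a stated universe, using either the plain one-sided Fisher exact test or
#' its conservative EASE-score variant (the default, as in DAVID-style
#' annotation tools). Query genes outside the universe are dropped with a
#' warning; each set's membership is intersected with the universe and sets
#' left empty are not tested. Benjamini-Hochberg q-values are computed over
#' all terms tested in the call (one multiple-testing family per call).
#'
#' @param query character vector of gene symbols.
#' @param sets a \linkS4class{GeneSetList}.
#' @param universe character vector of gene symbols (non-empty).
#' @param method \code{"ease"} (default) or \code{"fisher"}; selects the
#'   p-value used for ranking, filtering and FDR adjustment.
#' @return data.frame with one row per tested set, columns \code{term_id},
#'   \code{term_name}, \code{k}, \code{n}, \code{K}, \code{N},
#'   \code{p_fisher}, \code{p_ease}, \code{p_value} (the chosen method's),
#'   \code{q_bh}; sorted by ascending \code{p_value} with ties broken by
#'   \code{term_id}.
#' @export
enrichGeneSets <- function(query, sets, universe,
                           method = c("ease", "fisher")) {
  method <- match.arg(method)
  universe <- unique(normalizeSymbol(universe))
  if (length(universe) == 0) stop("usage error: empty universe")
  query <- unique(normalizeSymbol(query))
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0)
    warning(length(dropped), " query gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  n <- length(query); N <- length(universe)
  ids <- sets@ids
  rows <- lapply(seq_along(ids), function(i) {
    memb <- intersect(sets@members[[i]], universe)
    K <- length(memb)
    if (K == 0) return(NULL)
    k <- length(intersect(query, memb))
    data.frame(term_id = ids[i], term_name = sets@descriptions[i],
               k = k, n = n, K = K, N = N,
               p_fisher = fisherOverrep(k, n, K, N),
               p_ease = easeScore(k, n, K, N), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p_fisher = numeric(), p_ease = numeric(),
                      p_value = numeric(), q_bh = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$p_value <- if (method == "ease") res$p_ease else res$p_fisher
  res$q_bh <- bhFDR(res$p_value)
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "method") <- method
  res
}

#' Filter enrichment results by significance thresholds
#'
#' Keeps results with \code{p_value < pMax} and \code{q_bh < qMax}, both
#' strict inequalities (a result at exactly the threshold is excluded).
#'
#' @param results data.frame from [enrichGeneSets()] (or any frame with
#'   \code{p_value} and \code{q_bh} columns).
#' @param pMax raw p-value threshold, default 1e-3.
#' @param qMax FDR threshold, default 0.01.
#' @return the filtered data.frame.
#' @export
filterSignificant <- function(results, pMax = 1e-3, qMax = 0.01) {
  stopifnot(pMax > 0, pMax <= 1, qMax > 0, qMax <= 1)
  if (nrow(results) == 0) return(results)
  out <- results[results$p_value < pMax & results$q_bh < qMax, , drop = FALSE]
  rownames(out) <- NULL
  out
}
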