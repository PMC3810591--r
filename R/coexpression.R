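#' Read gene-pair correlation records
#'
#' @param path 3-column TSV with header \code{gene_a gene_b r}.
#' @param aliases optional alias map passed to [normalizeSymbol()].
#' @return data.frame (gene_a, gene_b, r) with normalized symbols.
#' @export
readCoexpressionPairs <- function(path, aliases = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, quote = "", fileEncoding = "UTF-8")
  need <- c("gene_a", "gene_b", "r")
  if (!all(need %in% names(df)))
    stop("schema error: expected columns gene_a, gene_b, r in ", path)
  data.frame(gene_a = normalizeSymbol(df$gene_a, aliases),
             gene_b = normalizeSymbol(df$gene_b, aliases),
             r = as.numeric(df$r), stringsAsFactors = FALSE)
}

#' Build a co-expression network from correlation pairs
#'
#' An edge is kept when the pair's correlation coefficient meets the
#' threshold: \code{r >= rMin} in signed mode (the default, reading
#' "equal to or greater than" literally as positive co-expression, inclusive
#' boundary) or \code{|r| >= rMin} in absolute mode. All genes mentioned in
#' the pair list remain nodes of the background.
#'
#' @param pairs data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{r} (each r in [-1, 1], gene_a != gene_b).
#' @param rMin correlation threshold in (0, 1], default 0.5.
#' @param mode \code{"signed"} or \code{"absolute"}.
#' @param provenance free-text origin.
#' @return an \linkS4class{InteractionNetwork}.
#' @export
coexpressionFromPairs <- function(pairs, rMin = 0.5,
                                  mode = c("signed", "absolute"),
                                  provenance = "coexpression") {
  mode <- match.arg(mode)
  stopifnot(rMin > 0, rMin <= 1)
  if (nrow(pairs) == 0)
    return(interactionNetwork(NULL, provenance = provenance))
  if (any(is.na(pairs$r)) || any(pairs$r < -1) || any(pairs$r > 1))
    stop("validation error: correlation coefficients must lie in [-1, 1]")
  if (any(pairs$gene_a == pairs$gene_b))
    stop("validation error: self-pairs are not allowed")
  keep <- if (mode == "signed") pairs$r >= rMin else abs(pairs$r) >= rMin
  interactionNetwork(
    data.frame(from = pairs$gene_a[keep], to = pairs$gene_b[keep],
               kind = "coexpression", stringsAsFactors = FALSE),
    nodes = unique(c(pairs$gene_a, pairs$gene_b)),
    provenance = provenance, quiet = TRUE)
}

#' Build a co-expression network from an expression matrix
#'
#' Computes the Pearson correlation for every gene pair of a genes x samples
#' matrix and thresholds it exactly as [coexpressionFromPairs()]. Zero-
#' variance gene rows are dropped with a warning; at least 3 samples are
#' required.
#'
#' @param expr numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns.
#' @param rMin,mode,provenance as in [coexpressionFromPairs()].
#' @return an \linkS4class{InteractionNetwork}.
#' @export
coexpressionFromMatrix <- function(expr, rMin = 0.5,
                                   mode = c("signed", "absolute"),
                                   provenance = "coexpression-matrix") {
  mode <- match.arg(mode)
  if (ncol(expr) < 3) stop("usage error: at least 3 samples required")
  if (is.null(rownames(expr))) stop("expression matrix must have gene rownames")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene row(s) dropped")
    expr <- expr[v > 0, , drop = FALSE]
  }
  coexpressionFromPairs(correlationPairs(expr), rMin = rMin, mode = mode,
                        provenance = provenance)
}

#' Exhaustive gene-pair Pearson correlations of an expression matrix
#'
#' @param expr numeric matrix, genes in rows with rownames.
#' @return data.frame (gene_a, gene_b, r) over all unordered gene pairs.
#' @export
correlationPairs <- function(expr) {
  genes <- normalizeSymbol(rownames(expr))
  if (length(genes) < 2)
    return(data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), stringsAsFactors = FALSE))
  cm <- stats::cor(t(expr))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  # numerical guard: cor() can exceed |1| by rounding
  data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
             r = pmin(1, pmax(-1, cm[idx])), stringsAsFactors = FALSE)
}
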