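#' Read gene sets in GMT format
#'
#' Each row is \code{set_id<TAB>description<TAB>gene1<TAB>gene2...}. Member
#' symbols are normalized and deduplicated; sets left empty are dropped with
#' a warning; rows with fewer than three fields are a parse error.
#'
#' @param path path to the GMT file.
#' @param aliases optional alias map passed to [normalizeSymbol()].
#' @return a \linkS4class{GeneSetList} preserving file order.
#' @export
readGMT <- function(path, aliases = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ids <- character(); desc <- character(); members <- list()
  for (i in seq_along(lines)) {
    # count separators on the raw line: trailing tabs (an id + description
    # with no members) are an empty set, not a malformed row
    if (lengths(regmatches(lines[i], gregexpr("\t", lines[i], fixed = TRUE))) < 2)
      stop(sprintf("parse error: GMT row %d of %s has fewer than 3 fields",
                   i, path))
    tk <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(tk) < 2) tk <- c(tk, "")
    genes <- trimws(tk[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      warning(sprintf("empty gene set '%s' dropped (row %d)", tk[1], i))
      next
    }
    ids <- c(ids, trimws(tk[1]))
    desc <- c(desc, trimws(tk[2]))
    members <- c(members, list(unique(normalizeSymbol(genes, aliases))))
  }
  new("GeneSetList", ids = ids, descriptions = desc, members = members)
}

#' Construct a GeneSetList in code
#'
#' @param members named list of character vectors (names are the set ids).
#' @param descriptions optional descriptions (default the ids).
#' @return a \linkS4class{GeneSetList}.
#' @export
geneSetList <- function(members, descriptions = names(members)) {
  new("GeneSetList", ids = names(members),
      descriptions = as.character(descriptions),
      members = lapply(members, function(m) unique(normalizeSymbol(m))))
}

#' Write gene sets in GMT format
#'
#' @param sets a \linkS4class{GeneSetList}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGMT <- function(sets, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(sets@ids))
    writeLines(paste(c(sets@ids[i], sets@descriptions[i], sets@members[[i]]),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a miRNA -> target map
#'
#' Rows are \code{mirna_id<TAB>gene_symbol}. miRNA ids are kept verbatim
#' (trimmed); target gene symbols are normalized. Duplicate pairs are
#' collapsed and the number of distinct pairs is reported with a message.
#'
#' @param path path to the 2-column TSV.
#' @param aliases optional alias map passed to [normalizeSymbol()].
#' @param quiet suppress the pair-count message.
#' @return a \linkS4class{MiRNATargetMap}.
#' @export
readMiRNATargets <- function(path, aliases = NULL, quiet = FALSE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(new("MiRNATargetMap"))
  toks <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(toks, function(t) sum(nzchar(trimws(t))) < 2, TRUE))
  if (length(bad) > 0)
    stop(sprintf("parse error: malformed miRNA-target row %d of %s",
                 bad[1], path))
  mir <- trimws(vapply(toks, `[[`, "", 1L))
  gene <- normalizeSymbol(vapply(toks, `[[`, "", 2L), aliases)
  keep <- !duplicated(paste(mir, gene, sep = "\r"))
  mir <- mir[keep]; gene <- gene[keep]
  tg <- split(gene, mir)
  tg <- tg[order(names(tg))]
  map <- new("MiRNATargetMap", targets = tg)
  if (!quiet)
    message(pairCount(map), " distinct miRNA-target pair(s) read")
  map
}

#' Construct a miRNA target map in code
#'
#' @param targets named list: miRNA id -> character vector of targets.
#' @return a \linkS4class{MiRNATargetMap}.
#' @export
mirnaTargetMap <- function(targets) {
  tg <- lapply(targets, function(g) unique(normalizeSymbol(g)))
  tg <- tg[order(names(tg))]
  new("MiRNATargetMap", targets = tg)
}

#' Write a miRNA -> target map as 2-column TSV
#'
#' @param map a \linkS4class{MiRNATargetMap}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeMiRNATargets <- function(map, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (m in names(map@targets))
    writeLines(paste(m, sort(map@targets[[m]]), sep = "\t"), con)
  invisible(path)
}

#' Read a one-column gene list
#'
#' @param path path to a text file with one gene symbol per line (blank
#'   lines skipped).
#' @param aliases optional alias map passed to [normalizeSymbol()].
#' @return sorted character vector of unique normalized symbols.
#' @export
readGeneList <- function(path, aliases = NULL) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(character())
  sort(unique(normalizeSymbol(lines, aliases)))
}
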