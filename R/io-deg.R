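.normTissue <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("other", length(x))
  out[grepl("hippo", x)] <- "hippocampus"
  out[grepl("cort", x)] <- "cortex"
  out
}

#' Construct a DEG table from a data.frame
#'
#' @param records data.frame with columns \code{gene}, \code{ratio} and
#'   optionally \code{tissue}, \code{age_months}.
#' @param provenance free-text origin.
#' @param tissue,age_months fallback values used when the corresponding
#'   column is absent.
#' @param aliases optional alias map passed to [normalizeSymbol()].
#' @return a \linkS4class{DEGTable}.
#' @export
DEGTable <- function(records, provenance = "", tissue = "other",
                     age_months = 1L, aliases = NULL) {
  if (!all(c("gene", "ratio") %in% names(records)))
    stop("schema error: records must have 'gene' and 'ratio' columns")
  rec <- data.frame(
    gene = normalizeSymbol(records$gene, aliases),
    ratio = as.numeric(records$ratio),
    tissue = .normTissue(if ("tissue" %in% names(records)) records$tissue else tissue),
    age_months = as.integer(if ("age_months" %in% names(records)) records$age_months else age_months),
    stringsAsFactors = FALSE)
  key <- paste(rec$gene, rec$tissue, rec$age_months, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (gene, tissue, age_months) records: ",
         paste(unique(rec$gene[duplicated(key)]), collapse = ", "))
  new("DEGTable", records = rec, provenance = provenance)
}

#' Read a differential-expression gene table
#'
#' Parses a delimited text file with a header row into a
#' \linkS4class{DEGTable}. The file must name at least a gene-symbol column
#' and a signed fold-change ratio column; symbols are normalized via
#' [normalizeSymbol()]. Ratios follow the signed linear convention of
#' microarray DEG tables: magnitude >= 1, negative sign = down-regulated.
#' When the file lacks tissue/age columns the \code{tissue} and
#' \code{age_months} arguments stamp every record (defaults "other" and 1).
#'
#' @param path path to the delimited file.
#' @param dialect named character vector mapping the canonical column names
#'   \code{gene}, \code{ratio}, \code{tissue}, \code{age_months} to the
#'   column names used in the file.
#' @param sep field separator (default tab).
#' @param tissue,age_months fallbacks when the file has no such columns.
#' @param aliases optional alias map passed to [normalizeSymbol()].
#' @return a \linkS4class{DEGTable}.
#' @examples
#' f <- system.file("extdata", "deg_hippocampus_06mo.tsv", package = "seednet")
#' nrow(degRecords(readDEGTable(f)))   # 12
#' @export
readDEGTable <- function(path,
                         dialect = c(gene = "gene", ratio = "ratio",
                                     tissue = "tissue", age_months = "age_months"),
                         sep = "\t", tissue = "other", age_months = 1L,
                         aliases = NULL) {
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, quote = "", fileEncoding = "UTF-8")
  for (col in c("gene", "ratio"))
    if (!(dialect[[col]] %in% names(df)))
      stop(sprintf("schema error: mandatory column '%s' not found in %s",
                   dialect[[col]], path))
  ratio <- suppressWarnings(as.numeric(df[[dialect[["ratio"]]]]))
  bad <- which(is.na(ratio))
  if (length(bad) > 0)
    stop(sprintf("parse error: unparseable ratio '%s' at data row %d of %s",
                 df[[dialect[["ratio"]]]][bad[1]], bad[1], path))
  rec <- data.frame(gene = df[[dialect[["gene"]]]], ratio = ratio,
                    stringsAsFactors = FALSE)
  tcol <- dialect[["tissue"]]
  if (!is.na(tcol) && tcol %in% names(df)) rec$tissue <- df[[tcol]]
  acol <- dialect[["age_months"]]
  if (!is.na(acol) && acol %in% names(df)) rec$age_months <- df[[acol]]
  DEGTable(rec, provenance = path, tissue = tissue, age_months = age_months,
           aliases = aliases)
}

#' Filter a DEG table by fold-change magnitude
#'
#' Keeps records whose absolute fold-change ratio exceeds \code{minFold}
#' (strictly, by default, matching the convention that a change is called
#' significant only when the magnitude exceeds the threshold) or is at least
#' \code{minFold} when \code{strict = FALSE}. Record order is preserved.
#'
#' @param table a \linkS4class{DEGTable}.
#' @param minFold positive fold-change threshold (>= 1), default 1.6.
#' @param strict logical; strict (>) or inclusive (>=) comparison.
#' @return the filtered \linkS4class{DEGTable}.
#' @export
filterDEG <- function(table, minFold = 1.6, strict = TRUE) {
  stopifnot(is(table, "DEGTable"), minFold >= 1)
  r <- table@records
  keep <- if (strict) abs(r$ratio) > minFold else abs(r$ratio) >= minFold
  new("DEGTable", records = r[keep, , drop = FALSE],
      provenance = table@provenance)
}

#' Seed gene symbols of a DEG table
#'
#' Unique normalized gene symbols of a (possibly filtered) DEG table,
#' optionally restricted by tissue and/or age, ready for use as seeds in
#' [extractSubnetwork()].
#'
#' @param table a \linkS4class{DEGTable}.
#' @param tissue optional tissue filter.
#' @param age_months optional age filter.
#' @return sorted character vector of unique gene symbols.
#' @export
degSeeds <- function(table, tissue = NULL, age_months = NULL) {
  r <- table@records
  if (!is.null(tissue)) r <- r[r$tissue %in% tissue, , drop = FALSE]
  if (!is.null(age_months)) r <- r[r$age_months %in% age_months, , drop = FALSE]
  sort(unique(r$gene))
}
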