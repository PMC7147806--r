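#' Hi-C end and pair categories
#'
#' End categories (mutually exclusive, exhaustive):
#' * `TE_FILTERED` — the end aligned to a canonical TE; such reads are
#'   filtered before any other call.
#' * `REPEAT_PCH` — the end aligned to a catalogued heterochromatic
#'   repeat (a separate reference; no genomic position).
#' * `UNIQUE_PCH` — mapped inside PCH with mapping quality >= 30.
#' * `MULTI_PCH` — mapped inside PCH with mapping quality 0 (the value
#'   aligners assign to multi-mapped reads).
#' * `UNIQUE_EU` — mapped inside derived euchromatin with mapping
#'   quality >= 30.
#' * `OTHER` — everything else (including PCH ends with 0 < mapq < 30).
#'
#' Pair classes: `PCH_PCH_UNIQUE` (both ends unique PCH), `EU_PCH` (one
#' unique euchromatic end, the other any of the three PCH categories),
#' `EU_EU` (both unique euchromatic), `DISCARD` otherwise (TE-filtered or
#' unclassifiable ends, and pairs of two non-unique PCH ends, which have
#' no locatable end).
#'
#' @name hic-categories
#' @aliases endCategories pairClasses
NULL

#' @rdname hic-categories
#' @export
endCategories <- function() {
  c("TE_FILTERED", "UNIQUE_PCH", "MULTI_PCH", "REPEAT_PCH", "UNIQUE_EU",
    "OTHER")
}

#' @rdname hic-categories
#' @export
pairClasses <- function() {
  c("PCH_PCH_UNIQUE", "EU_PCH", "EU_EU", "DISCARD")
}

# positions (arm, pos) inside a GRanges region set
.posIn <- function(arm, pos, regions) {
  ok <- !is.na(arm) & !is.na(pos)
  res <- logical(length(arm))
  if (!any(ok)) return(res)
  gr <- GRanges(arm[ok], IRanges(pos[ok], width = 1L))
  res[ok] <- overlapsAny(gr, regions, ignore.strand = TRUE)
  res
}

#' Classify aligned Hi-C read ends
#'
#' Vectorized classification of read ends into the six end categories,
#' with the precedence: canonical-TE filter first, then catalogued
#' repeats, then positional PCH calls (unique at mapq >= 30, multi at
#' mapq 0), then unique euchromatic calls, then `OTHER`.
#'
#' @param ends `data.frame` with columns `arm` (or `NA`), `pos` (1-based
#'   bp, `NA` iff `arm` is `NA`), `mapq` (0–255), `repeat_hit` (repeat
#'   name or `NA`), `te_hit` (logical)
#' @param annotation a [GenomeAnnotation-class]
#' @param catalog a [RepeatCatalog-class]
#' @param euchromatin optional precomputed [deriveEuchromatin()] result
#' @return factor of end categories, levels [endCategories()]
#' @export
classifyEnds <- function(ends, annotation, catalog, euchromatin = NULL) {
  stopifnot(is.data.frame(ends),
            all(c("arm", "pos", "mapq", "repeat_hit", "te_hit") %in%
                  names(ends)))
  if (any(ends$mapq < 0 | ends$mapq > 255, na.rm = TRUE))
    stop("mapq must lie in [0, 255]")
  if (is.null(euchromatin)) euchromatin <- deriveEuchromatin(annotation)
  n <- nrow(ends)
  cat <- rep("OTHER", n)
  inPch <- .posIn(ends$arm, ends$pos, pchRegions(annotation))
  inEu <- .posIn(ends$arm, ends$pos, euchromatin)
  mapq <- ends$mapq
  cat[inEu & !is.na(mapq) & mapq >= 30] <- "UNIQUE_EU"
  cat[inPch] <- "OTHER"
  cat[inPch & !is.na(mapq) & mapq == 0] <- "MULTI_PCH"
  cat[inPch & !is.na(mapq) & mapq >= 30] <- "UNIQUE_PCH"
  rep_ok <- isRepeat(catalog, ends$repeat_hit)
  cat[rep_ok] <- "REPEAT_PCH"
  cat[ends$te_hit %in% TRUE] <- "TE_FILTERED"
  factor(cat, levels = endCategories())
}

# pair class from two end-category vectors (the 6x6 rule)
.pairClass <- function(cat1, cat2) {
  cat1 <- as.character(cat1); cat2 <- as.character(cat2)
  pchSet <- c("UNIQUE_PCH", "MULTI_PCH", "REPEAT_PCH")
  cls <- rep("DISCARD", length(cat1))
  drop <- cat1 %in% c("TE_FILTERED", "OTHER") |
          cat2 %in% c("TE_FILTERED", "OTHER")
  both_upch <- cat1 == "UNIQUE_PCH" & cat2 == "UNIQUE_PCH"
  eu_pch <- (cat1 == "UNIQUE_EU" & cat2 %in% pchSet) |
            (cat2 == "UNIQUE_EU" & cat1 %in% pchSet)
  eu_eu <- cat1 == "UNIQUE_EU" & cat2 == "UNIQUE_EU"
  cls[both_upch] <- "PCH_PCH_UNIQUE"
  cls[eu_pch] <- "EU_PCH"
  cls[eu_eu] <- "EU_EU"
  cls[drop] <- "DISCARD"
  factor(cls, levels = pairClasses())
}

#' Classify Hi-C read pairs
#'
#' Applies [classifyEnds()] to both ends of each pair and assigns the
#' pair class (see [hic-categories]).
#'
#' @param pairs `data.frame` with columns `read_id`, `arm1`, `pos1`,
#'   `mapq1`, `repeat1`, `te1`, `arm2`, `pos2`, `mapq2`, `repeat2`, `te2`
#'   (as written by [writePairs()] / [simulateHicPairs()])
#' @param annotation a [GenomeAnnotation-class]
#' @param catalog a [RepeatCatalog-class]
#' @return the input with added columns `cat1`, `cat2`, `pair_class`
#' @export
classifyPairs <- function(pairs, annotation, catalog) {
  need <- c("arm1", "pos1", "mapq1", "repeat1", "te1",
            "arm2", "pos2", "mapq2", "repeat2", "te2")
  stopifnot(is.data.frame(pairs), all(need %in% names(pairs)))
  eu <- deriveEuchromatin(annotation)
  e1 <- data.frame(arm = pairs$arm1, pos = pairs$pos1, mapq = pairs$mapq1,
                   repeat_hit = pairs$repeat1, te_hit = pairs$te1)
  e2 <- data.frame(arm = pairs$arm2, pos = pairs$pos2, mapq = pairs$mapq2,
                   repeat_hit = pairs$repeat2, te_hit = pairs$te2)
  pairs$cat1 <- classifyEnds(e1, annotation, catalog, euchromatin = eu)
  pairs$cat2 <- classifyEnds(e2, annotation, catalog, euchromatin = eu)
  pairs$pair_class <- .pairClass(pairs$cat1, pairs$cat2)
  pairs
}

#' Per-category count summary of classified pairs
#'
#' @param pairs classified pairs (from [classifyPairs()])
#' @return list with `ends` (end-category counts over both ends) and
#'   `pairs` (pair-class counts); each sums to the respective input size.
#' @export
categorySummary <- function(pairs) {
  stopifnot(all(c("cat1", "cat2", "pair_class") %in% names(pairs)))
  endTab <- table(factor(c(as.character(pairs$cat1),
                           as.character(pairs$cat2)),
                         levels = endCategories()))
  pairTab <- table(factor(pairs$pair_class, levels = pairClasses()))
  list(ends = as.data.frame(endTab, responseName = "count"),
       pairs = as.data.frame(pairTab, responseName = "count"))
}

#' Read and write pairs tables
#'
#' Tab-separated pairs tables with a header; positions are 1-based on
#' disk. `readPairs()` accepts both raw tables (11 columns) and
#' classified tables (with `cat1`, `cat2`, `pair_class` appended).
#'
#' @param file path
#' @return `data.frame`
#' @export
readPairs <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  for (col in c("te1", "te2"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  for (col in c("repeat1", "repeat2"))
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  df
}

#' @rdname readPairs
#' @param pairs a pairs `data.frame`
#' @param comments optional character vector written as `#` header lines
#' @export
writePairs <- function(pairs, file, comments = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(comments))
    writeLines(paste0("# ", comments), con)
  utils::write.table(pairs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
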