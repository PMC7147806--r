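#' Build the genome annotation from arms and PCH boundary intervals
#'
#' Assembles the [GenomeAnnotation-class] object from an arm table and
#' BED-style pericentromeric-heterochromatin (PCH) intervals. Every arm of
#' a chromosome listed in `hetChromosomes` is forced to be entirely PCH
#' (intervals are auto-created when absent), mirroring how the 4th and Y
#' chromosomes are treated as fully heterochromatic. Validation is eager:
#' unknown arms, malformed or overlapping intervals raise an error.
#'
#' @param boundaries PCH intervals: a `GRanges` (seqnames = arm names,
#'   e.g. imported from BED with [readBoundaries()]), or a `data.frame`
#'   with columns `arm`, `start`, `end` in BED convention (0-based,
#'   half-open).
#' @param arms `data.frame` with columns `arm`, `chrom`, `length` (bp);
#'   the row order fixes the deterministic arm order.
#' @param hetChromosomes chromosome names treated as entirely
#'   heterochromatic.
#' @param euOffsetBp buffer (bp) excluded from euchromatin inward of each
#'   PCH boundary; default 500,000 (conservative euchromatin definition).
#' @return a validated `GenomeAnnotation`.
#' @examples
#' arms <- data.frame(arm = c("2L", "4"), chrom = c("2", "4"),
#'                    length = c(23e6, 1.3e6))
#' bed <- data.frame(arm = "2L", start = 22e6, end = 23e6)
#' ann <- loadAnnotation(bed, arms, hetChromosomes = "4")
#' @export
loadAnnotation <- function(boundaries, arms, hetChromosomes = character(),
                           euOffsetBp = 500000) {
  stopifnot(is.data.frame(arms),
            all(c("arm", "chrom", "length") %in% names(arms)))
  arms$arm <- as.character(arms$arm)
  arms$chrom <- as.character(arms$chrom)
  arms$length <- as.numeric(arms$length)

  if (is.data.frame(boundaries)) {
    stopifnot(all(c("arm", "start", "end") %in% names(boundaries)))
    if (any(boundaries$end <= boundaries$start))
      stop("malformed PCH interval: end must exceed start")
    gr <- GRanges(boundaries$arm,
                  IRanges(boundaries$start + 1L, boundaries$end))
  } else if (methods::is(boundaries, "GRanges")) {
    gr <- granges(boundaries)
  } else stop("boundaries must be a GRanges or a BED-like data.frame")

  unknown <- setdiff(as.character(seqnames(gr)), arms$arm)
  if (length(unknown))
    stop("PCH intervals on unknown arm(s): ", paste(unknown, collapse = ", "))

  hetArms <- arms$arm[arms$chrom %in% hetChromosomes]
  if (length(hetArms)) {
    gr <- gr[!(as.character(seqnames(gr)) %in% hetArms)]
    full <- GRanges(hetArms,
                    IRanges(1L, arms$length[match(hetArms, arms$arm)]))
    gr <- suppressWarnings(c(gr, full))
  }
  gr <- GRanges(factor(as.character(seqnames(gr)), levels = arms$arm),
                ranges(gr))
  gr <- sort(gr)
  methods::new("GenomeAnnotation", arms = arms, pch = gr,
               hetChromosomes = as.character(hetChromosomes),
               euOffset = as.numeric(euOffsetBp))
}

#' @rdname GenomeAnnotation-class
#' @export
setMethod("armTable", "GenomeAnnotation", function(object) object@arms)

#' @rdname GenomeAnnotation-class
#' @export
setMethod("pchRegions", "GenomeAnnotation", function(object) object@pch)

#' @rdname GenomeAnnotation-class
#' @export
setMethod("hetChromosomes", "GenomeAnnotation",
          function(object) object@hetChromosomes)

#' @rdname GenomeAnnotation-class
#' @export
setMethod("euOffset", "GenomeAnnotation", function(object) object@euOffset)

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation with", nrow(object@arms), "arms,",
      length(object@pch), "PCH interval(s)\n")
  cat("  arms:", paste(object@arms$arm, collapse = ", "), "\n")
  cat("  PCH total:", sum(width(object@pch)), "bp;",
      "euchromatin offset:", object@euOffset, "bp\n")
  if (length(object@hetChromosomes))
    cat("  fully heterochromatic chromosome(s):",
        paste(object@hetChromosomes, collapse = ", "), "\n")
})

# named arm -> chromosome lookup
armChrom <- function(annotation) {
  stats::setNames(annotation@arms$chrom, annotation@arms$arm)
}

# named arm -> length lookup
armLengths <- function(annotation) {
  stats::setNames(annotation@arms$length, annotation@arms$arm)
}

# full genome as GRanges in arm order
genomeRanges <- function(annotation) {
  a <- annotation@arms
  GRanges(factor(a$arm, levels = a$arm), IRanges(1L, a$length))
}

#' Derive the conservative euchromatin intervals
#'
#' Euchromatin is each arm minus its PCH intervals minus a buffer of
#' `euOffset(annotation)` bp adjacent to every PCH boundary (0.5 Mb inward
#' by default, so only regions well distal of the epigenetic boundary are
#' called euchromatic). Fully heterochromatic chromosomes yield no
#' euchromatin.
#'
#' @param annotation a [GenomeAnnotation-class]
#' @return `GRanges` of euchromatin intervals in arm order.
#' @export
deriveEuchromatin <- function(annotation) {
  pch <- pchRegions(annotation)
  len <- armLengths(annotation)
  buffered <- GRanges(seqnames(pch),
    IRanges(pmax(1, start(pch) - euOffset(annotation)),
            pmin(len[as.character(seqnames(pch))],
                 end(pch) + euOffset(annotation))))
  eu <- setdiff(genomeRanges(annotation), buffered)
  eu[width(eu) > 0]
}

#' Tile PCH intervals into fixed-width windows
#'
#' Each PCH interval is tiled left to right into windows of `windowBp`
#' (100 kb by default); the final partial window is retained. Windows
#' carry their arm, chromosome and within-arm index and are ordered by
#' the arm order of the annotation, giving the deterministic layout of
#' the contact matrix.
#'
#' @param annotation a [GenomeAnnotation-class]
#' @param windowBp window width in bp (> 0)
#' @return `GRanges` with metadata columns `arm`, `chrom`, `window`.
#' @export
binPchWindows <- function(annotation, windowBp = 100000) {
  stopifnot(windowBp > 0)
  pch <- pchRegions(annotation)
  chrom <- armChrom(annotation)
  out <- lapply(seq_along(pch), function(i) {
    s <- start(pch)[i]; e <- end(pch)[i]
    ws <- seq(s, e, by = windowBp)
    we <- pmin(ws + windowBp - 1, e)
    GRanges(rep(as.character(seqnames(pch)[i]), length(ws)),
            IRanges(ws, we))
  })
  gr <- do.call(c, out)
  gr <- GRanges(factor(as.character(seqnames(gr)),
                       levels = annotation@arms$arm), ranges(gr))
  o <- order(as.integer(seqnames(gr)), start(gr))
  gr <- gr[o]
  armv <- as.character(seqnames(gr))
  mcols(gr)$arm <- armv
  mcols(gr)$chrom <- unname(chrom[armv])
  mcols(gr)$window <- as.integer(
    unlist(lapply(split(seq_along(gr), factor(armv, unique(armv))),
                  seq_along), use.names = FALSE))
  gr
}

#' Per-arm marginal weights for interaction expectations
#'
#' Computes the per-arm weights behind the expected interaction
#' proportions, from either a mappability track ("theoretical"
#' expectation) or classified read ends ("empirical" expectation).
#'
#' In `mappability` mode the weight of an arm is the number of
#' mappability-one bases inside its PCH intervals, optionally multiplied
#' by the mean copy number under an equal sex ratio (autosomes 2, X 1.5,
#' Y 0.5) when `sexAdjust = TRUE` — appropriate for unsexed embryo pools.
#' In `empirical` mode the weight is the count of unique-PCH read ends on
#' the arm; copy number is then implicit in the counts and no sex
#' adjustment is ever applied.
#'
#' @param source `mappability` mode: a `GRanges` with a numeric `score`
#'   (or logical `mappable`) column in \{0, 1\}. `empirical` mode: a
#'   classified pairs `data.frame` (see [classifyPairs()]).
#' @param annotation a [GenomeAnnotation-class]
#' @param mode `"mappability"` or `"empirical"`
#' @param sexAdjust apply the copy-number adjustment (mappability mode
#'   only)
#' @param xChrom,yChrom chromosome names of the X and Y
#' @return named numeric vector of weights over PCH-bearing arms, with
#'   attributes `provenance` and `sexAdjusted`.
#' @export
armMarginals <- function(source, annotation,
                         mode = c("mappability", "empirical"),
                         sexAdjust = FALSE, xChrom = "X", yChrom = "Y") {
  mode <- match.arg(mode)
  pch <- pchRegions(annotation)
  armsWithPch <- unique(as.character(seqnames(pch)))
  armsWithPch <- annotation@arms$arm[annotation@arms$arm %in% armsWithPch]
  if (mode == "mappability") {
    stopifnot(methods::is(source, "GRanges"))
    val <- if (!is.null(mcols(source)$mappable))
      as.numeric(mcols(source)$mappable) else mcols(source)$score
    if (is.null(val)) stop("mappability track needs a score column")
    if (!all(val %in% c(0, 1))) stop("mappability values must be 0 or 1")
    mappable <- source[val == 1]
    w <- vapply(armsWithPch, function(a) {
      sum(width(intersect(mappable[seqnames(mappable) == a],
                          pch[seqnames(pch) == a])))
    }, numeric(1))
    if (sexAdjust) {
      chrom <- armChrom(annotation)[armsWithPch]
      copy <- ifelse(chrom == xChrom, 1.5, ifelse(chrom == yChrom, 0.5, 2))
      w <- w * copy
    }
    provenance <- "mappability"
  } else {
    stopifnot(is.data.frame(source))
    if (!all(c("cat1", "cat2") %in% names(source)))
      stop("empirical mode needs a classified pairs data.frame")
    arm <- c(source$arm1[source$cat1 == "UNIQUE_PCH"],
             source$arm2[source$cat2 == "UNIQUE_PCH"])
    w <- vapply(armsWithPch, function(a) sum(arm == a, na.rm = TRUE),
                numeric(1))
    sexAdjust <- FALSE
    provenance <- "empirical_reads"
  }
  if (all(w == 0)) stop("all arm weights are zero")
  structure(w, provenance = provenance, sexAdjusted = sexAdjust)
}

#' Read an arm-length table
#'
#' Plain TSV with columns `arm`, `chrom`, `length` (header required).
#' @param file path
#' @return `data.frame`
#' @export
readArmTable <- function(file) {
  a <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("arm", "chrom", "length") %in% names(a)))
  a
}

#' Read PCH boundary intervals from BED
#'
#' @param file BED file (3+ columns; seqnames are arm names)
#' @return `GRanges`
#' @export
readBoundaries <- function(file) {
  rtracklayer::import(file, format = "BED")
}

#' Read a binary mappability track from bedGraph
#'
#' @param file bedGraph file with values in \{0, 1\}
#' @return `GRanges` with a `score` column
#' @export
readMappability <- function(file) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  if (!all(gr$score %in% c(0, 1)))
    stop("mappability values must be binary")
  gr
}
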