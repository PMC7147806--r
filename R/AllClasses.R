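#' @import methods
#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits Rle runValue
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths
#' @importFrom BiocGenerics start end width strand
NULL

#' GenomeAnnotation: arms, PCH partition and derived euchromatin
#'
#' The coordinate backbone for every analysis stage. Holds the chromosome
#' arms (name, chromosome, length), the pericentromeric-heterochromatin
#' (PCH) intervals per arm, the set of chromosomes treated as entirely
#' heterochromatic, and the conservative buffer (default 0.5 Mb) excluded
#' from "euchromatin" next to every PCH boundary.
#'
#' Arms are the sequence space: all `GRanges` in the package use arm names
#' as seqnames. Construct with [loadAnnotation()].
#'
#' @slot arms `data.frame` with columns `arm`, `chrom`, `length` (bp);
#'   row order fixes the deterministic arm order used for matrix layout.
#' @slot pch `GRanges` of PCH intervals (seqnames = arm names), disjoint
#'   and sorted within each arm.
#' @slot hetChromosomes character vector of chromosome names whose arms
#'   are entirely heterochromatic (e.g. the 4th and Y chromosomes).
#' @slot euOffset single non-negative number: bp excluded from euchromatin
#'   inward of each PCH boundary.
#' @aliases GenomeAnnotation
#' @seealso [loadAnnotation()], [deriveEuchromatin()], [binPchWindows()]
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
  representation(
    arms = "data.frame",
    pch = "GRanges",
    hetChromosomes = "character",
    euOffset = "numeric"
  )
)

setValidity("GenomeAnnotation", function(object) {
  a <- object@arms
  msgs <- character()
  if (!all(c("arm", "chrom", "length") %in% names(a)))
    return("arms must have columns arm, chrom, length")
  if (anyDuplicated(a$arm)) msgs <- c(msgs, "duplicated arm names")
  if (any(a$length <= 0)) msgs <- c(msgs, "arm lengths must be positive")
  if (length(object@euOffset) != 1L || is.na(object@euOffset) ||
      object@euOffset < 0)
    msgs <- c(msgs, "euOffset must be a single non-negative number")
  p <- object@pch
  if (!all(as.character(seqnames(p)) %in% a$arm))
    msgs <- c(msgs, "PCH intervals on unknown arms")
  len <- stats::setNames(a$length, a$arm)
  if (length(p)) {
    if (any(start(p) < 1L) ||
        any(end(p) > len[as.character(seqnames(p))]))
      msgs <- c(msgs, "PCH intervals outside arm bounds")
    byArm <- split(ranges(p), as.character(seqnames(p)))
    for (nm in names(byArm)) {
      r <- byArm[[nm]]
      if (length(r) > 1L) {
        if (is.unsorted(start(r)))
          msgs <- c(msgs, sprintf("PCH intervals on %s not sorted", nm))
        if (length(reduce(r, min.gapwidth = 0L)) != length(r))
          msgs <- c(msgs, sprintf("overlapping PCH intervals on %s", nm))
      }
    }
  }
  hetArms <- a$arm[a$chrom %in% object@hetChromosomes]
  for (nm in hetArms) {
    cov <- sum(width(p[seqnames(p) == nm]))
    if (cov != len[nm])
      msgs <- c(msgs,
        sprintf("arm %s of heterochromatic chromosome not fully PCH", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' RepeatCatalog: catalogued heterochromatic repeats
#'
#' A lookup of known heterochromatic simple and complex repeats. Read ends
#' aligned to one of these targets are classified as repeat-derived PCH
#' reads. Sequences are optional; only the names are needed for
#' classification.
#'
#' @slot repeatNames unique character vector of repeat names.
#' @slot sequences optional `DNAStringSet` (or `NULL`).
#' @aliases RepeatCatalog
#' @seealso [RepeatCatalog()], [isRepeat()], [readRepeatCatalog()]
#' @exportClass RepeatCatalog
setClass("RepeatCatalog",
  representation(repeatNames = "character", sequences = "ANY")
)

setValidity("RepeatCatalog", function(object) {
  msgs <- character()
  if (anyDuplicated(object@repeatNames))
    msgs <- c(msgs, "repeat names must be unique")
  if (any(is.na(object@repeatNames)) || any(object@repeatNames == ""))
    msgs <- c(msgs, "repeat names must be non-empty")
  if (!is.null(object@sequences) &&
      !methods::is(object@sequences, "DNAStringSet"))
    msgs <- c(msgs, "sequences must be NULL or a DNAStringSet")
  if (length(msgs)) msgs else TRUE
})

#' ContactMatrix: symmetric Hi-C counts over PCH windows
#'
#' Symmetric count matrix over the ordered 100-kb PCH windows, built from
#' read pairs whose both ends mapped uniquely to PCH, after removal of
#' same-arm pairs closer than the minimum separation (default 10 kb).
#'
#' @slot windows `GRanges` of PCH windows with metadata columns `arm`,
#'   `chrom` and `window` (index within arm), in deterministic arm order.
#' @slot counts symmetric non-negative integer matrix; `counts[i, j]` is
#'   the number of retained pairs linking windows `i` and `j` (the
#'   diagonal counts within-window pairs once).
#' @slot nPairsInput number of unique PCH-PCH pairs offered.
#' @slot nDroppedClose same-arm pairs removed by the separation filter.
#' @slot nDroppedOutside pairs with an end outside every window (reported,
#'   dropped).
#' @slot minSeparation the separation threshold used (bp).
#' @aliases ContactMatrix
#' @seealso [buildContactMatrix()], [partitionInteractions()]
#' @exportClass ContactMatrix
setClass("ContactMatrix",
  representation(
    windows = "GRanges",
    counts = "matrix",
    nPairsInput = "numeric",
    nDroppedClose = "numeric",
    nDroppedOutside = "numeric",
    minSeparation = "numeric"
  )
)

setValidity("ContactMatrix", function(object) {
  msgs <- character()
  n <- length(object@windows)
  if (!all(dim(object@counts) == c(n, n)))
    msgs <- c(msgs, "counts dimensions must match the window list")
  if (n && !isTRUE(all.equal(object@counts, t(object@counts))))
    msgs <- c(msgs, "counts must be symmetric")
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be non-negative")
  if (!all(c("arm", "chrom", "window") %in% names(mcols(object@windows))))
    msgs <- c(msgs, "windows need arm, chrom and window metadata")
  if (length(msgs)) msgs else TRUE
})

#' EnrichmentProfile: binned H3K9me2 enrichment around an anchor
#'
#' Per-bin H3K9me2 enrichment (library-size-normalized
#' `log2((chip + 1)/(input + 1))`) on a signed-distance grid of 1-kb bins
#' around a TE insertion (or any anchor interval), for one strain. Bins
#' overlapping other annotated features or falling outside the arm are
#' masked (`NA`).
#'
#' @slot anchor `GRanges` of length one (the TE site or interval).
#' @slot strain strain label.
#' @slot binBp bin width in bp.
#' @slot bins `data.frame` with columns `side` ("left"/"right"), `bin`
#'   (1-based distance rank from the anchor), `start`, `end`, `value`,
#'   `masked`.
#' @aliases EnrichmentProfile
#' @seealso [enrichmentProfile()], [spreadExtent()]
#' @exportClass EnrichmentProfile
setClass("EnrichmentProfile",
  representation(
    anchor = "GRanges",
    strain = "character",
    binBp = "numeric",
    bins = "data.frame"
  )
)

setValidity("EnrichmentProfile", function(object) {
  msgs <- character()
  if (length(object@anchor) != 1L)
    msgs <- c(msgs, "anchor must have length one")
  b <- object@bins
  need <- c("side", "bin", "start", "end", "value", "masked")
  if (!all(need %in% names(b)))
    return("bins must have columns side, bin, start, end, value, masked")
  if (!all(b$side %in% c("left", "right")))
    msgs <- c(msgs, "side must be left or right")
  if (sum(b$side == "left") != sum(b$side == "right"))
    msgs <- c(msgs, "grid must be symmetric about the anchor")
  bad <- !b$masked & !is.finite(b$value)
  if (any(bad)) msgs <- c(msgs, "unmasked bin values must be finite")
  if (length(msgs)) msgs else TRUE
})
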