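#' Total mass of a coverage track
#'
#' Sum of `width * score`, the library-size proxy used for depth
#' normalization of bedGraph coverage.
#'
#' @param gr coverage `GRanges` with a `score` column
#' @return a number
#' @export
trackTotal <- function(gr) {
  sum(as.numeric(width(gr)) * gr$score)
}

#' Read a coverage track from bedGraph
#'
#' @param file bedGraph path
#' @return `GRanges` with a `score` column
#' @export
readCoverage <- function(file) {
  rtracklayer::import(file, format = "bedGraph")
}

#' Write a coverage track as bedGraph
#'
#' @param gr coverage `GRanges` with a `score` column
#' @param file path
#' @export
writeCoverage <- function(gr, file) {
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

# mean coverage of [start, end] windows from one arm's coverage GRanges
.binMeans <- function(cov, arm, starts, ends, armLen) {
  v <- numeric(length(starts))
  sel <- as.character(seqnames(cov)) == arm
  covArm <- cov[sel]
  if (!length(covArm)) return(v)
  covArm <- GRanges(rep(arm, length(covArm)), ranges(covArm),
                    score = covArm$score)
  rl <- coverage(covArm, weight = covArm$score,
                 width = stats::setNames(armLen, arm))[[arm]]
  ok <- starts >= 1 & ends <= armLen
  if (any(ok)) {
    vw <- Views(rl, start = starts[ok], end = ends[ok])
    v[ok] <- viewMeans(vw)
  }
  v[!ok] <- NA_real_
  v
}

#' Binned H3K9me2 enrichment profile around an anchor
#'
#' Computes the per-bin enrichment value
#' `log2((chip_norm + 1)/(input_norm + 1))` on a signed-distance grid of
#' `binBp` bins extending `maxExtentBp` on each side of the anchor,
#' where `chip_norm`/`input_norm` are bin mean coverages scaled to a
#' common library size of 1e6 (reads-per-million). Bins overlapping
#' `mask` (other annotated TEs or islands) or extending beyond the arm
#' are masked.
#'
#' @param chip,input coverage `GRanges` (e.g. [readCoverage()])
#' @param anchor `GRanges` of length one: the TE insertion site or
#'   interval; right-side bins start at its end, left-side bins end at
#'   its start
#' @param annotation a [GenomeAnnotation-class] (for arm bounds)
#' @param binBp bin width (default 1 kb)
#' @param maxExtentBp maximal profiled extent per side (default 20 kb)
#' @param mask optional `GRanges` of bins to exclude
#' @param strain strain label stored in the profile
#' @param libSizes optional `c(chip =, input =)` override of the library
#'   totals (defaults to [trackTotal()] of each track)
#' @return an [EnrichmentProfile-class]
#' @export
enrichmentProfile <- function(chip, input, anchor, annotation,
                              binBp = 1000, maxExtentBp = 20000,
                              mask = NULL, strain = "strain",
                              libSizes = NULL) {
  stopifnot(methods::is(anchor, "GRanges"), length(anchor) == 1,
            binBp > 0, maxExtentBp >= binBp)
  arm <- as.character(seqnames(anchor))
  armLen <- armLengths(annotation)[arm]
  if (is.na(armLen)) stop("anchor arm not in annotation")
  if (start(anchor) < 1 || end(anchor) > armLen)
    stop("anchor outside arm bounds")
  nb <- floor(maxExtentBp / binBp)
  rs <- end(anchor) + (seq_len(nb) - 1) * binBp + 1
  re <- rs + binBp - 1
  le <- start(anchor) - (seq_len(nb) - 1) * binBp - 1
  ls <- le - binBp + 1
  starts <- c(ls, rs); ends <- c(le, re)
  side <- rep(c("left", "right"), each = nb)
  bin <- c(seq_len(nb), seq_len(nb))

  if (is.null(libSizes))
    libSizes <- c(chip = trackTotal(chip), input = trackTotal(input))
  if (any(libSizes <= 0)) stop("library sizes must be positive")
  fC <- 1e6 / libSizes[["chip"]]
  fI <- 1e6 / libSizes[["input"]]
  mC <- .binMeans(chip, arm, starts, ends, armLen)
  mI <- .binMeans(input, arm, starts, ends, armLen)
  val <- log2((mC * fC + 1) / (mI * fI + 1))
  masked <- is.na(val)
  if (!is.null(mask) && length(mask)) {
    ok <- !is.na(starts) & starts >= 1 & ends <= armLen
    binGr <- GRanges(rep(arm, sum(ok)),
                     IRanges(starts[ok], ends[ok]))
    hit <- overlapsAny(binGr, mask, ignore.strand = TRUE)
    masked[ok][hit] <- TRUE
  }
  val[masked] <- NA_real_
  bins <- data.frame(side = side, bin = bin, start = starts, end = ends,
                     value = val, masked = masked)
  methods::new("EnrichmentProfile", anchor = granges(anchor),
               strain = strain, binBp = binBp, bins = bins)
}

#' @rdname EnrichmentProfile-class
#' @export
setMethod("profileBins", "EnrichmentProfile", function(object) object@bins)

setMethod("show", "EnrichmentProfile", function(object) {
  b <- object@bins
  cat("EnrichmentProfile (", object@strain, ") around ",
      as.character(seqnames(object@anchor)), ":",
      start(object@anchor), "-", end(object@anchor), "\n", sep = "")
  cat(" ", sum(b$side == "left"), "x", object@binBp,
      "bp bins per side;", sum(b$masked), "masked\n")
})

# check two profiles share a grid
.sameGrid <- function(a, b) {
  identical(a@binBp, b@binBp) &&
    identical(a@bins[c("side", "bin", "start", "end")],
              b@bins[c("side", "bin", "start", "end")])
}

#' TE-induced H3K9me2 spread extent and magnitude
#'
#' Leverages between-strain differences: per side of the anchor, the
#' spread extent is the length of the maximal contiguous run of bins,
#' starting at the anchor, in which the focal-strain enrichment exceeds
#' the mean wildtype enrichment by more than `delta` (log2 units). The
#' magnitude is the mean percentage increase,
#' `100 * (2^(focal - wildtype) - 1)`, over the spread bins. A TE is
#' called spreading when the total extent reaches at least 1 kb. Masked
#' bins terminate a run.
#'
#' @param focal [EnrichmentProfile-class] of the TE-carrying strain
#' @param wildtypes list of wildtype profiles on the same grid
#' @param delta log2 difference threshold (default 0.5)
#' @param minSpreadBp spreading-call threshold on the total extent
#' @return list with `extent_left_bp`, `extent_right_bp`,
#'   `extent_total_bp`, `extent_total_kb`, `magnitude_pct`, `spreading`.
#' @export
spreadExtent <- function(focal, wildtypes, delta = 0.5,
                         minSpreadBp = 1000) {
  if (methods::is(wildtypes, "EnrichmentProfile"))
    wildtypes <- list(wildtypes)
  stopifnot(length(wildtypes) >= 1)
  for (wt in wildtypes)
    if (!.sameGrid(focal, wt)) stop("profiles are on different grids")
  wtVals <- vapply(wildtypes, function(p) p@bins$value,
                   numeric(nrow(focal@bins)))
  wtMean <- rowMeans(as.matrix(wtVals))
  diff <- focal@bins$value - wtMean
  b <- focal@bins
  runLen <- function(sideName) {
    o <- order(b$bin[b$side == sideName])
    d <- diff[b$side == sideName][o]
    ok <- !is.na(d) & d > delta
    r <- 0L
    for (x in ok) { if (!x) break; r <- r + 1L }
    r
  }
  nl <- runLen("left"); nr <- runLen("right")
  sel <- (b$side == "left" & b$bin <= nl) |
         (b$side == "right" & b$bin <= nr)
  mag <- if (nl + nr > 0)
    mean(100 * (2^diff[sel] - 1)) else 0
  totalBp <- (nl + nr) * focal@binBp
  list(extent_left_bp = nl * focal@binBp,
       extent_right_bp = nr * focal@binBp,
       extent_total_bp = totalBp,
       extent_total_kb = totalBp / 1000,
       magnitude_pct = mag,
       spreading = totalBp >= minSpreadBp)
}

#' Compare TE population frequencies between contact groups
#'
#' Group means and a Welch two-sample t-test on the raw population
#' frequencies of TEs with versus without PCH spatial interactions. With
#' fewer than two observations in a group (or zero variance in both) the
#' t statistic is undefined; means are still returned, and identical
#' distributions report p = 1.
#'
#' @param withPch frequencies (in `[0, 1]`) of TEs with PCH contact
#' @param withoutPch frequencies of TEs without PCH contact
#' @return list with `mean_with`, `mean_without`, `t`, `df`, `p`,
#'   `freq_with`, `freq_without`.
#' @export
comparePopulationFrequencies <- function(withPch, withoutPch) {
  stopifnot(length(withPch) >= 1, length(withoutPch) >= 1)
  if (any(c(withPch, withoutPch) < 0 | c(withPch, withoutPch) > 1))
    stop("frequencies must lie in [0, 1]")
  res <- list(mean_with = mean(withPch), mean_without = mean(withoutPch),
              t = NA_real_, df = NA_real_, p = NA_real_,
              freq_with = withPch, freq_without = withoutPch)
  if (length(withPch) >= 2 && length(withoutPch) >= 2) {
    tt <- tryCatch(stats::t.test(withPch, withoutPch),
                   error = function(e) NULL)
    if (!is.null(tt)) {
      res$t <- unname(tt$statistic)
      res$df <- unname(tt$parameter)
      res$p <- tt$p.value
    } else if (isTRUE(all.equal(mean(withPch), mean(withoutPch)))) {
      res$t <- 0; res$p <- 1  # both groups constant and equal
    }
  }
  res
}

#' Read a TE population-frequency table
#'
#' TSV with columns `te_id`, `frequency`, `group` (values `with_pch` /
#' `without_pch`).
#'
#' @param file path
#' @return `data.frame`
#' @export
readFrequencyTable <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("te_id", "frequency", "group") %in% names(df)))
  df
}
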