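#' Build euchromatic query windows around features
#'
#' H3K9me2 islands are padded by +/-1 kb, TE insertion sites/intervals by
#' +/-2 kb (the defined windows of the contact analysis); windows are
#' clipped to arm bounds. Features overlapping PCH are rejected with a
#' report (attribute `rejected`), since queries must lie in the
#' conservative euchromatin.
#'
#' @param features `GRanges` of features (seqnames = arm names); point
#'   insertions are width-1 ranges
#' @param annotation a [GenomeAnnotation-class]
#' @param kind `"island"`, `"te"` or `"control"`
#' @param padBp override the kind-specific padding (island/control
#'   1,000 bp; te 2,000 bp)
#' @return `GRanges` of query windows with metadata `region_id`, `kind`,
#'   `feature_start`, `feature_end`; rejected features (if any) are
#'   attached as attribute `rejected` and reported via a warning.
#' @export
makeQueryWindows <- function(features, annotation,
                             kind = c("island", "te", "control"),
                             padBp = NULL) {
  kind <- match.arg(kind)
  if (is.null(padBp)) padBp <- if (kind == "te") 2000 else 1000
  stopifnot(methods::is(features, "GRanges"))
  len <- armLengths(annotation)
  inPch <- overlapsAny(features, pchRegions(annotation),
                       ignore.strand = TRUE)
  rejected <- features[inPch]
  if (length(rejected))
    warning(length(rejected), " feature(s) inside PCH rejected")
  kept <- features[!inPch]
  ids <- mcols(kept)$region_id
  if (is.null(ids))
    ids <- paste0(kind, "_", which(!inPch))
  win <- GRanges(seqnames(kept),
    IRanges(pmax(1, start(kept) - padBp),
            pmin(len[as.character(seqnames(kept))], end(kept) + padBp)))
  mcols(win)$region_id <- ids
  mcols(win)$kind <- kind
  mcols(win)$feature_start <- start(kept)
  mcols(win)$feature_end <- end(kept)
  if (!is.null(mcols(kept)$multiplier))
    mcols(win)$multiplier <- mcols(kept)$multiplier
  attr(win, "rejected") <- rejected
  win
}

#' Euchromatin-PCH contact fraction per query window
#'
#' For each query window, finds the read pairs with one end mapped
#' uniquely inside the window (the informative pairs) and computes the
#' fraction whose other end is heterochromatic — all three PCH read
#' categories (`UNIQUE_PCH`, `MULTI_PCH`, `REPEAT_PCH`) count. The
#' per-arm breakdown uses `UNIQUE_PCH` other ends only, since only those
#' have a known arm. Windows with fewer than `minPairs` informative
#' pairs (1,000 by default) are flagged excluded. A pair with both ends
#' inside the same window is counted once (its other end is euchromatic).
#'
#' @param pairs classified pairs (from [classifyPairs()])
#' @param regions query windows ([makeQueryWindows()] or null regions)
#' @param annotation a [GenomeAnnotation-class]
#' @param minPairs exclusion floor on informative pairs
#' @param chunkSize regions scored per overlap batch (memory control)
#' @return `data.frame` with one row per region: `region_id`, `arm`,
#'   `width`, `n_pairs`, `frac_pch`, one `frac_pch_<arm>` column per
#'   PCH-bearing arm, `excluded`.
#' @export
euPchFraction <- function(pairs, regions, annotation, minPairs = 1000,
                          chunkSize = 5000) {
  stopifnot(all(c("cat1", "cat2") %in% names(pairs)))
  pchCats <- c("UNIQUE_PCH", "MULTI_PCH", "REPEAT_PCH")
  pchArms <- unique(as.character(seqnames(pchRegions(annotation))))
  pchArms <- armTable(annotation)$arm[armTable(annotation)$arm %in% pchArms]

  cat1 <- as.character(pairs$cat1); cat2 <- as.character(pairs$cat2)
  # one record per unique-EU end: its position and the other end's call
  u1 <- cat1 == "UNIQUE_EU"
  u2 <- cat2 == "UNIQUE_EU"
  endArm <- c(pairs$arm1[u1], pairs$arm2[u2])
  endPos <- c(pairs$pos1[u1], pairs$pos2[u2])
  pairIdx <- c(which(u1), which(u2))
  otherPch <- c(cat2[u1] %in% pchCats, cat1[u2] %in% pchCats)
  otherArm <- c(ifelse(cat2[u1] == "UNIQUE_PCH", pairs$arm2[u1], NA),
                ifelse(cat1[u2] == "UNIQUE_PCH", pairs$arm1[u2], NA))
  regionIds <- mcols(regions)$region_id
  lv <- union(as.character(unique(seqnames(regions))), unique(endArm))
  endsGr <- GRanges(factor(endArm, lv), IRanges(endPos, width = 1L))
  regions <- GRanges(factor(as.character(seqnames(regions)), lv),
                     ranges(regions))

  nReg <- length(regions)
  nP <- integer(nReg)
  kP <- integer(nReg)
  kArm <- matrix(0L, nReg, length(pchArms),
                 dimnames = list(NULL, pchArms))
  for (lo in seq(1L, max(nReg, 1L), by = chunkSize)) {
    if (!nReg) break
    hi <- min(lo + chunkSize - 1L, nReg)
    sub <- regions[lo:hi]
    ov <- findOverlaps(endsGr, sub, ignore.strand = TRUE)
    if (!length(ov)) next
    q <- queryHits(ov); r <- subjectHits(ov)
    # drop the duplicate record of pairs with both ends in one window
    key <- as.numeric(pairIdx[q]) * (hi - lo + 2) + r
    first <- !duplicated(key)
    q <- q[first]; r <- r[first]
    nP[lo:hi] <- nP[lo:hi] + tabulate(r, hi - lo + 1L)
    isPch <- otherPch[q]
    kP[lo:hi] <- kP[lo:hi] + tabulate(r[isPch], hi - lo + 1L)
    oa <- otherArm[q]
    for (a in pchArms) {
      sel <- !is.na(oa) & oa == a
      if (any(sel))
        kArm[lo:hi, a] <- kArm[lo:hi, a] + tabulate(r[sel], hi - lo + 1L)
    }
  }
  frac <- ifelse(nP > 0, kP / nP, NA_real_)
  ids <- regionIds
  if (is.null(ids)) ids <- paste0("region_", seq_len(nReg))
  out <- data.frame(region_id = ids,
                    arm = as.character(seqnames(regions)),
                    width = width(regions),
                    n_pairs = nP, frac_pch = frac,
                    stringsAsFactors = FALSE)
  for (a in pchArms)
    out[[paste0("frac_pch_", a)]] <- ifelse(nP > 0, kArm[, a] / nP,
                                            NA_real_)
  out$excluded <- nP < minPairs
  out
}

# eligible placement space: euchromatin minus exclusions, per arm
.eligibleSpace <- function(annotation, exclusions) {
  eu <- deriveEuchromatin(annotation)
  if (!is.null(exclusions) && length(exclusions))
    eu <- setdiff(eu, exclusions)
  eu[width(eu) > 0]
}

# sample k start positions for regions of width w on one arm
.samplePlacements <- function(space, arm, w, k) {
  sp <- space[as.character(seqnames(space)) == arm & width(space) >= w]
  slots <- width(sp) - w + 1
  if (!length(sp) || sum(slots) <= 0)
    stop("insufficient euchromatic space on arm ", arm,
         " for regions of ", w, " bp")
  iv <- sample.int(length(sp), k, replace = TRUE, prob = slots)
  off <- floor(stats::runif(k) * slots[iv])
  start(sp)[iv] + off
}

#' Sample matched random euchromatic null regions
#'
#' Draws `nSets` independent sets of random euchromatic regions without
#' H3K9me2 enrichment, each set mirroring the query template: one region
#' per template feature, on the same arm, of the same size (for
#' `sizeMatch = "exact"`, the island convention) or of a size drawn from
#' the template sizes in the same quantile bin (`sizeMatch =
#' "quantile"`, the TE convention). Null regions never overlap the
#' exclusion intervals (all H3K9me2-enriched regions).
#'
#' @param annotation a [GenomeAnnotation-class]
#' @param exclusions `GRanges` removed from the placement space
#' @param template query windows ([makeQueryWindows()])
#' @param nSets number of null sets (200 by default)
#' @param seed optional RNG seed
#' @param sizeMatch `"exact"` or `"quantile"`
#' @param quantileBins number of size-quantile bins (quartiles by
#'   default)
#' @return `GRanges` of null regions with metadata `set`, `template_id`,
#'   `region_id`, `size_bin`.
#' @export
sampleNullRegions <- function(annotation, exclusions, template,
                              nSets = 200, seed = NULL,
                              sizeMatch = c("exact", "quantile"),
                              quantileBins = 4) {
  sizeMatch <- match.arg(sizeMatch)
  if (!is.null(seed)) set.seed(seed)
  space <- .eligibleSpace(annotation, exclusions)
  tArm <- as.character(seqnames(template))
  tW <- width(template)
  tid <- mcols(template)$region_id
  if (is.null(tid)) tid <- paste0("t", seq_along(template))
  bins <- sizeQuantileBins(tW, quantileBins)

  n <- length(template)
  armOut <- rep(tArm, nSets)
  wOut <- if (sizeMatch == "exact") rep(tW, nSets) else {
    # draw a size from the template's own (arm-free) quantile bin
    unlist(lapply(seq_len(nSets), function(s) {
      vapply(seq_len(n), function(i) {
        pool <- tW[bins == bins[i]]
        pool[sample.int(length(pool), 1L)]
      }, numeric(1))
    }))
  }
  startOut <- numeric(length(armOut))
  for (a in unique(armOut)) {
    for (w in unique(wOut[armOut == a])) {
      sel <- armOut == a & wOut == w
      startOut[sel] <- .samplePlacements(space, a, w, sum(sel))
    }
  }
  gr <- GRanges(armOut, IRanges(startOut, width = wOut))
  mcols(gr)$set <- rep(seq_len(nSets), each = n)
  mcols(gr)$template_id <- rep(tid, nSets)
  mcols(gr)$region_id <- paste0("null_s", mcols(gr)$set, "_",
                                mcols(gr)$template_id)
  mcols(gr)$size_bin <- rep(bins, nSets)
  gr
}

#' Size-quantile bins of a query set
#'
#' Quartile bins (by default) of the query window sizes, used as the
#' stratification key when pooling null regions for the empirical
#' p-value. Computed per analysis (islands and TEs separately).
#'
#' @param widths window widths
#' @param nBins number of bins
#' @return integer bin per width
#' @export
sizeQuantileBins <- function(widths, nBins = 4) {
  if (length(unique(widths)) == 1L) return(rep(1L, length(widths)))
  br <- unique(stats::quantile(widths, probs = seq(0, 1, length.out =
                                                     nBins + 1)))
  as.integer(cut(widths, breaks = br, include.lowest = TRUE))
}

#' Empirical p-values from a matched null ensemble
#'
#' For each non-excluded query, pools the non-excluded null fractions
#' sharing the query's (arm, size-quantile bin) stratum and computes the
#' one-sided empirical p-value with the +1 pseudocount,
#' `p = (1 + #\{null >= observed\}) / (1 + #null)`. Significance is
#' called at p < 0.05 (nominal; the cohort-level binomial test plays the
#' role of a multiplicity check).
#'
#' @param queryRes [euPchFraction()] result for the query windows
#' @param nullRes [euPchFraction()] result for the null regions (needs
#'   the null `size_bin` and arm columns; pass `nullBins`/`nullArms` to
#'   override)
#' @param queryBins,nullBins integer size-quantile bins; query bins are
#'   computed from the query widths when omitted, null bins default to
#'   the `size_bin` metadata propagated by [sampleNullRegions()]
#' @param alpha significance threshold
#' @param quantileBins bins used when recomputing from widths
#' @return `queryRes` with added columns `empirical_p`, `n_null`,
#'   `significant`.
#' @export
empiricalPvalues <- function(queryRes, nullRes, queryBins = NULL,
                             nullBins = NULL, alpha = 0.05,
                             quantileBins = 4) {
  if (is.null(queryBins))
    queryBins <- sizeQuantileBins(queryRes$width, quantileBins)
  if (is.null(nullBins)) {
    if (!is.null(nullRes$size_bin)) nullBins <- nullRes$size_bin
    else nullBins <- sizeQuantileBins(nullRes$width, quantileBins)
  }
  ok <- !nullRes$excluded & !is.na(nullRes$frac_pch)
  nullArm <- nullRes$arm[ok]
  nullBin <- nullBins[ok]
  nullFrac <- nullRes$frac_pch[ok]
  p <- rep(NA_real_, nrow(queryRes))
  nNull <- integer(nrow(queryRes))
  for (i in seq_len(nrow(queryRes))) {
    if (queryRes$excluded[i] || is.na(queryRes$frac_pch[i])) next
    sel <- nullArm == queryRes$arm[i] & nullBin == queryBins[i]
    m <- sum(sel)
    nNull[i] <- m
    if (!m) next
    p[i] <- (1 + sum(nullFrac[sel] >= queryRes$frac_pch[i])) / (1 + m)
  }
  queryRes$empirical_p <- p
  queryRes$n_null <- nNull
  queryRes$significant <- !is.na(p) & p < alpha
  queryRes
}

#' Exact two-sided binomial enrichment test
#'
#' Cohort-level check that more query regions reached significance than
#' the 5% expected under the null: exact binomial test of `k` significant
#' out of `n` tested against `p0`, two-sided under the point-probability
#' (minlike) convention — the sum of `P(X = j)` over all `j` whose point
#' probability does not exceed `P(X = k)`.
#'
#' @param k significant count
#' @param n tested count
#' @param p0 null probability (0.05 for the 5% expectation)
#' @return the p-value
#' @export
enrichmentBinomial <- function(k, n, p0 = 0.05) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      k < 0 || n < 1 || k > n || k != round(k) || n != round(n))
    stop("k must be an integer in [0, n], n a positive integer")
  if (!(p0 > 0 && p0 < 1)) stop("p0 must lie in (0, 1)")
  stats::binom.test(k, n, p0)$p.value
}

#' Cohort enrichment summary
#'
#' @param k significant count (or vector, e.g. either/both replicate
#'   modes)
#' @param n tested count
#' @param p0 null probability
#' @param label optional labels per `k`
#' @return `data.frame` with `k`, `n`, `percent`, `binomial_p`
#' @export
cohortEnrichment <- function(k, n, p0 = 0.05, label = NULL) {
  pv <- vapply(k, enrichmentBinomial, numeric(1), n = n, p0 = p0)
  out <- data.frame(k = k, n = n, percent = 100 * k / n, binomial_p = pv)
  if (!is.null(label)) out <- cbind(label = label, out)
  out
}
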