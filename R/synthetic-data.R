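#' Configuration of the synthetic-data generators
#'
#' Bundles the seed and every generative parameter used by the
#' simulators. The defaults define a desk-scale five-arm toy genome
#' (four 2.4-Mb major arms carrying 0.5 Mb of PCH each, plus a fully
#' heterochromatic 0.4-Mb 4th chromosome; 10 Mb total, 24 PCH windows
#' of 100 kb) with a power-law intra-arm contact decay, a small uniform
#' cross-arm background, optional planted arm-pair and
#' euchromatin-PCH contact multipliers, a MAPQ emission model
#' (multi-mapped, repeat-derived and mid-quality ends), strain-paired
#' ChIP enrichment with TE-adjacent spread, a bimodal FISH distance
#' mixture and a two-group TE population-frequency model.
#'
#' @param seed integer seed; all randomness flows from it
#' @param ... overrides of any default field (see the source for the
#'   complete list)
#' @return a list of class `SyntheticConfig`
#' @export
syntheticConfig <- function(seed, ...) {
  cfg <- list(
    seed = seed,
    arms = data.frame(
      arm = c("2L", "2R", "3L", "3R", "4"),
      chrom = c("2", "2", "3", "3", "4"),
      length = c(2.4e6, 2.4e6, 2.4e6, 2.4e6, 4e5),
      pch_start = c(1.9e6, 0, 1.9e6, 0, 0),   # BED convention
      pch_end = c(2.4e6, 5e5, 2.4e6, 5e5, 4e5)
    ),
    hetChromosomes = "4",
    euOffsetBp = 5e5,
    windowBp = 1e5,
    minSeparationBp = 1e4,
    # contact model
    decayExponent = 1,
    decayMinBp = 1000,
    crossWeight = 0.1,
    armPairMultipliers = stats::setNames(numeric(0), character(0)),
    euPchBaseRate = 0.05,
    # feature placement
    nIslands = 24, islandSizeRange = c(2000, 6000), islandMultiplier = 1,
    nTes = 12, teMultiplier = 1, featureGapBp = 2000,
    placementMode = "spaced",
    islandPositions = NULL, tePositions = NULL,
    # MAPQ / repeat emission
    pMulti = 0.10, pRepeat = 0.05, pMid = 0.02, pTe = 0.005,
    zeroMapFrac = 0.2,
    repeatNames = c("AAGAG", "dodeca", "Rsp"),
    # ChIP model
    chipInputLevel = 100, chipIslandFold = 4, chipSpreadFold = 2,
    chipSpreadExtentBp = 4000, chipNoiseSd = 0.1, chipBinBp = 1000,
    chipTargetTotal = 2e9, nWildtypes = 2,
    sinkRegion = c(arm = "4", start = 1, end = 200000),
    # FISH mixture
    fishPi = 0.4, fishSigma0 = 0.1, fishMu1 = 1.5, fishSigma1 = 0.3,
    fishRadiusMean = 2.5, fishRadiusSd = 0.3,
    # TE population frequencies
    freqMeanWith = 9.7e-4, freqMeanWithout = 9.6e-3,
    nTeWith = 14, nTeWithout = 92
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$decayExponent > 0,
            cfg$crossWeight >= 0, cfg$crossWeight < 1,
            all(cfg$armPairMultipliers > 0),
            cfg$fishPi >= 0, cfg$fishPi <= 1,
            cfg$islandMultiplier > 0, cfg$teMultiplier > 0)
  class(cfg) <- "SyntheticConfig"
  cfg
}

# sample one placement of width w anywhere in `space`
.placeOne <- function(space, w) {
  sp <- space[width(space) >= w]
  if (!length(sp))
    stop("cannot fit a ", w, " bp feature into the remaining euchromatin")
  slots <- width(sp) - w + 1
  iv <- sample.int(length(sp), 1L, prob = slots)
  st <- start(sp)[iv] + floor(stats::runif(1) * slots[iv])
  GRanges(as.character(seqnames(sp))[iv], IRanges(st, width = w))
}

# place n features in euchromatin: "spaced" packs them without overlap
# (keeping gaps), "uniform" draws i.i.d. uniform placements, the design
# matched by the i.i.d. null resampling
.placeFeatures <- function(annotation, n, widths, gapBp, avoid = NULL,
                           mode = c("spaced", "uniform")) {
  mode <- match.arg(mode)
  space <- deriveEuchromatin(annotation)
  if (!is.null(avoid) && length(avoid))
    space <- setdiff(space, avoid + gapBp)
  placed <- GRanges()
  for (i in seq_len(n)) {
    g <- .placeOne(space, widths[i])
    placed <- suppressWarnings(c(placed, g))
    if (mode == "spaced") space <- setdiff(space, g + gapBp)
  }
  # full arm seqlevels in annotation order, for clean downstream merges
  GRanges(factor(as.character(seqnames(placed)),
                 levels = armTable(annotation)$arm), ranges(placed))
}

#' Require features to lie within derived euchromatin
#'
#' Errors when a feature extends beyond the conservative euchromatin
#' (inside PCH or closer than the 0.5-Mb buffer to a PCH boundary).
#'
#' @param features `GRanges`
#' @param annotation a [GenomeAnnotation-class]
#' @return the features, invisibly
#' @export
validateEuchromatic <- function(features, annotation) {
  eu <- deriveEuchromatin(annotation)
  within <- overlapsAny(features, eu, type = "within",
                        ignore.strand = TRUE)
  if (!all(within))
    stop(sum(!within), " feature(s) outside derived euchromatin ",
         "(PCH or the boundary buffer)")
  invisible(features)
}

#' Generate the toy genome and its annotation artifacts
#'
#' Deterministic given the seed. Produces the [GenomeAnnotation-class],
#' the binary mappability track (1 everywhere except a central segment
#' of each PCH block, emulating unmappable multi-copy repeat arrays),
#' the [RepeatCatalog-class], and H3K9me2 island / TE insertion
#' placements restricted to derived euchromatin (so every feature obeys
#' the > 0.5 Mb distance-to-boundary rule by construction; explicitly
#' supplied positions are validated against it).
#'
#' @param config a [syntheticConfig()]
#' @param seed RNG seed (defaults to `config$seed`)
#' @return list with `annotation`, `mappability`, `catalog`, `islands`,
#'   `tes`, `zeroMap`.
#' @export
makeToyGenome <- function(config, seed = config$seed) {
  set.seed(seed)
  a <- config$arms
  a <- a[a$pch_end > a$pch_start, ]
  bed <- data.frame(arm = a$arm, start = a$pch_start, end = a$pch_end)
  a <- config$arms
  ann <- loadAnnotation(bed, a[c("arm", "chrom", "length")],
                        hetChromosomes = config$hetChromosomes,
                        euOffsetBp = config$euOffsetBp)
  pch <- pchRegions(ann)
  zw <- round(width(pch) * config$zeroMapFrac)
  zs <- start(pch) + floor((width(pch) - zw) / 2)
  zeroMap <- GRanges(seqnames(pch), IRanges(zs, width = zw))
  zeroMap <- zeroMap[width(zeroMap) > 0]
  mappable <- setdiff(genomeRanges(ann), zeroMap)
  map <- suppressWarnings(c(mappable, zeroMap))
  map$score <- rep(c(1, 0), c(length(mappable), length(zeroMap)))
  map <- sort(map)
  catalog <- RepeatCatalog(config$repeatNames)

  if (!is.null(config$islandPositions)) {
    islands <- config$islandPositions
    validateEuchromatic(islands, ann)
  } else {
    iw <- round(stats::runif(config$nIslands, config$islandSizeRange[1],
                             config$islandSizeRange[2]))
    islands <- .placeFeatures(ann, config$nIslands, iw,
                              config$featureGapBp,
                              mode = config$placementMode)
  }
  if (length(islands)) {
    mcols(islands)$region_id <- paste0("isl_", seq_along(islands))
    mcols(islands)$multiplier <- rep_len(config$islandMultiplier,
                                         length(islands))
  }
  if (!is.null(config$tePositions)) {
    tes <- config$tePositions
    validateEuchromatic(tes, ann)
  } else {
    tes <- .placeFeatures(ann, config$nTes, rep(1L, config$nTes),
                          config$featureGapBp, avoid = islands,
                          mode = config$placementMode)
  }
  if (length(tes)) {
    mcols(tes)$region_id <- paste0("te_", seq_along(tes))
    mcols(tes)$multiplier <- rep_len(config$teMultiplier, length(tes))
  }
  list(annotation = ann, mappability = map, catalog = catalog,
       islands = islands, tes = tes, zeroMap = zeroMap)
}

# power-law distances on [lo, hi], density ~ s^(-alpha)
.rPowerLaw <- function(n, alpha, lo, hi) {
  u <- stats::runif(n)
  if (abs(alpha - 1) < 1e-12) {
    lo * (hi / lo)^u
  } else {
    a1 <- 1 - alpha
    (lo^a1 + u * (hi^a1 - lo^a1))^(1 / a1)
  }
}

# arm-pair multiplier matrix from named "a-b" entries
.multMatrix <- function(arms, multipliers) {
  M <- matrix(1, length(arms), length(arms),
              dimnames = list(arms, arms))
  for (nm in names(multipliers)) {
    ab <- strsplit(nm, "-", fixed = TRUE)[[1]]
    if (length(ab) != 2 || !all(ab %in% arms))
      stop("bad arm-pair multiplier name: ", nm)
    M[ab[1], ab[2]] <- multipliers[[nm]]
    M[ab[2], ab[1]] <- multipliers[[nm]]
  }
  M
}

# sample positions uniformly within a weighted interval set
.rUniformIn <- function(gr, n) {
  w <- width(gr)
  iv <- sample.int(length(gr), n, replace = TRUE, prob = w)
  pos <- start(gr)[iv] + floor(stats::runif(n) * w[iv])
  list(arm = as.character(seqnames(gr))[iv], pos = pos)
}

#' Simulate aligned Hi-C read pairs
#'
#' Each pair draws its first end uniformly over the genome; the second
#' end comes from a mixture of (i) an intra-arm power-law distance decay
#' `s^(-alpha)`, (ii) a uniform cross-arm background of total weight
#' `crossWeight`, redistributed across arm pairs by any planted
#' arm-pair multipliers, and (iii), for first ends inside a planted
#' euchromatic query window with multiplier `m > 1`, a
#' PCH-routed component of probability `min(0.95, m * euPchBaseRate)`
#' that sends the second end into mappable PCH (arms weighted by their
#' mappable PCH length). MAPQ, repeat-derived and canonical-TE emissions
#' follow the configured model; repeat-derived ends lose their genomic
#' position, as alignments to a repeat reference would.
#'
#' @param genome a [makeToyGenome()] result
#' @param config a [syntheticConfig()]
#' @param nPairs number of pairs
#' @param seed RNG seed (defaults to `config$seed`)
#' @return raw pairs `data.frame` (columns `read_id`, `arm1`, `pos1`,
#'   `mapq1`, `repeat1`, `te1`, and the same for end 2), ready for
#'   [classifyPairs()].
#' @export
simulateHicPairs <- function(genome, config, nPairs,
                             seed = config$seed) {
  stopifnot(nPairs > 0)
  set.seed(seed)
  ann <- genome$annotation
  arms <- armTable(ann)$arm
  len <- armLengths(ann)
  nA <- length(arms)

  arm1i <- sample.int(nA, nPairs, replace = TRUE, prob = len[arms])
  pos1 <- 1 + floor(stats::runif(nPairs) * len[arms][arm1i])

  # planted euchromatin-PCH query windows
  planted <- GRanges()
  for (feat in list(genome$islands, genome$tes)) {
    if (length(feat) && any(mcols(feat)$multiplier > 1)) {
      f <- feat[mcols(feat)$multiplier > 1]
      kind <- if (all(width(f) == 1)) "te" else "island"
      w <- suppressWarnings(makeQueryWindows(f, ann, kind = kind))
      planted <- suppressWarnings(c(planted, w))
    }
  }
  mult1 <- rep(1, nPairs)
  if (length(planted)) {
    g1 <- GRanges(arms[arm1i], IRanges(pos1, width = 1L))
    ov <- findOverlaps(g1, planted, select = "first")
    hit <- !is.na(ov)
    mult1[hit] <- mcols(planted)$multiplier[ov[hit]]
  }

  pchMappable <- intersect(genome$mappability[genome$mappability$score == 1],
                           pchRegions(ann))
  pRoute <- ifelse(mult1 > 1,
                   pmin(0.95, mult1 * config$euPchBaseRate), 0)
  routed <- stats::runif(nPairs) < pRoute

  arm2i <- integer(nPairs)
  pos2 <- numeric(nPairs)
  if (any(routed)) {
    r <- .rUniformIn(pchMappable, sum(routed))
    arm2i[routed] <- match(r$arm, arms)
    pos2[routed] <- r$pos
  }
  base <- !routed
  cross <- base & stats::runif(nPairs) < config$crossWeight
  intra <- base & !cross
  if (any(cross)) {
    M <- .multMatrix(arms, config$armPairMultipliers)
    for (ai in seq_len(nA)) {
      sel <- cross & arm1i == ai
      if (!any(sel)) next
      wts <- len[arms] * M[ai, ]
      wts[ai] <- 0
      tgt <- sample.int(nA, sum(sel), replace = TRUE, prob = wts)
      arm2i[sel] <- tgt
      pos2[sel] <- 1 + floor(stats::runif(sum(sel)) * len[arms][tgt])
    }
  }
  if (any(intra)) {
    idx <- which(intra)
    armI <- arm1i[idx]
    L <- len[arms][armI]
    p2 <- rep(NA_real_, length(idx))
    todo <- seq_along(idx)
    while (length(todo)) {
      s <- .rPowerLaw(length(todo), config$decayExponent,
                      config$decayMinBp, L[todo])
      dir <- ifelse(stats::runif(length(todo)) < 0.5, -1, 1)
      cand <- pos1[idx[todo]] + dir * round(s)
      ok <- cand >= 1 & cand <= L[todo]
      p2[todo[ok]] <- cand[ok]
      todo <- todo[!ok]
    }
    arm2i[idx] <- armI
    pos2[idx] <- p2
  }

  e1 <- .emitEnds(arms[arm1i], pos1, genome, config)
  e2 <- .emitEnds(arms[arm2i], pos2, genome, config)
  data.frame(read_id = sprintf("p%08d", seq_len(nPairs)),
             arm1 = e1$arm, pos1 = e1$pos, mapq1 = e1$mapq,
             repeat1 = e1$rep, te1 = e1$te,
             arm2 = e2$arm, pos2 = e2$pos, mapq2 = e2$mapq,
             repeat2 = e2$rep, te2 = e2$te,
             stringsAsFactors = FALSE)
}

# emission model: true (arm, pos) -> reported end fields
.emitEnds <- function(arm, pos, genome, config) {
  n <- length(arm)
  gr <- GRanges(arm, IRanges(pos, width = 1L))
  inPch <- overlapsAny(gr, pchRegions(genome$annotation))
  inZero <- overlapsAny(gr, genome$zeroMap)
  mapq <- sample(30:60, n, replace = TRUE)
  rep_hit <- rep(NA_character_, n)
  te_hit <- rep(FALSE, n)
  u <- stats::runif(n)
  # PCH ends
  isRep <- inPch & u < config$pRepeat
  isMid <- inPch & !isRep &
    u < config$pRepeat + config$pMid
  isMulti <- inPch & !isRep & !isMid &
    (inZero | u < config$pRepeat + config$pMid + config$pMulti)
  mapq[isMulti] <- 0L
  mapq[isMid] <- sample(5:29, sum(isMid), replace = TRUE)
  rep_hit[isRep] <- sample(config$repeatNames, sum(isRep),
                           replace = TRUE)
  mapq[isRep] <- 0L
  # euchromatic ends
  isTe <- !inPch & u < config$pTe
  isMidEu <- !inPch & !isTe & u < config$pTe + config$pMid
  te_hit[isTe] <- TRUE
  mapq[isMidEu] <- sample(5:29, sum(isMidEu), replace = TRUE)
  outArm <- ifelse(isRep, NA_character_, arm)
  outPos <- ifelse(isRep, NA_real_, pos)
  list(arm = outArm, pos = outPos, mapq = mapq, rep = rep_hit,
       te = te_hit)
}

#' Simulate strain-paired ChIP and input coverage
#'
#' The focal strain carries planted H3K9me2 spread of
#' `chipSpreadExtentBp` per side and fold `chipSpreadFold` around every
#' designated TE; wildtype strains are background-only there. H3K9me2
#' islands are enriched (`chipIslandFold`) in all strains, emulating
#' shared non-TE islands. Enrichment is planted directly on the scale
#' the estimator measures — the library-size-normalized, +1-pseudocount
#' log2 ratio — and every track is brought to exactly the same total
#' (`chipTargetTotal`) via a compensating block inside PCH, far from any
#' profiled window, so that with zero noise [spreadExtent()] recovers
#' the planted extent and magnitude exactly. Per-kb multiplicative
#' log-normal noise of sd `chipNoiseSd` (log2 units) is applied to the
#' ChIP tracks when positive.
#'
#' @param genome a [makeToyGenome()] result
#' @param config a [syntheticConfig()]
#' @param seed RNG seed (defaults to `config$seed`)
#' @param spreadTes indices of `genome$tes` carrying planted spread
#'   (default all)
#' @return list with `strains` (per strain: `chip`, `input` coverage
#'   `GRanges`), `spreadTes`, `libSize`.
#' @export
simulateChipProfiles <- function(genome, config, seed = config$seed,
                                 spreadTes = seq_along(genome$tes)) {
  set.seed(seed)
  ann <- genome$annotation
  I <- config$chipInputLevel
  Tt <- config$chipTargetTotal
  k <- 1e6 / Tt
  ext <- config$chipSpreadExtentBp
  sink <- GRanges(config$sinkRegion[["arm"]],
                  IRanges(as.numeric(config$sinkRegion[["start"]]),
                          as.numeric(config$sinkRegion[["end"]])))
  gen <- genomeRanges(ann)
  body <- setdiff(gen, sink)

  plantIsl <- if (length(genome$islands))
    granges(genome$islands) else GRanges()
  if (length(plantIsl))
    mcols(plantIsl)$p <- log2(config$chipIslandFold)
  spread <- GRanges()
  if (length(spreadTes) && length(genome$tes)) {
    tes <- genome$tes[spreadTes]
    spread <- GRanges(seqnames(tes),
                      IRanges(start(tes) - ext, end(tes) + ext))
    mcols(spread)$p <- log2(config$chipSpreadFold)
  }

  mkChip <- function(planted, noiseSd) {
    pieces <- body
    if (noiseSd > 0) {
      tiles <- unlist(tile(body, width = config$chipBinBp))
      pieces <- tiles
      eps <- stats::rnorm(length(tiles), 0, noiseSd)
    }
    # planted intervals lie inside body (features are euchromatic and
    # the profile extent never reaches the PCH sink), so disjoining the
    # union partitions body along both tile and feature boundaries
    pieces2 <- if (length(planted))
      disjoin(c(granges(pieces), granges(planted)))
    else granges(pieces)
    p <- rep(0, length(pieces2))
    if (length(planted)) {
      ov <- findOverlaps(pieces2, planted, select = "first")
      p[!is.na(ov)] <- mcols(planted)$p[ov[!is.na(ov)]]
    }
    e <- rep(0, length(pieces2))
    if (noiseSd > 0) {
      ov <- findOverlaps(pieces2, pieces, select = "first")
      e[!is.na(ov)] <- eps[ov[!is.na(ov)]]
    }
    val <- pmax(0, (I + 1 / k) * 2^(p + e) - 1 / k)
    gr <- pieces2
    gr$score <- val
    tot <- trackTotal(gr)
    if (tot > Tt)
      stop("chipTargetTotal too small for the planted enrichment")
    sinkGr <- sink
    sinkGr$score <- (Tt - tot) / width(sink)
    sort(c(gr, sinkGr))
  }
  mkInput <- function() {
    gr <- body
    gr$score <- rep(I, length(body))
    tot <- trackTotal(gr)
    sinkGr <- sink
    sinkGr$score <- (Tt - tot) / width(sink)
    sort(c(gr, sinkGr))
  }

  strains <- list()
  strains$focal <- list(chip = mkChip(c(plantIsl, spread),
                                      config$chipNoiseSd),
                        input = mkInput())
  for (i in seq_len(config$nWildtypes)) {
    strains[[paste0("wt", i)]] <-
      list(chip = mkChip(plantIsl, config$chipNoiseSd),
           input = mkInput())
  }
  list(strains = strains, spreadTes = spreadTes, libSize = Tt)
}

#' Simulate per-nucleus FISH focus distances
#'
#' Distances follow the mixture
#' `pi * |N(0, sigma0)| + (1 - pi) * N(mu1, sigma1)` truncated at zero;
#' nuclear radii are normal, truncated at zero.
#'
#' @param config a [syntheticConfig()]
#' @param nNuclei number of nuclei (>= 1)
#' @param seed RNG seed (defaults to `config$seed`)
#' @param group group label
#' @param mixturePi override of the near-zero weight `pi`
#' @return `data.frame` with `nucleus_id`, `group`, `distance_um`,
#'   `radius_um`.
#' @export
simulateFishDistances <- function(config, nNuclei,
                                  seed = config$seed, group = "focal",
                                  mixturePi = config$fishPi) {
  stopifnot(nNuclei >= 1, mixturePi >= 0, mixturePi <= 1)
  set.seed(seed)
  near <- stats::runif(nNuclei) < mixturePi
  d <- numeric(nNuclei)
  d[near] <- abs(stats::rnorm(sum(near), 0, config$fishSigma0))
  nf <- sum(!near)
  far <- stats::rnorm(nf, config$fishMu1, config$fishSigma1)
  while (any(far < 0))
    far[far < 0] <- stats::rnorm(sum(far < 0), config$fishMu1,
                                 config$fishSigma1)
  d[!near] <- far
  r <- stats::rnorm(nNuclei, config$fishRadiusMean, config$fishRadiusSd)
  while (any(r <= 0))
    r[r <= 0] <- stats::rnorm(sum(r <= 0), config$fishRadiusMean,
                              config$fishRadiusSd)
  data.frame(nucleus_id = sprintf("%s_n%05d", group, seq_len(nNuclei)),
             group = group, distance_um = d, radius_um = r,
             stringsAsFactors = FALSE)
}

#' Simulate TE population frequencies for the two contact groups
#'
#' Exponential frequency spectra (truncated at 1) with the configured
#' group means — rare variants dominating the PCH-contact group.
#'
#' @param config a [syntheticConfig()]
#' @param seed RNG seed (defaults to `config$seed`)
#' @return `data.frame` with `te_id`, `frequency`, `group`.
#' @export
simulateTeFrequencies <- function(config, seed = config$seed) {
  set.seed(seed)
  fw <- pmin(1, stats::rexp(config$nTeWith, 1 / config$freqMeanWith))
  fo <- pmin(1, stats::rexp(config$nTeWithout,
                            1 / config$freqMeanWithout))
  data.frame(
    te_id = c(sprintf("teW%03d", seq_along(fw)),
              sprintf("teO%03d", seq_along(fo))),
    frequency = c(fw, fo),
    group = rep(c("with_pch", "without_pch"),
                c(length(fw), length(fo))),
    stringsAsFactors = FALSE)
}

#' Write a full synthetic data bundle to disk
#'
#' Emits the standard formats the analysis consumes: arms TSV, PCH
#' boundaries BED, island/TE BEDs, mappability bedGraph, (classified)
#' pairs TSV, per-strain ChIP/input bedGraphs, FISH TSV and the TE
#' frequency TSV.
#'
#' @param genome a [makeToyGenome()] result
#' @param dir output directory (created if needed)
#' @param pairs optional pairs `data.frame`
#' @param chip optional [simulateChipProfiles()] result
#' @param fish optional FISH `data.frame`
#' @param freqs optional frequency `data.frame`
#' @return the directory, invisibly
#' @export
writeSyntheticData <- function(genome, dir, pairs = NULL, chip = NULL,
                               fish = NULL, freqs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- genome$annotation
  utils::write.table(armTable(ann), file.path(dir, "arms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rtracklayer::export(pchRegions(ann),
                      file.path(dir, "boundaries.bed"), format = "BED")
  if (length(genome$islands))
    rtracklayer::export(genome$islands, file.path(dir, "islands.bed"),
                        format = "BED")
  if (length(genome$tes))
    rtracklayer::export(genome$tes, file.path(dir, "tes.bed"),
                        format = "BED")
  writeCoverage(genome$mappability, file.path(dir, "mappability.bg"))
  if (!is.null(pairs))
    writePairs(pairs, file.path(dir, "pairs.tsv"))
  if (!is.null(chip)) {
    for (s in names(chip$strains)) {
      writeCoverage(chip$strains[[s]]$chip,
                    file.path(dir, paste0(s, "_chip.bg")))
      writeCoverage(chip$strains[[s]]$input,
                    file.path(dir, paste0(s, "_input.bg")))
    }
  }
  if (!is.null(fish))
    utils::write.table(fish, file.path(dir, "fish.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(freqs))
    utils::write.table(freqs, file.path(dir, "te_frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
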