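#' Build the PCH contact matrix
#'
#' Tallies unique PCH-PCH read pairs over the PCH windows. Same-arm pairs
#' whose mapping positions are within `minSeparationBp` of each other
#' (10 kb by default) are removed first — the analysis targets long-range
#' contacts, not local polymer neighborhood. Separation is undefined
#' across arms, so cross-arm pairs are always retained. Pairs with an end
#' outside every window are counted, reported and dropped.
#'
#' @param pairs classified pairs (from [classifyPairs()]); only
#'   `PCH_PCH_UNIQUE` rows are used
#' @param windows PCH windows from [binPchWindows()]
#' @param minSeparationBp same-arm separation threshold in bp
#' @return a [ContactMatrix-class]
#' @export
buildContactMatrix <- function(pairs, windows, minSeparationBp = 10000) {
  stopifnot(all(c("arm", "chrom", "window") %in% names(mcols(windows))))
  p <- pairs[pairs$pair_class == "PCH_PCH_UNIQUE", , drop = FALSE]
  nInput <- nrow(p)
  sameArm <- !is.na(p$arm1) & !is.na(p$arm2) & p$arm1 == p$arm2
  close <- sameArm & abs(p$pos1 - p$pos2) < minSeparationBp
  nClose <- sum(close)
  p <- p[!close, , drop = FALSE]

  n <- length(windows)
  counts <- matrix(0L, n, n)
  nOutside <- 0L
  if (nrow(p)) {
    lv <- union(seqlevels(windows), unique(c(p$arm1, p$arm2)))
    g1 <- GRanges(factor(p$arm1, lv), IRanges(p$pos1, width = 1L))
    g2 <- GRanges(factor(p$arm2, lv), IRanges(p$pos2, width = 1L))
    windows <- GRanges(factor(as.character(seqnames(windows)), lv),
                       ranges(windows), arm = mcols(windows)$arm,
                       chrom = mcols(windows)$chrom,
                       window = mcols(windows)$window)
    h1 <- findOverlaps(g1, windows, select = "first")
    h2 <- findOverlaps(g2, windows, select = "first")
    ok <- !is.na(h1) & !is.na(h2)
    nOutside <- sum(!ok)
    i <- pmin(h1[ok], h2[ok]); j <- pmax(h1[ok], h2[ok])
    tab <- table(factor(i + (j - 1) * n, levels = seq_len(n * n)))
    upper <- matrix(as.integer(tab), n, n)
    counts <- upper + t(upper) - diag(diag(upper), n)
  }
  methods::new("ContactMatrix", windows = windows, counts = counts,
               nPairsInput = nInput, nDroppedClose = nClose,
               nDroppedOutside = as.numeric(nOutside),
               minSeparation = minSeparationBp)
}

#' @rdname ContactMatrix-class
#' @export
setMethod("contactCounts", "ContactMatrix", function(object) object@counts)

#' @rdname ContactMatrix-class
#' @export
setMethod("contactWindows", "ContactMatrix",
          function(object) object@windows)

setMethod("show", "ContactMatrix", function(object) {
  n <- length(object@windows)
  cat("ContactMatrix over", n, "PCH windows on",
      length(unique(mcols(object@windows)$arm)), "arms\n")
  cat("  retained pair mass:", .pairMass(object@counts), "of",
      object@nPairsInput, "input pairs\n")
  cat("  dropped: ", object@nDroppedClose, " within ",
      object@minSeparation, " bp; ", object@nDroppedOutside,
      " outside windows\n", sep = "")
})

# total pair mass of a symmetric count matrix (diagonal counted once)
.pairMass <- function(m) (sum(m) + sum(diag(m))) / 2

# unordered arm-pair class label, in annotation arm order
.classLabel <- function(a, b, armOrder) {
  ia <- match(a, armOrder); ib <- match(b, armOrder)
  swap <- ib < ia
  lo <- ifelse(swap, b, a); hi <- ifelse(swap, a, b)
  ifelse(lo == hi, "intra_arm", paste(lo, hi, sep = "-"))
}

#' Sequential-exclusion partition of PCH-PCH interactions
#'
#' Aggregates the contact matrix into interaction classes and their
#' observed proportions at one of the three sequential levels:
#' * `all` — every retained pair; classes are the intra-arm aggregate,
#'   each inter-arm (same chromosome) pair and each inter-chromosome
#'   arm pair;
#' * `no_intra_arm` — intra-arm cells excluded, proportions over the
#'   remainder;
#' * `no_intra_chromosome` — only arm pairs on different chromosomes.
#'
#' @param cm a [ContactMatrix-class]
#' @param level `"all"`, `"no_intra_arm"` or `"no_intra_chromosome"`
#' @return `data.frame` with columns `class`, `arm1`, `arm2`, `count`,
#'   `proportion` (summing to 1), plus attributes `level` and
#'   `retained` (pair count at the level).
#' @export
partitionInteractions <- function(cm,
    level = c("all", "no_intra_arm", "no_intra_chromosome")) {
  level <- match.arg(level)
  w <- contactWindows(cm)
  arm <- mcols(w)$arm
  chrom <- mcols(w)$chrom
  m <- contactCounts(cm)
  n <- length(w)
  if (n == 0 || .pairMass(m) == 0) stop("empty contact matrix")
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  mass <- m[idx]
  a1 <- arm[idx[, 1]]; a2 <- arm[idx[, 2]]
  c1 <- chrom[idx[, 1]]; c2 <- chrom[idx[, 2]]
  keep <- switch(level,
    all = rep(TRUE, length(mass)),
    no_intra_arm = a1 != a2,
    no_intra_chromosome = c1 != c2)
  mass <- mass[keep]; a1 <- a1[keep]; a2 <- a2[keep]
  if (!length(mass) || sum(mass) == 0)
    stop("no interactions remain at level ", level)
  armOrder <- unique(arm)
  lab <- .classLabel(a1, a2, armOrder)
  agg <- rowsum(mass, lab)
  cls <- rownames(agg)
  o <- order(match(sub("-.*", "", cls), c(armOrder, "intra_arm")),
             match(sub(".*-", "", cls), c(armOrder, "intra_arm")))
  o <- o[order(cls[o] != "intra_arm", decreasing = TRUE)]
  cls <- cls[o]
  cnt <- agg[o, 1]
  arm1 <- ifelse(cls == "intra_arm", NA, sub("-.*", "", cls))
  arm2 <- ifelse(cls == "intra_arm", NA, sub(".*-", "", cls))
  out <- data.frame(class = cls, arm1 = arm1, arm2 = arm2, count = cnt,
                    proportion = cnt / sum(cnt), row.names = NULL)
  attr(out, "level") <- level
  attr(out, "retained") <- sum(cnt)
  out
}

#' Expected interaction proportions from arm weights
#'
#' Converts per-arm marginal weights ([armMarginals()]) into expected
#' class proportions at a given exclusion level: the expected mass of an
#' arm pair (a, b) is `2 * w_a * w_b` for a != b and `w_a^2` for the
#' intra-arm aggregate, normalized over the classes the level allows.
#' Invariant to global rescaling of the weights.
#'
#' @param weights named numeric vector from [armMarginals()]
#' @param annotation a [GenomeAnnotation-class]
#' @param level exclusion level as in [partitionInteractions()]
#' @return `data.frame` with columns `class`, `expected` (summing to 1)
#' @export
expectedProportions <- function(weights, annotation,
    level = c("all", "no_intra_arm", "no_intra_chromosome")) {
  level <- match.arg(level)
  arms <- names(weights)
  if (is.null(arms)) stop("weights must be named by arm")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative")
  chrom <- armChrom(annotation)[arms]
  grid <- expand.grid(i = seq_along(arms), j = seq_along(arms))
  grid <- grid[grid$i <= grid$j, ]
  a1 <- arms[grid$i]; a2 <- arms[grid$j]
  mass <- ifelse(a1 == a2, weights[a1]^2, 2 * weights[a1] * weights[a2])
  keep <- switch(level,
    all = rep(TRUE, nrow(grid)),
    no_intra_arm = a1 != a2,
    no_intra_chromosome = chrom[a1] != chrom[a2])
  a1 <- a1[keep]; a2 <- a2[keep]; mass <- mass[keep]
  if (!length(mass) || sum(mass) == 0)
    stop("level excludes every class")
  lab <- .classLabel(a1, a2, arms)
  agg <- rowsum(mass, lab)
  cls <- rownames(agg)
  o <- order(cls != "intra_arm", decreasing = TRUE)
  ord <- order(match(sub("-.*", "", cls), arms),
               match(sub(".*-", "", cls), arms))
  ord <- ord[order(cls[ord] != "intra_arm", decreasing = TRUE)]
  data.frame(class = cls[ord], expected = agg[ord, 1] / sum(agg),
             row.names = NULL)
}

# retained mask + class labels for arm-label pairs at a level
.pairLevelClass <- function(a1, a2, chrom, level, armOrder) {
  keep <- switch(level,
    all = rep(TRUE, length(a1)),
    no_intra_arm = a1 != a2,
    no_intra_chromosome = chrom[a1] != chrom[a2])
  list(keep = keep, label = .classLabel(a1, a2, armOrder))
}

#' One-sided permutation test for an interaction class
#'
#' Tests whether the observed proportion of pairs in a target arm-pair
#' class exceeds what label exchange would produce: each permutation
#' shuffles the second-end arm labels across the level-retained pairs
#' (preserving both marginal arm distributions); pairs falling into
#' level-excluded classes after shuffling are dropped from that
#' permutation's denominator. The one-sided p-value uses the +1
#' pseudocount convention, `p = (1 + #\{perm >= observed\}) / (1 + nPerm)`,
#' so the minimum attainable value at 10,000 permutations is 1/10,001.
#'
#' @param pairs classified pairs; only `PCH_PCH_UNIQUE` rows with both
#'   ends placed are used, after the same-arm separation filter
#' @param annotation a [GenomeAnnotation-class]
#' @param target length-2 character vector naming the target arm pair
#'   (unordered), e.g. `c("3L", "4")`
#' @param level exclusion level as in [partitionInteractions()]
#' @param nPerm number of permutations (10,000 by default)
#' @param seed optional RNG seed (recorded in the result)
#' @param minSeparationBp same-arm separation filter applied before
#'   testing
#' @param returnPermutations keep the permuted proportions (for
#'   diagnostics)
#' @param exact enumerate all `n!` pairings instead of sampling (only
#'   for n <= 9 pairs); the p-value is then the exact tail probability
#'   without pseudocount
#' @return list with `class`, `observed`, `pvalue`, `nPerm`, `nPairs`,
#'   `seed` and optionally `permuted`.
#' @export
permutationTest <- function(pairs, annotation, target,
    level = c("all", "no_intra_arm", "no_intra_chromosome"),
    nPerm = 10000, seed = NULL, minSeparationBp = 10000,
    returnPermutations = FALSE, exact = FALSE) {
  level <- match.arg(level)
  stopifnot(length(target) == 2, nPerm >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- pairs[pairs$pair_class == "PCH_PCH_UNIQUE", , drop = FALSE]
  sameArm <- p$arm1 == p$arm2
  p <- p[!(sameArm & abs(p$pos1 - p$pos2) < minSeparationBp), ,
         drop = FALSE]
  armOrder <- armTable(annotation)$arm
  chrom <- armChrom(annotation)
  lv <- .pairLevelClass(p$arm1, p$arm2, chrom, level, armOrder)
  a1 <- p$arm1[lv$keep]; a2 <- p$arm2[lv$keep]
  n <- length(a1)
  if (!n) stop("no pairs retained at level ", level)
  targetLabel <- .classLabel(target[1], target[2], armOrder)
  obsLab <- .classLabel(a1, a2, armOrder)
  if (!targetLabel %in% .levelClasses(armOrder, chrom, level))
    stop("target class ", targetLabel, " is excluded at level ", level)
  observed <- sum(obsLab == targetLabel) / n

  i1 <- match(a1, armOrder); i2 <- match(a2, armOrder)
  ch <- match(chrom[armOrder], unique(chrom[armOrder]))
  t1 <- match(target[1], armOrder); t2 <- match(target[2], armOrder)
  oneProp <- function(s2) {
    keep <- switch(level,
      all = rep(TRUE, n),
      no_intra_arm = i1 != s2,
      no_intra_chromosome = ch[i1] != ch[s2])
    hit <- (i1 == t1 & s2 == t2) | (i1 == t2 & s2 == t1)
    denom <- sum(keep)
    if (denom) sum(hit & keep) / denom else 0
  }
  if (exact) {
    if (n > 9) stop("exact enumeration is limited to 9 pairs")
    perms <- .allPermutations(n)
    permProp <- apply(perms, 1, function(ix) oneProp(i2[ix]))
    pval <- mean(permProp >= observed)
    nPerm <- nrow(perms)
  } else {
    permProp <- numeric(nPerm)
    for (k in seq_len(nPerm))
      permProp[k] <- oneProp(i2[sample.int(n)])
    pval <- (1 + sum(permProp >= observed)) / (1 + nPerm)
  }
  res <- list(class = targetLabel, observed = observed, pvalue = pval,
              nPerm = nPerm, nPairs = n, seed = seed, exact = exact)
  if (returnPermutations) res$permuted <- permProp
  res
}

# all permutations of 1..n as a matrix (n! rows), lexicographic
.allPermutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    rows <- (r + 1L):(r + nrow(sub))
    out[rows, 1] <- first
    out[rows, -1] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

# classes attainable at a level for a set of arms
.levelClasses <- function(armOrder, chrom, level) {
  grid <- expand.grid(i = seq_along(armOrder), j = seq_along(armOrder))
  grid <- grid[grid$i <= grid$j, ]
  a1 <- armOrder[grid$i]; a2 <- armOrder[grid$j]
  keep <- switch(level,
    all = rep(TRUE, nrow(grid)),
    no_intra_arm = a1 != a2,
    no_intra_chromosome = chrom[a1] != chrom[a2])
  unique(.classLabel(a1[keep], a2[keep], armOrder))
}

#' Write a contact matrix as annotated TSV
#'
#' Window annotations (arm, chromosome, index, interval) followed by the
#' dense symmetric counts.
#'
#' @param cm a [ContactMatrix-class]
#' @param file path
#' @export
writeContactMatrix <- function(cm, file) {
  w <- contactWindows(cm)
  ann <- data.frame(arm = mcols(w)$arm, chrom = mcols(w)$chrom,
                    window = mcols(w)$window, start = start(w),
                    end = end(w))
  m <- contactCounts(cm)
  colnames(m) <- paste0("w", seq_len(ncol(m)))
  utils::write.table(cbind(ann, m), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
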