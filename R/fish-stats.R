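#' Natural threshold of a bimodal FISH distance distribution
#'
#' Estimates the kernel density (Gaussian kernel, Silverman's
#' rule-of-thumb bandwidth) of per-nucleus focus-centre distances on
#' `[0, max]`. If the density has at least two modes, the natural
#' threshold is the distance at the density minimum between the first
#' two modes — the reproducible surrogate for the visually drawn valley
#' that separates nuclei with overlapping foci (the sharp peak near
#' zero) from the rest. A unimodal density (as for wildtype nuclei
#' lacking the near-zero peak) yields no threshold.
#'
#' Boundary grid points count as modes when the density decreases away
#' from them; modes below `modeMinFrac` of the maximum density are
#' ignored as kernel wiggle, and two neighbouring modes are treated as
#' one unless the valley between them dips below `valleyFrac` of the
#' smaller peak (a prominence requirement that rejects shoulder bumps).
#'
#' @param distances numeric vector of distances (µm), >= `minN` values
#' @param bw bandwidth rule or value for [stats::density()]
#' @param nGrid density grid size
#' @param minN minimum number of nuclei (30)
#' @param modeMinFrac relative height floor for modes
#' @param valleyFrac maximal valley-to-smaller-peak ratio for two modes
#'   to count as separate
#' @return list with `threshold` (µm or `NA`), `modality` ("bimodal" or
#'   "unimodal"), `modes` (mode positions), `bw`, `n`.
#' @export
naturalThreshold <- function(distances, bw = "nrd0", nGrid = 512,
                             minN = 30, modeMinFrac = 0.05,
                             valleyFrac = 0.8) {
  distances <- distances[!is.na(distances)]
  if (any(distances < 0)) stop("distances must be non-negative")
  if (length(distances) < minN)
    stop("need at least ", minN, " observations, got ", length(distances))
  d <- stats::density(distances, bw = bw, kernel = "gaussian",
                      from = 0, to = max(distances), n = nGrid)
  y <- d$y; x <- d$x; m <- length(y)
  isMode <- logical(m)
  isMode[1] <- y[1] > y[2]
  isMode[m] <- y[m] > y[m - 1]
  mid <- 2:(m - 1)
  isMode[mid] <- y[mid] > y[mid - 1] & y[mid] >= y[mid + 1]
  isMode[y < modeMinFrac * max(y)] <- FALSE
  peaks <- which(isMode)
  # merge peaks not separated by a sufficiently deep valley
  i <- 1L
  while (length(peaks) > 1 && i < length(peaks)) {
    lo <- peaks[i]; hi <- peaks[i + 1]
    vy <- min(y[lo:hi])
    if (vy > valleyFrac * min(y[lo], y[hi])) {
      drop <- if (y[lo] >= y[hi]) i + 1L else i
      peaks <- peaks[-drop]
      i <- max(1L, i - 1L)
    } else i <- i + 1L
  }
  modes <- x[peaks]
  if (length(peaks) >= 2) {
    lo <- peaks[1]; hi <- peaks[2]
    valley <- if (hi - lo < 2) lo else lo + which.min(y[(lo + 1):(hi - 1)])
    list(threshold = x[valley], modality = "bimodal", modes = modes,
         bw = d$bw, n = length(distances))
  } else {
    list(threshold = NA_real_, modality = "unimodal", modes = modes,
         bw = d$bw, n = length(distances))
  }
}

#' Fraction of nuclei with overlapping foci
#'
#' Two foci are "overlapping" when their distance is strictly below the
#' threshold.
#'
#' @param distances distances (µm)
#' @param threshold threshold (µm, > 0)
#' @return list with `fraction`, `n_overlap`, `n`.
#' @export
overlapFraction <- function(distances, threshold) {
  stopifnot(length(threshold) == 1, !is.na(threshold), threshold > 0)
  distances <- distances[!is.na(distances)]
  n <- length(distances)
  k <- sum(distances < threshold)
  list(fraction = if (n) k / n else NA_real_, n_overlap = k, n = n)
}

#' Two-group comparison of FISH distances
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on the (optionally
#' nuclear-size-relative) distances, and Fisher's exact test on the
#' overlap / non-overlap counts at a shared threshold. Relative
#' distances divide each absolute distance by the nuclear radius.
#'
#' @param distA,distB distances (µm) of the two groups
#' @param threshold shared overlap threshold (µm); `NA` skips the
#'   Fisher test
#' @param radiusA,radiusB nuclear radii (µm), required when
#'   `relative = TRUE`
#' @param relative compare relative distances
#' @return list with `mw_p`, `fisher_p`, `fisher_odds`, `overlap_a`,
#'   `overlap_b` (each an [overlapFraction()] result), `relative`.
#' @export
compareFociGroups <- function(distA, distB, threshold = NA,
                              radiusA = NULL, radiusB = NULL,
                              relative = FALSE) {
  if (relative) {
    if (is.null(radiusA) || is.null(radiusB))
      stop("relative distances require nuclear radii for both groups")
    if (any(c(radiusA, radiusB) <= 0, na.rm = TRUE))
      stop("radii must be positive")
    xA <- distA / radiusA
    xB <- distB / radiusB
  } else {
    xA <- distA; xB <- distB
  }
  mw <- stats::wilcox.test(xA, xB, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  res <- list(mw_p = mw$p.value, fisher_p = NA_real_,
              fisher_odds = NA_real_, overlap_a = NULL, overlap_b = NULL,
              relative = relative)
  if (!is.na(threshold)) {
    oa <- overlapFraction(distA, threshold)
    ob <- overlapFraction(distB, threshold)
    tab <- matrix(c(oa$n_overlap, oa$n - oa$n_overlap,
                    ob$n_overlap, ob$n - ob$n_overlap),
                  nrow = 2, byrow = TRUE)
    ft <- stats::fisher.test(tab)
    res$fisher_p <- ft$p.value
    res$fisher_odds <- unname(ft$estimate)
    res$overlap_a <- oa
    res$overlap_b <- ob
  }
  res
}

#' Read a FISH distance table
#'
#' TSV with columns `nucleus_id`, `group`, `distance_um` and optional
#' `radius_um`.
#'
#' @param file path
#' @return `data.frame`
#' @export
readFishTable <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("nucleus_id", "group", "distance_um") %in% names(df)))
  df
}

#' Threshold-and-compare wrapper over a FISH table
#'
#' Detects the natural threshold on the pooled distances of the two
#' groups (a shared threshold, as the compared panels use), reports
#' per-group overlap fractions, and runs the two-group tests.
#'
#' @param table FISH `data.frame` ([readFishTable()])
#' @param groups length-2 character: group labels to compare
#' @param relative use nuclear-size-relative distances
#' @param threshold optional fixed threshold overriding detection
#' @return list with `threshold` (a [naturalThreshold()] result or the
#'   fixed value), `comparison` ([compareFociGroups()]).
#' @export
fishCompare <- function(table, groups, relative = FALSE,
                        threshold = NULL) {
  stopifnot(length(groups) == 2,
            all(groups %in% table$group))
  a <- table[table$group == groups[1], ]
  b <- table[table$group == groups[2], ]
  thr <- if (is.null(threshold)) {
    nt <- naturalThreshold(c(a$distance_um, b$distance_um))
    nt
  } else list(threshold = threshold, modality = "fixed")
  cmp <- compareFociGroups(a$distance_um, b$distance_um,
                           threshold = thr$threshold,
                           radiusA = a$radius_um, radiusB = b$radius_um,
                           relative = relative)
  list(threshold = thr, comparison = cmp)
}
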