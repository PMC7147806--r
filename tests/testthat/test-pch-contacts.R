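test_that("contact matrix tallies pairs with the separation filter", {
  annM <- annMulti()
  w <- binPchWindows(annM, 1e5)
  cl <- classifyPairs(mkPairs(
    list("2L", 1.80e6, 60, "2L", 1.95e6, 60),  # same arm, 150 kb apart
    list("2L", 1.80e6, 60, "2L", 1.805e6, 60), # 5 kb apart -> dropped
    list("2L", 1.72e6, 60, "2R", 2.5e5, 60),   # inter-arm, kept always
    list("2R", 1e4, 60, "2R", 1.2e4, 60),      # 2 kb apart -> dropped
    list("3L", 1.75e6, 60, "4", 1e5, 60),
    list("4", 1e4, 60, "4", 2.9e5, 60)), annM, toyCatalog())
  cm <- buildContactMatrix(cl, w, minSeparationBp = 1e4)
  expect_equal(cm@nPairsInput, 6)
  expect_equal(cm@nDroppedClose, 2)
  m <- contactCounts(cm)
  expect_equal(m, t(m))
  # hand tally: retained pairs land in the expected window cells
  widx <- function(arm, k) which(mcols(w)$arm == arm &
                                 mcols(w)$window == k)
  expect_equal(m[widx("2L", 1), widx("2L", 3)], 1)
  expect_equal(m[widx("2L", 1), widx("2R", 3)], 1)
  expect_equal(m[widx("3L", 1), widx("4", 1)], 1)
  expect_equal(m[widx("4", 1), widx("4", 3)], 1)
  expect_equal((sum(m) + sum(diag(m))) / 2, 4)
})

test_that("sequential-exclusion partition reproduces hand arithmetic", {
  # toy tallies {2L:2L 6, 2L-2R 2, 2L-3L 1, 2R-3L 1}
  annT <- loadAnnotation(
    data.frame(arm = c("2L", "2R", "3L"), start = 0, end = 1e5),
    data.frame(arm = c("2L", "2R", "3L"), chrom = c("2", "2", "3"),
               length = c(1e6, 1e6, 1e6)), euOffsetBp = 0)
  w <- binPchWindows(annT, 1e5)
  pos <- function(arm) 5e4
  rows <- c(rep(list(list("2L", 1e4, 60, "2L", 9e4, 60)), 6),
            rep(list(list("2L", 1e4, 60, "2R", 5e4, 60)), 2),
            list(list("2L", 1e4, 60, "3L", 5e4, 60)),
            list(list("2R", 1e4, 60, "3L", 5e4, 60)))
  cl <- classifyPairs(do.call(mkPairs, rows), annT, toyCatalog())
  cm <- buildContactMatrix(cl, w, minSeparationBp = 1e4)
  pAll <- partitionInteractions(cm, "all")
  expect_equal(pAll$proportion[pAll$class == "intra_arm"], 0.6)
  expect_equal(sum(pAll$proportion), 1, tolerance = 1e-12)
  pNoArm <- partitionInteractions(cm, "no_intra_arm")
  getp <- function(p, cls) p$proportion[p$class == cls]
  expect_equal(getp(pNoArm, "2L-2R"), 0.5)
  expect_equal(getp(pNoArm, "2L-3L"), 0.25)
  expect_equal(getp(pNoArm, "2R-3L"), 0.25)
  pNoChr <- partitionInteractions(cm, "no_intra_chromosome")
  expect_equal(getp(pNoChr, "2L-3L"), 0.5)
  expect_equal(getp(pNoChr, "2R-3L"), 0.5)
  # retained counts never increase along the exclusion sequence
  expect_true(attr(pAll, "retained") >= attr(pNoArm, "retained"))
  expect_true(attr(pNoArm, "retained") >= attr(pNoChr, "retained"))
  # degenerate case: everything intra-arm
  clIntra <- classifyPairs(do.call(mkPairs, rows[1:6]), annT,
                           toyCatalog())
  cmIntra <- buildContactMatrix(clIntra, w, minSeparationBp = 1e4)
  pIntra <- partitionInteractions(cmIntra, "all")
  expect_equal(pIntra$proportion[pIntra$class == "intra_arm"], 1)
  expect_error(partitionInteractions(cmIntra, "no_intra_arm"),
               "no interactions")
})

test_that("expected proportions follow the weight-product formula", {
  annT <- loadAnnotation(
    data.frame(arm = c("2L", "2R", "3L"), start = 0, end = 1e5),
    data.frame(arm = c("2L", "2R", "3L"), chrom = c("2", "2", "3"),
               length = c(1e6, 1e6, 1e6)), euOffsetBp = 0)
  w <- c("2L" = 2, "2R" = 1, "3L" = 1)
  e <- expectedProportions(w, annT, "no_intra_chromosome")
  expect_equal(e$expected[e$class == "2L-3L"], 2/3)
  expect_equal(e$expected[e$class == "2R-3L"], 1/3)
  # rescaling invariance
  e2 <- expectedProportions(w * 1000, annT, "no_intra_chromosome")
  expect_equal(e$expected, e2$expected)
  # level=all includes the intra-arm aggregate: masses 4+1+1 : 2*2+2*1+2*2
  eAll <- expectedProportions(w, annT, "all")
  expect_equal(sum(eAll$expected), 1)
  expect_equal(eAll$expected[eAll$class == "intra_arm"], 6 / 16)
  # symmetric four-arm genome is uniform over cross-chromosome pairs
  annF <- loadAnnotation(
    data.frame(arm = c("2L", "2R", "3L", "3R"), start = 0, end = 1e5),
    data.frame(arm = c("2L", "2R", "3L", "3R"),
               chrom = c("2", "2", "3", "3"), length = 1e6),
    euOffsetBp = 0)
  eF <- expectedProportions(c("2L" = 1, "2R" = 1, "3L" = 1, "3R" = 1),
                            annF, "no_intra_chromosome")
  expect_equal(eF$expected, rep(0.25, 4))
})

test_that("permutation test matches the exhaustive enumeration oracle", {
  annT <- loadAnnotation(
    data.frame(arm = c("2L", "2R", "3L"), start = 0, end = 1e5),
    data.frame(arm = c("2L", "2R", "3L"), chrom = c("2", "2", "3"),
               length = c(1e6, 1e6, 1e6)), euOffsetBp = 0)
  chromMap <- c("2L" = "2", "2R" = "2", "3L" = "3")
  mk <- function(a1, a2) {
    rows <- mapply(function(x, y) list(x, 1e4, 60, y, 9e4, 60),
                   a1, a2, SIMPLIFY = FALSE)
    classifyPairs(do.call(mkPairs, rows), annT, toyCatalog())
  }
  # three pairs: all 3! pairings enumerated by the oracle
  a1 <- c("2L", "2R", "2L"); a2 <- c("3L", "3L", "2R")
  cl3 <- mk(a1, a2)
  oracle <- oraclePermDist(a1, a2, chromMap, c("2L", "3L"), "all")
  got <- permutationTest(cl3, annT, c("2L", "3L"), level = "all",
                         exact = TRUE, returnPermutations = TRUE,
                         minSeparationBp = 0)
  expect_equal(sort(got$permuted), sort(oracle))
  expect_equal(got$pvalue, mean(oracle >= got$observed))
  # larger case with level exclusion, still exhaustive (6! = 720)
  a1 <- c("2L", "2R", "2L", "3L", "2R", "2L", "3L")
  a2 <- c("3L", "3L", "2R", "2L", "2L", "3L", "2R")
  keep <- chromMap[a1] != chromMap[a2]  # the level's retained set
  cl6 <- mk(a1[keep], a2[keep])
  oracle6 <- oraclePermDist(a1[keep], a2[keep], chromMap,
                            c("2L", "3L"), "no_intra_chromosome")
  got6 <- permutationTest(cl6, annT, c("2L", "3L"),
                          level = "no_intra_chromosome", exact = TRUE,
                          returnPermutations = TRUE,
                          minSeparationBp = 0)
  expect_equal(sort(round(got6$permuted, 12)),
               sort(round(oracle6, 12)))
  # sampled mode converges to the same distribution
  smp <- permutationTest(cl6, annT, c("2L", "3L"),
                         level = "no_intra_chromosome", nPerm = 4000,
                         seed = 5, returnPermutations = TRUE,
                         minSeparationBp = 0)
  expect_true(all(round(smp$permuted, 12) %in%
                    round(unique(oracle6), 12)))
  qExact <- mean(oracle6 >= smp$observed)
  expect_lt(abs(smp$pvalue - qExact), 0.05)
})

test_that("permutation p-values are valid under an exchangeable null", {
  annT <- loadAnnotation(
    data.frame(arm = c("2L", "2R", "3L"), start = 0, end = 1e5),
    data.frame(arm = c("2L", "2R", "3L"), chrom = c("2", "2", "3"),
               length = c(1e6, 1e6, 1e6)), euOffsetBp = 0)
  set.seed(42)
  nRep <- 150
  pv <- numeric(nRep)
  for (r in seq_len(nRep)) {
    arms <- sample(c("2L", "2R", "3L"), 40, replace = TRUE)
    arms2 <- sample(c("2L", "2R", "3L"), 40, replace = TRUE)
    rows <- mapply(function(x, y) list(x, 1e4, 60, y, 9e4, 60),
                   arms, arms2, SIMPLIFY = FALSE)
    cl <- classifyPairs(do.call(mkPairs, rows), annT, toyCatalog())
    pv[r] <- permutationTest(cl, annT, c("2L", "3L"), level = "all",
                             nPerm = 99, seed = r,
                             minSeparationBp = 0)$pvalue
  }
  # p in (0, 1], never exactly zero, and super-uniformity at 5%/25%
  expect_true(all(pv > 0 & pv <= 1))
  expect_lt(mean(pv <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / nRep))
  expect_lt(mean(pv <= 0.25), 0.25 + 3 * sqrt(0.25 * 0.75 / nRep))
  # one-sided direction: an observed value far below the null mean
  # yields p near 1
  a1 <- c(rep("2L", 10), rep("2R", 10))
  a2 <- c(rep("2R", 10), rep("3L", 10))  # observed 2L-3L count is zero
  rows <- mapply(function(x, y) list(x, 1e4, 60, y, 9e4, 60), a1, a2,
                 SIMPLIFY = FALSE)
  cl <- classifyPairs(do.call(mkPairs, rows), annT, toyCatalog())
  res <- permutationTest(cl, annT, c("2L", "3L"), level = "all",
                         nPerm = 400, seed = 9, minSeparationBp = 0)
  expect_gt(res$pvalue, 0.5)
})
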