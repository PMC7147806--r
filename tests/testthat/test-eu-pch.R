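test_that("query windows get kind-specific padding and PCH rejection", {
  ann <- annSingle()  # 2L euchromatin [1, 8.5e6]
  isl <- GRanges("2L", IRanges(10001, 12000))
  w <- makeQueryWindows(isl, ann, kind = "island")
  expect_equal(start(w), 9001)
  expect_equal(end(w), 13000)
  expect_equal(width(w), 4000)
  # TE insertion point +/- 2 kb
  te <- GRanges("2L", IRanges(50001, 50001))
  wt <- makeQueryWindows(te, ann, kind = "te")
  expect_equal(width(wt), 4001)
  expect_equal(start(wt), 48001)
  # TE interval gets the same rule applied to both edges
  tei <- GRanges("2L", IRanges(50001, 50100))
  wti <- makeQueryWindows(tei, ann, kind = "te")
  expect_equal(start(wti), 48001)
  expect_equal(end(wti), 52100)
  # feature inside PCH is rejected with a report
  bad <- c(isl, GRanges("2L", IRanges(9.5e6, 9.501e6)))
  expect_warning(wb <- makeQueryWindows(bad, ann, kind = "island"),
                 "rejected")
  expect_equal(length(wb), 1L)
  expect_equal(length(attr(wb, "rejected")), 1L)
  # clipping at the arm start
  edge <- GRanges("2L", IRanges(500, 600))
  we <- makeQueryWindows(edge, ann, kind = "island")
  expect_equal(start(we), 1)
})

test_that("EU-PCH fractions follow the hand tally and the pair floor", {
  ann <- annMulti()
  catg <- toyCatalog()
  # 10 informative pairs in one window: other ends 2x unique-PCH on 2L,
  # 1x repeat, 7x euchromatic
  win <- GRanges("2L", IRanges(1e5 + 1, 1.1e5), region_id = "q1")
  rows <- c(
    rep(list(list("2L", 1.05e5, 60, "2L", 1.8e6, 60)), 2),
    rep(list(list("2L", 1.02e5, 60, "2R", 1e6, 60)), 7))
  pr <- do.call(mkPairs, rows)
  repRow <- data.frame(read_id = "rep1", arm1 = "2L", pos1 = 1.03e5,
                       mapq1 = 60, repeat1 = NA_character_, te1 = FALSE,
                       arm2 = NA_character_, pos2 = NA_real_, mapq2 = 0,
                       repeat2 = "AAGAG", te2 = FALSE,
                       stringsAsFactors = FALSE)
  cl <- classifyPairs(rbind(pr, repRow), ann, catg)
  res <- euPchFraction(cl, win, ann, minPairs = 10)
  expect_equal(res$n_pairs, 10)
  expect_equal(res$frac_pch, 0.3)
  expect_equal(res$frac_pch_2L, 0.2)
  expect_false(res$excluded)
  # same data against a floor of 11 -> excluded
  res2 <- euPchFraction(cl, win, ann, minPairs = 11)
  expect_true(res2$excluded)
  # a pair with both unique ends inside the window counts once
  both <- classifyPairs(do.call(mkPairs, c(rows, list(
    list("2L", 1.01e5, 60, "2L", 1.06e5, 60)))), ann, catg)
  resB <- euPchFraction(both, win, ann, minPairs = 1)
  expect_equal(resB$n_pairs, 10)
  expect_equal(resB$frac_pch, 0.2)
})

test_that("null regions are matched, exclusion-free and reproducible", {
  ann <- annMulti()
  excl <- GRanges("2L", IRanges(seq(2e5, 1.3e6, by = 1e5),
                                width = 5e4))
  tmpl <- GRanges(c("2L", "3R"), IRanges(c(1e5, 8e5), width = 4000),
                  region_id = c("a", "b"))
  ens <- sampleNullRegions(ann, excl, tmpl, nSets = 50, seed = 7)
  expect_equal(length(ens), 100L)
  expect_equal(sum(width(ens) == 4000), 100L)
  expect_equal(as.character(seqnames(ens[mcols(ens)$template_id == "a"])),
               rep("2L", 50))
  expect_false(any(overlapsAny(ens, excl)))
  eu <- deriveEuchromatin(ann)
  expect_true(all(overlapsAny(ens, eu, type = "within")))
  # determinism under a fixed seed
  ens2 <- sampleNullRegions(ann, excl, tmpl, nSets = 50, seed = 7)
  expect_identical(start(ens), start(ens2))
  # exclusions leaving one eligible placement force that placement
  ann1 <- loadAnnotation(
    data.frame(arm = "2L", start = 9e5, end = 1e6),
    data.frame(arm = "2L", chrom = "2", length = 1e6), euOffsetBp = 0)
  # euchromatin is [1, 9e5]; exclude all but [1, 1000]
  exclAll <- GRanges("2L", IRanges(1001, 9e5))
  t1 <- GRanges("2L", IRanges(5e5, width = 1000), region_id = "x")
  e1 <- sampleNullRegions(ann1, exclAll, t1, nSets = 20, seed = 3)
  expect_true(all(start(e1) == 1 & end(e1) == 1000))
  # insufficient space errors with the arm named
  t2 <- GRanges("2L", IRanges(5e5, width = 5000), region_id = "y")
  expect_error(sampleNullRegions(ann1, exclAll, t2, nSets = 2, seed = 1),
               "2L")
})

test_that("empirical p-values use the +1 pseudocount over the stratum", {
  qr <- data.frame(region_id = "q", arm = "2L", width = 4000,
                   n_pairs = 2000, frac_pch = 0.35, excluded = FALSE)
  nulls <- data.frame(region_id = paste0("n", 1:5), arm = "2L",
                      width = 4000, n_pairs = 2000,
                      frac_pch = c(0.1, 0.2, 0.3, 0.4, 0.5),
                      excluded = FALSE, size_bin = 1L)
  res <- empiricalPvalues(qr, nulls, queryBins = 1L)
  expect_equal(res$empirical_p, (1 + 2) / (1 + 5))
  # observed above every null in a 200-value pool
  nulls2 <- data.frame(region_id = paste0("n", 1:200), arm = "2L",
                       width = 4000, n_pairs = 2000,
                       frac_pch = runif(200, 0, 0.2),
                       excluded = FALSE, size_bin = 1L)
  res2 <- empiricalPvalues(qr, nulls2, queryBins = 1L)
  expect_equal(res2$empirical_p, 1 / 201)
  expect_true(res2$significant)
  # monotone non-increasing in the observed fraction
  obs <- seq(0, 0.5, by = 0.05)
  ps <- vapply(obs, function(o) {
    q <- qr; q$frac_pch <- o
    empiricalPvalues(q, nulls2, queryBins = 1L)$empirical_p
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  # excluded nulls drop out of the pool; empty stratum -> NA
  nulls3 <- nulls; nulls3$excluded <- TRUE
  res3 <- empiricalPvalues(qr, nulls3, queryBins = 1L)
  expect_true(is.na(res3$empirical_p))
  expect_false(res3$significant)
})

test_that("exact binomial enrichment agrees with full enumeration", {
  # every n <= 25 against the point-probability oracle
  set.seed(1)
  for (n in 1:25) {
    for (k in unique(c(0, sample(0:n, min(n + 1, 5))))) {
      for (p0 in c(0.05, 0.2, 0.5)) {
        expect_equal(enrichmentBinomial(k, n, p0),
                     oracleBinom(k, n, p0), tolerance = 1e-9,
                     label = sprintf("k=%d n=%d p0=%g", k, n, p0))
      }
    }
  }
  expect_equal(enrichmentBinomial(1, 1, 0.5), 1.0)
  expect_equal(enrichmentBinomial(3, 10, 0.2), 0.4296, tolerance = 1e-3)
  expect_error(enrichmentBinomial(5, 4, 0.05), "k must")
  expect_error(enrichmentBinomial(1, 4, 1.2), "p0")
})
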