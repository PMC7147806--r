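test_that("toy genome artifacts are deterministic and well-placed", {
  cfg <- syntheticConfig(seed = 5)
  g1 <- makeToyGenome(cfg)
  g2 <- makeToyGenome(cfg)
  expect_identical(start(g1$islands), start(g2$islands))
  expect_identical(start(g1$tes), start(g2$tes))
  expect_identical(as.data.frame(g1$mappability),
                   as.data.frame(g2$mappability))
  # PCH windows: 4 arms x 5 plus 4 on the heterochromatic 4th
  w <- binPchWindows(g1$annotation, cfg$windowBp)
  expect_equal(length(w), 24L)
  # islands and TEs live strictly inside derived euchromatin
  eu <- deriveEuchromatin(g1$annotation)
  expect_true(all(overlapsAny(g1$islands, eu, type = "within")))
  expect_true(all(overlapsAny(g1$tes, eu, type = "within")))
  # a feature closer than 0.5 Mb to the PCH boundary is rejected
  cfgBad <- syntheticConfig(seed = 5,
    islandPositions = GRanges("2L", IRanges(1.5e6, 1.502e6)))
  expect_error(makeToyGenome(cfgBad), "euchromatin")
  # mappability is binary and complete
  expect_true(all(g1$mappability$score %in% c(0, 1)))
  expect_equal(sum(width(g1$mappability)),
               sum(armTable(g1$annotation)$length))
})

test_that("simulated pairs are seed-deterministic with the decay slope", {
  cfg <- syntheticConfig(seed = 6)
  g <- makeToyGenome(cfg)
  p1 <- simulateHicPairs(g, cfg, 2000, seed = 60)
  p2 <- simulateHicPairs(g, cfg, 2000, seed = 60)
  expect_identical(p1, p2)
  # log-log regression of same-arm contact counts vs distance
  # recovers the decay exponent alpha = 1 within 0.1
  pr <- simulateHicPairs(g, cfg, 1e5, seed = 61)
  sameArm <- !is.na(pr$arm1) & !is.na(pr$arm2) & pr$arm1 == pr$arm2
  s <- abs(pr$pos1 - pr$pos2)[sameArm]
  s <- s[s >= 2000 & s <= 5e5]
  h <- hist(log10(s), breaks = 30, plot = FALSE)
  keep <- h$counts > 0
  bw <- diff(10^h$breaks)
  fit <- lm(log10(h$counts[keep] / bw[keep]) ~ h$mids[keep])
  expect_lt(abs(unname(coef(fit)[2]) + 1), 0.1)
})

test_that("uniform reads over mappable PCH tie the two expectations", {
  cfg <- syntheticConfig(seed = 8)
  g <- makeToyGenome(cfg)
  ann <- g$annotation
  set.seed(80)
  pchMap <- GenomicRanges::intersect(
    g$mappability[g$mappability$score == 1], pchRegions(ann))
  n <- 1e5
  iv <- sample.int(length(pchMap), n, replace = TRUE,
                   prob = width(pchMap))
  pos <- start(pchMap)[iv] + floor(runif(n) * width(pchMap)[iv])
  cl <- data.frame(arm1 = as.character(seqnames(pchMap))[iv],
                   pos1 = pos, cat1 = "UNIQUE_PCH",
                   arm2 = NA, pos2 = NA, cat2 = "OTHER")
  emp <- armMarginals(cl, ann, mode = "empirical")
  theo <- armMarginals(g$mappability, ann, mode = "mappability")
  expect_lt(max(abs(emp / sum(emp) - theo / sum(theo))), 0.01)
})

test_that("MAPQ emission exercises every end category", {
  cfg <- syntheticConfig(seed = 9)
  g <- makeToyGenome(cfg)
  pr <- simulateHicPairs(g, cfg, 20000, seed = 90)
  cl <- classifyPairs(pr, g$annotation, g$catalog)
  cats <- table(factor(c(as.character(cl$cat1), as.character(cl$cat2)),
                       levels = endCategories()))
  expect_true(all(cats > 0))
  # repeat-derived ends carry no genomic position
  expect_true(all(is.na(cl$pos1[cl$cat1 == "REPEAT_PCH"])))
})

test_that("ChIP, FISH and frequency simulators honor their models", {
  cfg <- syntheticConfig(seed = 10, nIslands = 4, nTes = 4,
                         featureGapBp = 45000, chipNoiseSd = 0)
  g <- makeToyGenome(cfg)
  ch <- simulateChipProfiles(g, cfg, seed = 100)
  # all tracks share one exact library size
  for (s in names(ch$strains)) {
    expect_equal(trackTotal(ch$strains[[s]]$chip), cfg$chipTargetTotal)
    expect_equal(trackTotal(ch$strains[[s]]$input), cfg$chipTargetTotal)
  }
  # fold 1 means no spread anywhere
  cfg1 <- syntheticConfig(seed = 10, nIslands = 4, nTes = 4,
                          featureGapBp = 45000, chipNoiseSd = 0,
                          chipSpreadFold = 1)
  g1 <- makeToyGenome(cfg1)
  ch1 <- simulateChipProfiles(g1, cfg1, seed = 100)
  mask <- granges(g1$islands)
  f <- enrichmentProfile(ch1$strains$focal$chip, ch1$strains$focal$input,
                         g1$tes[1], g1$annotation, mask = mask)
  wts <- lapply(c("wt1", "wt2"), function(s)
    enrichmentProfile(ch1$strains[[s]]$chip, ch1$strains[[s]]$input,
                      g1$tes[1], g1$annotation, mask = mask))
  expect_false(spreadExtent(f, wts)$spreading)
  # identical tracks under the same seed
  ch2 <- simulateChipProfiles(g, cfg, seed = 100)
  expect_equal(as.data.frame(ch$strains$focal$chip),
               as.data.frame(ch2$strains$focal$chip))
  # FISH mixture: pi = 0 is unimodal; tables are seed-deterministic
  f0 <- simulateFishDistances(cfg, 400, seed = 101, mixturePi = 0)
  expect_equal(naturalThreshold(f0$distance_um)$modality, "unimodal")
  fa <- simulateFishDistances(cfg, 400, seed = 102)
  fb <- simulateFishDistances(cfg, 400, seed = 102)
  expect_identical(fa, fb)
  expect_true(all(fa$distance_um >= 0) && all(fa$radius_um > 0))
  # frequency table: both groups in [0, 1] with the configured sizes
  fr <- simulateTeFrequencies(cfg, seed = 103)
  expect_equal(table(fr$group)[["with_pch"]], cfg$nTeWith)
  expect_equal(table(fr$group)[["without_pch"]], cfg$nTeWithout)
  expect_true(all(fr$frequency >= 0 & fr$frequency <= 1))
})

test_that("synthetic bundles round-trip through standard formats", {
  cfg <- syntheticConfig(seed = 12, nIslands = 4, nTes = 3)
  g <- makeToyGenome(cfg)
  pr <- simulateHicPairs(g, cfg, 3000, seed = 120)
  fish <- simulateFishDistances(cfg, 100, seed = 121)
  freqs <- simulateTeFrequencies(cfg, seed = 122)
  dir <- tempfile("bundle")
  writeSyntheticData(g, dir, pairs = pr, fish = fish, freqs = freqs)
  # boundaries BED -> annotation identical to the source
  bgr <- readBoundaries(file.path(dir, "boundaries.bed"))
  arms <- readArmTable(file.path(dir, "arms.tsv"))
  ann2 <- loadAnnotation(bgr, arms, hetChromosomes = "4",
                         euOffsetBp = cfg$euOffsetBp)
  expect_equal(as.data.frame(granges(pchRegions(ann2))),
               as.data.frame(granges(pchRegions(g$annotation))))
  # mappability bedGraph round-trips with identical mappable mass
  map2 <- readMappability(file.path(dir, "mappability.bg"))
  expect_equal(sum(width(map2[map2$score == 1])),
               sum(width(g$mappability[g$mappability$score == 1])))
  # pairs and tables load back with the same dimensions
  pr2 <- readPairs(file.path(dir, "pairs.tsv"))
  expect_equal(nrow(pr2), nrow(pr))
  expect_equal(readFishTable(file.path(dir, "fish.tsv"))$distance_um,
               fish$distance_um, tolerance = 1e-6)
  fr2 <- readFrequencyTable(file.path(dir, "te_frequencies.tsv"))
  expect_equal(fr2$frequency, freqs$frequency, tolerance = 1e-9)
})
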