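#' Run the full PCH contact analysis pipeline
#'
#' Executes classification, the PCH-PCH contact analysis (matrix,
#' sequential-exclusion partitions, expectations, permutation test on a
#' target arm pair) and, when query features are present, the
#' euchromatin-PCH analysis with the matched-resampling null. Writes
#' TSV reports (with a `#` comment header carrying the seed) when
#' `outDir` is given, and keeps a conservation audit: at every filter
#' the input and surviving counts are logged, and end-category and
#' pair-class counts must reconcile with the number of input pairs.
#'
#' @param pairs raw or classified pairs `data.frame`
#' @param genome a [makeToyGenome()]-style list (`annotation`,
#'   `catalog`, `mappability`, optional `islands`)
#' @param outDir optional output directory
#' @param windowBp PCH window width
#' @param minSeparationBp same-arm separation filter
#' @param nPerm permutations for the target arm pair (0 skips the test)
#' @param permTarget target arm pair for the permutation test
#' @param permLevel exclusion level of the permutation test
#' @param nSets null sets for the euchromatin-PCH stage
#' @param minPairs informative-pair floor
#' @param seed seed for the stochastic stages
#' @return list with `classified`, `summary`, `matrix`, `partitions`,
#'   `expected`, `permutation`, `euResults`, `audit`.
#' @export
runPipeline <- function(pairs, genome, outDir = NULL,
                        windowBp = 100000, minSeparationBp = 10000,
                        nPerm = 1000, permTarget = c("3L", "4"),
                        permLevel = "no_intra_chromosome",
                        nSets = 200, minPairs = 1000, seed = 1) {
  ann <- genome$annotation
  audit <- list()
  note <- function(stage, input, surviving) {
    audit[[length(audit) + 1]] <<- data.frame(
      stage = stage, input = input, surviving = surviving)
  }

  if (!"pair_class" %in% names(pairs)) {
    pairs <- classifyPairs(pairs, ann, genome$catalog)
  }
  n <- nrow(pairs)
  summ <- categorySummary(pairs)
  stopifnot(sum(summ$ends$count) == 2 * n,
            sum(summ$pairs$count) == n)
  note("classify_pairs", n, n)

  windows <- binPchWindows(ann, windowBp)
  nPch <- sum(pairs$pair_class == "PCH_PCH_UNIQUE")
  note("select_pch_pch_unique", n, nPch)
  cm <- buildContactMatrix(pairs, windows, minSeparationBp)
  retained <- .pairMass(contactCounts(cm))
  stopifnot(retained + cm@nDroppedClose + cm@nDroppedOutside == nPch)
  note("separation_filter", nPch, nPch - cm@nDroppedClose)
  note("window_assignment", nPch - cm@nDroppedClose, retained)

  partitions <- list()
  for (lv in c("all", "no_intra_arm", "no_intra_chromosome")) {
    p <- tryCatch(partitionInteractions(cm, lv), error = function(e) NULL)
    partitions[[lv]] <- p
    if (!is.null(p)) note(paste0("partition_", lv), retained,
                          attr(p, "retained"))
  }
  weights <- armMarginals(genome$mappability, ann, mode = "mappability")
  expected <- lapply(
    stats::setNames(nm = names(partitions)[!vapply(partitions, is.null,
                                                   logical(1))]),
    function(lv) expectedProportions(weights, ann, lv))

  permutation <- NULL
  if (nPerm > 0 && !is.null(partitions[[permLevel]]) &&
      .classLabel(permTarget[1], permTarget[2], armTable(ann)$arm) %in%
        partitions[[permLevel]]$class) {
    permutation <- permutationTest(pairs, ann, permTarget,
                                   level = permLevel, nPerm = nPerm,
                                   seed = seed,
                                   minSeparationBp = minSeparationBp)
  }

  euResults <- NULL
  if (!is.null(genome$islands) && length(genome$islands)) {
    queries <- suppressWarnings(
      makeQueryWindows(genome$islands, ann, kind = "island"))
    qr <- euPchFraction(pairs, queries, ann, minPairs = minPairs)
    note("eu_pch_informative", length(queries),
         sum(!qr$excluded))
    nulls <- sampleNullRegions(ann, genome$islands, queries,
                               nSets = nSets, seed = seed + 1)
    nr <- euPchFraction(pairs, nulls, ann, minPairs = minPairs)
    nr$size_bin <- mcols(nulls)$size_bin
    euResults <- empiricalPvalues(qr, nr)
  }

  audit <- do.call(rbind, audit)
  res <- list(classified = pairs, summary = summ, matrix = cm,
              partitions = partitions, expected = expected,
              permutation = permutation, euResults = euResults,
              audit = audit, seed = seed)
  if (!is.null(outDir)) .writeReports(res, outDir, seed)
  res
}

.writeReports <- function(res, outDir, seed) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(paste("seed:", seed),
           paste("generated:", format(Sys.time(), "%Y-%m-%d")))
  wr <- function(df, name) {
    con <- file(file.path(outDir, name), "w")
    on.exit(close(con))
    writeLines(paste0("# ", hdr), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(res$summary$ends, "end_categories.tsv")
  wr(res$summary$pairs, "pair_classes.tsv")
  writeContactMatrix(res$matrix, file.path(outDir, "contact_matrix.tsv"))
  for (lv in names(res$partitions))
    if (!is.null(res$partitions[[lv]]))
      wr(res$partitions[[lv]], paste0("partition_", lv, ".tsv"))
  for (lv in names(res$expected))
    wr(res$expected[[lv]], paste0("expected_", lv, ".tsv"))
  if (!is.null(res$permutation))
    wr(data.frame(res$permutation[c("class", "observed", "pvalue",
                                    "nPerm", "nPairs")]),
       "permutation.tsv")
  if (!is.null(res$euResults)) wr(res$euResults, "eu_pch.tsv")
  wr(res$audit, "audit.tsv")
  invisible(outDir)
}

#' Check the conservation audit of a pipeline run
#'
#' Asserts that counts reconcile across the logged filters: surviving
#' counts never exceed inputs, and each stage's input matches the
#' previous stage's survivors where the stages chain.
#'
#' @param audit the `audit` data.frame of [runPipeline()]
#' @return `TRUE` (invisibly) or an error
#' @export
checkAudit <- function(audit) {
  stopifnot(all(audit$surviving <= audit$input))
  chain <- c("select_pch_pch_unique", "separation_filter",
             "window_assignment")
  for (i in seq_len(length(chain) - 1)) {
    a <- audit[audit$stage == chain[i], ]
    b <- audit[audit$stage == chain[i + 1], ]
    if (nrow(a) && nrow(b) && a$surviving != b$input)
      stop("audit mismatch between ", chain[i], " and ", chain[i + 1])
  }
  invisible(TRUE)
}
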