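# in-code fixtures shared across the suite

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# single 10-Mb arm with terminal PCH plus a fully heterochromatic 4th
annSingle <- function(euOffsetBp = 5e5) {
  arms <- data.frame(arm = c("2L", "4"), chrom = c("2", "4"),
                     length = c(10e6, 1.3e6))
  bed <- data.frame(arm = "2L", start = 9e6, end = 10e6)
  loadAnnotation(bed, arms, hetChromosomes = "4",
                 euOffsetBp = euOffsetBp)
}

# four arms on two chromosomes plus heterochromatic 4; PCH at the
# centromeric end of every major arm
annMulti <- function(euOffsetBp = 2e5) {
  arms <- data.frame(arm = c("2L", "2R", "3L", "3R", "4"),
                     chrom = c("2", "2", "3", "3", "4"),
                     length = c(2e6, 2e6, 2e6, 2e6, 3e5))
  bed <- data.frame(arm = c("2L", "2R", "3L", "3R"),
                    start = c(1.7e6, 0, 1.7e6, 0),
                    end = c(2e6, 3e5, 2e6, 3e5))
  loadAnnotation(bed, arms, hetChromosomes = "4",
                 euOffsetBp = euOffsetBp)
}

toyCatalog <- function() RepeatCatalog(c("AAGAG", "dodeca", "Rsp"))

# uniform mappability-1 track over an annotation's genome
uniformMap <- function(ann) {
  a <- armTable(ann)
  gr <- GRanges(a$arm, IRanges(1, a$length))
  gr$score <- 1
  gr
}

# build a raw pairs data.frame from compact end descriptions
mkPairs <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(arm1 = r[[1]], pos1 = as.numeric(r[[2]]),
               mapq1 = as.numeric(r[[3]]),
               arm2 = r[[4]], pos2 = as.numeric(r[[5]]),
               mapq2 = as.numeric(r[[6]]),
               stringsAsFactors = FALSE)
  }))
  df$read_id <- sprintf("r%03d", seq_len(nrow(df)))
  df$repeat1 <- NA_character_; df$repeat2 <- NA_character_
  df$te1 <- FALSE; df$te2 <- FALSE
  df[c("read_id", "arm1", "pos1", "mapq1", "repeat1", "te1",
       "arm2", "pos2", "mapq2", "repeat2", "te2")]
}
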