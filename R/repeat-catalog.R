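#' Construct a repeat catalog
#'
#' @param repeatNames unique character vector of heterochromatic repeat
#'   names
#' @param sequences optional `DNAStringSet` of the repeat sequences
#' @return a [RepeatCatalog-class]
#' @examples
#' cat <- RepeatCatalog(c("AAGAG", "dodeca", "rsp"))
#' isRepeat(cat, c("AAGAG", "roo"))
#' @export
RepeatCatalog <- function(repeatNames, sequences = NULL) {
  methods::new("RepeatCatalog", repeatNames = as.character(repeatNames),
               sequences = sequences)
}

#' Read a repeat catalog from FASTA (and optional name list)
#'
#' @param fasta FASTA file of heterochromatic repeat sequences
#' @param names optional file with one repeat name per line restricting
#'   the catalog
#' @return a [RepeatCatalog-class]
#' @export
readRepeatCatalog <- function(fasta, names = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  nm <- sub("\\s.*$", "", names(seqs))
  names(seqs) <- nm
  if (!is.null(names)) {
    keep <- readLines(names)
    keep <- keep[nzchar(keep)]
    seqs <- seqs[nm %in% keep]
    nm <- names(seqs)
  }
  RepeatCatalog(nm, seqs)
}

#' @rdname RepeatCatalog-class
#' @export
setMethod("isRepeat", "RepeatCatalog", function(object, names) {
  !is.na(names) & names %in% object@repeatNames
})

#' @rdname RepeatCatalog-class
#' @param x a `RepeatCatalog`
#' @export
setMethod("length", "RepeatCatalog", function(x) length(x@repeatNames))

setMethod("show", "RepeatCatalog", function(object) {
  cat("RepeatCatalog with", length(object@repeatNames), "repeat(s)",
      if (is.null(object@sequences)) "(names only)\n" else "(with sequences)\n")
})
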