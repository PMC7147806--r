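#' @rdname GenomeAnnotation-class
#' @param object,x a `GenomeAnnotation`
#' @export
setGeneric("armTable", function(object) standardGeneric("armTable"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("pchRegions", function(object) standardGeneric("pchRegions"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("hetChromosomes",
  function(object) standardGeneric("hetChromosomes"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("euOffset", function(object) standardGeneric("euOffset"))

#' @rdname RepeatCatalog-class
#' @param object a `RepeatCatalog`
#' @param names character vector of alignment target names
#' @export
setGeneric("isRepeat", function(object, names) standardGeneric("isRepeat"))

#' @rdname ContactMatrix-class
#' @param object a `ContactMatrix`
#' @export
setGeneric("contactCounts", function(object) standardGeneric("contactCounts"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("contactWindows",
  function(object) standardGeneric("contactWindows"))

#' @rdname EnrichmentProfile-class
#' @param object an `EnrichmentProfile`
#' @export
setGeneric("profileBins", function(object) standardGeneric("profileBins"))
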