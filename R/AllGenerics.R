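#' @rdname GenomeAnnotation-class
#' @param x a package object
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("introns", function(x) standardGeneric("introns"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("windowWidth", function(x) standardGeneric("windowWidth"))

#' @rdname VariantSet-class
#' @param x a package object
#' @export
setGeneric("variantRecords", function(x) standardGeneric("variantRecords"))

#' @rdname VariantSet-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname UniqueVariantSet-class
#' @param x a package object
#' @export
setGeneric("uniqueVariants", function(x) standardGeneric("uniqueVariants"))

#' @rdname UniqueVariantSet-class
#' @export
setGeneric("passPolicy", function(x) standardGeneric("passPolicy"))

#' @rdname PositionProfile-class
#' @param x a package object
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' @rdname PositionProfile-class
#' @export
setGeneric("profileTotals", function(x) standardGeneric("profileTotals"))
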