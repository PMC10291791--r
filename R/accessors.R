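#' @describeIn GenomeAnnotation-class exon intervals as a `GRanges`
#' @export
setMethod("exons", "GenomeAnnotation", function(x) x@exons)

#' @describeIn GenomeAnnotation-class derived intron intervals as a `GRanges`
#' @export
setMethod("introns", "GenomeAnnotation", function(x) x@introns)

#' @describeIn GenomeAnnotation-class flanking window half-width W (bp)
#' @export
setMethod("windowWidth", "GenomeAnnotation", function(x) x@windowWidth)

#' @describeIn PositionProfile-class the flanking window half-width used
#' @export
setMethod("windowWidth", "PositionProfile", function(x) x@windowWidth)

#' @describeIn VariantSet-class per-observation records as a data.frame
#' @export
setMethod("variantRecords", "VariantSet", function(x) x@records)

#' @describeIn VariantSet-class sample identifiers present in the set
#' @export
setMethod("sampleIds", "VariantSet", function(x) x@samples)

#' @describeIn UniqueVariantSet-class deduplicated variants as a data.frame
#' @export
setMethod("uniqueVariants", "UniqueVariantSet", function(x) x@variants)

#' @describeIn UniqueVariantSet-class the pass-aggregation policy used
#' @export
setMethod("passPolicy", "UniqueVariantSet", function(x) x@policy)

#' @describeIn PositionProfile-class the per-bucket profile table
#' @export
setMethod("profileTable", "PositionProfile", function(x) x@table)

#' @describeIn PositionProfile-class partition totals (counts and gene counts)
#' @export
setMethod("profileTotals", "PositionProfile", function(x) x@totals)

setMethod("show", "GenomeAnnotation", function(object) {
  ntx <- length(unique(mcols(object@exons)$transcript_id))
  cat("GenomeAnnotation:", ntx, "transcripts,",
      length(object@exons), "exons,", length(object@introns), "introns;",
      "W =", object@windowWidth, "bp\n")
})

setMethod("show", "VariantSet", function(object) {
  cat("VariantSet:", nrow(object@records), "records from",
      length(object@samples), "sample(s)\n")
  if (nrow(object@records)) {
    tab <- table(object@records$vclass)
    cat("  ", paste(names(tab), as.integer(tab), collapse = ", "), "\n")
  }
})

setMethod("show", "UniqueVariantSet", function(object) {
  df <- object@variants
  cat("UniqueVariantSet:", nrow(df), "unique variants (policy:",
      object@policy, ")\n")
  if (nrow(df))
    cat("  pass:", sum(df$any_pass), " false:", sum(!df$any_pass), "\n")
})

setMethod("show", "PositionProfile", function(object) {
  tb <- object@table
  cat("PositionProfile over d = 1..", object@windowWidth, "\n", sep = "")
  if (nrow(tb) && any(tb$raw_count > 0)) {
    cat("  flanking raw:", sum(tb$raw_count),
        " pass:", sum(tb$pass_count),
        " deleterious:", sum(tb$deleterious_count), "\n")
    cat("  argmax(pass) = ", tb$d[which.max(tb$pass_count)],
        ", argmin(pass, d<=150) = ",
        tb$d[which.min(tb$pass_count[tb$d <= 150])], "\n", sep = "")
  }
})
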