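#' @import methods
#' @importFrom GenomicRanges GRanges mcols findOverlaps seqnames start end strand width
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors queryHits subjectHits DataFrame metadata
NULL

.VARIANT_COLUMNS <- c(
  "sample_id", "chrom", "pos", "ref", "alt", "vclass",
  "QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "DP", "DV",
  "af_popmax", "clinsig", "cadd", "dpsi_zscore", "dbscsnv"
)

#' Gene annotation with derived introns and flanking-window width
#'
#' Holds transcript exon structures as a `GRanges`, the intron intervals
#' derived from them, and the half-width W of the exon-flanking intronic
#' window (default 200 bp) used for splice-site offset assignment. All
#' coordinates are 1-based inclusive; chromosome names are stored without a
#' `chr` prefix.
#'
#' @slot exons `GRanges` with metadata columns `transcript_id`, `gene_id`,
#'   `exon_rank` (1-based in transcript orientation).
#' @slot introns `GRanges` with metadata columns `transcript_id`, `gene_id`,
#'   `intron_rank`.
#' @slot windowWidth integer(1), flanking window half-width W in bp.
#'
#' @seealso [loadAnnotation()], [classifyPosition()]
#' @export
setClass("GenomeAnnotation",
  slots = c(exons = "GRanges", introns = "GRanges", windowWidth = "integer")
)

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  if (length(object@windowWidth) != 1L || is.na(object@windowWidth) ||
      object@windowWidth < 1L)
    msg <- c(msg, "windowWidth must be a single integer >= 1")
  need <- c("transcript_id", "gene_id", "exon_rank")
  if (!all(need %in% colnames(mcols(object@exons))))
    msg <- c(msg, "exons must carry transcript_id, gene_id, exon_rank")
  needi <- c("transcript_id", "gene_id", "intron_rank")
  if (length(object@introns) &&
      !all(needi %in% colnames(mcols(object@introns))))
    msg <- c(msg, "introns must carry transcript_id, gene_id, intron_rank")
  if (length(object@exons) &&
      any(mcols(object@exons)$exon_rank < 1L, na.rm = TRUE))
    msg <- c(msg, "exon_rank must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Per-sample variant records with QC metrics and annotation scores
#'
#' One row per called variant observation in one sample, after multi-allelic
#' splitting. QC metrics (QD, FS, MQ, MQRankSum, ReadPosRankSum, DP, DV) and
#' annotation scores (af_popmax, clinsig, cadd, dpsi_zscore, dbscsnv) may be
#' missing (`NA`); missing is never silently coerced to zero.
#'
#' @slot records data.frame with the fixed column set given by
#'   `IntronProfiler:::.VARIANT_COLUMNS`.
#' @slot samples character vector of the sample identifiers contributing
#'   records.
#'
#' @seealso [readVariants()], [dedupUnique()]
#' @export
setClass("VariantSet",
  slots = c(records = "data.frame", samples = "character")
)

setValidity("VariantSet", function(object) {
  df <- object@records
  msg <- character()
  missing_cols <- setdiff(.VARIANT_COLUMNS, names(df))
  if (length(missing_cols))
    return(paste("records lacks columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(df)) {
    if (any(df$pos < 1L, na.rm = TRUE)) msg <- c(msg, "pos must be >= 1")
    if (any(df$ref == df$alt, na.rm = TRUE)) msg <- c(msg, "ref must differ from alt")
    snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L
    if (any(df$vclass != ifelse(snv, "SNV", "INDEL")))
      msg <- c(msg, "vclass must be SNV iff ref and alt are single bases")
    if (any(df$DP < 0, na.rm = TRUE) || any(df$DV < 0, na.rm = TRUE))
      msg <- c(msg, "DP and DV must be nonnegative")
    both <- !is.na(df$DP) & !is.na(df$DV)
    if (any(df$DV[both] > df$DP[both]))
      msg <- c(msg, "DV must not exceed DP")
  }
  if (length(msg)) msg else TRUE
})

#' Cross-sample deduplicated variants
#'
#' One row per distinct (chrom, pos, ref, alt) key: a variant observed in
#' several samples is counted once. Carries the aggregated pass status under
#' the configured policy, the mean read depth over observations, and the
#' best (most extreme) annotation scores over observations.
#'
#' @slot variants data.frame with one row per unique variant.
#' @slot policy character(1), the pass-aggregation policy used
#'   (`any_pass`, `majority` or `all_pass`).
#'
#' @seealso [dedupUnique()], [deleteriousFilter()]
#' @export
setClass("UniqueVariantSet",
  slots = c(variants = "data.frame", policy = "character")
)

setValidity("UniqueVariantSet", function(object) {
  df <- object@variants
  need <- c("chrom", "pos", "ref", "alt", "vclass", "n_samples", "n_obs",
            "any_pass", "mean_dp", "af_popmax", "clinsig", "cadd",
            "dpsi_zscore", "dbscsnv")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    return(paste("variants lacks columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(df) && any(df$n_samples < 1L))
    return("n_samples must be >= 1")
  if (nrow(df) && anyDuplicated(df[c("chrom", "pos", "ref", "alt")]))
    return("variant keys must be unique")
  TRUE
})

#' Per-position profile of flanking intronic variants
#'
#' The per-bucket table has one row for each offset d in 1..W with raw,
#' pass, false and deleterious unique-variant counts, the false proportion
#' FP = false/raw (NA where raw is 0), and the mean read depth. The totals
#' list records raw/pass/deleterious counts and distinct-gene counts for
#' the exonic / intronic / flanking / deep-intronic partitions.
#'
#' @slot table data.frame with columns `d`, `raw_count`, `pass_count`,
#'   `false_count`, `fp`, `mean_depth`, `deleterious_count`.
#' @slot totals named list of partition totals.
#' @slot windowWidth integer(1), W.
#'
#' @seealso [buildProfile()], [writeProfileTables()]
#' @export
setClass("PositionProfile",
  slots = c(table = "data.frame", totals = "list", windowWidth = "integer")
)

setValidity("PositionProfile", function(object) {
  tb <- object@table
  need <- c("d", "raw_count", "pass_count", "false_count", "fp",
            "mean_depth", "deleterious_count")
  missing_cols <- setdiff(need, names(tb))
  if (length(missing_cols))
    return(paste("table lacks columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(tb)) {
    if (any(tb$raw_count != tb$pass_count + tb$false_count))
      return("raw_count must equal pass_count + false_count")
    if (any(tb$deleterious_count > tb$pass_count))
      return("deleterious_count must not exceed pass_count")
    ok <- tb$raw_count > 0
    if (any(abs(tb$fp[ok] - tb$false_count[ok] / tb$raw_count[ok]) > 1e-12))
      return("fp must equal false_count / raw_count where raw_count > 0")
    if (any(!is.na(tb$fp[!ok])))
      return("fp must be NA where raw_count is 0")
  }
  TRUE
})

#' Configuration of the synthetic exome-cohort generator
#'
#' Encodes the designed per-position structure the generator emulates: a
#' variant intensity lambda(d) with its minimum at d = 2 and peak at d = 9,
#' sequencing depth decaying with distance from the exon (half-life
#' parameterisation, midpoint near d = 50), an S-shaped QC-failure
#' probability logistic in depth, and a deleterious-annotation enrichment
#' spike at d = 5. See the package vignette for the rationale behind each
#' default.
#'
#' @seealso [syntheticConfig()], [generateAnnotation()], [generateCohort()],
#'   [truthTable()]
#' @export
setClass("SyntheticConfig",
  slots = c(
    seed = "integer",
    nSamples = "integer",
    nGenes = "integer",
    exonsPerGene = "integer",      # length-2 range
    exonLengthRange = "integer",   # length-2 range
    intronLengthRange = "integer", # length-2 range
    windowWidth = "integer",
    lambda1 = "numeric",
    lambda2 = "numeric",
    lambdaPrePeak = "numeric",
    peakPos = "integer",
    lambdaPeak = "numeric",
    lambdaPostPeak = "numeric",
    farPos = "integer",
    lambdaFar = "numeric",
    lambdaEnd = "numeric",
    depthPlateau = "numeric",
    depthFloor = "numeric",
    depthHalfLife = "numeric",
    qcFailBase = "numeric",
    qcFailMidpoint = "numeric",
    qcFailSlope = "numeric",
    carrierProb = "numeric",
    delBase = "numeric",
    delSpikePos = "integer",
    delSpikeProb = "numeric",
    exonicLambda = "numeric",
    exonicDepth = "numeric",
    deepLambda = "numeric",
    indelFraction = "numeric"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  rng2 <- function(x, what) {
    if (length(x) != 2L || any(is.na(x)) || x[1] > x[2])
      paste(what, "must be an ordered length-2 range") else character()
  }
  msg <- c(msg,
           rng2(object@exonsPerGene, "exonsPerGene"),
           rng2(object@exonLengthRange, "exonLengthRange"),
           rng2(object@intronLengthRange, "intronLengthRange"))
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@windowWidth < 1L) msg <- c(msg, "windowWidth must be >= 1")
  if (length(object@intronLengthRange) == 2L &&
      !is.na(object@intronLengthRange[1]) && object@intronLengthRange[1] < 3L)
    msg <- c(msg, "intron length below 3 is not allowed")
  if (!(object@lambda2 < object@lambda1 && object@lambda1 < object@lambdaPeak))
    msg <- c(msg, "need lambda2 < lambda1 < lambdaPeak")
  probs <- c(object@qcFailBase, object@carrierProb, object@delBase,
             object@delSpikeProb, object@indelFraction)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "probability parameters must lie in [0, 1]")
  if (object@depthFloor >= object@depthPlateau || object@depthHalfLife <= 0)
    msg <- c(msg, "depth model must be monotone non-increasing (plateau > floor, half-life > 0)")
  if (object@exonsPerGene[1] < 1L) msg <- c(msg, "exonsPerGene must be >= 1")
  if (length(msg)) msg else TRUE
})
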