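#' Default mapping of VCF tags to QC metric and annotation fields
#'
#' Each entry maps an internal field to a VCF location: `"info:<TAG>"` for
#' an INFO tag, `"format:<TAG>"` for a per-sample FORMAT tag, and the
#' special `"format:AD[alt]"` for the alt-supporting read count of the
#' FORMAT AD field (the conventional stand-in for the nonstandard DV tag
#' when no DV tag exists).
#'
#' @return named list of field locations.
#' @export
defaultFieldMap <- function() {
  list(
    QD = "info:QD", FS = "info:FS", MQ = "info:MQ",
    MQRankSum = "info:MQRankSum", ReadPosRankSum = "info:ReadPosRankSum",
    DP = "info:DP", DV = "format:AD[alt]",
    af_popmax = "info:AF_POPMAX", clinsig = "info:CLNSIG",
    cadd = "info:CADD", dpsi_zscore = "info:DPSI_Z",
    dbscsnv = "info:DBSCSNV"
  )
}

.NUMERIC_FIELDS <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "DP",
                     "DV", "af_popmax", "cadd", "dpsi_zscore", "dbscsnv")

# pull a scalar-per-record vector out of an expanded VCF for one field
.extractField <- function(vcf, spec, field, sample_col, n) {
  numeric_field <- field %in% .NUMERIC_FIELDS
  na <- if (numeric_field) rep(NA_real_, n) else rep(NA_character_, n)
  if (is.null(spec)) return(na)
  if (grepl("^info:", spec)) {
    tag <- sub("^info:", "", spec)
    if (!tag %in% colnames(VariantAnnotation::info(vcf))) {
      warning("INFO tag '", tag, "' not present in VCF; field '", field,
              "' treated as missing")
      return(na)
    }
    val <- VariantAnnotation::info(vcf)[[tag]]
    if (is(val, "List") || is.list(val)) {
      # numeric tags are per-record scalars after expand(); string tags
      # (e.g. multi-label CLNSIG) keep every comma-separated token
      val <- vapply(val, function(x) {
        if (!length(x)) NA_character_
        else if (numeric_field) as.character(x[[1]])
        else paste(as.character(x), collapse = ",")
      }, character(1))
    }
    if (numeric_field) suppressWarnings(as.numeric(val)) else as.character(val)
  } else if (grepl("^format:", spec)) {
    tag <- sub("^format:(AD\\[alt\\]|[^[]+).*", "\\1", spec)
    want_alt <- identical(tag, "AD[alt]")
    if (want_alt) tag <- "AD"
    gmats <- VariantAnnotation::geno(vcf)
    if (!tag %in% names(gmats)) {
      warning("FORMAT tag '", tag, "' not present in VCF; field '", field,
              "' treated as missing")
      return(na)
    }
    g <- gmats[[tag]]
    g <- if (length(dim(g)) == 3L) g[, sample_col, , drop = FALSE]
         else g[, sample_col, drop = FALSE]
    if (want_alt) {
      if (is.list(g)) {
        val <- vapply(g, function(x)
          if (length(x) >= 2L) as.numeric(x[2]) else NA_real_, numeric(1))
      } else if (length(dim(g)) == 3L && dim(g)[3] >= 2L) {
        val <- as.numeric(g[, 1L, 2L])
      } else {
        val <- rep(NA_real_, n)
      }
    } else {
      val <- if (is.list(g))
        vapply(g, function(x) if (length(x)) as.numeric(x[1]) else NA_real_,
               numeric(1))
      else as.numeric(g)
    }
    if (numeric_field) val else as.character(val)
  } else {
    warning("unrecognised field_map entry '", spec, "' for field '", field,
            "'; treated as missing")
    na
  }
}

#' Read an annotated VCF into per-sample variant records
#'
#' Parses a VCF 4.x file (plain or bgzipped) with
#' \pkg{VariantAnnotation}, splits multi-allelic sites into one record per
#' alt allele (per-allele INFO/FORMAT tags are matched by allele index),
#' classifies each record as SNV or INDEL, and extracts QC metrics and
#' annotation scores according to `fieldMap`. Missing tags become `NA`
#' fields, never zeros.
#'
#' @param path VCF file.
#' @param sampleId identifier recorded on every emitted record; if the VCF
#'   is multi-sample and `sampleId` matches a sample column, that column's
#'   FORMAT values are used (otherwise the first column).
#' @param fieldMap see [defaultFieldMap()].
#' @return a [VariantSet-class].
#' @export
readVariants <- function(path, sampleId, fieldMap = defaultFieldMap()) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  # a header-only VCF is a legitimate empty callset
  n_body <- sum(!startsWith(readLines(path, warn = FALSE), "#"))
  if (n_body == 0L)
    return(new("VariantSet", records = .emptyRecords(), samples = sampleId))
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vcf <- VariantAnnotation::expand(vcf)
  n <- length(vcf)
  if (n == 0L) {
    return(new("VariantSet", records = .emptyRecords(), samples = sampleId))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(VariantAnnotation::alt(vcf))

  keep <- !is.na(alt) & nzchar(alt) & alt != "*" & alt != "." & ref != alt
  if (!all(keep)) {
    vcf <- vcf[keep]
    rr <- rr[keep]; ref <- ref[keep]; alt <- alt[keep]
    n <- length(vcf)
  }
  if (n == 0L)
    return(new("VariantSet", records = .emptyRecords(), samples = sampleId))

  vcf_samples <- colnames(vcf)
  sample_col <- if (length(vcf_samples) && sampleId %in% vcf_samples)
    match(sampleId, vcf_samples) else 1L

  df <- data.frame(
    sample_id = sampleId,
    chrom = normalizeChrom(seqnames(rr)),
    pos = start(rr),
    ref = ref, alt = alt,
    vclass = ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "INDEL"),
    stringsAsFactors = FALSE
  )
  for (field in setdiff(.VARIANT_COLUMNS, names(df)))
    df[[field]] <- .extractField(vcf, fieldMap[[field]], field, sample_col, n)
  rownames(df) <- NULL
  new("VariantSet", records = df[.VARIANT_COLUMNS], samples = sampleId)
}

.emptyRecords <- function() {
  df <- data.frame(sample_id = character(), chrom = character(),
                   pos = integer(), ref = character(), alt = character(),
                   vclass = character(), stringsAsFactors = FALSE)
  for (f in .NUMERIC_FIELDS) df[[f]] <- numeric()
  df$clinsig <- character()
  df[.VARIANT_COLUMNS]
}

#' Read a cohort of per-sample VCFs
#'
#' @param paths VCF files, one per sample.
#' @param sampleIds identifiers (defaults to file base names).
#' @param fieldMap see [defaultFieldMap()].
#' @return a combined [VariantSet-class].
#' @export
readVcfCohort <- function(paths, sampleIds = NULL,
                          fieldMap = defaultFieldMap()) {
  if (is.null(sampleIds))
    sampleIds <- sub("\\.vcf(\\.gz|\\.bgz)?$", "", basename(paths))
  stopifnot(length(paths) == length(sampleIds))
  sets <- mapply(readVariants, paths, sampleIds,
                 MoreArgs = list(fieldMap = fieldMap), SIMPLIFY = FALSE)
  combineVariantSets(sets)
}

#' Combine several VariantSet objects
#' @param sets list of [VariantSet-class] objects.
#' @return a single [VariantSet-class].
#' @export
combineVariantSets <- function(sets) {
  recs <- data.table::rbindlist(lapply(sets, variantRecords))
  new("VariantSet", records = as.data.frame(recs),
      samples = unique(unlist(lapply(sets, sampleIds))))
}

#' Deduplicate variant records across samples
#'
#' Collapses records to one row per distinct (chrom, pos, ref, alt) key: a
#' variant detected in multiple samples is counted as one. Pass status is
#' aggregated over observations under `policy`: `any_pass` (default; the
#' variant passes if it passes in at least one sample), `majority`, or
#' `all_pass`. `mean_dp` averages DP over observations where DP is present,
#' and annotation scores are aggregated to the best observed value
#' (minimum allele frequency, maximum cadd/dpsi/dbscSNV; clinsig labels are
#' concatenated so benign tokens survive aggregation).
#'
#' @param vs a [VariantSet-class].
#' @param policy pass-aggregation policy.
#' @param thresholds,missing forwarded to [hardFilter()].
#' @return a [UniqueVariantSet-class].
#' @export
dedupUnique <- function(vs, policy = c("any_pass", "majority", "all_pass"),
                        thresholds = hardFilterThresholds(),
                        missing = "pass") {
  policy <- match.arg(policy)
  df <- variantRecords(vs)
  if (nrow(df) == 0L) {
    empty <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        vclass = character(), n_samples = integer(),
                        n_obs = integer(), any_pass = logical(),
                        mean_dp = numeric(), af_popmax = numeric(),
                        clinsig = character(), cadd = numeric(),
                        dpsi_zscore = numeric(), dbscsnv = numeric())
    return(new("UniqueVariantSet", variants = empty, policy = policy))
  }
  verdict <- hardFilter(df, thresholds = thresholds, missing = missing)
  dt <- as.data.table(df)
  dt[, .passed := verdict$passed]
  maxna <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  minna <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  agg <- dt[, {
    pass <- switch(policy,
      any_pass = any(.passed),
      majority = mean(.passed) > 0.5,
      all_pass = all(.passed))
    cl <- unique(clinsig[!is.na(clinsig) & nzchar(clinsig) & clinsig != "."])
    list(vclass = vclass[1],
         n_samples = data.table::uniqueN(sample_id),
         n_obs = .N,
         any_pass = pass,
         mean_dp = if (all(is.na(DP))) NA_real_ else mean(DP, na.rm = TRUE),
         af_popmax = minna(af_popmax),
         clinsig = if (length(cl)) paste(cl, collapse = ",") else NA_character_,
         cadd = maxna(cadd),
         dpsi_zscore = maxna(dpsi_zscore),
         dbscsnv = maxna(dbscsnv))
  }, by = .(chrom, pos, ref, alt)]
  setorder(agg, chrom, pos, ref, alt)
  new("UniqueVariantSet", variants = as.data.frame(agg), policy = policy)
}
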