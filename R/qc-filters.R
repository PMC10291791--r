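#' Hard-filter thresholds for SNVs and indels
#'
#' Defaults reproduce the GATK-style hard-filter expressions the pipeline
#' classifies variants with: an SNV fails when
#' `QD < 2.0 | FS > 60.0 | MQ < 40.0 | MQRankSum < -12.5 |
#' ReadPosRankSum < -8.0 | DP < 20 | DV < 8`; an indel when
#' `QD < 2.0 | FS > 200.0 | ReadPosRankSum < -20.0 | DP < 20 | DV < 8`.
#' Every threshold can be overridden.
#'
#' @param snv,indel named lists of thresholds for the two branches.
#' @return list with elements `snv` and `indel`.
#' @export
hardFilterThresholds <- function(
    snv = list(QD = 2.0, FS = 60.0, MQ = 40.0, MQRankSum = -12.5,
               ReadPosRankSum = -8.0, DP = 20, DV = 8),
    indel = list(QD = 2.0, FS = 200.0, ReadPosRankSum = -20.0,
                 DP = 20, DV = 8)) {
  list(snv = snv, indel = indel)
}

# criterion direction: TRUE where the metric value violates the criterion
.violations <- function(df, thr, missing_policy) {
  viol <- function(metric, bad) {
    v <- bad(df[[metric]], thr[[metric]])
    if (missing_policy == "fail") v[is.na(v)] <- TRUE else v[is.na(v)] <- FALSE
    v
  }
  out <- list()
  for (metric in names(thr)) {
    out[[metric]] <- switch(metric,
      QD = viol("QD", `<`),
      FS = viol("FS", `>`),
      MQ = viol("MQ", `<`),
      MQRankSum = viol("MQRankSum", `<`),
      ReadPosRankSum = viol("ReadPosRankSum", `<`),
      DP = viol("DP", `<`),
      DV = viol("DV", `<`),
      stop("unknown hard-filter criterion: ", metric))
  }
  out
}

#' Apply the hard filter to variant records
#'
#' Pure, vectorised pass/false classification. The branch is chosen by
#' `vclass` (SNV or INDEL); a record fails when any criterion of its branch
#' is violated. A missing metric never triggers a violation under the
#' default `missing = "pass"` policy (rank-sum annotations are legitimately
#' absent for e.g. hom-alt sites); `missing = "fail"` treats a missing
#' metric as a violation.
#'
#' @param records a [VariantSet-class] or a data.frame carrying `vclass`
#'   and the QC metric columns.
#' @param thresholds output of [hardFilterThresholds()].
#' @param missing `"pass"` or `"fail"`.
#' @return data.frame with `passed` (logical) and `failed_criteria`
#'   (semicolon-joined criterion names; `""` iff passed).
#' @examples
#' rec <- data.frame(vclass = "SNV", QD = 1.5, FS = 10, MQ = 60,
#'                   MQRankSum = 0, ReadPosRankSum = 0, DP = 100, DV = 50)
#' hardFilter(rec)  # fails on QD
#' @export
hardFilter <- function(records, thresholds = hardFilterThresholds(),
                       missing = c("pass", "fail")) {
  missing <- match.arg(missing)
  df <- if (is(records, "VariantSet")) variantRecords(records) else records
  stopifnot("vclass" %in% names(df))
  n <- nrow(df)
  failed <- character(n)
  for (branch in c("snv", "indel")) {
    sel <- if (branch == "snv") df$vclass == "SNV" else df$vclass == "INDEL"
    if (!any(sel)) next
    thr <- thresholds[[branch]]
    # ensure metric columns exist (absent column == missing metric)
    sub <- df[sel, , drop = FALSE]
    for (metric in names(thr))
      if (is.null(sub[[metric]])) sub[[metric]] <- NA_real_
    v <- .violations(sub, thr, missing)
    vm <- do.call(cbind, v)
    failed[sel] <- apply(vm, 1L, function(row)
      paste(names(thr)[row], collapse = ";"))
  }
  data.frame(passed = failed == "", failed_criteria = failed,
             stringsAsFactors = FALSE)
}

#' Deleterious-cascade thresholds
#'
#' Defaults: population maximum allele frequency below 0.05, clinical
#' significance not Benign/Likely_benign, CADD above 10, SPIDEX dpsi
#' z-score at least 2, dbscSNV above 0.6.
#'
#' @param af_popmax,cadd,dpsi_zscore,dbscsnv numeric cutoffs.
#' @export
deleteriousThresholds <- function(af_popmax = 0.05, cadd = 10,
                                  dpsi_zscore = 2, dbscsnv = 0.6) {
  list(af_popmax = af_popmax, cadd = cadd, dpsi_zscore = dpsi_zscore,
       dbscsnv = dbscsnv)
}

.BENIGN_TOKENS <- c("benign", "likely_benign")

# TRUE where a clinsig label contains a benign token; NA labels are allowed
.isBenign <- function(clinsig) {
  out <- logical(length(clinsig))
  has <- !is.na(clinsig) & nzchar(clinsig) & clinsig != "."
  if (any(has)) {
    toks <- strsplit(tolower(clinsig[has]), "[,/|;[:space:]]+")
    out[has] <- vapply(toks, function(t) any(t %in% .BENIGN_TOKENS),
                       logical(1))
  }
  out
}

#' Apply the deleterious filter cascade to unique variants
#'
#' A pass variant is deleterious when (1) its population maximum allele
#' frequency is below the cutoff (a missing frequency is treated as rare:
#' novel variants have no database entry), (2) its clinical-significance
#' label does not contain a Benign/Likely_benign token (case-insensitive,
#' split on comma/slash/pipe), and (3) the in-silico scores satisfy
#' `CADD > 10 & dpsi_zscore >= 2 & dbscSNV > 0.6`. Under the default
#' `scores = "present"` policy the conjunction is evaluated only over
#' scores that are present, requiring at least one present score (dbscSNV
#' is only defined near canonical splice sites, so a strict three-way AND
#' would empty the deep flank); `scores = "strict"` requires all three
#' present and satisfied. `dpsiAbsolute = TRUE` compares `|z|` instead of
#' the signed z-score.
#'
#' @param uniques a [UniqueVariantSet-class] or data.frame with columns
#'   `any_pass`, `af_popmax`, `clinsig`, `cadd`, `dpsi_zscore`, `dbscsnv`.
#' @param thresholds output of [deleteriousThresholds()].
#' @param scores `"present"` or `"strict"` score-combination policy.
#' @param dpsiAbsolute compare the SPIDEX z-score by absolute value.
#' @param requirePass restrict the deleterious set to pass variants
#'   (default TRUE; deleterious variants are a subset of pass variants).
#' @return logical vector, one element per unique variant.
#' @export
deleteriousFilter <- function(uniques, thresholds = deleteriousThresholds(),
                              scores = c("present", "strict"),
                              dpsiAbsolute = FALSE, requirePass = TRUE) {
  scores <- match.arg(scores)
  df <- if (is(uniques, "UniqueVariantSet")) uniqueVariants(uniques) else uniques
  n <- nrow(df)
  if (n == 0L) return(logical(0))

  freq_ok <- is.na(df$af_popmax) | df$af_popmax < thresholds$af_popmax
  clin_ok <- !.isBenign(df$clinsig)

  z <- if (dpsiAbsolute) abs(df$dpsi_zscore) else df$dpsi_zscore
  cadd_ok <- df$cadd > thresholds$cadd
  dpsi_ok <- z >= thresholds$dpsi_zscore
  dbsc_ok <- df$dbscsnv > thresholds$dbscsnv

  if (scores == "strict") {
    score_ok <- !is.na(cadd_ok) & cadd_ok &
      !is.na(dpsi_ok) & dpsi_ok & !is.na(dbsc_ok) & dbsc_ok
  } else {
    present <- cbind(!is.na(cadd_ok), !is.na(dpsi_ok), !is.na(dbsc_ok))
    ok <- cbind(cadd_ok, dpsi_ok, dbsc_ok)
    ok[!present] <- TRUE                     # absent score cannot veto
    score_ok <- rowSums(present) >= 1L & rowSums(ok) == 3L
  }

  out <- freq_ok & clin_ok & score_ok
  if (requirePass && !is.null(df$any_pass)) out <- out & df$any_pass
  out
}
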