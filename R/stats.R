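#' Per-sample, per-bucket variant count matrix
#'
#' Counts, for each sample, the records falling in each flanking offset
#' bucket d in 1..W — the per-sample quantities the paired t-tests
#' compare. `which = "pass"` restricts to records passing the hard filter.
#'
#' @param vs a [VariantSet-class].
#' @param ann a [GenomeAnnotation-class].
#' @param which `"raw"` or `"pass"`.
#' @param thresholds,missing forwarded to [hardFilter()].
#' @return integer matrix, samples in rows and buckets 1..W in columns.
#' @export
sampleCountMatrix <- function(vs, ann, which = c("raw", "pass"),
                              thresholds = hardFilterThresholds(),
                              missing = "pass") {
  which <- match.arg(which)
  df <- variantRecords(vs)
  samples <- sampleIds(vs)
  W <- windowWidth(ann)
  m <- matrix(0L, nrow = length(samples), ncol = W,
              dimnames = list(samples, as.character(seq_len(W))))
  if (nrow(df) == 0L) return(m)
  asn <- classifyPosition(df$chrom, df$pos, ann)
  keep <- asn$region == "intronic_flanking"
  if (which == "pass")
    keep <- keep & hardFilter(df, thresholds, missing)$passed
  if (!any(keep)) return(m)
  tt <- table(factor(df$sample_id[keep], levels = samples),
              factor(asn$d[keep], levels = seq_len(W)))
  m[] <- as.integer(tt)
  m
}

#' Per-sample false proportions for a region partition
#'
#' For each sample, the share of its own records (in the given region
#' class) failing the hard filter — the per-sample FP values compared by
#' the flanking-versus-exonic test.
#'
#' @param vs a [VariantSet-class].
#' @param ann a [GenomeAnnotation-class].
#' @param region `"intronic_flanking"` or `"exonic"`.
#' @param thresholds,missing forwarded to [hardFilter()].
#' @return named list: `fp` (numeric per sample), `pooled`
#'   (c(pass, false) pooled counts).
#' @export
perSampleFp <- function(vs, ann,
                        region = c("intronic_flanking", "exonic"),
                        thresholds = hardFilterThresholds(),
                        missing = "pass") {
  region <- match.arg(region)
  df <- variantRecords(vs)
  samples <- sampleIds(vs)
  asn <- classifyPosition(df$chrom, df$pos, ann)
  sel <- asn$region == region
  passed <- hardFilter(df, thresholds, missing)$passed
  fp <- vapply(samples, function(s) {
    i <- sel & df$sample_id == s
    if (!any(i)) NA_real_ else mean(!passed[i])
  }, numeric(1))
  list(fp = fp,
       pooled = c(pass = sum(passed[sel]), false = sum(!passed[sel])))
}

#' Paired t-test between two offset buckets of a count matrix
#'
#' Two-sided t-test on the per-sample counts at buckets `i` and `j`
#' (paired by sample; Welch unpaired when `paired = FALSE`). Zero variance
#' of the paired differences yields `NA` with a warning, never a silent 0
#' or 1.
#'
#' @param m matrix from [sampleCountMatrix()].
#' @param i,j bucket indices (columns), `i != j`.
#' @param paired pair observations by sample (default TRUE).
#' @return p-value, or `NA` when degenerate.
#' @export
pairwiseCountTtest <- function(m, i, j, paired = TRUE) {
  stopifnot(i != j)
  if (nrow(m) < 2L) stop("need at least 2 samples for a t-test")
  x <- m[, i]; y <- m[, j]
  degenerate <- if (paired) stats::var(x - y) == 0 else
    (stats::var(x) == 0 && stats::var(y) == 0)
  if (is.na(degenerate) || degenerate) {
    warning("zero variance comparing buckets ", i, " and ", j,
            "; p reported as missing")
    return(NA_real_)
  }
  tryCatch(stats::t.test(x, y, paired = paired)$p.value,
           error = function(e) {
             warning("degenerate t-test comparing buckets ", i, " and ", j,
                     ": ", conditionMessage(e), "; p reported as missing")
             NA_real_
           })
}

#' Fisher's exact test between the FP of two offset buckets
#'
#' Two-sided Fisher's exact p-value on the pooled 2x2 table
#' `[[pass_i, false_i], [pass_j, false_j]]` (two-sidedness by summing
#' hypergeometric probabilities of tables at most as probable as the
#' observed one). An empty bucket yields `NA`.
#'
#' @param profile a [PositionProfile-class].
#' @param i,j bucket offsets.
#' @return p-value, or `NA` when a bucket is empty.
#' @export
pairwiseFpFisher <- function(profile, i, j) {
  tb <- profileTable(profile)
  ri <- tb[tb$d == i, ]; rj <- tb[tb$d == j, ]
  if (nrow(ri) != 1L || nrow(rj) != 1L)
    stop("buckets must exist in the profile")
  if (ri$raw_count == 0L || rj$raw_count == 0L) return(NA_real_)
  .fisher2x2(ri$pass_count, ri$false_count, rj$pass_count, rj$false_count)
}

# two-sided Fisher's exact p for the table [[a, b], [c, d]]
.fisher2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Pairwise positional test matrix
#'
#' Runs the configured test for every bucket pair and returns symmetric
#' matrices of raw and BH-adjusted p-values (the per-position significance
#' structure of the positional comparisons).
#'
#' @param x a count matrix (for `test = "t_test"`) or a
#'   [PositionProfile-class] (for `test = "fisher_exact"`).
#' @param test which test to run pairwise.
#' @param buckets bucket offsets to compare (default all columns / all d).
#' @param paired forwarded to [pairwiseCountTtest()].
#' @return list with `test`, symmetric matrices `p` and `p_adj`
#'   (diagonal NA).
#' @export
pairwiseMatrix <- function(x, test = c("t_test", "fisher_exact"),
                           buckets = NULL, paired = TRUE) {
  test <- match.arg(test)
  if (test == "t_test") {
    stopifnot(is.matrix(x))
    if (is.null(buckets)) buckets <- seq_len(ncol(x))
  } else {
    stopifnot(is(x, "PositionProfile"))
    if (is.null(buckets)) buckets <- profileTable(x)$d
  }
  k <- length(buckets)
  p <- matrix(NA_real_, k, k, dimnames = list(buckets, buckets))
  for (a in seq_len(k - 1L)) {
    for (b in seq(a + 1L, k)) {
      pv <- if (test == "t_test")
        suppressWarnings(pairwiseCountTtest(x, buckets[a], buckets[b],
                                            paired = paired))
      else pairwiseFpFisher(x, buckets[a], buckets[b])
      p[a, b] <- p[b, a] <- pv
    }
  }
  list(test = test, p = p, p_adj = bhAdjust(p))
}

#' Benjamini-Hochberg adjustment
#'
#' For a symmetric p-value matrix the step-up adjustment runs over the
#' upper triangle and is mirrored back; for a vector it is
#' `p.adjust(..., "BH")`. Output is invariant under permutation of input
#' order, monotone, bounded by 1 and never below the raw p-value.
#'
#' @param p numeric vector or symmetric matrix of p-values in (0, 1].
#' @return adjusted p-values with the same shape.
#' @export
bhAdjust <- function(p) {
  if (is.matrix(p)) {
    ut <- upper.tri(p)
    adj <- p
    adj[ut] <- stats::p.adjust(p[ut], method = "BH")
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    adj
  } else {
    stats::p.adjust(p, method = "BH")
  }
}

#' Flanking-versus-exonic false-proportion test
#'
#' Two-sided paired t-test on per-sample FP values in the flanking
#' intronic region versus the exonic region; a pooled-count Fisher's exact
#' test on the aggregated 2x2 pass/false table is reported alongside, so
#' either reading of the comparison is inspectable.
#'
#' @param fpFlanking,fpExonic per-sample FP vectors of equal length
#'   (e.g. from [perSampleFp()]).
#' @param pooledFlanking,pooledExonic optional `c(pass, false)` pooled
#'   counts for the Fisher test.
#' @return list with `p_t` (paired t), `p_fisher` (pooled; NA when pooled
#'   counts not supplied), and the mean FP difference `delta_fp`.
#' @export
flankingVsExonicFpTest <- function(fpFlanking, fpExonic,
                                   pooledFlanking = NULL,
                                   pooledExonic = NULL) {
  stopifnot(length(fpFlanking) == length(fpExonic))
  if (length(fpFlanking) < 2L) stop("need at least 2 samples")
  keep <- !is.na(fpFlanking) & !is.na(fpExonic)
  x <- fpFlanking[keep]; y <- fpExonic[keep]
  diffs <- x - y
  p_t <- if (length(diffs) < 2L || stats::var(diffs) == 0) {
    warning("zero variance of paired FP differences; p reported as missing")
    NA_real_
  } else tryCatch(stats::t.test(x, y, paired = TRUE)$p.value,
                  error = function(e) {
                    warning("degenerate paired FP comparison: ",
                            conditionMessage(e), "; p reported as missing")
                    NA_real_
                  })
  p_f <- NA_real_
  if (!is.null(pooledFlanking) && !is.null(pooledExonic) &&
      sum(pooledFlanking) > 0 && sum(pooledExonic) > 0) {
    p_f <- stats::fisher.test(rbind(pooledFlanking, pooledExonic))$p.value
  }
  list(p_t = p_t, p_fisher = p_f, delta_fp = mean(diffs))
}

#' Minimal sample size for a paired t-test at target power
#'
#' Searches the smallest integer n such that a paired t-test with
#' standardized effect size dz (noncentrality dz * sqrt(n), n - 1 degrees
#' of freedom) attains at least the requested power at significance level
#' alpha. Power is computed from the noncentral t distribution:
#' two-tailed, `P(T' > t_crit) + P(T' < -t_crit)` with
#' `t_crit = qt(1 - alpha/2, n - 1)`.
#'
#' @param effectSize standardized effect size dz (> 0).
#' @param alpha significance level in (0, 1).
#' @param power target power in (0, 1).
#' @param tails 1 or 2.
#' @param nMax search bound.
#' @return smallest integer n (total pairs) reaching the target power.
#' @examples
#' powerSampleSize(0.5, alpha = 0.05, power = 0.95)  # 54
#' @export
powerSampleSize <- function(effectSize, alpha = 0.05, power = 0.95,
                            tails = 2, nMax = 100000L) {
  stopifnot(effectSize > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            tails %in% c(1, 2))
  for (n in 2:nMax) {
    if (pairedTPower(n, effectSize, alpha, tails) >= power)
      return(as.integer(n))
  }
  stop("target power not attainable within nMax = ", nMax)
}

#' Power of the paired t-test at a given sample size
#'
#' @param n number of pairs (>= 2).
#' @param effectSize standardized effect size dz.
#' @param alpha significance level.
#' @param tails 1 or 2.
#' @return attained power.
#' @export
pairedTPower <- function(n, effectSize, alpha = 0.05, tails = 2) {
  ncp <- effectSize * sqrt(n)
  df <- n - 1
  if (tails == 2) {
    tc <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    1 - stats::pt(tc, df, ncp)
  }
}

#' Write a pairwise test matrix in long format
#'
#' Long-format TSV (`i`, `j`, `test`, `p`, `p_adj`, `sig_05`, `sig_01`)
#' over the upper triangle, with significance flags at 0.05 and 0.01 on
#' the raw p-values.
#'
#' @param pm output of [pairwiseMatrix()].
#' @param path output file.
#' @param alpha significance levels for the mask columns.
#' @export
writePairwiseTable <- function(pm, path, alpha = c(0.05, 0.01)) {
  buckets <- as.integer(rownames(pm$p))
  ut <- which(upper.tri(pm$p), arr.ind = TRUE)
  df <- data.frame(i = buckets[ut[, 1]], j = buckets[ut[, 2]],
                   test = pm$test, p = pm$p[ut], p_adj = pm$p_adj[ut])
  df$sig_05 <- !is.na(df$p) & df$p < alpha[1]
  df$sig_01 <- !is.na(df$p) & df$p < alpha[2]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
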