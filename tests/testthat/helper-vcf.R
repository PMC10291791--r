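# independent minimal VCF writer for fixtures (deliberately not the
# package's synthetic-cohort writer)

vcfFixtureHeader <- function(sample_id, per_allele = FALSE) {
  num <- if (per_allele) "A" else "1"
  c("##fileformat=VCFv4.2",
    "##contig=<ID=1,length=100000>",
    "##contig=<ID=2,length=100000>",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"fs\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"mq\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"mqrs\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"rprs\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##INFO=<ID=AF_POPMAX,Number=1,Type=Float,Description=\"af\">",
    "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"clnsig\">",
    sprintf("##INFO=<ID=CADD,Number=%s,Type=Float,Description=\"cadd\">", num),
    sprintf("##INFO=<ID=DPSI_Z,Number=%s,Type=Float,Description=\"dpsi\">", num),
    sprintf("##INFO=<ID=DBSCSNV,Number=%s,Type=Float,Description=\"dbsc\">", num),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id))
}

# df columns: chrom, pos, ref, alt and optionally QD, FS, MQ, MQRankSum,
# ReadPosRankSum, DP, DV, af_popmax, clinsig, cadd, dpsi_zscore, dbscsnv
writeTestVcf <- function(df, path, sample_id = "S1") {
  info_keys <- c(QD = "QD", FS = "FS", MQ = "MQ", MQRankSum = "MQRankSum",
                 ReadPosRankSum = "ReadPosRankSum", DP = "DP",
                 af_popmax = "AF_POPMAX", clinsig = "CLNSIG", cadd = "CADD",
                 dpsi_zscore = "DPSI_Z", dbscsnv = "DBSCSNV")
  lines <- vcfFixtureHeader(sample_id)
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    info <- character()
    for (col in names(info_keys)) {
      v <- row[[col]]
      if (!is.null(v) && length(v) == 1L && !is.na(v))
        info <- c(info, paste0(info_keys[[col]], "=", v))
    }
    if (!length(info)) info <- "."
    has_ad <- !is.null(row$DV) && !is.na(row$DV)
    dp_for_ad <- if (!is.null(row$DP) && !is.na(row$DP)) row$DP else row$DV
    fmt <- if (has_ad) sprintf("GT:AD\t0/1:%d,%d",
                               as.integer(max(dp_for_ad - row$DV, 0)),
                               as.integer(row$DV))
           else "GT\t0/1"
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s\t%s",
                              row$chrom, as.integer(row$pos), row$ref,
                              row$alt, paste(info, collapse = ";"), fmt))
  }
  writeLines(lines, path)
  invisible(path)
}

# a metrics row that comfortably satisfies every hard-filter criterion
nominalQc <- function(...) {
  out <- list(QD = 20, FS = 10, MQ = 60, MQRankSum = 0, ReadPosRankSum = 0,
              DP = 100, DV = 50)
  utils::modifyList(out, list(...))
}

# build a PositionProfile directly from per-bucket pass/false counts
makeProfile <- function(d, pass, false, W = max(d)) {
  tab <- data.frame(d = seq_len(W), raw_count = 0L, pass_count = 0L,
                    false_count = 0L, fp = NA_real_, mean_depth = NA_real_,
                    deleterious_count = 0L)
  i <- match(d, tab$d)
  tab$pass_count[i] <- as.integer(pass)
  tab$false_count[i] <- as.integer(false)
  tab$raw_count <- tab$pass_count + tab$false_count
  ok <- tab$raw_count > 0
  tab$fp[ok] <- tab$false_count[ok] / tab$raw_count[ok]
  new("PositionProfile", table = tab, totals = list(),
      windowWidth = as.integer(W))
}

# independent full-enumeration two-sided Fisher oracle for a 2x2 table
fisherEnumOracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  k <- max(0L, c1 - r2):min(r1, c1)
  pk <- stats::dhyper(k, r1, r2, c1)
  pobs <- stats::dhyper(a, r1, r2, c1)
  sum(pk[pk <= pobs * (1 + 1e-7)])
}
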