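# Hand-built 50-record fixture covering every criterion of both
# hard-filter branches and every deleterious-cascade criterion, with
# hand-computed expected labels. Each row is one VCF record; rows 49/50
# share one variant key across two samples.

cascadeFixture <- function() {
  rec <- function(id, sample, vclass, exp_pass, exp_del, ...,
                  af = NA, clin = NA, cadd = NA, dpsi = NA, dbsc = NA) {
    qc <- nominalQc(...)
    data.frame(id = id, sample = sample,
               chrom = "1", pos = 1100L + 3L * id,
               ref = "A", alt = if (vclass == "SNV") "G" else "AT",
               QD = qc$QD, FS = qc$FS, MQ = qc$MQ,
               MQRankSum = qc$MQRankSum, ReadPosRankSum = qc$ReadPosRankSum,
               DP = qc$DP, DV = qc$DV,
               af_popmax = af, clinsig = clin, cadd = cadd,
               dpsi_zscore = dpsi, dbscsnv = dbsc,
               expected_pass = exp_pass, expected_deleterious = exp_del,
               stringsAsFactors = FALSE)
  }
  rows <- list(
    # --- SNV hard-filter branch, one criterion at a time (boundaries
    # included: every printed comparison is strict) ---
    rec(1, "S1", "SNV", FALSE, FALSE, QD = 1.5),
    rec(2, "S1", "SNV", TRUE, FALSE, QD = 2.0),
    rec(3, "S1", "SNV", FALSE, FALSE, FS = 60.5),
    rec(4, "S1", "SNV", TRUE, FALSE, FS = 60.0),
    rec(5, "S1", "SNV", FALSE, FALSE, MQ = 39.9),
    rec(6, "S1", "SNV", TRUE, FALSE, MQ = 40.0),
    rec(7, "S1", "SNV", FALSE, FALSE, MQRankSum = -13),
    rec(8, "S1", "SNV", TRUE, FALSE, MQRankSum = -12.5),
    rec(9, "S1", "SNV", FALSE, FALSE, ReadPosRankSum = -8.5),
    rec(10, "S1", "SNV", TRUE, FALSE, ReadPosRankSum = -8.0),
    rec(11, "S1", "SNV", FALSE, FALSE, DP = 19, DV = 8),
    rec(12, "S1", "SNV", TRUE, FALSE, DP = 20, DV = 8),
    rec(13, "S1", "SNV", FALSE, FALSE, DV = 7),
    rec(14, "S1", "SNV", TRUE, FALSE, DV = 8),
    rec(15, "S1", "SNV", FALSE, FALSE, QD = 1.0, DP = 10, DV = 5),
    # missing metrics never violate under the default policy
    rec(16, "S1", "SNV", TRUE, FALSE, MQRankSum = NA),
    rec(17, "S1", "SNV", FALSE, FALSE, ReadPosRankSum = NA, QD = 1.5),
    rec(18, "S1", "SNV", TRUE, FALSE, QD = NA, FS = NA, MQ = NA,
        MQRankSum = NA, ReadPosRankSum = NA),
    # --- INDEL branch: looser FS / ReadPosRankSum, no MQ criteria ---
    rec(19, "S1", "INDEL", TRUE, FALSE, FS = 100),
    rec(20, "S1", "SNV", FALSE, FALSE, FS = 100),   # same metrics, SNV branch
    rec(21, "S1", "INDEL", FALSE, FALSE, FS = 250),
    rec(22, "S1", "INDEL", TRUE, FALSE, ReadPosRankSum = -15),
    rec(23, "S1", "SNV", FALSE, FALSE, ReadPosRankSum = -15),
    rec(24, "S1", "INDEL", FALSE, FALSE, ReadPosRankSum = -25),
    rec(25, "S1", "INDEL", TRUE, FALSE, MQ = 20, MQRankSum = -20),
    rec(26, "S1", "INDEL", FALSE, FALSE, QD = 1.0),
    rec(27, "S1", "INDEL", FALSE, FALSE, DP = 19, DV = 8),
    rec(28, "S1", "INDEL", FALSE, FALSE, DV = 7),
    rec(29, "S1", "INDEL", TRUE, FALSE),
    rec(30, "S1", "SNV", TRUE, FALSE),
    # --- deleterious cascade on QC-passing records ---
    rec(31, "S1", "SNV", TRUE, TRUE, af = 0.01, cadd = 15, dpsi = 2.5,
        dbsc = 0.9),
    rec(32, "S1", "SNV", TRUE, FALSE, af = 0.001, clin = "Benign",
        cadd = 30, dpsi = 3, dbsc = 0.95),
    rec(33, "S1", "SNV", TRUE, FALSE, af = 0.2, cadd = 15, dpsi = 2.5,
        dbsc = 0.9),
    rec(34, "S1", "SNV", TRUE, TRUE, cadd = 15),       # present-scores policy
    rec(35, "S1", "SNV", TRUE, FALSE, cadd = 9),
    rec(36, "S1", "SNV", TRUE, TRUE, dpsi = 2.0),      # z >= 2 boundary
    rec(37, "S1", "SNV", TRUE, FALSE, dpsi = 1.9, dbsc = 0.9),
    rec(38, "S1", "SNV", TRUE, FALSE, dbsc = 0.6),     # needs > 0.6
    rec(39, "S1", "SNV", TRUE, TRUE, dbsc = 0.61),
    rec(40, "S1", "SNV", TRUE, FALSE, af = 0.001),     # no score present
    rec(41, "S1", "SNV", TRUE, FALSE, clin = "Likely_benign", cadd = 15),
    rec(42, "S1", "SNV", TRUE, FALSE, clin = "Benign/Likely_benign",
        cadd = 15),
    rec(43, "S1", "SNV", TRUE, TRUE, clin = "Uncertain_significance",
        cadd = 15),
    rec(44, "S1", "SNV", TRUE, FALSE, clin = "benign", cadd = 15),
    rec(45, "S1", "SNV", TRUE, FALSE, clin = "Pathogenic,Benign", cadd = 15),
    rec(46, "S1", "SNV", TRUE, TRUE, af = 0.049, cadd = 15),
    rec(47, "S1", "SNV", TRUE, FALSE, af = 0.05, cadd = 15),
    rec(48, "S1", "SNV", TRUE, FALSE, dpsi = -3),      # signed comparison
    # deleterious is a subset of pass: extreme scores cannot rescue a
    # QC-failing variant
    rec(49, "S1", "SNV", FALSE, FALSE, DP = 5, DV = 2, af = 0.0001,
        cadd = 30, dpsi = 3, dbsc = 0.99)
  )
  df <- do.call(rbind, rows)
  # record 50: the same variant key as record 49, passing in sample S2 ->
  # unique variant any_pass = TRUE, and the aggregated (best) annotation
  # makes it deleterious
  r50 <- rows[[49]]
  r50$id <- 50; r50$sample <- "S2"
  r50$DP <- 100; r50$DV <- 50
  r50$expected_pass <- TRUE
  r50$expected_deleterious <- TRUE
  rbind(df, r50)
}

# write the fixture as per-sample VCFs; returns file paths + the table
writeCascadeFixture <- function(dir) {
  df <- cascadeFixture()
  paths <- character()
  for (s in unique(df$sample)) {
    p <- file.path(dir, paste0(s, ".vcf"))
    writeTestVcf(df[df$sample == s, ], p, s)
    paths[s] <- p
  }
  list(paths = paths, table = df)
}
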