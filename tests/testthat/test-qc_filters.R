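test_that("each SNV hard-filter criterion fails independently and is named", {
  cases <- list(
    list(over = list(QD = 1.5), crit = "QD"),
    list(over = list(FS = 60.5), crit = "FS"),
    list(over = list(MQ = 39.9), crit = "MQ"),
    list(over = list(MQRankSum = -12.6), crit = "MQRankSum"),
    list(over = list(ReadPosRankSum = -8.1), crit = "ReadPosRankSum"),
    list(over = list(DP = 19), crit = "DP"),
    list(over = list(DV = 7), crit = "DV"))
  for (cs in cases) {
    rec <- cbind(data.frame(vclass = "SNV"), do.call(nominalQc, cs$over))
    v <- hardFilter(rec)
    expect_false(v$passed, info = cs$crit)
    expect_equal(v$failed_criteria, cs$crit)
  }
  nominal <- cbind(data.frame(vclass = "SNV"), nominalQc())
  expect_true(hardFilter(nominal)$passed)
  # boundary values pass: the printed comparisons are strict
  for (over in list(list(QD = 2.0), list(FS = 60.0), list(MQ = 40.0),
                    list(MQRankSum = -12.5), list(ReadPosRankSum = -8.0),
                    list(DP = 20), list(DV = 8))) {
    rec <- cbind(data.frame(vclass = "SNV"), do.call(nominalQc, over))
    expect_true(hardFilter(rec)$passed)
  }
})

test_that("the INDEL branch differs from the SNV branch as specified", {
  # FS = 100 passes as INDEL (limit 200) but fails as SNV (limit 60)
  qc <- nominalQc(FS = 100)
  expect_true(hardFilter(cbind(data.frame(vclass = "INDEL"), qc))$passed)
  expect_false(hardFilter(cbind(data.frame(vclass = "SNV"), qc))$passed)
  # no MQ / MQRankSum criteria for indels
  qc2 <- nominalQc(MQ = 10, MQRankSum = -30)
  expect_true(hardFilter(cbind(data.frame(vclass = "INDEL"), qc2))$passed)
  expect_false(hardFilter(cbind(data.frame(vclass = "SNV"), qc2))$passed)
  # ReadPosRankSum limit -20 for indels
  qc3 <- nominalQc(ReadPosRankSum = -15)
  expect_true(hardFilter(cbind(data.frame(vclass = "INDEL"), qc3))$passed)
  qc4 <- nominalQc(ReadPosRankSum = -25)
  expect_false(hardFilter(cbind(data.frame(vclass = "INDEL"), qc4))$passed)
  # multiple violations are all named
  qc5 <- nominalQc(QD = 1, DP = 10)
  expect_equal(hardFilter(cbind(data.frame(vclass = "SNV"), qc5))$failed_criteria,
               "QD;DP")
})

test_that("missing metrics never violate by default, but can by config", {
  rec <- cbind(data.frame(vclass = "SNV"),
               nominalQc(MQRankSum = NA, ReadPosRankSum = NA))
  expect_true(hardFilter(rec)$passed)
  v <- hardFilter(rec, missing = "fail")
  expect_false(v$passed)
  expect_match(v$failed_criteria, "MQRankSum")
})

test_that("hard filter is pure and monotone in DP/DV and QD", {
  rec <- cbind(data.frame(vclass = "SNV"), nominalQc(DP = 5, DV = 3))
  expect_false(hardFilter(rec)$passed)
  for (dp in c(10, 19, 20, 50)) {
    r <- cbind(data.frame(vclass = "SNV"), nominalQc(DP = dp, DV = dp))
    expect_equal(hardFilter(r)$passed, dp >= 20)
  }
  pass_rec <- cbind(data.frame(vclass = "SNV"), nominalQc())
  fail_rec <- pass_rec; fail_rec$QD <- 1.99
  expect_true(hardFilter(pass_rec)$passed)
  expect_false(hardFilter(fail_rec)$passed)
  # identical metrics give identical verdicts regardless of other columns
  rec2 <- cbind(pass_rec, sample_id = "X", pos = 99L)
  expect_equal(hardFilter(rec2)$passed, hardFilter(pass_rec)$passed)
})

test_that("deleterious cascade follows frequency, clinsig and score rules", {
  base <- data.frame(any_pass = TRUE, af_popmax = 0.01, clinsig = NA,
                     cadd = 15, dpsi_zscore = 2.5, dbscsnv = 0.9)
  expect_true(deleteriousFilter(base))
  expect_false(deleteriousFilter(transform(base, clinsig = "Benign")))
  expect_false(deleteriousFilter(transform(base, af_popmax = 0.2)))
  expect_false(deleteriousFilter(transform(base, cadd = 9)))
  expect_false(deleteriousFilter(transform(base, dpsi_zscore = 1.5)))
  expect_false(deleteriousFilter(transform(base, dbscsnv = 0.5)))
  # missing af is treated as rare
  expect_true(deleteriousFilter(transform(base, af_popmax = NA)))
  # deleterious requires pass
  expect_false(deleteriousFilter(transform(base, any_pass = FALSE)))
})

test_that("present-scores policy differs from strict AND on missing scores", {
  only_cadd <- data.frame(any_pass = TRUE, af_popmax = NA, clinsig = NA,
                          cadd = 15, dpsi_zscore = NA, dbscsnv = NA)
  expect_true(deleteriousFilter(only_cadd, scores = "present"))
  expect_false(deleteriousFilter(only_cadd, scores = "strict"))
  none <- transform(only_cadd, cadd = NA)
  expect_false(deleteriousFilter(none, scores = "present"))
  # a present failing score vetoes even when others pass
  mixed <- transform(only_cadd, dpsi_zscore = 1.0)
  expect_false(deleteriousFilter(mixed, scores = "present"))
})

test_that("clinsig token matching is case-insensitive over joined labels", {
  base <- data.frame(any_pass = TRUE, af_popmax = NA, clinsig = NA,
                     cadd = 15, dpsi_zscore = NA, dbscsnv = NA)
  for (lab in c("Benign", "likely_benign", "Benign/Likely_benign",
                "Pathogenic,Benign", "BENIGN"))
    expect_false(deleteriousFilter(transform(base, clinsig = lab)),
                 info = lab)
  for (lab in c("Pathogenic", "Uncertain_significance",
                "Conflicting_interpretations"))
    expect_true(deleteriousFilter(transform(base, clinsig = lab)),
                info = lab)
})

test_that("signed versus absolute SPIDEX comparison is configurable", {
  neg <- data.frame(any_pass = TRUE, af_popmax = NA, clinsig = NA,
                    cadd = NA, dpsi_zscore = -3, dbscsnv = NA)
  expect_false(deleteriousFilter(neg))
  expect_true(deleteriousFilter(neg, dpsiAbsolute = TRUE))
})

test_that("threshold overrides are honoured", {
  rec <- cbind(data.frame(vclass = "SNV"), nominalQc(DP = 15, DV = 10))
  thr <- hardFilterThresholds(snv = list(QD = 2, FS = 60, MQ = 40,
                                         MQRankSum = -12.5,
                                         ReadPosRankSum = -8, DP = 10,
                                         DV = 8))
  expect_false(hardFilter(rec)$passed)
  expect_true(hardFilter(rec, thresholds = thr)$passed)
  base <- data.frame(any_pass = TRUE, af_popmax = NA, clinsig = NA,
                     cadd = 8, dpsi_zscore = NA, dbscsnv = NA)
  expect_false(deleteriousFilter(base))
  expect_true(deleteriousFilter(base,
                                thresholds = deleteriousThresholds(cadd = 5)))
})
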