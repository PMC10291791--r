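test_that("positions classify to the expected side and offset", {
  ann <- toyAnnotation()  # + strand, exons [1001,1100] [1501,1600]
  res <- classifyPosition("1", c(1109, 1500, 1301, 1050, 1101, 5000), ann)
  expect_equal(res$region, c("intronic_flanking", "intronic_flanking",
                             "intronic_flanking", "exonic",
                             "intronic_flanking", "intergenic"))
  expect_equal(res$d, c(9L, 1L, 200L, NA, 1L, NA))
  expect_equal(res$side, c("donor", "acceptor", "acceptor", NA, "donor", NA))
  # at 1301 the donor distance is 201 (> W) and the acceptor distance 200
})

test_that("minus-strand orientation flips donor and acceptor", {
  ann <- toyAnnotation(strand = "-")
  res <- classifyPosition("1", c(1492, 1109), ann)
  # the genomically-right exon is transcriptionally upstream: its left
  # boundary is the donor site
  expect_equal(res$side, c("donor", "acceptor"))
  expect_equal(res$d, c(9L, 9L))
})

test_that("a donor/acceptor distance tie resolves to donor", {
  ex <- data.frame(chrom = "1", start = c(1001L, 1502L),
                   end = c(1100L, 1600L), strand = "+",
                   transcript_id = "TX1", gene_id = "G1")
  ann <- IntronProfiler:::.buildAnnotation(ex, 250)  # intron [1101,1501], odd
  res <- classifyPosition("1", 1301, ann)
  expect_equal(res$side, "donor")
  expect_equal(res$d, 201L)
})

test_that("deep intronic and unknown chromosomes classify correctly", {
  ex <- data.frame(chrom = "1", start = c(1L, 1002L), end = c(100L, 1101L),
                   strand = "+", transcript_id = "TX1", gene_id = "G1")
  ann <- IntronProfiler:::.buildAnnotation(ex, 200)  # intron [101,1001], L=901
  res <- classifyPosition("1", c(300, 550, 802), ann)
  expect_equal(res$region, c("intronic_flanking", "deep_intronic",
                             "intronic_flanking"))
  expect_warning(res2 <- classifyPosition("99", 50, ann), "absent")
  expect_equal(res2$region, "intergenic")
})

test_that("multi-transcript assignment: exonic precedence, minimal d, lex tie", {
  ann <- multiTxAnnotation()  # W = 50
  # 1205: d = 6 from the shared donor boundary at 1200 in both TXA1 and
  # TXA2 -> tie on d, lexicographically TXA1 wins
  res <- classifyPosition("1", 1205, ann)
  expect_equal(res$region, "intronic_flanking")
  expect_equal(res$d, 6L)
  expect_equal(res$transcript_id, "TXA1")
  # 1605: exonic in TXA2 though intronic in TXA1 -> exonic precedence
  res2 <- classifyPosition("1", 1605, ann)
  expect_equal(res2$region, "exonic")
  expect_equal(res2$transcript_id, "TXA2")
  # 1590: d = 10 from TXA2's acceptor at 1599; TXA1's boundaries are
  # hundreds of bases away -> minimal d across transcripts wins
  res3 <- classifyPosition("1", 1590, ann)
  expect_equal(res3$d, 10L)
  expect_equal(res3$side, "acceptor")
  expect_equal(res3$transcript_id, "TXA2")
  # 1900: beyond W of every boundary of the transcript containing it
  expect_equal(classifyPosition("1", 1900, ann)$region, "deep_intronic")
})

test_that("classifyPosition matches the brute-force oracle on random cases", {
  set.seed(101)
  ann <- randomAnnotation(25, W = 60L)
  ex <- exons(ann)
  pos <- sample(max(end(ex)) + 200L, 2000L)
  chrom <- as.character(sample(1:3, 2000L, replace = TRUE))
  got <- classifyPosition(chrom, pos, ann)
  want <- oracleClassify(chrom, pos, ann)
  expect_equal(got$region, want$region)
  expect_equal(got$d, want$d)
  expect_equal(got$side, want$side)
  fl <- got$region == "intronic_flanking" | got$region == "exonic"
  expect_equal(got$transcript_id[fl], want$transcript_id[fl])
})

test_that("profile tallies match hand counts on a fixture", {
  ann <- toyAnnotation()
  # three uniques at d = 9 (one failing), one deleterious unique at d = 5
  uv <- data.frame(
    chrom = "1", pos = c(1109L, 1110L, 1111L, 1105L),
    ref = "A", alt = "G", vclass = "SNV",
    n_samples = 1L, n_obs = 1L,
    any_pass = c(TRUE, TRUE, FALSE, TRUE),
    mean_dp = c(100, 50, 10, 80),
    af_popmax = NA_real_, clinsig = NA_character_,
    cadd = c(NA, NA, NA, 15), dpsi_zscore = NA_real_, dbscsnv = NA_real_)
  # d for pos 1109/1110/1111 is 9/10/11 on the donor side; 1105 -> d = 5
  uv$pos <- c(1109L, 1109L, 1109L, 1105L)
  uv$ref <- c("A", "C", "G", "A"); uv$alt <- c("G", "T", "A", "T")
  uvs <- new("UniqueVariantSet", variants = uv, policy = "any_pass")
  prof <- buildProfile(uvs, ann)
  tb <- profileTable(prof)
  expect_equal(tb$raw_count[tb$d == 9], 3L)
  expect_equal(tb$pass_count[tb$d == 9], 2L)
  expect_equal(tb$false_count[tb$d == 9], 1L)
  expect_equal(tb$fp[tb$d == 9], 1 / 3)
  expect_equal(tb$mean_depth[tb$d == 9], mean(c(100, 50, 10)))
  # empty bucket: fp is missing, not zero
  expect_true(is.na(tb$fp[tb$d == 100]))
  expect_equal(tb$raw_count[tb$d == 100], 0L)
  # single deleterious spike at d = 5
  expect_equal(tb$deleterious_count[tb$d == 5], 1L)
  expect_equal(sum(tb$deleterious_count), 1L)
})

test_that("gene counts are distinct genes per partition and subset", {
  ann <- multiTxAnnotation()
  uv <- data.frame(
    chrom = c("1", "1", "2"),
    pos = c(1205L, 1210L, 710L),   # GA flanking, GA flanking, GB flanking
    ref = "A", alt = "G", vclass = "SNV", n_samples = 1L, n_obs = 1L,
    any_pass = c(TRUE, TRUE, FALSE),
    mean_dp = 50, af_popmax = NA_real_, clinsig = NA_character_,
    cadd = NA_real_, dpsi_zscore = NA_real_, dbscsnv = NA_real_)
  uvs <- new("UniqueVariantSet", variants = uv, policy = "any_pass")
  expect_equal(geneCounts(uvs, ann, "intronic_flanking", "raw"), 2L)
  # GB contributes only a false variant -> excluded from the pass count
  expect_equal(geneCounts(uvs, ann, "intronic_flanking", "pass"), 1L)
  empty <- new("UniqueVariantSet", variants = uv[0, ], policy = "any_pass")
  expect_equal(geneCounts(empty, ann, "intronic_flanking", "raw"), 0L)
})

test_that("short introns assign each base to its nearer boundary only", {
  # intron [101,130], L = 30 < 2W: donor gets d 1..15, acceptor d 1..15
  ex <- data.frame(chrom = "1", start = c(1L, 131L), end = c(100L, 200L),
                   strand = "+", transcript_id = "TX1", gene_id = "G1")
  ann <- IntronProfiler:::.buildAnnotation(ex, 200)
  res <- classifyPosition("1", 101:130, ann)
  expect_true(all(res$region == "intronic_flanking"))
  expect_equal(sum(res$side == "donor"), 15L)
  expect_equal(sum(res$side == "acceptor"), 15L)
  expect_equal(max(res$d), 15L)
  # every base assigned exactly once per bucket/side (no double counting)
  expect_equal(nrow(res), 30L)
  expect_false(any(duplicated(res[c("d", "side")])))
})
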