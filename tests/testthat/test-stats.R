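test_that("paired t-test matches the closed-form statistic", {
  set.seed(3)
  m <- matrix(rpois(40, 30), nrow = 10, ncol = 4)
  m[, 2] <- m[, 1] + 5 + round(rnorm(10, 0, 1))
  p <- pairwiseCountTtest(m, 1, 2)
  expect_lt(p, 0.001)
  # independent closed form: t = mean(d) / (sd(d)/sqrt(n)), n-1 df
  d <- m[, 1] - m[, 2]
  t_stat <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(p, 2 * pt(-abs(t_stat), length(d) - 1))
  # Welch unpaired variant also matches stats::t.test
  expect_equal(pairwiseCountTtest(m, 1, 3, paired = FALSE),
               t.test(m[, 1], m[, 3])$p.value)
})

test_that("degenerate t-test inputs give missing p or errors", {
  m <- matrix(rep(c(5L, 7L), each = 6), nrow = 6)
  expect_warning(p <- pairwiseCountTtest(m, 1, 2), "zero variance")
  expect_true(is.na(p))
  m1 <- matrix(c(1L, 2L), nrow = 1)
  expect_error(pairwiseCountTtest(m1, 1, 2), "at least 2 samples")
})

test_that("t-test p agrees with a permutation approximation", {
  set.seed(11)
  m <- cbind(a = rpois(12, 20), b = rpois(12, 26))
  p <- pairwiseCountTtest(m, 1, 2)
  d <- m[, 1] - m[, 2]
  t_obs <- abs(mean(d) / (sd(d) / sqrt(length(d))))
  perm <- replicate(4000, {
    s <- sample(c(-1, 1), length(d), replace = TRUE)
    ds <- d * s
    abs(mean(ds) / (sd(ds) / sqrt(length(ds))))
  })
  p_perm <- mean(perm >= t_obs - 1e-12)
  expect_lt(abs(p - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 4000) + 0.01)
})

test_that("Fisher p-values equal hypergeometric enumeration on examples", {
  prof <- makeProfile(d = c(1, 2, 3, 4),
                      pass = c(5, 5, 10, 0), false = c(5, 5, 0, 10))
  expect_equal(pairwiseFpFisher(prof, 1, 2), 1.0)
  expect_equal(pairwiseFpFisher(prof, 3, 4), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(IntronProfiler:::.fisher2x2(3, 1, 1, 3),
               fisherEnumOracle(3, 1, 1, 3), tolerance = 1e-12)
  expect_equal(round(IntronProfiler:::.fisher2x2(3, 1, 1, 3), 4), 0.4857)
  # empty bucket -> missing
  prof2 <- makeProfile(d = c(1, 2), pass = c(3, 0), false = c(1, 0))
  expect_true(is.na(pairwiseFpFisher(prof2, 1, 2)))
})

test_that("BH adjustment follows the step-up recurrence and is stable", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bhAdjust(0.07), 0.07)
  p <- matrix(NA_real_, 4, 4)
  vals <- c(0.001, 0.01, 0.02, 0.3, 0.04, 0.9)
  p[upper.tri(p)] <- vals
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  adj <- bhAdjust(p)
  expect_true(isSymmetric(adj))
  expect_true(all(adj[upper.tri(adj)] >= p[upper.tri(p)]))
  expect_true(all(adj[upper.tri(adj)] <= 1))
  # permutation invariance
  perm <- sample(4)
  adj2 <- bhAdjust(p[perm, perm])
  expect_equal(adj2, adj[perm, perm])
})

test_that("pairwise matrices are symmetric with missing diagonals", {
  set.seed(8)
  m <- matrix(rpois(50, 20), nrow = 10, ncol = 5)
  pm <- pairwiseMatrix(m, "t_test")
  expect_true(isSymmetric(pm$p))
  expect_true(all(is.na(diag(pm$p))))
  prof <- makeProfile(d = 1:4, pass = c(30, 40, 25, 10),
                      false = c(5, 2, 10, 30))
  pf <- pairwiseMatrix(prof, "fisher_exact")
  expect_true(isSymmetric(pf$p))
  expect_true(all(pf$p[upper.tri(pf$p)] > 0 & pf$p[upper.tri(pf$p)] <= 1))
  tmp <- tempfile(fileext = ".tsv")
  writePairwiseTable(pf, tmp)
  tab <- read.delim(tmp)
  expect_equal(nrow(tab), 6L)
  expect_named(tab, c("i", "j", "test", "p", "p_adj", "sig_05", "sig_01"))
})

test_that("flanking-vs-exonic comparison behaves across regimes", {
  x <- rep(0.5, 10)
  expect_warning(res <- flankingVsExonicFpTest(x, x), "zero variance")
  expect_true(is.na(res$p_t))
  set.seed(21)
  fe <- pmin(pmax(rnorm(50, 0.1, 0.01), 0), 1)
  ff <- fe + 0.15 + rnorm(50, 0, 0.02)
  res2 <- flankingVsExonicFpTest(ff, fe, c(100, 60), c(500, 25))
  expect_lt(res2$p_t, 1e-20)
  expect_lt(res2$p_fisher, 1e-10)
  expect_equal(res2$delta_fp, 0.15, tolerance = 0.05)
  # n = 2 with distinct differences: closed form with 1 df
  r3 <- flankingVsExonicFpTest(c(0.3, 0.5), c(0.1, 0.2))
  d <- c(0.2, 0.3)
  t_stat <- mean(d) / (sd(d) / sqrt(2))
  expect_equal(r3$p_t, 2 * pt(-abs(t_stat), 1))
})

test_that("power computation reproduces reference sample sizes", {
  expect_equal(powerSampleSize(0.5, alpha = 0.05, power = 0.95, tails = 2),
               54L)
  expect_equal(powerSampleSize(0.5, alpha = 0.05, power = 0.80, tails = 2),
               34L)
  # independent cross-check against stats::power.t.test
  ref <- ceiling(power.t.test(delta = 0.5, sd = 1, sig.level = 0.05,
                              power = 0.80, type = "paired")$n)
  expect_equal(powerSampleSize(0.5, 0.05, 0.80, 2), as.integer(ref))
  # a huge effect saturates at the smallest n whose single-digit degrees
  # of freedom can support the test at all
  expect_lte(powerSampleSize(10, 0.05, 0.80, 2), 3L)
  expect_error(powerSampleSize(0.001, 0.05, 0.999, 2, nMax = 50L),
               "not attainable")
})

test_that("power and sample size are monotone in their parameters", {
  n_base <- powerSampleSize(0.5, 0.05, 0.90)
  expect_lte(powerSampleSize(0.8, 0.05, 0.90), n_base)   # larger effect
  expect_lte(powerSampleSize(0.5, 0.10, 0.90), n_base)   # looser alpha
  expect_gte(powerSampleSize(0.5, 0.05, 0.99), n_base)   # more power
  pw <- vapply(c(10, 20, 40, 80), pairedTPower, numeric(1),
               effectSize = 0.5)
  expect_true(all(diff(pw) > 0))
})

test_that("per-sample count matrices and FP vectors are consistent", {
  ann <- toyAnnotation()
  dirp <- tempfile(); dir.create(dirp)
  mk <- function(s, pos, dp) {
    df <- cbind(data.frame(chrom = "1", pos = pos, ref = "A", alt = "G"),
                nominalQc())
    df$DP <- dp; df$DV <- pmin(dp, 10)
    writeTestVcf(df, file.path(dirp, paste0(s, ".vcf")), s)
  }
  # sample A: flanking d=9 (pass), d=9 another allele? same pos new ref ->
  # keep distinct positions; exonic at 1050 failing
  p1 <- mk("A", c(1109L, 1110L, 1050L), c(100L, 100L, 5L))
  p2 <- mk("B", c(1109L, 1495L), c(100L, 5L))
  vs <- readVcfCohort(c(p1, p2))
  m_raw <- sampleCountMatrix(vs, ann, "raw")
  expect_equal(dim(m_raw), c(2L, 200L))
  expect_equal(m_raw["A", "9"], 1L)
  expect_equal(m_raw["A", "10"], 1L)
  expect_equal(m_raw["B", "6"], 1L)   # 1495 is d = 6 from acceptor at 1500
  m_pass <- sampleCountMatrix(vs, ann, "pass")
  expect_equal(m_pass["B", "6"], 0L)  # DP = 5 fails
  fp <- perSampleFp(vs, ann, "exonic")
  expect_equal(unname(fp$fp["A"]), 1.0)  # the single exonic record fails
  expect_true(is.na(fp$fp["B"]))
  expect_equal(unname(fp$pooled), c(0, 1))
})
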