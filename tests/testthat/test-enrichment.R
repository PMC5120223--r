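test_that("FPKM arithmetic and scale invariance", {
  expect_equal(computeFPKM(10, 1000, 1e6), 10)
  expect_equal(computeFPKM(0, 123, 456), 0)
  expect_equal(computeFPKM(3, 500, 2e6), 3)
  expect_error(computeFPKM(1, 100, 0), "library size")
  # doubling counts and library size together leaves FPKM unchanged
  set.seed(1)
  x <- rpois(20, 40); len <- sample(200:2000, 20); ls <- 5e5
  expect_equal(computeFPKM(2 * x, len, 2 * ls), computeFPKM(x, len, ls))
})

test_that("conditional binomial test matches closed forms and binom.test", {
  expect_equal(testEnrichment(0, 0, 1e6, 2e6), 1)
  expect_equal(testEnrichment(10, 0, 1e6, 1e6), 0.5^10)
  expect_equal(testEnrichment(5, 5, 1e6, 1e6), 638 / 1024)
  expect_error(testEnrichment(-1, 0, 1, 1), "non-negative")
  expect_error(testEnrichment(1, 0, 0, 1), "library sizes")
  # independent route: stats::binom.test one-sided tail
  set.seed(2)
  for (i in 1:25) {
    xc <- rpois(1, 30); xs <- rpois(1, 30)
    sc <- runif(1, 5e5, 2e6); ss <- runif(1, 5e5, 2e6)
    if (xc + xs == 0) next
    want <- binom.test(xc, xc + xs, sc / (sc + ss),
                       alternative = "greater")$p.value
    expect_equal(testEnrichment(xc, xs, sc, ss), want)
  }
})

test_that("NB likelihood-ratio variant is one-sided and sane", {
  # strong enrichment -> small p; depletion -> p near 1
  expect_lt(testEnrichmentNB(400, 50, 1e6, 1e6), 0.01)
  expect_gt(testEnrichmentNB(50, 400, 1e6, 1e6), 0.99)
  expect_equal(testEnrichmentNB(0, 0, 1e6, 1e6), 1)
  # dispersion 0 reduces to the Poisson deviance test, more powerful
  expect_lt(testEnrichmentNB(100, 50, 1e6, 1e6, dispersion = 0),
            testEnrichmentNB(100, 50, 1e6, 1e6, dispersion = 0.1))
})

test_that("BH adjustment matches the longhand step-up oracle", {
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhAdjust(p), oracle_bh(p))
  }
  # q >= p always
  p <- runif(500)
  expect_true(all(bhAdjust(p) >= p))
})

test_that("callTargets applies floor, test, BH, direction, biotype, intersection", {
  # one replicate, five transcripts engineered to exercise each filter:
  # t1 keep; t2 fails BH; t3 below FPKM floor in both; t4 enriched but
  # noncoding; t5 keep
  counts <- cbind(control_IP_rep1 = c(100L, 6L, 0L, 100L, 100L),
                  shCPEB4_IP_rep1 = c(0L, 2L, 0L, 0L, 0L))
  rownames(counts) <- paste0("t", 1:5)
  x <- RipExperiment(counts, lengths = rep(1000L, 5),
                     biotypes = c("coding", "coding", "coding",
                                  "noncoding", "coding"),
                     condition = c("control_IP", "shCPEB4_IP"),
                     replicate = c(1L, 1L),
                     librarySizes = c(1e6, 1e6))
  res <- callTargets(x)
  rec <- res$records[["1"]]
  expect_identical(res$bound, c("t1", "t5"))
  expect_true(rec$low_expression[3])
  expect_true(is.na(rec$p[3]))                       # floored, never tested
  # BH over the 4 tested transcripts: t2 p = P(Bin(8,1/2) >= 6) = 37/256
  expect_equal(rec$p[2], 37 / 256)
  expect_equal(rec$q[2], 37 / 256)                   # largest p, q = p
  expect_false(rec$significant[2])
  expect_true(rec$significant[4] && !rec$bound[4])   # noncoding excluded
  expect_true(all(rec$q >= rec$p, na.rm = TRUE))

  # a transcript significant in replicate 1 only is dropped by intersection
  counts2 <- cbind(control_IP_rep1 = c(100L, 80L), shCPEB4_IP_rep1 = c(0L, 0L),
                   control_IP_rep2 = c(100L, 10L), shCPEB4_IP_rep2 = c(0L, 10L))
  rownames(counts2) <- c("a", "b")
  x2 <- RipExperiment(counts2, c(1000L, 1000L), c("coding", "coding"),
                      condition = rep(c("control_IP", "shCPEB4_IP"), 2),
                      replicate = c(1L, 1L, 2L, 2L),
                      librarySizes = rep(1e6, 4))
  res2 <- callTargets(x2)
  expect_true(res2$records[["1"]]$bound[2])
  expect_false(res2$records[["2"]]$bound[2])
  expect_identical(res2$bound, "a")
})

test_that("callTargets rejects a replicate missing a condition", {
  counts <- cbind(control_IP_rep1 = c(5L, 5L))
  rownames(counts) <- c("a", "b")
  x <- RipExperiment(counts, c(100L, 100L), c("coding", "coding"),
                     condition = "control_IP", replicate = 1L,
                     librarySizes = 10)
  expect_error(callTargets(x), "replicate 1")
})

test_that("RipExperiment validity catches malformed containers", {
  counts <- cbind(a = c(1L, 2L), b = c(3L, 4L))
  rownames(counts) <- c("t1", "t2")
  expect_error(RipExperiment(counts, c(100L, 100L), c("coding", "coding"),
                             condition = c("IP", "input"),
                             replicate = c(1L, 1L)),
               "condition")
  expect_error(RipExperiment(counts, c(100L, 100L), c("coding", "coding"),
                             condition = c("control_IP", "control_IP"),
                             replicate = c(1L, 1L)),
               "unique")
  expect_error(RipExperiment(counts, c(0L, 100L), c("coding", "coding"),
                             condition = c("control_IP", "shCPEB4_IP"),
                             replicate = c(1L, 1L)),
               "length")
})

test_that("qPCR fold enrichment follows delta-delta-Ct", {
  expect_equal(ripFoldEnrichment(20, 18, 25, 23), 1)   # equal delta-Ct
  expect_equal(ripFoldEnrichment(19, 18, 25, 23), 2)   # one cycle earlier
  expect_equal(ripFoldEnrichment(20, 18, 26, 18), 64)
  expect_error(ripFoldEnrichment(Inf, 18, 26, 18), "finite")
})

test_that("the conditional test holds its level on null paired pull-downs", {
  # no planted targets: p-values should be conservative at 5%
  sim <- simulateRipCounts(nTranscripts = 2000L, nBound = 0L,
                           enrichmentFold = 4, dispersion = 0.1,
                           librarySizeFactors = rep(1, 4), seed = 17)
  cnt <- SummarizedExperiment::assay(sim$experiment, "counts")
  p <- testEnrichment(cnt[, 1], cnt[, 2], sum(cnt[, 1]), sum(cnt[, 2]))
  se3 <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_lte(mean(p < 0.05), 0.05 + se3)
})
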