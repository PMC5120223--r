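# Build a MotifMap directly from interval specs, bypassing the scanner.
make_map <- function(len, starts, ends, kinds, id = "t") {
  o <- order(starts, ends, kinds)
  h <- IRanges::IRanges(start = starts[o], end = ends[o])
  S4Vectors::mcols(h) <- S4Vectors::DataFrame(kind = kinds[o],
                                              pattern = rep("x", length(o)))
  cpeTargets:::MotifMap(id, len, h)
}

test_that("rule table gives the expected class on canonical configurations", {
  # no CPE of either kind -> not a polyadenylation target
  m <- make_map(200L, c(10L), c(15L), c("HEX"))
  expect_identical(classifyRegulation(m)$klass, "non_regulated")

  # CPE ending 30 nt upstream of a HEX, no overlap -> activation-competent
  m <- make_map(200L, c(10L, 47L), c(16L, 52L), c("CPE", "HEX"))
  call <- classifyRegulation(m)
  expect_identical(call$klass, "activation_competent")
  expect_identical(call$dist_cpe_hex, 30L)
  expect_false(call$cpe_hex_overlap)

  # CPE over [1,7], HEX over [5,10]: shared positions -> repression
  m <- make_map(50L, c(1L, 5L), c(7L, 10L), c("CPE", "HEX"))
  call <- classifyRegulation(m)
  expect_identical(call$klass, "repression_configured")
  expect_true(call$cpe_hex_overlap)
  expect_identical(call$dist_cpe_hex, 0L)
})

test_that("rule table is exhaustively correct over distance/overlap grid", {
  rules <- regulationRules(dMin = 0L, dMax = 100L)
  # CPE fixed at [10,16]; HEX placed at every offset in a window around it
  for (hexStart in c(2L, 8L, 14L, 17L, 20L, 60L, 117L, 118L, 150L)) {
    hexEnd <- hexStart + 5L
    m <- make_map(300L, c(10L, hexStart), c(16L, hexEnd), c("CPE", "HEX"))
    call <- classifyRegulation(m, rules)
    overlaps <- hexStart <= 16L && hexEnd >= 10L
    gap <- if (overlaps) 0L else
      if (hexStart > 16L) hexStart - 16L - 1L else 10L - hexEnd - 1L
    want <- if (overlaps) "repression_configured"
      else if (gap <= 100L) "activation_competent" else "non_regulated"
    expect_identical(call$klass, want, label = paste("hex at", hexStart))
    if (!overlaps)
      expect_identical(call$dist_cpe_hex, gap)
  }
})

test_that("non-consensus CPEs count toward activation, HEXNC does not", {
  m <- make_map(200L, c(10L, 30L), c(17L, 35L), c("CPENC", "HEX"))
  expect_identical(classifyRegulation(m)$klass, "activation_competent")
  # a non-consensus hexamer alone does not satisfy the HEX requirement
  m2 <- make_map(200L, c(10L, 30L), c(16L, 35L), c("CPE", "HEXNC"))
  expect_identical(classifyRegulation(m2)$klass, "non_regulated")
})

test_that("every map receives exactly one class and features are populated", {
  set.seed(99)
  kinds <- c("CPE", "CPENC", "HEX", "HEXNC", "ARE", "PBS")
  for (i in 1:50) {
    n <- sample(0:6, 1)
    starts <- if (n) sort(sample.int(140L, n)) else integer(0)
    m <- make_map(160L, starts, starts + 5L,
                  if (n) sample(kinds, n, replace = TRUE) else character(0))
    call <- classifyRegulation(m)
    expect_true(call$klass %in% c("activation_competent",
                                  "repression_configured", "non_regulated"))
    expect_false(anyNA(call[c("n_cpe", "n_cpe_nc", "n_hex", "n_are",
                              "n_pbs", "cpe_hex_overlap")]))
    # distance present iff both a CPE-family and a consensus HEX hit exist
    expect_identical(is.na(call$dist_cpe_hex),
                     call$n_cpe + call$n_cpe_nc == 0L || call$n_hex == 0L)
  }
})

test_that("the distance window is configurable", {
  m <- make_map(300L, c(10L, 67L), c(16L, 72L), c("CPE", "HEX")) # gap 50
  expect_identical(classifyRegulation(m, regulationRules(0, 100))$klass,
                   "activation_competent")
  expect_identical(classifyRegulation(m, regulationRules(0, 30))$klass,
                   "non_regulated")
  expect_identical(classifyRegulation(m, regulationRules(60, 100))$klass,
                   "non_regulated")
  expect_error(regulationRules(10, 5))
})

test_that("scanBatch preserves order, filters, and rejects duplicates", {
  seqs <- Biostrings::RNAStringSet(c(
    act = paste0("GGCG", "UUUUAU", strrep("C", 20), "AAUAAA", "GGCGGC"),
    rep_ = "GGCGUUUUAAUAAAGGCGGC",
    none = "GGCGCCGGCGCGGCCGGCGC"))
  res <- scanBatch(seqs)
  expect_identical(res$calls$transcript_id, c("act", "rep_", "none"))
  expect_identical(res$calls$klass,
                   c("activation_competent", "repression_configured",
                     "non_regulated"))
  expect_identical(res$regulated, c("act", "rep_"))

  dup <- Biostrings::RNAStringSet(c(a = "ACGU", a = "ACGG"))
  expect_error(scanBatch(dup), "duplicate transcript id.*a")

  empty <- Biostrings::RNAStringSet()
  names(empty) <- character(0)
  res0 <- scanBatch(empty)
  expect_identical(nrow(res0$calls), 0L)
  expect_identical(res0$regulated, character(0))
})

test_that("scanBatch output is reproducible on identical input", {
  set.seed(5)
  seqs <- Biostrings::RNAStringSet(setNames(random_rna(20, 80, 30),
                                            paste0("s", 1:20)))
  r1 <- scanBatch(seqs)
  r2 <- scanBatch(seqs)
  expect_identical(as.data.frame(r1$calls), as.data.frame(r2$calls))
  expect_identical(lapply(r1$maps, map_as_table),
                   lapply(r2$maps, map_as_table))
})
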