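make_ranking <- function(N, seed = 1) {
  set.seed(seed)
  rankedList(sprintf("g%03d", 1:N), round(rnorm(N), 6))
}

test_that("ranked lists are sorted descending with lexicographic tie-break", {
  r <- rankedList(c("b", "a", "c"), c(1, 2, 1))
  expect_identical(r$gene_id, c("a", "b", "c"))
  expect_identical(r$stat, c(2, 1, 1))
  expect_error(rankedList(c("a", "a"), c(1, 2)), "unique")
  expect_error(rankedList("a", NaN), "finite")
})

test_that("enrichment score hits its closed-form extremes", {
  r <- make_ranking(100)
  # the top 10 genes as the set, unweighted: all hits precede all misses
  top <- r$gene_id[1:10]
  expect_equal(enrichmentScore(r, top, weight = 0)$es, 1)
  # a set at the very bottom mirrors to -1 + k/N at best before the hits,
  # and the maximum deviation is the pre-hit deficit
  expect_error(enrichmentScore(r, "absent"), "intersect")
  expect_error(enrichmentScore(r, r$gene_id), "degenerate")
})

test_that("unweighted score equals the enumeration oracle", {
  r10 <- make_ranking(10)
  got <- enrichmentScore(r10, r10$gene_id[c(2, 5, 9)], weight = 0)
  expect_equal(got$es, oracle_es_unweighted(10, c(2, 5, 9)))
  # exhaustive over all placements for small N
  for (N in 4:8) {
    rN <- make_ranking(N, seed = N)
    sets <- combn(N, 2, simplify = FALSE)
    for (s in sets) {
      expect_equal(enrichmentScore(rN, rN$gene_id[s], weight = 0)$es,
                   oracle_es_unweighted(N, s),
                   label = paste("N =", N, "set", paste(s, collapse = ",")))
    }
  }
})

test_that("reversing the ranking mirrors the position pattern (weight 0)", {
  set.seed(8)
  for (i in 1:20) {
    N <- 12L
    pos <- sort(sample.int(N, 4))
    r <- make_ranking(N, seed = i)
    fwd <- enrichmentScore(r, r$gene_id[pos], weight = 0)$es
    # the same gene set on the reversed list occupies mirrored positions
    r_rev <- r[rev(seq_len(N)), ]
    rev_es <- enrichmentScore(r_rev, r$gene_id[pos], weight = 0)$es
    expect_equal(rev_es, oracle_es_unweighted(N, N + 1L - rev(pos)))
    expect_equal(fwd, oracle_es_unweighted(N, pos))
  }
})

test_that("weighted score agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(21)
  for (i in 1:10) {
    N <- 50L
    r <- make_ranking(N, seed = 100 + i)
    s <- sample(r$gene_id, 8)
    got <- enrichmentScore(r, s, weight = 1)$es
    stats <- setNames(r$stat, r$gene_id)
    want <- fgsea::calcGseaStat(stats, selectedStats = which(r$gene_id %in% s),
                                gseaParam = 1, scoreType = "std")
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("es stays within [-1, 1] over randomized trials", {
  set.seed(31)
  for (i in 1:50) {
    N <- sample(10:80, 1)
    r <- make_ranking(N, seed = 1000 + i)
    k <- sample(1:(N - 1), 1)
    for (w in c(0, 1)) {
      es <- enrichmentScore(r, sample(r$gene_id, k), weight = w)$es
      expect_gte(es, -1); expect_lte(es, 1)
    }
  }
})

test_that("permutation test is reproducible and pins extreme sets", {
  r <- make_ranking(200)
  sets <- list(top = r$gene_id[1:15],
               rand = sample(r$gene_id, 15))
  a <- permutationTest(r, sets, nPerm = 200, seed = 5)
  b <- permutationTest(r, sets, nPerm = 200, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # a perfectly separated top set: no null permutation can beat it
  expect_equal(a$perm_p[1], 1 / 201)
  expect_true(all(a$perm_p >= 0 & a$perm_p <= 1))
  expect_true(all(a$fdr_q >= a$perm_p))
  expect_error(permutationTest(r, list(s = "nope"), nPerm = 100, seed = 1),
               "empty")
  expect_error(permutationTest(r, sets, nPerm = 10, seed = 1), "nPerm")
})

test_that("set comparison does exact arithmetic", {
  A <- paste0("m", 1:331)
  B <- c(paste0("m", 1:19), paste0("r", 1:500))   # 19 shared
  cmp <- compareTargetSets(A, B)
  expect_identical(length(cmp$uniqueA), 312L)
  expect_equal(cmp$fraction_uniqueA, 312 / 331)
  expect_equal(compareTargetSets(A, A)$fraction_uniqueA, 0)
  expect_equal(compareTargetSets(A, "zzz")$fraction_uniqueA, 1)
  expect_error(compareTargetSets(character(0), A), "empty")
})

test_that("method concordance reports both coefficients faithfully", {
  x <- c(0.5, -1.2, 2.1, 0.3, -0.7, 1.8, 0.9, -2.2, 1.1, 0.2)
  same <- methodConcordance(x, x)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$spearman_r, 1)
  expect_true(same$significant)

  y <- exp(x)   # monotone, nonlinear
  mc <- methodConcordance(x, y)
  expect_equal(mc$spearman_r, 1)
  expect_lt(mc$pearson_r, 1)

  # brute-force Pearson from the covariance formula
  z <- c(1.2, 0.3, -0.8, 2.2, 0.0, -1.5, 0.7, 1.9, -0.2, 0.5)
  r_hand <- sum((x - mean(x)) * (z - mean(z))) /
    sqrt(sum((x - mean(x))^2) * sum((z - mean(z))^2))
  rho_hand <- {
    rx <- rank(x); rz <- rank(z)
    sum((rx - mean(rx)) * (rz - mean(rz))) /
      sqrt(sum((rx - mean(rx))^2) * sum((rz - mean(rz))^2))
  }
  mc2 <- methodConcordance(x, z)
  expect_equal(mc2$pearson_r, r_hand)
  expect_equal(mc2$spearman_r, rho_hand)
  expect_error(methodConcordance(x, rep(1, 10)), "variance")
  expect_error(methodConcordance(1:2, 1:2), "length >= 3")
})
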