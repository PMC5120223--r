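#' @importFrom stats cor.test
NULL

#' Build a deterministic ranked gene list
#'
#' Stores genes sorted by decreasing ranking statistic (e.g. a t statistic
#' contrasting a lineage against the rest), with ties broken by gene id
#' (lexicographic) so the ranking is fully deterministic.
#'
#' @param geneIDs unique gene identifiers.
#' @param stat finite ranking statistic, one value per gene.
#' @return a `DataFrame` with columns `gene_id` and `stat`, sorted, of class
#'   contract used by [enrichmentScore()] and [permutationTest()].
#' @export
rankedList <- function(geneIDs, stat) {
  geneIDs <- as.character(geneIDs)
  if (length(geneIDs) != length(stat))
    stop("'geneIDs' and 'stat' must have equal length")
  if (anyDuplicated(geneIDs))
    stop("gene ids must be unique")
  if (any(!is.finite(stat)))
    stop("ranking statistics must be finite")
  o <- order(-stat, geneIDs)
  DataFrame(gene_id = geneIDs[o], stat = as.numeric(stat[o]))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list top to bottom accumulating a running sum: a gene in
#' the set ("hit") adds its weight `|stat|^weight` (normalized so all hit
#' weights sum to 1), a gene outside the set ("miss") subtracts
#' `1 / (N - Nhit)`. The enrichment score is the running-sum value of maximum
#' absolute deviation from zero (signed); `weight = 0` gives the classical
#' unweighted KS statistic.
#'
#' @param ranking a [rankedList()] (or any data frame with `gene_id`, `stat`).
#' @param geneSet character vector of gene ids; its intersection with the
#'   ranking must be non-empty and strictly smaller than the ranking.
#' @param weight exponent on `|stat|` for hit increments (default 1).
#' @return a list with `es` (in `[-1, 1]`) and `running` (length-N numeric).
#' @export
enrichmentScore <- function(ranking, geneSet, weight = 1) {
  hit <- ranking$gene_id %in% geneSet
  nHit <- sum(hit)
  N <- length(hit)
  if (nHit == 0L) stop("gene set does not intersect the ranking")
  if (nHit == N) stop("gene set covers the whole ranking (degenerate)")
  w <- abs(ranking$stat)^weight
  inc <- numeric(N)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (N - nHit)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' Permutation test for gene-set enrichment
#'
#' Builds a null distribution for each gene set by drawing `nPerm` random
#' same-size gene sets from the ranking (gene-label permutation),
#' `perm_p = (1 + #permutations with |es_null| >= |es|) / (1 + nPerm)`.
#' Permutation p-values are BH-adjusted across the supplied sets, and sets
#' with `fdr_q < fdrMax` are flagged enriched (default cutoff 0.25, the
#' conventional exploratory GSEA threshold).
#'
#' @inheritParams enrichmentScore
#' @param geneSets a named list of gene-id vectors (a single character vector
#'   is treated as one set named `"set1"`).
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed; the same seed always gives identical results.
#' @param fdrMax BH threshold for the `enriched` flag.
#' @return a `DataFrame` with one row per set: `set`, `size` (genes in the
#'   ranking), `es`, `perm_p`, `fdr_q`, `enriched`, `n_perm`.
#' @export
permutationTest <- function(ranking, geneSets, nPerm = 1000L, seed = 1L,
                            weight = 1, fdrMax = 0.25) {
  if (is.character(geneSets)) geneSets <- list(set1 = geneSets)
  if (is.null(names(geneSets)) || any(!nzchar(names(geneSets))))
    stop("gene sets must be named")
  nPerm <- as.integer(nPerm)
  if (nPerm < 100L) stop("need nPerm >= 100")
  N <- nrow(ranking)
  w <- abs(ranking$stat)^weight

  esOf <- function(hit) {
    nHit <- sum(hit)
    inc <- numeric(N)
    inc[hit] <- w[hit] / sum(w[hit])
    inc[!hit] <- -1 / (N - nHit)
    running <- cumsum(inc)
    running[which.max(abs(running))]
  }

  set.seed(seed)
  es <- numeric(length(geneSets))
  permP <- numeric(length(geneSets))
  size <- integer(length(geneSets))
  for (i in seq_along(geneSets)) {
    hit <- ranking$gene_id %in% geneSets[[i]]
    k <- sum(hit)
    if (k == 0L || k == N)
      stop("gene set '", names(geneSets)[i],
           "' is empty or covers the whole ranking")
    size[i] <- k
    es[i] <- esOf(hit)
    null <- vapply(seq_len(nPerm), function(b) {
      hb <- logical(N)
      hb[sample.int(N, k)] <- TRUE
      esOf(hb)
    }, numeric(1))
    permP[i] <- (1 + sum(abs(null) >= abs(es[i]))) / (1 + nPerm)
  }
  q <- bhAdjust(permP)
  DataFrame(set = names(geneSets), size = size, es = es, perm_p = permP,
            fdr_q = q, enriched = q < fdrMax, n_perm = nPerm)
}

#' Compare two target sets
#'
#' Exact set arithmetic between two collections of transcript/gene ids, e.g.
#' bound sets called in two cell systems.
#'
#' @param setA,setB character vectors of ids (duplicates collapsed).
#' @return a list with `shared`, `uniqueA`, `uniqueB` (id vectors) and
#'   `fraction_uniqueA` = `|A \ B| / |A|`.
#' @examples
#' compareTargetSets(c("a", "b", "c"), c("c", "d"))$fraction_uniqueA # 2/3
#' @export
compareTargetSets <- function(setA, setB) {
  setA <- unique(as.character(setA)); setB <- unique(as.character(setB))
  if (length(setA) == 0L)
    stop("'setA' is empty: fraction of unique targets is undefined")
  shared <- intersect(setA, setB)
  uniqueA <- setdiff(setA, setB)
  list(shared = shared, uniqueA = uniqueA, uniqueB = setdiff(setB, setA),
       fraction_uniqueA = length(uniqueA) / length(setA))
}

#' Pearson/Spearman concordance of two effect-size vectors
#'
#' Computes both correlation coefficients with two-sided p-values for paired
#' log2 fold changes from two analysis methods (or two cell systems). The
#' `significant` flag follows a coefficient-threshold convention (both
#' coefficients > 0.5), which is unusual — most analyses threshold the
#' p-value — but is retained here as the decision rule of the upstream
#' protocol this mirrors; report `pearson_p`/`spearman_p` when a standard
#' test is wanted.
#'
#' @param x,y paired finite numeric vectors, length >= 3.
#' @return a list with `pearson_r`, `pearson_p`, `spearman_r`, `spearman_p`,
#'   `significant`.
#' @export
methodConcordance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need paired vectors of length >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  pe <- cor.test(x, y, method = "pearson")
  sp <- cor.test(x, y, method = "spearman", exact = FALSE)
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_r = unname(sp$estimate), spearman_p = sp$p.value,
       significant = unname(pe$estimate) > 0.5 && unname(sp$estimate) > 0.5)
}
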