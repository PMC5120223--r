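#' @importFrom stats rpois rgamma rlnorm rnorm runif
NULL

#' Simulate a paired-replicate RIP-seq count table with planted bound set
#'
#' Generates transcript-level counts for `nReplicates` paired
#' (control-IP, knockdown-IP) libraries. Transcript abundances `q_i` are
#' log-normal; a planted subset of `nBound` transcripts is enriched
#' `enrichmentFold`-fold in the control-IP library of every replicate.
#' Counts are `Poisson(s_j * q_i * e_ij * G_ir)` where `G_ir ~
#' Gamma(1/dispersion, 1/dispersion)` is a transcript-specific
#' immunoprecipitation-efficiency factor *shared by the two libraries of a
#' replicate* (crosslinking and pull-down of a transcript vary between
#' experiments, but the paired libraries of one experiment share that
#' variation). Marginally each count is exactly
#' `NB(mean = s_j * q_i * e_ij, variance = mu + dispersion * mu^2)`;
#' `dispersion = 0` degenerates to Poisson. Because the pair shares `G_ir`,
#' the conditional binomial test of [testEnrichment()] is exactly calibrated
#' on these data.
#'
#' @param nTranscripts number of transcripts (default 2000).
#' @param nBound planted bound transcripts (default 50), `<= nTranscripts`;
#'   always planted as coding transcripts.
#' @param enrichmentFold mean control/knockdown IP ratio for bound
#'   transcripts (> 1; default 4).
#' @param dispersion NB dispersion `phi` (variance `mu + phi mu^2`),
#'   default 0.1.
#' @param nReplicates paired replicates (default 2).
#' @param librarySizeFactors relative sequencing depths, one per sample in
#'   order (ctrl rep1, sh rep1, ctrl rep2, sh rep2, ...); default
#'   `c(1.0, 1.3, 0.8, 1.1)` so library-size offsets are exercised.
#' @param meanDepth median IP depth (fragments) of an unenriched transcript
#'   at size factor 1 (default 50).
#' @param abundanceSdLog log-normal sd of transcript abundances (default 0.5).
#' @param noncodingFraction fraction of (unbound) transcripts labelled
#'   noncoding (default 0.05).
#' @param lengthRange transcript length range, nt (default 500-5000).
#' @param seed integer seed; same seed, identical table.
#' @return a list with `experiment` (a [RipExperiment-class]), `bound`
#'   (planted bound ids) and `truth` (data frame: `transcript_id`, `bound`,
#'   `biotype`).
#' @export
simulateRipCounts <- function(nTranscripts = 2000L, nBound = 50L,
                              enrichmentFold = 4, dispersion = 0.1,
                              nReplicates = 2L,
                              librarySizeFactors = c(1.0, 1.3, 0.8, 1.1),
                              meanDepth = 50, abundanceSdLog = 0.5,
                              noncodingFraction = 0.05,
                              lengthRange = c(500L, 5000L), seed = 1L) {
  if (nBound > nTranscripts) stop("'nBound' must be <= 'nTranscripts'")
  if (enrichmentFold <= 1) stop("'enrichmentFold' must be > 1")
  if (dispersion < 0) stop("'dispersion' must be >= 0")
  if (noncodingFraction < 0 || noncodingFraction > 1)
    stop("'noncodingFraction' must lie in [0, 1]")
  nSamples <- 2L * nReplicates
  if (length(librarySizeFactors) != nSamples)
    stop("need one library size factor per sample (", nSamples, ")")

  set.seed(seed)
  ids <- sprintf("tx%04d", seq_len(nTranscripts))
  boundIdx <- if (nBound > 0) sort(sample.int(nTranscripts, nBound))
              else integer(0)
  biotype <- rep("coding", nTranscripts)
  nonboundIdx <- setdiff(seq_len(nTranscripts), boundIdx)
  nNC <- round(noncodingFraction * length(nonboundIdx))
  if (nNC > 0) biotype[sample(nonboundIdx, nNC)] <- "noncoding"
  lengths <- sample(seq(lengthRange[1], lengthRange[2]), nTranscripts,
                    replace = TRUE)
  q <- rlnorm(nTranscripts, meanlog = log(meanDepth), sdlog = abundanceSdLog)

  condition <- rep(c("control_IP", "shCPEB4_IP"), nReplicates)
  replicate <- rep(seq_len(nReplicates), each = 2L)
  counts <- matrix(0L, nTranscripts, nSamples,
                   dimnames = list(ids, paste0(condition, "_rep", replicate)))
  for (r in seq_len(nReplicates)) {
    G <- if (dispersion > 0)
      rgamma(nTranscripts, shape = 1 / dispersion, rate = 1 / dispersion)
    else rep(1, nTranscripts)
    for (cond in c("control_IP", "shCPEB4_IP")) {
      j <- which(replicate == r & condition == cond)
      e <- rep(1, nTranscripts)
      if (cond == "control_IP") e[boundIdx] <- enrichmentFold
      counts[, j] <- rpois(nTranscripts,
                           librarySizeFactors[j] * q * e * G)
    }
  }
  x <- RipExperiment(counts, lengths, biotype, condition, replicate)
  list(experiment = x, bound = ids[boundIdx],
       truth = data.frame(transcript_id = ids,
                          bound = seq_len(nTranscripts) %in% boundIdx,
                          biotype = biotype))
}

## Random ACGU sequence with no catalogue hit, by whole-sequence rejection
## against the active catalogue (stays valid under reconfigured catalogues).
.patternFree <- function(len, concrete, maxTries = 2000L) {
  if (len == 0L) return("")
  flat <- unlist(concrete, use.names = FALSE)
  lens <- unique(nchar(flat))
  for (i in seq_len(maxTries)) {
    s <- paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
               collapse = "")
    win <- .windowTable(s, lens)
    hit <- any(vapply(flat,
                      function(pat) any(win[[as.character(nchar(pat))]] == pat),
                      logical(1)))
    if (!hit) return(s)
  }
  stop("could not sample a pattern-free background of length ", len,
       " (catalogue too dense); use shorter UTRs or a sparser catalogue")
}

#' Simulate 3'-UTRs with planted regulation classes
#'
#' Backgrounds are pattern-free by rejection sampling against the active
#' catalogue; planted designs implant exact element arrangements per
#' requested class: a consensus CPE followed, within the rule window, by a
#' consensus HEX (`activation_competent`); a CPE overlapping a HEX
#' (`repression_configured`, the `UUUUAAUAAA` arrangement); or nothing
#' (`non_regulated`). Each assembled sequence is verified to classify as
#' intended (junction-created spurious elements trigger resampling of the
#' background), so the emitted truth table is exact.
#'
#' @param n number of UTRs.
#' @param classMix named proportions over
#'   `activation_competent`/`repression_configured`/`non_regulated`
#'   (must sum to 1); class counts are allocated exactly
#'   (largest-remainder rounding).
#' @param lengthRange UTR length range, nt; must be able to host the designs.
#' @param catalogue,rules scanning catalogue and classification rules the
#'   plants are designed against.
#' @param transcriptIDs optional ids for the emitted UTRs (length `n`);
#'   defaults to `utr0001, ...`. Useful to tie the UTRs to the transcripts of
#'   a simulated count table.
#' @param seed integer seed.
#' @return a list with `utrs` (named `RNAStringSet`, `mcols()$biotype` set to
#'   `"coding"`) and `truth` (data frame: `transcript_id`, `klass`).
#' @export
simulateUTRs <- function(n = 100L,
                         classMix = c(activation_competent = 0.4,
                                      repression_configured = 0.3,
                                      non_regulated = 0.3),
                         lengthRange = c(120L, 260L),
                         catalogue = defaultCatalogue(),
                         rules = regulationRules(),
                         transcriptIDs = NULL, seed = 1L) {
  classMix <- unlist(classMix)            # accept a named list from configs
  if (!setequal(names(classMix), .REGULATION_CLASSES))
    stop("'classMix' must be named with the three regulation classes")
  if (abs(sum(classMix) - 1) > 1e-8 || any(classMix < 0))
    stop("'classMix' proportions must be non-negative and sum to 1")
  classMix <- classMix[.REGULATION_CLASSES]

  ## exact largest-remainder allocation
  raw <- classMix * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
  }

  concrete <- .concreteCatalogue(catalogue)
  dLo <- max(rules$dMin, 5L)
  dHi <- max(dLo, min(rules$dMax, 40L))
  designFor <- function(klass) {
    switch(klass,
      activation_competent = {
        gap <- sample(seq(dLo, dHi), 1L)
        list(parts = c("UUUUAU", "<GAP>", "AAUAAA"), gap = gap)
      },
      repression_configured = list(parts = "UUUUAAUAAA", gap = 0L),
      non_regulated = list(parts = character(0), gap = 0L))
  }
  minLen <- 6L + dHi + 6L + 10L
  if (lengthRange[1] < minLen)
    stop("'lengthRange' too short to host the planted designs (need >= ",
         minLen, " nt)")

  if (is.null(transcriptIDs)) transcriptIDs <- sprintf("utr%04d", seq_len(n))
  if (length(transcriptIDs) != n || anyDuplicated(transcriptIDs))
    stop("'transcriptIDs' must be ", n, " unique ids")
  set.seed(seed)
  klass <- rep(.REGULATION_CLASSES, cnt)
  klass <- sample(klass)                       # shuffle class order
  ids <- transcriptIDs
  seqs <- character(n)
  for (i in seq_len(n)) {
    len <- sample(seq(lengthRange[1], lengthRange[2]), 1L)
    for (try in seq_len(200L)) {
      d <- designFor(klass[i])
      insert <- if (length(d$parts) == 0) "" else
        paste(ifelse(d$parts == "<GAP>",
                     .patternFree(d$gap, concrete), d$parts),
              collapse = "")
      m <- nchar(insert)
      pos <- if (m == 0L) 0L else sample.int(len - m + 1L, 1L)
      left <- .patternFree(if (m == 0L) len else pos - 1L, concrete)
      right <- .patternFree(if (m == 0L) 0L else len - m - pos + 1L, concrete)
      s <- paste0(left, insert, right)
      call <- classifyRegulation(
        scanUTR(s, catalogue, transcriptID = ids[i]), rules)
      if (call$klass == klass[i]) { seqs[i] <- s; break }
    }
    if (!nzchar(seqs[i]))
      stop("failed to plant class '", klass[i], "' for ", ids[i])
  }
  utrs <- RNAStringSet(seqs)
  names(utrs) <- ids
  mcols(utrs)$biotype <- rep("coding", n)
  list(utrs = utrs, truth = data.frame(transcript_id = ids, klass = klass))
}

#' Simulate a two-channel cell intensity table with planted co-expression
#'
#' Emits `round(n * coexpressionFraction)` dual-expressing cells (correlated
#' bivariate log-normal intensities, clipped to the 8-bit range with both
#' channels at or above the background threshold) and splits the remainder
#' between red-only, green-only and background populations. Intensities are
#' integers in `[0, 255]`.
#'
#' @param n number of cells.
#' @param coexpressionFraction planted fraction of dual-expressing cells.
#' @param threshold background threshold (see [backgroundThreshold()]).
#' @param meanLog,sdLog log-scale location/scale of expressed-channel
#'   intensities.
#' @param correlation latent log-scale correlation of the dual population
#'   (default 0.7, the order of marker co-variation reported for dual-stained
#'   tumour tissue).
#' @param seed integer seed.
#' @return a list with `cells` (data frame `cell_id`, `red`, `green`),
#'   `truth` (data frame with the planted population per cell) and
#'   `fraction` (exact planted dual fraction, `nDual / n`).
#' @export
simulateCells <- function(n = 5000L, coexpressionFraction = 0.9,
                          threshold = backgroundThreshold(),
                          meanLog = log(120), sdLog = 0.35,
                          correlation = 0.7, seed = 1L) {
  if (coexpressionFraction < 0 || coexpressionFraction > 1)
    stop("'coexpressionFraction' must lie in [0, 1]")
  set.seed(seed)
  nDual <- round(n * coexpressionFraction)
  nRest <- n - nDual
  nRed <- floor(nRest / 3); nGreen <- floor(nRest / 3)
  nBg <- nRest - nRed - nGreen

  clipHi <- function(x) pmin(255L, pmax(0L, as.integer(round(x))))
  expressed <- function(m) {
    z1 <- rnorm(m); z2 <- correlation * z1 +
      sqrt(1 - correlation^2) * rnorm(m)
    cbind(exp(meanLog + sdLog * z1), exp(meanLog + sdLog * z2))
  }
  dual <- expressed(nDual)
  dual <- cbind(pmax(threshold, clipHi(dual[, 1])),
                pmax(threshold, clipHi(dual[, 2])))
  lowSig <- function(m) if (m > 0) sample(0:max(0L, threshold - 1L), m,
                                          replace = TRUE) else integer(0)
  red <- cbind(pmax(threshold, clipHi(exp(meanLog + sdLog * rnorm(nRed)))),
               lowSig(nRed))
  green <- cbind(lowSig(nGreen),
                 pmax(threshold,
                      clipHi(exp(meanLog + sdLog * rnorm(nGreen)))))
  bg <- cbind(lowSig(nBg), lowSig(nBg))
  mat <- rbind(dual, red, green, bg)
  pop <- rep(c("dual", "red_only", "green_only", "background"),
             c(nDual, nRed, nGreen, nBg))
  o <- sample.int(n)
  cells <- data.frame(cell_id = sprintf("cell%05d", seq_len(n)),
                      red = as.integer(mat[o, 1]),
                      green = as.integer(mat[o, 2]))
  list(cells = cells,
       truth = data.frame(cell_id = cells$cell_id, population = pop[o]),
       fraction = nDual / n)
}
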