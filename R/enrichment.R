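#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#'   rowData<- colData<-
#' @importFrom stats pbinom p.adjust dnbinom pchisq setNames
NULL

.CONDITIONS <- c("control_IP", "shCPEB4_IP")

#' RipExperiment: transcript-level RIP-seq count container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with the annotation
#' the enrichment caller needs: a `counts` assay of non-negative integers,
#' `rowData` columns `length` (nt) and `biotype` (`coding`/`noncoding`), and
#' `colData` columns `condition` (`control_IP` or `shCPEB4_IP`), `replicate`
#' and `library_size` (total mapped fragments, at least the column sum).
#'
#' @export
setClass("RipExperiment", contains = "SummarizedExperiment")

setValidity("RipExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cnt <- assay(object, "counts")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    msg <- c(msg, "counts must be non-negative integers")
  rd <- rowData(object); cd <- colData(object)
  if (!all(c("length", "biotype") %in% colnames(rd)))
    msg <- c(msg, "rowData needs 'length' and 'biotype'")
  else {
    if (any(rd$length < 1)) msg <- c(msg, "transcript lengths must be >= 1")
    if (!all(rd$biotype %in% c("coding", "noncoding")))
      msg <- c(msg, "biotype must be 'coding' or 'noncoding'")
  }
  if (!all(c("condition", "replicate", "library_size") %in% colnames(cd)))
    msg <- c(msg, "colData needs 'condition', 'replicate', 'library_size'")
  else {
    if (!all(cd$condition %in% .CONDITIONS))
      msg <- c(msg, "condition must be 'control_IP' or 'shCPEB4_IP'")
    if (anyDuplicated(paste(cd$condition, cd$replicate)))
      msg <- c(msg, "every (condition, replicate) pair must be unique")
    if (any(cd$library_size < colSums(cnt)))
      msg <- c(msg, "library_size must be >= the column sum of counts")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RipExperiment
#'
#' @param counts integer matrix, transcripts x samples, with rownames
#'   (transcript ids) and colnames (sample ids).
#' @param lengths transcript lengths in nt (recycled/matched to rows).
#' @param biotypes `"coding"`/`"noncoding"` per transcript.
#' @param condition,replicate sample metadata, one entry per column.
#' @param librarySizes total mapped fragments per sample; defaults to the
#'   column sums of `counts`.
#' @return a [RipExperiment-class] object.
#' @export
RipExperiment <- function(counts, lengths, biotypes, condition, replicate,
                          librarySizes = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(librarySizes)) librarySizes <- colSums(counts)
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(length = as.integer(lengths),
                        biotype = as.character(biotypes)),
    colData = DataFrame(condition = as.character(condition),
                        replicate = as.integer(replicate),
                        library_size = as.numeric(librarySizes)))
  new("RipExperiment", se)
}

#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @describeIn RipExperiment library sizes (total mapped fragments) per sample
#' @param x a `RipExperiment`.
#' @export
setMethod("librarySizes", "RipExperiment",
          function(x) setNames(colData(x)$library_size, colnames(x)))

#' @export
setGeneric("txLengths", function(x) standardGeneric("txLengths"))

#' @describeIn RipExperiment transcript lengths in nucleotides
#' @export
setMethod("txLengths", "RipExperiment",
          function(x) setNames(rowData(x)$length, rownames(x)))

#' @export
setGeneric("txBiotypes", function(x) standardGeneric("txBiotypes"))

#' @describeIn RipExperiment transcript biotypes
#' @export
setMethod("txBiotypes", "RipExperiment",
          function(x) setNames(rowData(x)$biotype, rownames(x)))

#' Fragments per kilobase of transcript per million mapped reads
#'
#' `FPKM = counts * 1e9 / (length_nt * library_size)`. Vectorized over
#' transcripts; doubling all counts together with the library size leaves the
#' value unchanged.
#'
#' @param counts fragment counts.
#' @param lengthNt transcript length(s), nt, >= 1.
#' @param librarySize total mapped fragments in the sample, >= 1.
#' @return numeric FPKM values.
#' @examples
#' computeFPKM(10, 1000, 1e6) # 10
#' @export
computeFPKM <- function(counts, lengthNt, librarySize) {
  if (any(librarySize < 1)) stop("library size must be >= 1")
  if (any(lengthNt < 1)) stop("transcript length must be >= 1")
  if (any(counts < 0)) stop("counts must be non-negative")
  counts * 1e9 / (lengthNt * librarySize)
}

#' Exact conditional binomial enrichment test
#'
#' One-sided test for enrichment of a transcript in the control-IP library
#' relative to the knockdown-IP library of the same replicate. Conditional on
#' the pair total `t = xCtrl + xSh`, the control count is
#' `Binomial(t, sCtrl / (sCtrl + sSh))` under the null of equal underlying
#' rates, so `p = P(X >= xCtrl)`; `p = 1` when `t = 0`. The conditioning
#' cancels any multiplicative factor shared by the two libraries of a pair
#' (transcript-specific immunoprecipitation efficiency), which is what makes
#' the test exact for paired pull-downs; it does *not* absorb overdispersion
#' that is independent between the two libraries (see [testEnrichmentNB()]).
#'
#' @param xCtrl,xSh fragment counts in the control-IP and knockdown-IP
#'   samples (vectorized).
#' @param sCtrl,sSh library sizes of the two samples.
#' @return one-sided p-values in `[0, 1]`.
#' @examples
#' testEnrichment(10, 0, 1e6, 1e6) # 0.5^10
#' @export
testEnrichment <- function(xCtrl, xSh, sCtrl, sSh) {
  if (any(xCtrl < 0) || any(xSh < 0)) stop("counts must be non-negative")
  if (any(sCtrl <= 0) || any(sSh <= 0)) stop("library sizes must be > 0")
  t <- xCtrl + xSh
  pi0 <- sCtrl / (sCtrl + sSh)
  p <- pbinom(xCtrl - 1, t, pi0, lower.tail = FALSE)
  p[t == 0] <- 1
  p
}

#' Negative-binomial likelihood-ratio enrichment test (fixed dispersion)
#'
#' One-sided likelihood-ratio test of a common rate against sample-specific
#' rates, with counts modelled `NB(mean, dispersion)` (variance
#' `mu + dispersion * mu^2`) independently in the two libraries. Intended for
#' simulation studies of the regime where the paired libraries carry
#' *independent* overdispersion — there the conditional binomial test of
#' [testEnrichment()] is anti-conservative, while this test is asymptotically
#' calibrated (at a substantial cost in power for single-pair designs).
#'
#' @inheritParams testEnrichment
#' @param dispersion NB dispersion (0 reduces to the Poisson deviance test).
#' @return one-sided p-values.
#' @export
testEnrichmentNB <- function(xCtrl, xSh, sCtrl, sSh, dispersion = 0.1) {
  if (any(xCtrl < 0) || any(xSh < 0)) stop("counts must be non-negative")
  if (dispersion < 0) stop("dispersion must be >= 0")
  q0 <- (xCtrl + xSh) / (sCtrl + sSh)
  ll <- function(x, mu) {
    out <- numeric(length(x))
    z <- mu == 0
    out[z] <- ifelse(x[z] == 0, 0, -Inf)
    if (dispersion == 0)
      out[!z] <- stats::dpois(x[!z], mu[!z], log = TRUE)
    else
      out[!z] <- dnbinom(x[!z], mu = mu[!z], size = 1 / dispersion, log = TRUE)
    out
  }
  mu0c <- sCtrl * q0; mu0s <- sSh * q0
  stat <- pmax(0, 2 * ((ll(xCtrl, xCtrl) + ll(xSh, xSh)) -
                       (ll(xCtrl, mu0c) + ll(xSh, mu0s))))
  up <- xCtrl / sCtrl > xSh / sSh
  tail <- pchisq(stat, df = 1, lower.tail = FALSE)
  p <- ifelse(up, tail / 2, 1 - tail / 2)
  p[xCtrl + xSh == 0] <- 1
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with the input vector. Backed by
#' [stats::p.adjust()] after input validation.
#'
#' @param p p-values in `[0, 1]` (NA allowed; propagated).
#' @return adjusted p-values ("q-values") in input order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

## log2 fold change on library-size-normalized counts with pseudocount 0.5,
## scaled to the mean library size of the pair so the pseudocount acts on a
## count-like magnitude.
.log2fc <- function(xCtrl, xSh, sCtrl, sSh) {
  s0 <- (sCtrl + sSh) / 2
  log2((xCtrl * s0 / sCtrl + 0.5) / (xSh * s0 / sSh + 0.5))
}

#' Call bound transcripts from a RIP experiment
#'
#' Per replicate: transcripts with FPKM below `fpkmFloor` in *both* conditions
#' are excluded; the remaining transcripts are tested for control-IP
#' enrichment; BH adjustment is computed over the tested (post-floor) set
#' only; significant means `q < qMax` with positive log2 fold change;
#' noncoding transcripts are excluded from the bound set. The final bound set
#' is the intersection of the per-replicate bound sets (replicates corroborate,
#' they are never pooled).
#'
#' @param x a [RipExperiment-class] with >= 1 replicate carrying both
#'   conditions.
#' @param fpkmFloor FPKM floor (default 0.05).
#' @param qMax BH-adjusted significance cutoff (default 0.05).
#' @param test `"binomial"` for the exact conditional test (default) or
#'   `"nb"` for the fixed-dispersion likelihood-ratio variant.
#' @param dispersion dispersion used when `test = "nb"`.
#' @return a list with `records` (per-replicate `DataFrame`s: `transcript_id`,
#'   `fpkm_control`, `fpkm_sh`, `log2fc`, `p`, `q` and the flags
#'   `low_expression`, `noncoding`, `significant`, `bound`) and `bound`
#'   (character vector: the intersected bound set, input row order).
#' @export
callTargets <- function(x, fpkmFloor = 0.05, qMax = 0.05,
                        test = c("binomial", "nb"), dispersion = 0.1) {
  stopifnot(is(x, "RipExperiment"))
  test <- match.arg(test)
  cd <- colData(x)
  reps <- sort(unique(cd$replicate))
  cnt <- assay(x, "counts")
  lens <- rowData(x)$length
  noncoding <- rowData(x)$biotype == "noncoding"
  ids <- rownames(x)

  records <- list()
  boundSets <- list()
  for (r in reps) {
    ic <- which(cd$replicate == r & cd$condition == "control_IP")
    is_ <- which(cd$replicate == r & cd$condition == "shCPEB4_IP")
    if (length(ic) != 1L || length(is_) != 1L)
      stop("replicate ", r, " must have exactly one control_IP and one ",
           "shCPEB4_IP sample")
    xc <- cnt[, ic]; xs <- cnt[, is_]
    sc <- cd$library_size[ic]; ss <- cd$library_size[is_]
    fpkm_c <- computeFPKM(xc, lens, sc)
    fpkm_s <- computeFPKM(xs, lens, ss)
    low <- fpkm_c < fpkmFloor & fpkm_s < fpkmFloor

    p <- rep(NA_real_, length(xc))
    tested <- !low
    p[tested] <- switch(test,
      binomial = testEnrichment(xc[tested], xs[tested], sc, ss),
      nb = testEnrichmentNB(xc[tested], xs[tested], sc, ss, dispersion))
    q <- rep(NA_real_, length(p))
    q[tested] <- bhAdjust(p[tested])
    lfc <- .log2fc(xc, xs, sc, ss)
    significant <- !is.na(q) & q < qMax & lfc > 0
    bound <- significant & !noncoding & !low
    records[[as.character(r)]] <- DataFrame(
      transcript_id = ids, fpkm_control = fpkm_c, fpkm_sh = fpkm_s,
      log2fc = lfc, p = p, q = q,
      low_expression = low, noncoding = noncoding,
      significant = significant, bound = bound)
    boundSets[[as.character(r)]] <- ids[bound]
  }
  bound <- Reduce(intersect, boundSets)
  list(records = records, bound = ids[ids %in% bound])
}

#' RIP-qPCR fold enrichment (delta-delta-Ct)
#'
#' Fold enrichment of a target mRNA in the immunoprecipitated fraction,
#' normalized to input expression, with the nonspecific (IgG/control)
#' antibody as reference:
#' `FE = 2^[(ctIpControlAb - ctInputControlAb) - (ctIp - ctInput)]`.
#'
#' @param ctIp,ctInput Ct values for the specific antibody IP and its input.
#' @param ctIpControlAb,ctInputControlAb Ct values for the control-antibody
#'   IP and its input.
#' @return fold enrichment (1 = no enrichment over the control antibody).
#' @examples
#' ripFoldEnrichment(20, 18, 26, 18) # 64
#' @export
ripFoldEnrichment <- function(ctIp, ctInput, ctIpControlAb, ctInputControlAb) {
  vals <- c(ctIp, ctInput, ctIpControlAb, ctInputControlAb)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  2^((ctIpControlAb - ctInputControlAb) - (ctIp - ctInput))
}
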