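#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- new2
#' @importFrom IRanges IRanges
NULL

.MOTIF_KINDS <- c("CPE", "CPENC", "HEX", "HEXNC", "ARE", "PBS")
.REGULATION_CLASSES <- c("activation_competent", "repression_configured", "non_regulated")

#' MotifMap: positions of polyadenylation-associated elements on one 3'-UTR
#'
#' A `MotifMap` records every catalogue match on a single 3'-UTR as an
#' [IRanges::IRanges] (1-based, closed intervals on the UTR, 5'->3'), with the
#' element kind (`CPE`, `CPENC`, `HEX`, `HEXNC`, `ARE`, `PBS`) and the matched
#' pattern carried in the metadata columns. Hits are stored sorted by start,
#' then end, then kind, so two scans of the same sequence are identical.
#'
#' @slot transcriptID single transcript identifier.
#' @slot utrLength UTR length in nucleotides.
#' @slot hits `IRanges` of matches with metadata columns `kind` and `pattern`.
#'
#' @seealso [scanUTR()], [classifyRegulation()]
#' @export
setClass("MotifMap",
  slots = c(transcriptID = "character", utrLength = "integer", hits = "IRanges"))

setValidity("MotifMap", function(object) {
  msg <- character()
  if (length(object@transcriptID) != 1L || is.na(object@transcriptID) ||
      !nzchar(object@transcriptID))
    msg <- c(msg, "'transcriptID' must be a single non-empty string")
  if (length(object@utrLength) != 1L || is.na(object@utrLength) ||
      object@utrLength < 1L)
    msg <- c(msg, "'utrLength' must be a single integer >= 1")
  h <- object@hits
  mc <- mcols(h)
  if (is.null(mc) || !all(c("kind", "pattern") %in% colnames(mc)))
    msg <- c(msg, "hits must carry 'kind' and 'pattern' metadata columns")
  else if (!all(mc$kind %in% .MOTIF_KINDS))
    msg <- c(msg, "hit kinds must be one of CPE, CPENC, HEX, HEXNC, ARE, PBS")
  if (length(h) > 0L) {
    if (min(IRanges::start(h)) < 1L || max(IRanges::end(h)) > object@utrLength)
      msg <- c(msg, "all hits must lie within [1, utrLength]")
    o <- order(IRanges::start(h), IRanges::end(h), as.character(mcols(h)$kind))
    if (!identical(o, seq_along(h)))
      msg <- c(msg, "hits must be sorted by start, end, kind")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MotifMap number of motif hits on the UTR
#' @param x,object a `MotifMap`.
#' @export
setMethod("length", "MotifMap", function(x) length(x@hits))

setMethod("show", "MotifMap", function(object) {
  counts <- table(factor(mcols(object@hits)$kind, levels = .MOTIF_KINDS))
  cat("MotifMap for ", object@transcriptID,
      " (", object@utrLength, " nt UTR)\n", sep = "")
  cat("  ", sum(counts), " hits: ",
      paste(sprintf("%s=%d", names(counts), as.integer(counts)), collapse = " "),
      "\n", sep = "")
  invisible(object)
})

#' @export
setGeneric("transcriptID", function(x) standardGeneric("transcriptID"))

#' @describeIn MotifMap transcript identifier
#' @export
setMethod("transcriptID", "MotifMap", function(x) x@transcriptID)

#' @export
setGeneric("utrLength", function(x) standardGeneric("utrLength"))

#' @describeIn MotifMap UTR length in nucleotides
#' @export
setMethod("utrLength", "MotifMap", function(x) x@utrLength)

#' @export
setGeneric("motifHits", function(x, kind = NULL) standardGeneric("motifHits"))

#' @describeIn MotifMap the hit `IRanges`, optionally restricted to one kind
#' @param kind optional element kind to filter on.
#' @export
setMethod("motifHits", "MotifMap", function(x, kind = NULL) {
  if (is.null(kind)) return(x@hits)
  kind <- match.arg(kind, .MOTIF_KINDS)
  x@hits[mcols(x@hits)$kind == kind]
})

#' @export
setGeneric("motifCounts", function(x) standardGeneric("motifCounts"))

#' @describeIn MotifMap named count of hits per element kind
#' @export
setMethod("motifCounts", "MotifMap", function(x) {
  tab <- table(factor(mcols(x@hits)$kind, levels = .MOTIF_KINDS))
  stats::setNames(as.integer(tab), names(tab))
})

## validate = FALSE is reserved for the scanner, whose output satisfies the
## invariants by construction (and is checked against an oracle in the tests)
MotifMap <- function(transcriptID, utrLength, hits, validate = TRUE) {
  S4Vectors::new2("MotifMap", transcriptID = as.character(transcriptID),
                  utrLength = as.integer(utrLength), hits = hits,
                  check = validate)
}
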