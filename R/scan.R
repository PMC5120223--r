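#' @importFrom Biostrings RNAStringSet readBStringSet writeXStringSet
NULL

## Normalize user input (character / DNAString(Set) / RNAString(Set)) to an
## uppercase RNA character string. DNA input is converted T -> U.
.asRNAString <- function(x) {
  s <- toupper(as.character(x))
  chartr("T", "U", s)
}

.checkAlphabet <- function(seq, id, ambiguous = c("reject", "mask")) {
  ambiguous <- match.arg(ambiguous)
  chars <- unique(strsplit(seq, "")[[1]])
  hard <- setdiff(chars, names(.IUPAC_RNA))
  if (length(hard))
    stop("transcript '", id, "': non-nucleotide character(s): ",
         paste(hard, collapse = ", "))
  amb <- setdiff(chars, c("A", "C", "G", "U"))
  if (length(amb) && ambiguous == "reject")
    stop("transcript '", id, "': ambiguous base(s) ",
         paste(amb, collapse = ", "),
         " rejected (set ambiguous = \"mask\" to scan past them)")
  invisible(TRUE)
}

#' Scan one 3'-UTR for polyadenylation-associated elements
#'
#' Reports every position at which any catalogue pattern matches, including
#' overlapping and self-overlapping matches. A window matching both a
#' consensus and a non-consensus pattern of the same family (CPE/CPENC or
#' HEX/HEXNC) at identical coordinates is reported once, with the consensus
#' kind, so element counts are never double-counted. Matching is exact on
#' concrete patterns after IUPAC expansion; ambiguous bases in the *sequence*
#' are either rejected (default) or masked (never match).
#'
#' @param utr sequence (character, `DNAString`/`RNAString`, or a length-1
#'   `XStringSet`); DNA input is converted `T -> U`.
#' @param catalogue a [motifCatalogue()]; defaults to [defaultCatalogue()].
#' @param transcriptID identifier recorded on the returned map (defaults to
#'   the name of `utr` if present, else `"utr"`).
#' @param ambiguous policy for non-ACGU bases in the sequence: `"reject"`
#'   (error naming the transcript) or `"mask"`.
#' @return a [MotifMap].
#' @examples
#' scanUTR("UUUUAAUAAA", transcriptID = "toy")
#' @export
scanUTR <- function(utr, catalogue = defaultCatalogue(),
                    transcriptID = NULL, ambiguous = c("reject", "mask")) {
  if (is.null(transcriptID))
    transcriptID <- if (!is.null(names(utr))) names(utr)[1] else "utr"
  seq <- .asRNAString(utr)
  if (nchar(seq) < 1L)
    stop("transcript '", transcriptID, "': empty sequence")
  .checkAlphabet(seq, transcriptID, ambiguous)

  subject <- chartr("N", "-", seq)  # masked N can never equal an ACGU pattern
  n <- nchar(subject)
  kindVec <- as.character(catalogue$kind)     # plain vectors: hot loop below
  patVec <- as.character(catalogue$pattern)
  windows <- .windowTable(subject, unique(nchar(patVec)))
  starts <- integer(0); ends <- integer(0)
  kinds <- character(0); pats <- character(0)
  for (i in seq_along(patVec)) {
    kd <- kindVec[i]
    src <- patVec[i]                          # reported pattern: as configured
    L <- nchar(src)
    if (L > n) next
    win <- windows[[as.character(L)]]
    for (pat in .expandPattern(src)) {
      at <- which(win == pat)
      if (length(at)) {
        starts <- c(starts, at)
        ends <- c(ends, at + L - 1L)
        kinds <- c(kinds, rep(kd, length(at)))
        pats <- c(pats, rep(src, length(at)))
      }
    }
  }

  ## same-window consensus/non-consensus collision -> keep the consensus kind
  if (length(starts)) {
    fam <- sub("NC$", "", kinds)
    key <- paste(fam, starts, ends)
    consensus_keys <- key[!endsWith(kinds, "NC")]
    drop <- endsWith(kinds, "NC") & key %in% consensus_keys
    ## identical window reported by two patterns of one kind: keep once
    dup <- duplicated(paste(kinds, starts, ends))
    keep <- !drop & !dup
    starts <- starts[keep]; ends <- ends[keep]
    kinds <- kinds[keep]; pats <- pats[keep]
    o <- order(starts, ends, kinds)
    starts <- starts[o]; ends <- ends[o]; kinds <- kinds[o]; pats <- pats[o]
  }

  MotifMap(transcriptID, nchar(seq), .newHits(starts, ends, kinds, pats),
           validate = FALSE)
}

## Low-overhead IRanges-with-mcols builder for the scanner hot path;
## equivalent to IRanges() + mcols<- (covered by the oracle tests).
.newHits <- function(starts, ends, kinds, pats) {
  meta <- S4Vectors::new2("DFrame",
                          listData = list(kind = as.character(kinds),
                                          pattern = as.character(pats)),
                          nrows = length(starts), check = FALSE)
  S4Vectors::new2("IRanges", start = as.integer(starts),
                  width = as.integer(ends - starts + 1L),
                  elementMetadata = meta, check = FALSE)
}

## All length-L windows of a sequence, one character vector per length.
.windowTable <- function(seq, lengths) {
  n <- nchar(seq)
  out <- lapply(lengths, function(L) {
    if (L > n) return(character(0))
    at <- seq_len(n - L + 1L)
    substring(seq, at, at + L - 1L)
  })
  names(out) <- as.character(lengths)
  out
}

#' Combinatorial classification rules
#'
#' Parameters of the activation/repression rule table applied by
#' [classifyRegulation()]: a transcript is *activation-competent* when it has
#' at least one CPE (consensus or non-consensus) and at least one consensus
#' HEX, with the nearest CPE-HEX gap inside `[dMin, dMax]` nucleotides and no
#' CPE overlapping a HEX; a CPE overlapping a HEX marks the UTR
#' *repression-configured*; anything else is *non-regulated*. The distance
#' window is exposed, not asserted: published scans do not agree on a single
#' threshold, and `dMax = 100` nt is a deliberate, overridable default.
#'
#' @param dMin,dMax allowed gap (nt) between the nearest CPE and HEX.
#' @return a named list with class `"regulationRules"`.
#' @export
regulationRules <- function(dMin = 0L, dMax = 100L) {
  dMin <- as.integer(dMin); dMax <- as.integer(dMax)
  if (is.na(dMin) || is.na(dMax) || dMin < 0L || dMax < dMin)
    stop("need 0 <= dMin <= dMax")
  structure(list(dMin = dMin, dMax = dMax), class = "regulationRules")
}

#' Classify one UTR for cytoplasmic-polyadenylation competence
#'
#' Applies the combinatorial rule table of [regulationRules()] to a
#' [MotifMap]. A pure function of the map content: the same map and rules
#' always give the same call. The CPE side of the rules pools consensus and
#' non-consensus CPEs; the HEX side uses consensus hexanucleotides only
#' (non-consensus HEX are reported as features but carry no rule weight).
#'
#' @param map a [MotifMap].
#' @param rules a [regulationRules()] object.
#' @return a one-row [S4Vectors::DataFrame] with `transcript_id`, `klass`
#'   (one of `activation_competent`, `repression_configured`,
#'   `non_regulated`) and the feature columns `n_cpe`, `n_cpe_nc`, `n_hex`,
#'   `n_hex_nc`, `n_are`, `n_pbs`, `dist_cpe_hex` (NA when either element is
#'   missing) and `cpe_hex_overlap`.
#' @examples
#' classifyRegulation(scanUTR("UUUUAAUAAA", transcriptID = "toy"))
#' @export
classifyRegulation <- function(map, rules = regulationRules()) {
  stopifnot(is(map, "MotifMap"), inherits(rules, "regulationRules"))
  n <- motifCounts(map)
  cpe <- motifHits(map)[mcols(motifHits(map))$kind %in% c("CPE", "CPENC")]
  hex <- motifHits(map, "HEX")

  dist_cpe_hex <- NA_integer_
  overlap <- FALSE
  if (length(cpe) && length(hex)) {
    overlap <- any(IRanges::overlapsAny(cpe, hex))
    nearest <- IRanges::distanceToNearest(cpe, hex)
    dist_cpe_hex <- as.integer(min(mcols(nearest)$distance))
  }

  klass <- if (overlap) {
    "repression_configured"
  } else if (length(cpe) >= 1L && length(hex) >= 1L &&
             !is.na(dist_cpe_hex) &&
             dist_cpe_hex >= rules$dMin && dist_cpe_hex <= rules$dMax) {
    "activation_competent"
  } else {
    "non_regulated"
  }

  DataFrame(transcript_id = transcriptID(map), klass = klass,
            n_cpe = n[["CPE"]], n_cpe_nc = n[["CPENC"]],
            n_hex = n[["HEX"]], n_hex_nc = n[["HEXNC"]],
            n_are = n[["ARE"]], n_pbs = n[["PBS"]],
            dist_cpe_hex = dist_cpe_hex, cpe_hex_overlap = overlap)
}

#' Scan and classify a batch of 3'-UTRs
#'
#' Runs [scanUTR()] and [classifyRegulation()] over a set of UTRs, preserving
#' input order, and returns the subset of transcripts classified as regulated
#' by cytoplasmic polyadenylation (any class other than `non_regulated`).
#'
#' @param utrs an `RNAStringSet`/`DNAStringSet` with unique names, or the path
#'   of a FASTA file (read with [readUTRFasta()]; description lines may carry
#'   `biotype=coding|noncoding`, default `coding`).
#' @inheritParams scanUTR
#' @param rules a [regulationRules()] object.
#' @return a list with `calls` (one-row-per-record `DataFrame` of
#'   classification features, plus `biotype`), `maps` (list of [MotifMap]),
#'   and `regulated` (character vector of transcript ids with
#'   `klass != "non_regulated"`).
#' @export
scanBatch <- function(utrs, catalogue = defaultCatalogue(),
                      rules = regulationRules(),
                      ambiguous = c("reject", "mask")) {
  if (is.character(utrs) && length(utrs) == 1L && file.exists(utrs))
    utrs <- readUTRFasta(utrs)
  ids <- names(utrs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all UTR records must be named")
  if (anyDuplicated(ids))
    stop("duplicate transcript id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  biotype <- if (!is.null(mcols(utrs)$biotype)) mcols(utrs)$biotype
             else rep("coding", length(utrs))

  maps <- vector("list", length(utrs))
  calls <- vector("list", length(utrs))
  for (i in seq_along(utrs)) {
    maps[[i]] <- scanUTR(utrs[[i]], catalogue, transcriptID = ids[i],
                         ambiguous = ambiguous)
    calls[[i]] <- classifyRegulation(maps[[i]], rules)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    classifyRegulation(scanUTR("A", transcriptID = "x"))[0, ]
  calls$biotype <- biotype
  names(maps) <- ids
  list(calls = calls, maps = maps,
       regulated = calls$transcript_id[calls$klass != "non_regulated"])
}
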