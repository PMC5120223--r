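#' @importFrom utils read.delim write.table
#' @importFrom GenomicRanges GRanges
#' @importFrom fgsea gmtPathways
NULL

#' Read 3'-UTR sequences from FASTA
#'
#' Accepts DNA or RNA alphabet (T is converted to U) and wrapped lines.
#' The description line may carry a `biotype=coding|noncoding` tag after the
#' id (default `coding`); the biotype is returned in `mcols()`.
#'
#' @param path FASTA file.
#' @return an `RNAStringSet` named by transcript id, with `mcols()$biotype`.
#' @export
readUTRFasta <- function(path) {
  raw <- readBStringSet(path)
  if (length(raw) == 0L) {
    out <- RNAStringSet()
    mcols(out)$biotype <- character(0)
    return(out)
  }
  desc <- names(raw)
  ids <- sub("\\s.*$", "", desc)
  if (anyDuplicated(ids))
    stop("duplicate transcript id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  biotype <- ifelse(grepl("biotype=noncoding", desc), "noncoding", "coding")
  seqs <- chartr("Tt", "Uu", as.character(raw))
  out <- RNAStringSet(toupper(seqs))
  names(out) <- ids
  mcols(out)$biotype <- biotype
  out
}

#' Write 3'-UTR sequences to FASTA
#'
#' Writes an `RNAStringSet`, appending a `biotype=` tag to the description
#' line when `mcols()$biotype` is present, so [readUTRFasta()] round-trips.
#'
#' @param utrs a named `RNAStringSet`.
#' @param path output file.
#' @export
writeUTRFasta <- function(utrs, path) {
  out <- utrs
  if (!is.null(mcols(utrs)$biotype))
    names(out) <- paste0(names(utrs), " biotype=", mcols(utrs)$biotype)
  writeXStringSet(out, path, width = 70L)
  invisible(path)
}

#' Write motif maps as GFF3
#'
#' One feature per motif hit, 1-based inclusive coordinates on the UTR
#' (`seqid` = transcript id, `type` = element kind), with a
#' `##gff-version 3` header.
#'
#' @param maps a list of [MotifMap] objects (e.g. `scanBatch()$maps`).
#' @param path output file.
#' @export
writeMotifGFF3 <- function(maps, path) {
  grl <- lapply(maps, function(m) {
    h <- motifHits(m)
    if (length(h) == 0L) return(GRanges())
    gr <- GRanges(seqnames = transcriptID(m), ranges = h, strand = "+")
    mcols(gr)$type <- mcols(h)$kind
    mcols(gr)$Name <- mcols(h)$pattern
    gr
  })
  gr <- suppressWarnings(do.call(c, unname(grl)))
  mcols(gr)$source <- "cpeTargets"
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read a RIP count table plus sidecar annotation and sample sheet
#'
#' `countsPath`: TSV, first column `transcript_id`, remaining columns one per
#' sample. `annotPath`: TSV with `transcript_id`, `length`, `biotype`.
#' `samplesPath`: TSV with `sample`, `condition`, `replicate` and optionally
#' `library_size` (defaults to the column sums).
#'
#' @param countsPath,samplesPath,annotPath TSV file paths.
#' @return a [RipExperiment-class].
#' @export
readRipExperiment <- function(countsPath, samplesPath, annotPath) {
  cnt <- read.delim(countsPath, check.names = FALSE)
  annot <- read.delim(annotPath)
  samples <- read.delim(samplesPath)
  mat <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(mat) <- cnt[[1]]
  if (!all(samples$sample %in% colnames(mat)))
    stop("sample sheet names sample(s) missing from the count table")
  mat <- mat[, samples$sample, drop = FALSE]
  i <- match(rownames(mat), annot$transcript_id)
  if (anyNA(i)) stop("annotation missing for some transcripts")
  RipExperiment(mat, annot$length[i], annot$biotype[i],
                samples$condition, samples$replicate,
                if ("library_size" %in% colnames(samples))
                  samples$library_size else NULL)
}

#' Write per-replicate enrichment results and the bound set
#'
#' One TSV per replicate (`enrichment_rep<r>.tsv`) and `bound_set.txt`
#' (one transcript id per line).
#'
#' @param res result of [callTargets()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeEnrichmentResults <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in names(res$records)) {
    write.table(as.data.frame(res$records[[r]]),
                file.path(dir, paste0("enrichment_rep", r, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(res$bound, file.path(dir, "bound_set.txt"))
  invisible(dir)
}

#' Read a ranked-statistic TSV (gene_id, stat)
#'
#' @param path TSV with columns `gene_id` and `stat`.
#' @return a [rankedList()].
#' @export
readRanking <- function(path) {
  d <- read.delim(path)
  rankedList(d$gene_id, d$stat)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, then member ids, tab
#'   separated).
#' @return a named list of character vectors.
#' @export
readGeneSets <- function(path) gmtPathways(path)

#' Read a per-cell intensity TSV
#'
#' @param path TSV with columns `cell_id`, `red`, `green` (0-255).
#' @return a data frame, validated.
#' @export
readCellTable <- function(path) {
  d <- read.delim(path)
  .checkCells(d)
  d
}
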