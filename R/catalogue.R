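## Element catalogue: the patterns scanned for on 3'-UTRs, RNA alphabet with
## IUPAC degeneracy allowed at single positions.

## package-local caches (per-session): default catalogue, pattern expansions
.cache <- new.env(parent = emptyenv())

.IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U"))

#' Build and validate a motif element catalogue
#'
#' A catalogue is a [S4Vectors::DataFrame] with one row per pattern and columns
#' `kind` and `pattern`. Kinds are the six element families scanned for on
#' 3'-UTRs: consensus and non-consensus cytoplasmic polyadenylation elements
#' (`CPE`, `CPENC`), consensus and non-consensus polyadenylation
#' hexanucleotides (`HEX`, `HEXNC`), AU-rich elements (`ARE`) and
#' Pumilio-binding sites (`PBS`). Patterns are RNA-alphabet strings; IUPAC
#' degeneracy codes are allowed.
#'
#' @param kind character vector of element kinds.
#' @param pattern character vector of RNA patterns, same length as `kind`.
#' @return a validated catalogue `DataFrame`.
#' @examples
#' motifCatalogue(c("CPE", "HEX"), c("UUUUAU", "AAUAAA"))
#' @export
motifCatalogue <- function(kind, pattern) {
  kind <- as.character(kind)
  pattern <- toupper(as.character(pattern))
  if (length(kind) != length(pattern) || length(kind) == 0L)
    stop("'kind' and 'pattern' must be non-empty vectors of equal length")
  bad <- setdiff(unique(kind), .MOTIF_KINDS)
  if (length(bad))
    stop("unknown element kind(s): ", paste(bad, collapse = ", "))
  letters_used <- unique(strsplit(paste(pattern, collapse = ""), "")[[1]])
  badchr <- setdiff(letters_used, names(.IUPAC_RNA))
  if (length(badchr))
    stop("patterns must use the RNA alphabet plus IUPAC codes; offending: ",
         paste(badchr, collapse = ", "))
  if (anyDuplicated(pattern))
    stop("duplicated pattern(s): ",
         paste(unique(pattern[duplicated(pattern)]), collapse = ", "))
  DataFrame(kind = kind, pattern = pattern)
}

#' Default element catalogue
#'
#' Returns the six element kinds with their default patterns:
#' \describe{
#'   \item{CPE}{`UUUUAU`, `UUUUAAU` — the `UUUUA(1-2)U` consensus.}
#'   \item{CPENC}{U-rich non-consensus variants (`UUUUAAAU`, `UUUUCAU`,
#'     `UUUUCAAU`). Non-consensus CPE repertoires differ between published
#'     scans; these defaults are deliberately conservative and meant to be
#'     overridden from configuration when a specific variant table is in use.}
#'   \item{HEX}{`AAUAAA`, the canonical polyadenylation hexanucleotide.}
#'   \item{HEXNC}{the eleven common single-substitution hexamer variants,
#'     led by `AUUAAA`.}
#'   \item{ARE}{`AUUUA`, the core AU-rich element pentamer.}
#'   \item{PBS}{`UGUANAUA`, the Pumilio response element (one degenerate
#'     position).}
#' }
#'
#' Every entry can be replaced by passing a custom [motifCatalogue()] to the
#' scanning functions, or via the `catalogue` block of a pipeline YAML config.
#'
#' @return a catalogue `DataFrame` (see [motifCatalogue()]).
#' @examples
#' defaultCatalogue()
#' @export
defaultCatalogue <- function() {
  if (!is.null(.cache$default)) return(.cache$default)
  .cache$default <- motifCatalogue(
    kind = c("CPE", "CPE",
             "CPENC", "CPENC", "CPENC",
             "HEX",
             rep("HEXNC", 11L),
             "ARE",
             "PBS"),
    pattern = c("UUUUAU", "UUUUAAU",
                "UUUUAAAU", "UUUUCAU", "UUUUCAAU",
                "AAUAAA",
                "AUUAAA", "UAUAAA", "AGUAAA", "AAGAAA", "AAUAUA",
                "AAUACA", "AAUGAA", "CAUAAA", "GAUAAA", "ACUAAA", "AAUAGA",
                "AUUUA",
                "UGUANAUA"))
  .cache$default
}

## Expand one IUPAC pattern into the concrete sequences it denotes (memoised;
## catalogues are small and stable within a session).
.expandPattern <- function(pattern) {
  key <- paste0("x_", pattern)
  hit <- .cache[[key]]
  if (!is.null(hit)) return(hit)
  chars <- strsplit(pattern, "")[[1]]
  out <- ""
  for (ch in chars) out <- as.vector(outer(out, .IUPAC_RNA[[ch]], paste0))
  .cache[[key]] <- out
  out
}

## kind -> character vector of concrete (degeneracy-free) patterns
.concreteCatalogue <- function(catalogue) {
  split(unlist(lapply(catalogue$pattern, .expandPattern),
               use.names = FALSE),
        rep(catalogue$kind, vapply(catalogue$pattern,
                                   function(p) length(.expandPattern(p)),
                                   integer(1))))
}

## Catalogue override used by pipeline configs: a named list kind -> patterns.
.catalogueFromList <- function(lst) {
  motifCatalogue(rep(names(lst), lengths(lst)),
                 unlist(lst, use.names = FALSE))
}
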