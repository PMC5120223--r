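# Independent oracles: deliberately naive re-derivations used to check the
# package implementations. They share no code with R/.

# IUPAC expansion done from scratch (RNA alphabet).
oracle_iupac <- c(A = "A", C = "C", G = "G", U = "U",
                  R = "AG", Y = "CU", S = "CG", W = "AU", K = "GU", M = "AC",
                  B = "CGU", D = "AGU", H = "ACU", V = "ACG", N = "ACGU")

oracle_char_matches <- function(seq_char, pat_char) {
  seq_char %in% strsplit(oracle_iupac[[pat_char]], "")[[1]]
}

# Test every pattern at every offset by per-character comparison.
# Returns a data.frame(start, end, kind, pattern) with 1-based closed
# coordinates, consensus/non-consensus same-window collisions resolved to
# the consensus kind and exact duplicates within a kind collapsed, sorted.
oracle_scan <- function(seq, catalogue_df) {
  s <- strsplit(seq, "")[[1]]
  rows <- list()
  for (i in seq_len(nrow(catalogue_df))) {
    pat <- strsplit(catalogue_df$pattern[i], "")[[1]]
    L <- length(pat)
    if (L > length(s)) next
    for (off in seq_len(length(s) - L + 1L)) {
      ok <- TRUE
      for (j in seq_len(L)) {
        if (!oracle_char_matches(s[off + j - 1L], pat[j])) { ok <- FALSE; break }
      }
      if (ok)
        rows[[length(rows) + 1L]] <- data.frame(
          start = off, end = off + L - 1L,
          kind = catalogue_df$kind[i], pattern = catalogue_df$pattern[i])
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      kind = character(0), pattern = character(0)))
  d <- do.call(rbind, rows)
  fam <- sub("NC$", "", d$kind)
  key <- paste(fam, d$start, d$end)
  consensus <- key[!grepl("NC$", d$kind)]
  d <- d[!(grepl("NC$", d$kind) & key %in% consensus), , drop = FALSE]
  d <- d[!duplicated(paste(d$kind, d$start, d$end)), , drop = FALSE]
  d <- d[order(d$start, d$end, d$kind), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# Hit table of a MotifMap in the oracle's format.
map_as_table <- function(map) {
  h <- motifHits(map)
  data.frame(start = IRanges::start(h), end = IRanges::end(h),
             kind = as.character(S4Vectors::mcols(h)$kind),
             pattern = as.character(S4Vectors::mcols(h)$pattern))
}

# Benjamini-Hochberg step-up written out longhand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Unweighted KS running-sum enrichment score from hit positions alone.
oracle_es_unweighted <- function(N, hit_positions) {
  k <- length(hit_positions)
  step <- ifelse(seq_len(N) %in% hit_positions, 1 / k, -1 / (N - k))
  run <- cumsum(step)
  run[which.max(abs(run))]
}

random_rna <- function(n, len_max = 60L, len_min = 1L) {
  vapply(seq_len(n), function(i) {
    len <- sample(seq(len_min, len_max), 1L)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Vectorized brute-force scan over many sequences at once: every concrete
# pattern is compared by substring equality at every offset. Returns one
# data.frame with a seq index column, same dedupe/sort rules as oracle_scan.
oracle_scan_batch <- function(seqs, catalogue_df) {
  lens <- nchar(seqs)
  out <- list()
  for (i in seq_len(nrow(catalogue_df))) {
    src <- catalogue_df$pattern[i]
    chars <- strsplit(src, "")[[1]]
    concrete <- ""
    for (ch in chars)
      concrete <- as.vector(outer(concrete,
                                  strsplit(oracle_iupac[[ch]], "")[[1]],
                                  paste0))
    L <- nchar(src)
    for (pat in concrete) {
      for (off in seq_len(max(lens) - L + 1L)) {
        hit <- which(substring(seqs, off, off + L - 1L) == pat)
        if (length(hit))
          out[[length(out) + 1L]] <- data.frame(
            seq = hit, start = off, end = off + L - 1L,
            kind = catalogue_df$kind[i], pattern = src, row = i)
      }
    }
  }
  if (!length(out))
    return(data.frame(seq = integer(0), start = integer(0),
                      end = integer(0), kind = character(0),
                      pattern = character(0)))
  d <- do.call(rbind, out)
  d <- d[order(d$seq, d$row, d$start), ]     # catalogue-row accumulation order
  fam <- sub("NC$", "", d$kind)
  key <- paste(d$seq, fam, d$start, d$end)
  consensus <- key[!grepl("NC$", d$kind)]
  d <- d[!(grepl("NC$", d$kind) & key %in% consensus), , drop = FALSE]
  d <- d[!duplicated(paste(d$seq, d$kind, d$start, d$end)), , drop = FALSE]
  d <- d[order(d$seq, d$start, d$end, d$kind), c("seq", "start", "end",
                                                 "kind", "pattern")]
  rownames(d) <- NULL
  d
}
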