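# Reference implementations used only by the tests. They are deliberately
# naive, written from the definitions, and independent of the package
# internals, so that agreement with them is evidence of correctness rather
# than of shared code.

REF_BASES <- c("A", "C", "G", "T")

ref_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(unname(comp[strsplit(s, "", fixed = TRUE)[[1L]]])),
        collapse = "")
}

ref_rotations <- function(s) {
  n <- nchar(s)
  vapply(seq_len(n), function(k) {
    paste0(substring(s, k, n), substring(s, 1L, k - 1L))
  }, character(1L))
}

# TRUE when the motif is not a whole-number repetition of a shorter string
ref_minimal <- function(m) {
  p <- nchar(m)
  if (p == 1L) return(TRUE)
  for (d in seq_len(p - 1L)) {
    if (p %% d != 0L) next
    if (paste(rep(substring(m, 1L, d), p %/% d), collapse = "") == m) {
      return(FALSE)
    }
  }
  TRUE
}

# Canonical class representative: lexicographic minimum over all rotations
# of the motif and of its reverse complement
ref_canonical <- function(m) {
  min(c(ref_rotations(m), ref_rotations(ref_revcomp(m))))
}

ref_random_seq <- function(len, gc) {
  paste(sample(REF_BASES, len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Naive brute-force scanner: character vectors, explicit loops, greedy
# left-to-right with periods tried in increasing order at each position.
ref_scan <- function(s, min_repeats = c(6L, 3L, 3L, 3L, 3L, 3L),
                     max_period = 6L) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  ok <- ch %in% REF_BASES
  starts <- integer(0L); periods <- integer(0L); copies <- integer(0L)
  i <- 1L
  while (i <= n) {
    emitted <- FALSE
    if (ok[i]) {
      for (p in seq_len(max_period)) {
        if (i + p - 1L > n || !all(ok[i:(i + p - 1L)])) break
        motif <- paste(ch[i:(i + p - 1L)], collapse = "")
        j <- i + p
        while (j <= n && ok[j] && ch[j] == ch[j - p]) j <- j + 1L
        cp <- (j - i) %/% p
        if (cp < min_repeats[p]) next
        if (!ref_minimal(motif)) next
        starts <- c(starts, i)
        periods <- c(periods, p)
        copies <- c(copies, cp)
        i <- i + p * cp
        emitted <- TRUE
        break
      }
    }
    if (!emitted) i <- i + 1L
  }
  data.frame(start = starts, end = starts + periods * copies - 1L,
             period = periods, copies = copies)
}

# Independent compound-chaining oracle: two loci belong to the same chain
# iff the gap between them is <= dmax, which is equivalent to merging the
# intervals [start, end + dmax] (allowing adjacency). Returns one group id
# per locus; loci must lie on a single contig.
ref_chain_groups <- function(starts, ends, dmax) {
  if (length(starts) == 0L) return(integer(0L))
  red <- IRanges::reduce(IRanges::IRanges(starts, ends + dmax))
  hits <- IRanges::findOverlaps(IRanges::IRanges(starts, starts), red)
  as.integer(S4Vectors::subjectHits(hits))
}

# All-pairs interval-overlap oracle for coding classification
ref_regions <- function(loci, cds) {
  out <- rep("noncoding", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    for (j in seq_len(nrow(cds))) {
      if (loci$contig_id[i] == cds$contig_id[j] &&
          loci$start[i] <= cds$end[j] && cds$start[j] <= loci$end[i]) {
        out[i] <- "coding"
        break
      }
    }
  }
  out
}

# A short sequence with no microsatellite under the default thresholds,
# usable as inert spacer when constructing genomes by hand.
REF_SPACER <- "GATCGTACGGATCCTAGCAT"
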