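#' Scan parameters for perfect microsatellite detection
#'
#' Bundles the minimum copy-number thresholds used to call a perfect tandem
#' repeat a microsatellite. The defaults (6 copies for mononucleotide
#' repeats, 3 copies for periods 2-6) are the thresholds customarily used
#' for small prokaryotic genomes.
#'
#' @param min_repeats Integer vector of length `max_period`: the minimum
#'   number of complete motif copies required for each motif period
#'   (element 1 = mononucleotide, element 2 = dinucleotide, ...). All
#'   values must be >= 2; fewer than two copies is not a repeat.
#' @param max_period Largest motif length considered, between 1 and 6.
#' @return An object of class `scan_params`.
#' @examples
#' scan_params()                      # 6,3,3,3,3,3 over periods 1-6
#' scan_params(c(10, 6, 4), max_period = 3)
#' @export
scan_params <- function(min_repeats = c(6L, 3L, 3L, 3L, 3L, 3L),
                        max_period = 6L) {
  max_period <- as.integer(max_period)
  if (length(max_period) != 1L || is.na(max_period) ||
      max_period < 1L || max_period > 6L) {
    stop("`max_period` must be a single integer in 1..6")
  }
  min_repeats <- as.integer(min_repeats)
  if (length(min_repeats) < max_period) {
    stop("`min_repeats` must supply a threshold for every period up to ",
         max_period)
  }
  min_repeats <- min_repeats[seq_len(max_period)]
  if (anyNA(min_repeats) || any(min_repeats < 2L)) {
    stop("all `min_repeats` thresholds must be integers >= 2")
  }
  structure(list(min_repeats = min_repeats, max_period = max_period),
            class = "scan_params")
}

#' @export
print.scan_params <- function(x, ...) {
  cat("SSR scan parameters\n")
  cat("  min repeats (period 1..", x$max_period, "): ",
      paste(x$min_repeats, collapse = ", "), "\n", sep = "")
  invisible(x)
}

.DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#' @param s Character vector of DNA strings (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(s) {
  vapply(s, function(x) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

# TRUE when the motif is not a whole-number repetition of any shorter string
.is_minimal_period <- function(motif) {
  p <- nchar(motif)
  if (p <= 1L) return(TRUE)
  for (d in seq_len(p - 1L)) {
    if (p %% d == 0L &&
        strrep(substr(motif, 1L, d), p %/% d) == motif) {
      return(FALSE)
    }
  }
  TRUE
}

.proper_divisors <- function(p) {
  d <- seq_len(max(p - 1L, 0L))
  d[p %% d == 0L]
}

.rotations <- function(s) {
  p <- nchar(s)
  vapply(seq_len(p) - 1L, function(k) {
    paste0(substr(s, k + 1L, p), substr(s, 1L, k))
  }, character(1L))
}

#' Canonical (standard) motif of a microsatellite
#'
#' Microsatellite motifs that differ only by phase (cyclic rotation) or by
#' strand (reverse complement) describe the same repeat. This function maps
#' every motif to the lexicographically smallest string (byte order,
#' A < C < G < T) among all cyclic rotations of the motif and of its
#' reverse complement, so that e.g. `GT`, `TG`, `CA` and `AC` all report as
#' `AC`. The mapping is idempotent and constant on each equivalence class,
#' which is what makes per-motif abundance matrices well defined.
#'
#' @param motif Character vector of motifs (length 1-6 each, A/C/G/T only).
#' @return Character vector of canonical class representatives.
#' @examples
#' standardize_motif(c("GT", "TC", "GCC"))  # "AC" "AG" "CCG"
#' @export
standardize_motif <- function(motif) {
  if (!is.character(motif)) stop("`motif` must be a character vector")
  up <- toupper(motif)
  if (any(nchar(up) < 1L) || any(grepl("[^ACGT]", up))) {
    stop("motifs must be non-empty strings over the alphabet A/C/G/T")
  }
  uniq <- unique(up)
  canon <- vapply(uniq, function(m) {
    cands <- c(.rotations(m), .rotations(reverse_complement(m)))
    sort(cands, method = "radix")[1L]
  }, character(1L))
  unname(canon[match(up, uniq)])
}

#' Enumerate all standard motifs of a given period
#'
#' Brute-force enumeration of every minimal-period motif of the requested
#' length, collapsed to canonical class representatives (see
#' [standardize_motif()]). Period 1 yields the two classes A and C; period
#' 2 yields the four classes AC, AG, AT, CG.
#'
#' @param period Motif length, 1-6.
#' @return Sorted character vector of canonical motifs.
#' @export
enumerate_standard_motifs <- function(period) {
  period <- as.integer(period)
  if (length(period) != 1L || is.na(period) || period < 1L || period > 6L) {
    stop("`period` must be a single integer in 1..6")
  }
  grid <- do.call(expand.grid,
                  c(rep(list(.DNA_BASES), period),
                    stringsAsFactors = FALSE))
  all_motifs <- do.call(paste0, grid)
  minimal <- all_motifs[vapply(all_motifs, .is_minimal_period, logical(1L))]
  sort(unique(standardize_motif(minimal)), method = "radix")
}

# Core scanner. Takes one contig as a single string; returns a
# data.frame(start, end, period, copies). The greedy left-to-right
# resolution lives in compiled code (src/scan.cpp): at each position
# periods are tried in increasing order; the first qualifying maximal run
# is emitted (truncated to whole motif copies) and scanning resumes
# immediately after its end, so reported loci never overlap.
.scan_string <- function(s, params) {
  .scan_seq_cpp(s, params$min_repeats, params$max_period)
}

# Same scan over a character vector of single bases (the representation
# used by the synthetic-genome generator).
.scan_chars <- function(x, params) {
  .scan_string(paste(x, collapse = ""), params)
}

.empty_ssr_loci <- function() {
  data.frame(genome_id = character(0L), contig_id = character(0L),
              start = integer(0L), end = integer(0L), period = integer(0L),
              motif = character(0L), standard_motif = character(0L),
              repeats = integer(0L), length = integer(0L))
}

#' Detect all perfect microsatellites in a genome
#'
#' Scans every contig for perfect tandem repeats of motif period 1-6 that
#' meet the copy-number thresholds in `params`. Runs never cross an
#' ambiguity character (N etc.) or a contig boundary; partial trailing
#' motif copies are truncated from the reported span; every reported motif
#' has minimal period (an (AC)3 run is never additionally reported with
#' period 4 or 6). Overlaps are resolved greedily: contigs are scanned
#' left to right, periods tried in increasing order at each position, and
#' scanning resumes immediately after each emitted locus, so the returned
#' loci are mutually non-overlapping — the convention of MISA/Krait-style
#' repeat scanners.
#'
#' @param genome A `genome_record` (see [read_fasta()] or [genome_record()]).
#' @param params A [scan_params()] object.
#' @return A data.frame with one row per locus and columns `genome_id`,
#'   `contig_id`, `start`, `end` (1-based inclusive), `period`, `motif`
#'   (as observed), `standard_motif` (canonical class), `repeats`
#'   (complete copies) and `length` (bases), sorted by contig then start.
#' @examples
#' g <- genome_record("demo", c(c1 = "GGATATATATAGG"))
#' scan_ssrs(g)
#' @export
scan_ssrs <- function(genome, params = scan_params()) {
  stopifnot(inherits(genome, "genome_record"), inherits(params, "scan_params"))
  res <- lapply(names(genome$contigs), function(cid) {
    s <- genome$contigs[[cid]]
    hits <- .scan_string(s, params)
    if (nrow(hits) == 0L) return(NULL)
    motif <- substring(s, hits$start, hits$start + hits$period - 1L)
    data.frame(genome_id = genome$genome_id, contig_id = cid,
               start = hits$start, end = hits$end, period = hits$period,
               motif = motif, standard_motif = standardize_motif(motif),
               repeats = hits$copies,
               length = hits$period * hits$copies)
  })
  res <- res[!vapply(res, is.null, logical(1L))]
  if (!length(res)) return(.empty_ssr_loci())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
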