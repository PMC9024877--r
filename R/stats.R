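.PERIOD_NAMES <- c("mono", "di", "tri", "tetra", "penta", "hexa")

#' Rank label of the mono/di/tri repeat-type composition
#'
#' Orders the mononucleotide, dinucleotide and trinucleotide SSR counts of
#' a genome and returns a label such as `"di>tri>mono"`. Tied counts are
#' joined with `"="` and the result carries a logical `tie` attribute so
#' ambiguous orderings can be flagged downstream.
#'
#' @param type_counts Numeric vector of per-period SSR counts; elements
#'   1-3 (mono, di, tri) must be present.
#' @return Length-1 character label with attribute `tie`.
#' @examples
#' classify_pattern(c(1000, 3000, 2000))  # "di>tri>mono"
#' @export
classify_pattern <- function(type_counts) {
  if (length(type_counts) < 3L || anyNA(type_counts[1:3])) {
    stop("`type_counts` must supply counts for periods 1-3")
  }
  v <- as.numeric(type_counts[1:3])
  names(v) <- .PERIOD_NAMES[1:3]
  o <- order(-v)  # stable: ties keep mono < di < tri order
  sep <- ifelse(v[o][-1L] == v[o][-3L], "=", ">")
  label <- paste0(names(v)[o][1L], sep[1L], names(v)[o][2L], sep[2L],
                  names(v)[o][3L])
  structure(label, tie = any(sep == "="))
}

#' Per-genome microsatellite summary statistics
#'
#' Computes the per-genome survey statistics: locus counts (nSSR, nCSSR,
#' ncSSR), the percentage of SSRs engaged in compound loci
#' (cSSR% = 100 * ncSSR / nSSR), relative abundance (RA, loci per kb of
#' genome) and relative density (RD, repeat base pairs per kb) for SSRs
#' and CSSRs, repeat-type composition by period, the mono/di/tri pattern
#' label, and coding fractions. RD for compound loci uses the full locus
#' span including interruptions, treating the compound locus as one
#' genomic feature. Denominators use the total assembly length including
#' ambiguity bases; 1 kb = 1000 bp exactly.
#'
#' @param genome A [genome_record()].
#' @param ssrs SSR loci of this genome (annotated by [build_cssrs()]).
#' @param cssrs CSSR loci of this genome.
#' @param ssr_regions,cssr_regions Optional region call vectors from
#'   [classify_regions()] (NULL when the genome has no annotation, in
#'   which case coding fractions are reported as NA).
#' @return One-row data.frame (`genome_summary` row); the `Z`-related
#'   columns are filled later at cohort level.
#' @export
summarize_genome <- function(genome, ssrs, cssrs,
                             ssr_regions = NULL, cssr_regions = NULL) {
  stopifnot(inherits(genome, "genome_record"))
  if (genome$total_length == 0L) {
    stop("genome '", genome$genome_id, "' has size 0")
  }
  kb <- genome$total_length / 1000
  nSSR <- nrow(ssrs)
  nCSSR <- nrow(cssrs)
  ncSSR <- if (nCSSR > 0L) sum(cssrs$complexity) else 0L
  type_counts <- vapply(1:6, function(p) sum(ssrs$period == p), integer(1L))
  pat <- classify_pattern(type_counts)
  out <- data.frame(
    genome_id = genome$genome_id,
    subclade = genome$subclade,
    genome_size = genome$total_length,
    gc_content = genome$gc_content,
    nSSR = nSSR,
    nCSSR = nCSSR,
    ncSSR = as.integer(ncSSR),
    cSSR_pct = if (nSSR > 0L) 100 * ncSSR / nSSR else NA_real_,
    RA_ssr = nSSR / kb,
    RD_ssr = sum(ssrs$length) / kb,
    RA_cssr = nCSSR / kb,
    RD_cssr = if (nCSSR > 0L) sum(cssrs$span_length) / kb else 0,
    pattern = as.character(pat),
    pattern_tie = attr(pat, "tie"),
    coding_fraction_ssr = if (is.null(ssr_regions)) NA_real_
                          else coding_fraction(ssr_regions),
    coding_fraction_cssr = if (is.null(cssr_regions)) NA_real_
                           else coding_fraction(cssr_regions),
    nCSSR_exp = NA_real_,
    Z = NA_real_
  )
  tc <- as.data.frame(as.list(type_counts))
  names(tc) <- paste0("n_", .PERIOD_NAMES)
  cbind(out, tc)
}

#' Relative-abundance matrix of standard motifs across genomes
#'
#' Builds the motifs x genomes matrix of relative abundance (loci per kb)
#' underlying the standard-motif heatmap. A motif appears as a row iff it
#' was observed in at least one genome; motifs absent from a genome get 0
#' in that genome's column. Per-genome column sums therefore reproduce
#' RA_ssr exactly.
#'
#' @param loci Pooled SSR loci data.frame across the cohort.
#' @param genome_sizes Named numeric vector: genome id -> assembly length
#'   in bases; defines the column set and order.
#' @param periods Periods to include (default all, 1-6).
#' @return Numeric matrix; rownames are standard motifs sorted by period
#'   then alphabetically, colnames are genome ids.
#' @export
motif_ra_matrix <- function(loci, genome_sizes, periods = 1:6) {
  gids <- names(genome_sizes)
  if (is.null(gids)) stop("`genome_sizes` must be named by genome id")
  loci <- loci[loci$period %in% periods, , drop = FALSE]
  motifs <- unique(loci[, c("period", "standard_motif")])
  motifs <- motifs[order(motifs$period,
                         motifs$standard_motif, method = "radix"), ,
                   drop = FALSE]
  mat <- matrix(0, nrow = nrow(motifs), ncol = length(gids),
                dimnames = list(motifs$standard_motif, gids))
  if (nrow(loci) > 0L) {
    counts <- table(factor(loci$standard_motif,
                           levels = motifs$standard_motif),
                    factor(loci$genome_id, levels = gids))
    mat <- sweep(unclass(counts), 2L, genome_sizes[gids] / 1000, "/")
    dimnames(mat) <- list(motifs$standard_motif, gids)
  }
  mat
}
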