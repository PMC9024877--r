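.empty_cssr_loci <- function() {
  data.frame(genome_id = character(0L), cssr_id = character(0L),
             contig_id = character(0L), start = integer(0L),
             end = integer(0L), complexity = integer(0L),
             compound_motif = character(0L), span_length = integer(0L),
             member_count = integer(0L))
}

#' Assemble compound microsatellites (CSSRs) from individual SSRs
#'
#' Two adjacent SSRs on the same contig belong to the same compound locus
#' when the gap between them — the number of bases strictly between the end
#' of one and the start of the next — is at most `dmax` (10 bp by
#' convention for prokaryotic surveys; a gap of 0 means the repeats abut).
#' A CSSR is a maximal chain of at least two such SSRs; its complexity is
#' the number of member SSRs and its compound motif joins the members'
#' standard motifs in genomic order, e.g. `"A-AC-AGC"`. Member SSRs keep
#' their identity: they still count towards nSSR, which is what makes
#' cSSR% = ncSSR/nSSR a well-defined fraction.
#'
#' @param loci SSR loci data.frame from [scan_ssrs()], sorted by contig and
#'   start with no overlaps (the scanner guarantees both).
#' @param dmax Maximum allowed gap in bases between adjacent members.
#' @return A list with `cssrs` (data.frame: `genome_id`, `cssr_id`,
#'   `contig_id`, `start`, `end`, `complexity`, `compound_motif`,
#'   `span_length`, `member_count`) and `loci` (the input with added
#'   logical `in_cssr` and character `cssr_id` columns).
#' @examples
#' g <- genome_record("demo", c(c1 = "AAAAAACGCGTACACAC"))
#' build_cssrs(scan_ssrs(g), dmax = 10)
#' @export
build_cssrs <- function(loci, dmax = 10L) {
  stopifnot(is.data.frame(loci), dmax >= 0)
  loci$in_cssr <- logical(nrow(loci))
  loci$cssr_id <- rep(NA_character_, nrow(loci))
  if (nrow(loci) == 0L) {
    return(list(cssrs = .empty_cssr_loci(), loci = loci))
  }
  key <- paste(loci$genome_id, loci$contig_id, sep = "\r")
  groups <- split(seq_len(nrow(loci)), factor(key, levels = unique(key)))
  cssr_rows <- list()
  for (idx in groups) {
    s <- loci$start[idx]; e <- loci$end[idx]
    if (is.unsorted(s, strictly = TRUE) ||
        (length(idx) > 1L && any(s[-1L] <= e[-length(e)]))) {
      stop("internal contract violated: SSR loci must be sorted and ",
           "non-overlapping within each contig")
    }
    gap <- if (length(idx) > 1L) s[-1L] - e[-length(e)] - 1L else integer(0L)
    chain <- cumsum(c(TRUE, gap > dmax))
    for (ch in split(seq_along(idx), chain)) {
      if (length(ch) < 2L) next
      members <- idx[ch]
      gid <- loci$genome_id[members[1L]]
      cid <- loci$contig_id[members[1L]]
      cssr_id <- sprintf("%s:%s:%d", gid, cid, loci$start[members[1L]])
      loci$in_cssr[members] <- TRUE
      loci$cssr_id[members] <- cssr_id
      cssr_rows[[length(cssr_rows) + 1L]] <- data.frame(
        genome_id = gid, cssr_id = cssr_id, contig_id = cid,
        start = loci$start[members[1L]],
        end = loci$end[members[length(members)]],
        complexity = length(members),
        compound_motif = paste(loci$standard_motif[members],
                               collapse = "-"),
        span_length = loci$end[members[length(members)]] -
          loci$start[members[1L]] + 1L,
        member_count = length(members))
    }
  }
  cssrs <- if (length(cssr_rows)) do.call(rbind, cssr_rows)
           else .empty_cssr_loci()
  rownames(cssrs) <- NULL
  list(cssrs = cssrs, loci = loci)
}

#' Complexity spectrum of compound microsatellites
#'
#' Tabulates how many CSSRs have each complexity (number of member SSRs)
#' and the corresponding proportions. Pooling across genomes is achieved
#' simply by passing the concatenated CSSR table.
#'
#' @param cssrs CSSR data.frame from [build_cssrs()].
#' @return data.frame with columns `complexity`, `count`, `proportion`
#'   (proportions sum to 1 over non-empty input).
#' @export
complexity_spectrum <- function(cssrs) {
  if (nrow(cssrs) == 0L) {
    return(data.frame(complexity = integer(0L), count = integer(0L),
                      proportion = numeric(0L)))
  }
  tb <- table(cssrs$complexity)
  data.frame(complexity = as.integer(names(tb)),
             count = as.integer(tb),
             proportion = as.numeric(tb) / sum(tb))
}

#' Compound-motif patterns unique to a single genome
#'
#' A compound-motif pattern (e.g. `"AC-AGC"`) is called unique when it
#' occurs in exactly one genome of the cohort, regardless of how many
#' times it occurs there. Patterns are compared as given in genomic order;
#' no reverse-collapsing is applied.
#'
#' @param cssrs Pooled CSSR data.frame (column `genome_id` identifies the
#'   genome of each compound locus).
#' @param genome_ids Optional character vector fixing the genome set and
#'   order of the output (genomes with no CSSRs then report 0).
#' @return list with `per_genome` (data.frame `genome_id`,
#'   `n_unique_motifs`) and `total` (sum over genomes).
#' @export
unique_compound_motifs <- function(cssrs, genome_ids = NULL) {
  if (is.null(genome_ids)) genome_ids <- unique(cssrs$genome_id)
  if (length(genome_ids) < 1L) stop("at least one genome is required")
  pres <- unique(cssrs[, c("genome_id", "compound_motif")])
  n_genomes <- table(pres$compound_motif)
  uniq_patterns <- names(n_genomes)[n_genomes == 1L]
  hit <- pres[pres$compound_motif %in% uniq_patterns, , drop = FALSE]
  counts <- table(factor(hit$genome_id, levels = genome_ids))
  per_genome <- data.frame(genome_id = genome_ids,
                           n_unique_motifs = as.integer(counts))
  list(per_genome = per_genome, total = sum(per_genome$n_unique_motifs))
}
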