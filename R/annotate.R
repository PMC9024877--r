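#' Classify loci as coding or noncoding by CDS overlap
#'
#' A locus is coding when its span overlaps any CDS interval by at least
#' one base; adjacency is not overlap. Compound loci are classified by
#' their full span, not per member. With no annotation available the
#' region is reported as NA (missing), never as zero/noncoding.
#'
#' @param loci data.frame with columns `contig_id`, `start`, `end` (SSR or
#'   CSSR table).
#' @param annotation An [annotation_index()], or NULL when the genome has
#'   no annotation.
#' @return Character vector, one of `"coding"`/`"noncoding"` per locus
#'   (all NA when `annotation` is NULL). Loci on contigs outside the
#'   annotation's contig namespace are classified noncoding with a warning.
#' @export
classify_regions <- function(loci, annotation = NULL) {
  n <- nrow(loci)
  if (is.null(annotation)) return(rep(NA_character_, n))
  stopifnot(inherits(annotation, "annotation_index"))
  if (n == 0L) return(character(0L))
  unknown <- !(loci$contig_id %in% names(annotation$contig_lengths))
  if (any(unknown)) {
    warning("loci on contig(s) unknown to the annotation classified ",
            "noncoding: ",
            paste(unique(loci$contig_id[unknown]), collapse = ", "))
  }
  region <- rep("noncoding", n)
  cds <- annotation$cds
  if (nrow(cds) > 0L) {
    for (cid in unique(loci$contig_id)) {
      qi <- which(loci$contig_id == cid)
      si <- cds$contig_id == cid
      if (!any(si)) next
      hit <- IRanges::overlapsAny(
        IRanges::IRanges(loci$start[qi], loci$end[qi]),
        IRanges::IRanges(cds$start[si], cds$end[si]))
      region[qi[hit]] <- "coding"
    }
  }
  region
}

#' Percentage of classified loci falling in coding sequence
#'
#' @param region Character vector of `"coding"`/`"noncoding"` calls (NAs
#'   allowed and dropped).
#' @return Percentage in \[0, 100\], or NA when no locus is classified.
#' @export
coding_fraction <- function(region) {
  region <- region[!is.na(region)]
  if (length(region) == 0L) return(NA_real_)
  100 * mean(region == "coding")
}
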