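#' Construct a genome record
#'
#' Container for one genome assembly: an ordered set of contig sequences
#' plus derived statistics. Sequences are uppercased and U is mapped to T;
#' GC content is computed over unambiguous bases only, i.e.
#' (G + C) / (A + C + G + T), so ambiguity codes never enter the
#' denominator.
#'
#' @param genome_id Genome identifier.
#' @param contigs Named character vector of contig sequences; names are the
#'   contig ids and must be unique.
#' @param subclade Optional subclade/group label carried through outputs.
#' @return An object of class `genome_record` with elements `genome_id`,
#'   `contigs`, `total_length`, `gc_content`, `subclade`.
#' @export
genome_record <- function(genome_id, contigs, subclade = NA_character_) {
  if (!is.character(contigs) || length(contigs) < 1L) {
    stop("`contigs` must be a non-empty named character vector")
  }
  ids <- names(contigs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every contig must be named")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate contig ids in genome '", genome_id, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  contigs <- chartr("U", "T", toupper(contigs))
  names(contigs) <- ids
  counts <- .base_counts(contigs)
  denom <- sum(counts)
  structure(list(
    genome_id = as.character(genome_id),
    contigs = contigs,
    total_length = sum(nchar(contigs)),
    gc_content = if (denom > 0L) (counts[["G"]] + counts[["C"]]) / denom
                 else NA_real_,
    subclade = subclade
  ), class = "genome_record")
}

.base_counts <- function(seqs) {
  freq <- Biostrings::letterFrequency(Biostrings::BStringSet(seqs),
                                      letters = c("A", "C", "G", "T"))
  colSums(freq)
}

#' @export
print.genome_record <- function(x, ...) {
  cat("Genome '", x$genome_id, "': ", length(x$contigs), " contig(s), ",
      x$total_length, " bp, GC ", sprintf("%.2f%%", 100 * x$gc_content),
      "\n", sep = "")
  invisible(x)
}

# Fraction of characters outside the IUPAC nucleotide alphabet above which
# a record is rejected as not nucleotide sequence.
.MAX_NON_NUC_FRACTION <- 0.1
.IUPAC <- "ACGTURYSWKMBDHVN"

#' Read a genome assembly from FASTA
#'
#' Reads a (multi-record) FASTA file into a [genome_record()]. Sequences
#' are uppercased, U is mapped to T, and soft-masked (lowercase) sequence
#' is treated as ordinary sequence. Contig ids are the first whitespace
#' token of each header.
#'
#' @param path Path to the FASTA file.
#' @param genome_id Identifier for the genome.
#' @param subclade Optional subclade/group label.
#' @return A `genome_record`.
#' @export
read_fasta <- function(path, genome_id, subclade = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file '", path, "' contains no sequences")
  }
  seqs <- chartr("U", "T", toupper(as.character(set)))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1L), 1L)
  names(seqs) <- ids
  if (anyDuplicated(ids)) {
    stop("duplicate contig ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad_frac <- vapply(seqs, function(s) {
    n <- nchar(s)
    if (n == 0L) return(0)
    kept <- nchar(gsub(paste0("[", .IUPAC, "]"), "", s))
    kept / n
  }, numeric(1L))
  if (any(bad_frac > .MAX_NON_NUC_FRACTION)) {
    stop("record(s) not nucleotide-dominant in '", path, "': ",
         paste(ids[bad_frac > .MAX_NON_NUC_FRACTION], collapse = ", "))
  }
  genome_record(genome_id, seqs, subclade = subclade)
}

#' Construct a CDS annotation index
#'
#' @param genome_id Genome identifier.
#' @param cds data.frame with columns `contig_id`, `start`, `end`
#'   (1-based inclusive). Intervals may overlap.
#' @param contig_lengths Named integer vector of contig lengths, defining
#'   the contig namespace of the genome.
#' @return An object of class `annotation_index`.
#' @export
annotation_index <- function(genome_id, cds, contig_lengths) {
  stopifnot(is.data.frame(cds),
            all(c("contig_id", "start", "end") %in% names(cds)))
  if (nrow(cds) > 0L) {
    if (any(cds$start < 1L) || any(cds$start > cds$end)) {
      stop("CDS intervals must satisfy 1 <= start <= end")
    }
    lens <- contig_lengths[cds$contig_id]
    if (any(is.na(lens)) || any(cds$end > lens)) {
      stop("CDS interval outside contig bounds")
    }
    cds <- cds[order(cds$contig_id, cds$start, cds$end), , drop = FALSE]
    rownames(cds) <- NULL
  }
  structure(list(genome_id = as.character(genome_id),
                 cds = cds,
                 contig_lengths = contig_lengths),
            class = "annotation_index")
}

#' Read CDS features from a GFF3 annotation
#'
#' Imports a GFF3 file and indexes the intervals of features of type
#' `CDS` (by default); all other feature types are ignored and strand is
#' ignored, since placement of a repeat is defined by overlap, not by
#' reading frame. Features on contigs absent from the genome are skipped
#' with a warning; intervals extending past a contig end are clipped with
#' a warning.
#'
#' @param path Path to the GFF3 file.
#' @param genome The matching [genome_record()].
#' @param feature_type Feature type to index (default `"CDS"`).
#' @return An `annotation_index`.
#' @export
read_gff_cds <- function(path, genome, feature_type = "CDS") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  stopifnot(inherits(genome, "genome_record"))
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   stop("failed to parse GFF3 file '", path, "': ",
                        conditionMessage(e), call. = FALSE)
                 })
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == feature_type]
  cds <- data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
  lens <- nchar(genome$contigs)
  unknown <- !(cds$contig_id %in% names(lens))
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " ", feature_type,
            " feature(s) on contig(s) absent from genome '",
            genome$genome_id, "': ",
            paste(unique(cds$contig_id[unknown]), collapse = ", "))
    cds <- cds[!unknown, , drop = FALSE]
  }
  if (nrow(cds) > 0L) {
    lim <- lens[cds$contig_id]
    clip <- cds$end > lim | cds$start < 1L
    if (any(clip)) {
      warning("clipping ", sum(clip), " ", feature_type,
              " interval(s) to contig bounds")
      cds$start <- pmax(cds$start, 1L)
      cds$end <- pmin(cds$end, lim)
    }
  }
  annotation_index(genome$genome_id, cds, lens)
}

#' Read a cohort manifest
#'
#' A cohort manifest is a tab-separated file with columns `genome_id`,
#' `fasta_path` and optionally `gff_path` and `subclade`. Relative paths
#' are resolved against the manifest's own directory.
#'
#' @param path Path to the manifest TSV.
#' @return data.frame with columns `genome_id`, `fasta_path`, `gff_path`,
#'   `subclade` (missing optional columns filled with NA).
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "fasta_path") %in% names(m))) {
    stop("manifest must have columns `genome_id` and `fasta_path`")
  }
  if (is.null(m$gff_path)) m$gff_path <- NA_character_
  if (is.null(m$subclade)) m$subclade <- NA_character_
  base <- dirname(path)
  resolve <- function(p) {
    ifelse(is.na(p) | p == "" | grepl("^(/|[A-Za-z]:)", p),
           p, file.path(base, p))
  }
  m$fasta_path <- resolve(m$fasta_path)
  m$gff_path <- resolve(m$gff_path)
  m[, c("genome_id", "fasta_path", "gff_path", "subclade")]
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
}

#' Read back an ssr_loci table written by [write_survey_tables()]
#' @param path Path to `ssr_loci.tsv`.
#' @return data.frame with the original column types.
#' @export
read_ssr_loci <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = c(
    genome_id = "character", contig_id = "character", start = "integer",
    end = "integer", period = "integer", motif = "character",
    standard_motif = "character", repeats = "integer", length = "integer",
    region = "character", in_cssr = "logical"))
}

#' Write all survey result tables
#'
#' Writes the fixed set of deterministic TSV outputs of a survey run plus a
#' JSON run manifest echoing every parameter, so that identical inputs and
#' configuration always produce byte-identical output files.
#'
#' Files written: `ssr_loci.tsv`, `cssr_loci.tsv`, `genome_summary.tsv`,
#' `motif_ra_matrix.tsv`, `correlations.tsv`, `unique_motifs.tsv`,
#' `z_scores.tsv`, `cohort_report.tsv`, `run_manifest.json`.
#'
#' @param result A survey result list as returned by [run_survey()] or
#'   [survey_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
write_survey_tables <- function(result, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  files <- c(ssr_loci = "ssr_loci.tsv", cssr_loci = "cssr_loci.tsv",
             genome_summary = "genome_summary.tsv",
             motif_ra_matrix = "motif_ra_matrix.tsv",
             correlations = "correlations.tsv",
             unique_motifs = "unique_motifs.tsv",
             z_scores = "z_scores.tsv",
             cohort_report = "cohort_report.tsv")
  .write_tsv(result$loci, file.path(out_dir, files["ssr_loci"]))
  .write_tsv(result$cssrs, file.path(out_dir, files["cssr_loci"]))
  .write_tsv(result$summaries, file.path(out_dir, files["genome_summary"]))
  ra <- as.data.frame(result$motif_ra)
  ra <- cbind(standard_motif = rownames(result$motif_ra), ra)
  rownames(ra) <- NULL
  .write_tsv(ra, file.path(out_dir, files["motif_ra_matrix"]))
  .write_tsv(result$correlations, file.path(out_dir, files["correlations"]))
  .write_tsv(result$unique_motifs$per_genome,
             file.path(out_dir, files["unique_motifs"]))
  .write_tsv(result$z_scores, file.path(out_dir, files["z_scores"]))
  .write_tsv(result$report, file.path(out_dir, files["cohort_report"]))
  manifest <- result$params
  manifest$n_genomes <- nrow(result$summaries)
  manifest$files <- unname(files)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(file.path(out_dir, c(files, "run_manifest.json")))
}
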