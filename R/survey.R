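.SSR_COLS <- c("genome_id", "contig_id", "start", "end", "period",
               "motif", "standard_motif", "repeats", "length", "region",
               "in_cssr", "cssr_id")
.CSSR_COLS <- c("genome_id", "contig_id", "start", "end", "complexity",
                "compound_motif", "span_length", "member_count", "region",
                "cssr_id")

.empty_summaries <- function() {
  g <- genome_record("x", c(c1 = "ACGT"))
  summarize_genome(g, .empty_ssr_loci(), .empty_cssr_loci())[0L, ,
                                                            drop = FALSE]
}

.empty_correlations <- function() {
  data.frame(pair = character(0L), var1 = character(0L),
             var2 = character(0L), rho = numeric(0L),
             p_value = numeric(0L), n = integer(0L))
}

#' Run the full microsatellite survey over in-memory genomes
#'
#' Executes every stage of the pipeline — SSR scan, compound assembly,
#' coding/noncoding classification, per-genome summaries, motif abundance
#' matrix, cohort mean complexity and Z index, Pearson correlations,
#' unique compound motifs and the cohort report — over a list of genomes
#' already in memory.
#'
#' @param genomes List of [genome_record()] objects.
#' @param annotations Optional list of [annotation_index()] objects (or
#'   NULL elements), parallel to `genomes` or named by genome id.
#' @param params [scan_params()] for the SSR scan.
#' @param dmax Compound-locus gap threshold in bases.
#' @param z_denominator `"sqrt"` or `"linear"` (see [z_scores()]).
#' @param pearson_pairs Optional correlation panel (see [pearson_table()]).
#' @return A list of class `ssr_survey` with elements `loci`, `cssrs`,
#'   `summaries`, `motif_ra`, `correlations`, `z_scores`,
#'   `unique_motifs`, `report` and `params`.
#' @export
survey_cohort <- function(genomes, annotations = NULL,
                          params = scan_params(), dmax = 10L,
                          z_denominator = c("sqrt", "linear"),
                          pearson_pairs = NULL) {
  z_denominator <- match.arg(z_denominator)
  stopifnot(is.list(genomes))
  gids <- vapply(genomes, function(g) g$genome_id, character(1L))
  if (anyDuplicated(gids)) stop("duplicate genome ids in cohort")
  get_ann <- function(i) {
    if (is.null(annotations)) return(NULL)
    a <- if (!is.null(names(annotations))) annotations[[gids[i]]]
         else annotations[[i]]
    a
  }
  loci_all <- list(); cssr_all <- list(); summ_all <- list()
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    ssrs <- scan_ssrs(g, params)
    comp <- build_cssrs(ssrs, dmax = dmax)
    ssrs <- comp$loci
    cssrs <- comp$cssrs
    ann <- get_ann(i)
    ssrs$region <- classify_regions(ssrs, ann)
    cssrs$region <- classify_regions(cssrs, ann)
    summ_all[[i]] <- summarize_genome(
      g, ssrs, cssrs,
      ssr_regions = if (is.null(ann)) NULL else ssrs$region,
      cssr_regions = if (is.null(ann)) NULL else cssrs$region)
    loci_all[[i]] <- ssrs[, .SSR_COLS]
    cssr_all[[i]] <- cssrs[, .CSSR_COLS]
  }
  loci <- if (length(loci_all)) do.call(rbind, loci_all)
          else {
            e <- .empty_ssr_loci()
            e$region <- character(0L); e$in_cssr <- logical(0L)
            e$cssr_id <- character(0L)
            e
          }
  cssrs <- if (length(cssr_all)) do.call(rbind, cssr_all)
           else {
             e <- .empty_cssr_loci()
             e$region <- character(0L)
             e[, .CSSR_COLS]
           }
  rownames(loci) <- rownames(cssrs) <- NULL
  summaries <- if (length(summ_all)) do.call(rbind, summ_all)
               else .empty_summaries()
  rownames(summaries) <- NULL
  sizes <- stats::setNames(summaries$genome_size, summaries$genome_id)
  motif_ra <- motif_ra_matrix(loci, sizes)
  z <- data.frame(genome_id = character(0L), ncSSR = integer(0L),
                  nCSSR_obs = integer(0L), nCSSR_exp = numeric(0L),
                  Z = numeric(0L))
  if (nrow(summaries) > 0L && any(summaries$nCSSR > 0L)) {
    c_bar <- mean_complexity(summaries)
    z <- z_scores(summaries, c_bar, denominator = z_denominator)
    summaries$nCSSR_exp <- z$nCSSR_exp
    summaries$Z <- z$Z
  }
  correlations <- if (nrow(summaries) >= 3L) {
    pearson_table(summaries, pearson_pairs)
  } else .empty_correlations()
  uniq <- unique_compound_motifs(cssrs, genome_ids = gids)
  report <- cohort_report(summaries, cssrs)
  structure(list(
    loci = loci, cssrs = cssrs, summaries = summaries,
    motif_ra = motif_ra, correlations = correlations, z_scores = z,
    unique_motifs = uniq, report = report,
    params = list(min_repeats = params$min_repeats,
                  max_period = params$max_period, dmax = dmax,
                  z_denominator = z_denominator,
                  pearson_pairs = if (is.null(pearson_pairs)) "default"
                                  else "custom")
  ), class = "ssr_survey")
}

#' @export
print.ssr_survey <- function(x, ...) {
  cat("Microsatellite survey: ", nrow(x$summaries), " genome(s), ",
      sum(x$summaries$nSSR), " SSRs, ", sum(x$summaries$nCSSR),
      " CSSRs\n", sep = "")
  invisible(x)
}

#' Run the survey end-to-end from a cohort manifest
#'
#' Reads every genome (and its optional GFF3 annotation) named in the
#' manifest, runs [survey_cohort()], and optionally writes all result
#' tables. A failure on one genome (missing file, malformed input) is
#' recorded and reported without aborting the remaining cohort.
#'
#' @param manifest Path to a manifest TSV (see [read_cohort_manifest()])
#'   or an equivalent data.frame.
#' @param out_dir Optional output directory for [write_survey_tables()].
#' @inheritParams survey_cohort
#' @return The `ssr_survey` result, with an extra `failures` data.frame
#'   (`genome_id`, `error`) and a `status` code (0 = clean run, 1 =
#'   partial failure).
#' @export
run_survey <- function(manifest, out_dir = NULL, params = scan_params(),
                       dmax = 10L, z_denominator = c("sqrt", "linear"),
                       pearson_pairs = NULL) {
  if (is.character(manifest)) manifest <- read_cohort_manifest(manifest)
  if (!is.data.frame(manifest) || nrow(manifest) < 1L) {
    stop("manifest must name at least one genome")
  }
  if (is.null(manifest$gff_path)) manifest$gff_path <- NA_character_
  if (is.null(manifest$subclade)) manifest$subclade <- NA_character_
  genomes <- list(); annotations <- list()
  failures <- data.frame(genome_id = character(0L), error = character(0L))
  for (i in seq_len(nrow(manifest))) {
    gid <- manifest$genome_id[i]
    res <- tryCatch({
      g <- read_fasta(manifest$fasta_path[i], gid,
                      subclade = manifest$subclade[i])
      a <- if (!is.na(manifest$gff_path[i]) &&
               nzchar(manifest$gff_path[i])) {
        read_gff_cds(manifest$gff_path[i], g)
      } else NULL
      list(g = g, a = a)
    }, error = function(e) {
      message("genome '", gid, "' failed: ", conditionMessage(e))
      conditionMessage(e)
    })
    if (is.character(res)) {
      failures <- rbind(failures,
                        data.frame(genome_id = gid, error = res))
    } else {
      genomes[[length(genomes) + 1L]] <- res$g
      annotations[[length(genomes)]] <- res$a
    }
  }
  if (!length(genomes)) stop("no genome in the manifest could be read")
  out <- survey_cohort(genomes, annotations, params = params,
                       dmax = dmax, z_denominator = z_denominator,
                       pearson_pairs = pearson_pairs)
  out$failures <- failures
  out$status <- if (nrow(failures) > 0L) 1L else 0L
  if (!is.null(out_dir)) write_survey_tables(out, out_dir)
  out
}
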