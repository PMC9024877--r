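#!/usr/bin/env Rscript
# Step 3 — cohort-level narrative tables.
#
# Reads the survey outputs of step 2 and derives the headline tables of a
# genome-wide repeat survey: recovery against the planted truth, the
# complexity spectrum, and the repeat-type pattern tally. Writes three
# small TSVs to results/.
#
# Usage: Rscript analysis/03_cohort_stats.R   (requires 02_survey.R first)

suppressPackageStartupMessages(library(ssrsurvey))

root <- normalizePath(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE)[1])), ".."))
survey_dir <- file.path(root, "scratch", "survey")
cohort_dir <- file.path(root, "scratch", "cohort")
results <- file.path(root, "results")
if (!dir.exists(survey_dir)) {
  stop("run analysis/02_survey.R first (missing ", survey_dir, ")")
}
tsv <- function(...) read.delim(file.path(...), check.names = FALSE)

loci <- read_ssr_loci(file.path(survey_dir, "ssr_loci.tsv"))
cssrs <- tsv(survey_dir, "cssr_loci.tsv")
truth_ssr <- tsv(cohort_dir, "truth_ssr.tsv")
truth_cssr <- tsv(cohort_dir, "truth_cssr.tsv")
summaries <- tsv(survey_dir, "genome_summary.tsv")

# recovery of the planted truth, per genome
key <- function(d) paste(d$genome_id, d$contig_id, d$start, d$end)
recovery <- data.frame(
  genome_id = summaries$genome_id,
  ssr_planted = as.integer(table(factor(truth_ssr$genome_id,
                                        summaries$genome_id))),
  ssr_found = summaries$nSSR,
  cssr_planted = as.integer(table(factor(truth_cssr$genome_id,
                                         summaries$genome_id))),
  cssr_found = summaries$nCSSR)
recovery$ssr_recovered_pct <- 100 *
  vapply(split(key(loci) %in% key(truth_ssr), loci$genome_id), mean,
         numeric(1))[recovery$genome_id]
write.table(recovery, file.path(results, "planted_recovery.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

spectrum <- complexity_spectrum(cssrs)
write.table(spectrum, file.path(results, "complexity_spectrum.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

patterns <- as.data.frame(table(pattern = summaries$pattern),
                          responseName = "n_genomes")
write.table(patterns, file.path(results, "pattern_tally.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("recovery, complexity spectrum and pattern tally written to",
    results, "\n")
print(recovery)
print(spectrum)
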