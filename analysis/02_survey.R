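#!/usr/bin/env Rscript
# Step 2 — survey the simulated cohort from its on-disk manifest.
#
# Runs the full pipeline (scan, compound assembly, coding placement,
# per-genome and cohort statistics) over scratch/cohort/manifest.tsv.
# The complete table set, including the large per-locus tables, goes to
# scratch/survey/; the small per-genome and cohort tables are copied to
# results/.
#
# Usage: Rscript analysis/02_survey.R   (requires 01_simulate.R first)

suppressPackageStartupMessages(library(ssrsurvey))

root <- normalizePath(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE)[1])), ".."))
manifest <- file.path(root, "scratch", "cohort", "manifest.tsv")
if (!file.exists(manifest)) {
  stop("run analysis/01_simulate.R first (missing ", manifest, ")")
}
survey_dir <- file.path(root, "scratch", "survey")
results <- file.path(root, "results")
dir.create(results, showWarnings = FALSE)

sv <- run_survey(manifest, out_dir = survey_dir)
if (sv$status != 0L) {
  print(sv$failures)
  stop("survey finished with failures")
}
print(sv)

small <- c("genome_summary.tsv", "motif_ra_matrix.tsv",
           "correlations.tsv", "unique_motifs.tsv", "z_scores.tsv",
           "cohort_report.tsv")
ok <- file.copy(file.path(survey_dir, small), results, overwrite = TRUE)
stopifnot(all(ok))
cat("full tables in", survey_dir, "\n")
cat("summary tables copied to", results, "\n")
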