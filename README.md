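# ssrsurvey

Genome-wide survey of perfect microsatellites (SSRs) and compound
microsatellites (CSSRs) in small genome assemblies, with a
synthetic-genome generator that plants repeats with exact ground truth so
the entire pipeline can be validated end to end without external data.

## What it does

- **Scan** every contig for perfect tandem repeats of motif period 1–6.
  Default thresholds: at least 6 copies for mononucleotide motifs, 3 for
  periods 2–6. Runs never cross an ambiguity base or a contig boundary;
  trailing partial copies are truncated; every motif is reported with its
  minimal period. Overlaps are resolved greedily (left to right, shortest
  period first), the convention of MISA/Krait-style scanners. The core
  loop is compiled (Rcpp).
- **Standardize motifs**: each motif maps to the lexicographically
  smallest string among all cyclic rotations of itself and of its reverse
  complement, collapsing phase and strand (`GT`, `TG`, `CA`, `AC` → `AC`).
  Classes per period 1–6: 2, 4, 10, 33, 102, 350.
- **Assemble compound loci**: a CSSR is a maximal chain of ≥ 2 SSRs in
  which adjacent members are separated by at most `dmax` bases
  (default 10). Complexity = number of members; the compound motif joins
  the members' standard motifs, e.g. `"A-AC-AGC"`.
- **Place loci** in coding or noncoding sequence by overlap with CDS
  features from a GFF3 annotation.
- **Summarize**: per-genome relative abundance (loci/kb) and density
  (bp/kb), cSSR% (= 100·ncSSR/nSSR), repeat-type composition patterns,
  per-motif abundance matrix, compound complexity spectrum, the cohort
  mean complexity C̄, a Z index of compound representation
  (Z = (obs − exp)/√exp with exp = ncSSR/C̄), and Pearson correlations of
  repeat counts with genome size and GC content.
- **Simulate**: `generate_genome()` / `generate_cohort()` build genomes
  whose backgrounds are scrubbed of incidental repeats and whose planted
  loci are recovered by the scanner *exactly* — the generator verifies
  scan-vs-truth identity before returning.

## Quick start

```r
library(ssrsurvey)

# synthetic self-validation
sim <- generate_genome(plant_config(genome_size = 2e5,
                                    ssr_plan = default_ssr_plan(60),
                                    cssr_plan = default_cssr_plan(8),
                                    seed = 1), "demo")
sv <- survey_cohort(list(sim$genome), list(sim$annotation))
all.equal(sv$loci$start, sim$truth$ssr$start)   # TRUE

# real data: manifest TSV with genome_id, fasta_path [, gff_path, subclade]
sv <- run_survey("manifest.tsv", out_dir = "survey_out")
sv$summaries
sv$correlations
```

## Repository layout

- `R/`, `src/` — the package (scanner, standardization, compound
  assembly, annotation, statistics, simulator, pipeline driver).
- `analysis/` — numbered narrative scripts: `01_simulate.R` writes a
  synthetic cohort to `scratch/`, `02_survey.R` surveys it,
  `03_cohort_stats.R` derives the cohort tables. Small outputs land in
  `results/`; `scratch/` is disposable.
- `tests/testthat/` — unit and acceptance tests, checked against naive
  reference implementations written independently of the package code.
- `scripts/acceptance.R` — standalone acceptance run:
  `Rscript scripts/acceptance.R --seed 1 --out acceptance.json`.
- `vignettes/` — methods vignette describing every definition and
  formula.

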