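---
title: "Surveying microsatellites and compound microsatellites with ssrsurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying microsatellites and compound microsatellites with ssrsurvey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrsurvey)
```

## Definitions

A **microsatellite (SSR)** is a perfect tandem repeat of a 1–6 bp motif.
A run qualifies when it reaches the copy-number threshold for its motif
period — by default at least **6 copies** for mononucleotide motifs and
**3 copies** for periods 2–6, the thresholds customary for small
prokaryotic genomes:

```{r}
scan_params()
```

The scanner reports maximal perfect runs, truncated to whole motif
copies, with three structural guarantees:

1. runs never cross an ambiguity character (`N` etc.) or a contig
   boundary;
2. every motif is reported with its **minimal period** — an `(AC)3` run
   is never additionally reported as period 4 or 6;
3. overlaps are resolved greedily: contigs are scanned left to right,
   periods tried in increasing order at each position, and scanning
   resumes after each emitted locus, so reported loci never overlap
   (the MISA/Krait convention).

```{r}
g <- genome_record("demo", c(c1 = "GGATATATATAGGCCCCCCCC"))
scan_ssrs(g)
```

## Standard motifs

Motifs differing only by phase (cyclic rotation) or strand (reverse
complement) describe the same repeat, so each motif is mapped to the
lexicographically smallest string among all rotations of itself and of
its reverse complement:

```{r}
standardize_motif(c("GT", "TG", "CA", "AC", "TC", "GCC"))
enumerate_standard_motifs(2)
vapply(1:6, function(p) length(enumerate_standard_motifs(p)), integer(1))
```

Periods 1–6 partition into 2, 4, 10, 33, 102 and 350 classes — the two
mononucleotide and four dinucleotide repeat types are the familiar
special cases.

## Compound microsatellites

Two adjacent SSRs belong to the same **compound locus (CSSR)** when the
gap between them (bases strictly between the end of one and the start of
the next) is at most `dmax`, 10 bp by default. A CSSR is a maximal chain
of at least two SSRs; its **complexity** is the member count and its
compound motif joins the members' standard motifs in genomic order.
Member SSRs keep their identity and still count towards nSSR, which makes
cSSR% = 100·ncSSR/nSSR a well-defined percentage.

```{r}
g <- genome_record("demo", c(c1 = "AAAAAACGTGATACACAC"))
build_cssrs(scan_ssrs(g), dmax = 10)$cssrs
```

## Per-genome statistics

For a genome of size $L$ (bp, ambiguity bases included) with loci
$1,\dots,n$:

- **Relative abundance** $\mathrm{RA} = n / (L/1000)$ — loci per kb;
- **Relative density** $\mathrm{RD} = \sum_i \ell_i / (L/1000)$ — repeat
  bases per kb, where for compound loci $\ell_i$ is the full span
  including interruptions;
- **cSSR%** $= 100 \cdot \mathrm{ncSSR}/\mathrm{nSSR}$, the share of SSRs
  engaged in compound loci;
- the **pattern label** orders the mono/di/tri counts
  (e.g. `"di>tri>mono"`), flagging ties;
- loci are **coding** when they overlap any CDS interval of the GFF3
  annotation by at least one base (`classify_regions()`).

The per-motif abundance matrix (`motif_ra_matrix()`) splits RA by
standard motif, so its column sums reproduce each genome's RA exactly.

## Cohort statistics

The cohort mean complexity is the mean of per-genome member ratios,
$\bar C = \mathrm{mean}_i(\mathrm{ncSSR}_i/\mathrm{nCSSR}_i)$. Under
cohort-average compounding a genome's expected number of compound loci is
$E_i = \mathrm{ncSSR}_i/\bar C$, and the **Z index** standardizes the
observed deviation:

$$Z_i = \frac{\mathrm{nCSSR}_i - E_i}{\sqrt{E_i}}.$$

```{r}
s <- data.frame(genome_id = "g1", ncSSR = 400, nCSSR = 200)
z_scores(s, c_bar = 2.5)   # E = 160, Z = 40/sqrt(160) ~ 3.162
```

Pearson correlations (via `stats::cor.test`) relate nSSR and nCSSR to
genome size, GC content and each other — the standard panel of
genome-wide repeat surveys.

## Synthetic genomes with exact truth

`generate_genome()` samples a background at the target GC, then
iteratively substitutes bases inside any incidental run until a scan of
the background finds nothing. Planted features — individual SSRs and
compound loci with prescribed motifs, copy numbers and gaps — are
inserted with more than `dmax` bases of clearance so independent features
never chain, and a final repair pass guarantees that scanning the
finished genome returns **exactly** the planted truth. A tiled CDS track
provides an annotation whose truth region calls are computed by modular
arithmetic, independently of the pipeline's interval-overlap route.

```{r}
sim <- generate_genome(plant_config(genome_size = 1e5,
                                    ssr_plan = default_ssr_plan(30),
                                    cssr_plan = default_cssr_plan(4),
                                    seed = 42), "toy")
sv <- survey_cohort(list(sim$genome), list(sim$annotation))
identical(sv$loci$start, sim$truth$ssr$start)
sv$summaries[, c("nSSR", "nCSSR", "ncSSR", "cSSR_pct", "RA_ssr")]
```

`generate_cohort()` scales this to many genomes with sizes and GC drawn
from realistic ranges and planted counts proportional to genome size,
which is what the acceptance checks use to verify that the survey
recovers a known size–count correlation.

## Running on real assemblies

```r
# manifest.tsv: genome_id  fasta_path  gff_path  subclade
sv <- run_survey("manifest.tsv", out_dir = "survey_out")
```

`run_survey()` isolates per-genome read failures (reported in
`sv$failures` with `sv$status == 1`) and writes nine deterministic result
tables, including `genome_summary.tsv`, `motif_ra_matrix.tsv`,
`correlations.tsv` and `cohort_report.tsv`.
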