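test_that("genome_record normalizes sequence and computes GC", {
  g <- genome_record("g", c(c1 = "acgu"))
  expect_equal(g$contigs[["c1"]], "ACGT")
  expect_equal(g$gc_content, 0.5)
  expect_equal(g$total_length, 4L)
  # ambiguity bases count towards length but not towards the GC ratio
  g2 <- genome_record("g", c(c1 = "ACGNNN"))
  expect_equal(g2$total_length, 6L)
  expect_equal(g2$gc_content, 2 / 3)
  expect_error(genome_record("g", c("ACGT")), "named")
  expect_error(genome_record("g", c(c1 = "ACGT", c1 = "ACGT")),
               "duplicate contig ids")
})

test_that("GC content is strand-symmetric", {
  set.seed(31)
  s <- ref_random_seq(5000, 0.62)
  g1 <- genome_record("f", c(c1 = s))
  g2 <- genome_record("r", c(c1 = ref_revcomp(s)))
  expect_equal(g1$gc_content, g2$gc_content)
})

test_that("read_fasta round-trips sequences and parses headers", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1 some description here", "ACGTACGTAC", "GGTT",
               ">c2", "acgtn"), path)
  g <- read_fasta(path, "g1", subclade = "5.1")
  expect_equal(names(g$contigs), c("c1", "c2"))
  expect_equal(g$contigs[["c1"]], "ACGTACGTACGGTT")
  expect_equal(g$contigs[["c2"]], "ACGTN")
  expect_equal(g$subclade, "5.1")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa"), "g"),
               "not found")
})

test_that("read_fasta rejects non-nucleotide records and duplicate ids", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKLVINLIFE", ">c1", "ACGT"), path)
  expect_error(read_fasta(path, "g"), "nucleotide-dominant")
  path2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1", "ACGT", ">c1", "GGCC"), path2)
  expect_error(read_fasta(path2, "g"), "duplicate")
})

test_that("read_gff_cds keeps CDS features only and validates bounds", {
  g <- genome_record("g", c(c1 = strrep("GATC", 100L)))
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\ttest\tgene\t1\t300\t.\t+\t.\tID=gene1",
    "c1\ttest\tCDS\t10\t90\t.\t+\t0\tID=cds1",
    "c1\ttest\tCDS\t120\t200\t.\t-\t0\tID=cds2"), path)
  ann <- read_gff_cds(path, g)
  expect_s3_class(ann$cds, "data.frame")
  expect_equal(nrow(ann$cds), 2L)          # the gene line is ignored
  expect_equal(ann$cds$start, c(10L, 120L))
  expect_equal(ann$cds$end, c(90L, 200L))

  # features on unknown contigs are skipped with a warning
  path2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\ttest\tCDS\t10\t90\t.\t+\t0\tID=a",
    "cX\ttest\tCDS\t5\t50\t.\t+\t0\tID=b"), path2)
  expect_warning(ann2 <- read_gff_cds(path2, g), "absent from genome")
  expect_equal(nrow(ann2$cds), 1L)

  # intervals past the contig end are clipped with a warning
  path3 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\ttest\tCDS\t350\t999\t.\t+\t0\tID=c"), path3)
  expect_warning(ann3 <- read_gff_cds(path3, g), "clipping")
  expect_equal(ann3$cds$end, 400L)
})

test_that("cohort manifests resolve relative paths against their location", {
  dir <- withr::local_tempdir()
  writeLines(c(">c1", "ACGTACGT"), file.path(dir, "a.fasta"))
  writeLines("genome_id\tfasta_path\ng1\ta.fasta",
             file.path(dir, "manifest.tsv"))
  m <- read_cohort_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(m$fasta_path, file.path(dir, "a.fasta"))
  expect_true(is.na(m$gff_path))
  expect_true(file.exists(m$fasta_path))
  expect_error(read_cohort_manifest(file.path(dir, "missing.tsv")),
               "not found")
})

test_that("survey tables write deterministically and loci round-trip", {
  sim <- generate_genome(
    plant_config(genome_size = 4e4, ssr_plan = default_ssr_plan(15L),
                 cssr_plan = default_cssr_plan(2L), seed = 3L), "g1")
  sv <- survey_cohort(list(sim$genome), list(sim$annotation))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_survey_tables(sv, d1)
  write_survey_tables(sv, d2)
  expect_true(all(file.exists(f1)))
  for (f in basename(f1)) {   # identical input => byte-identical output
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  back <- read_ssr_loci(file.path(d1, "ssr_loci.tsv"))
  for (col in c("start", "end", "period", "motif", "standard_motif",
                "repeats", "length", "region", "in_cssr")) {
    expect_identical(back[[col]], sv$loci[[col]])
  }
})
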