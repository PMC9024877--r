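small_config <- function(seed = 7L, ...) {
  plant_config(genome_size = 1.2e5, gc_content = 0.58,
               ssr_plan = default_ssr_plan(40L),
               cssr_plan = default_cssr_plan(6L), seed = seed, ...)
}

test_that("identical seed and configuration reproduce the genome exactly", {
  a <- generate_genome(small_config(), "g")
  b <- generate_genome(small_config(), "g")
  expect_identical(a$genome$contigs, b$genome$contigs)
  expect_identical(a$truth$ssr, b$truth$ssr)
  expect_identical(a$truth$cssr, b$truth$cssr)
  c <- generate_genome(small_config(seed = 8L), "g")
  expect_false(identical(a$genome$contigs, c$genome$contigs))
})

test_that("the survey recovers the planted truth exactly at small scale", {
  sim <- generate_genome(small_config(), "g1")
  sv <- survey_cohort(list(sim$genome), list(sim$annotation))
  expect_equal(nrow(sv$loci), nrow(sim$truth$ssr))
  for (col in c("contig_id", "start", "end", "period", "motif",
                "standard_motif", "repeats", "length", "in_cssr",
                "cssr_id", "region")) {
    expect_equal(sv$loci[[col]], sim$truth$ssr[[col]])
  }
  expect_equal(nrow(sv$cssrs), nrow(sim$truth$cssr))
  for (col in c("cssr_id", "start", "end", "complexity",
                "compound_motif", "span_length", "region")) {
    expect_equal(sv$cssrs[[col]], sim$truth$cssr[[col]])
  }
})

test_that("background GC tracks the requested target", {
  sim <- generate_genome(small_config(), "g1")
  expect_lt(abs(sim$truth$background_gc - 0.58), 0.01)
  expect_lt(abs(sim$genome$gc_content - 0.58), 0.02)
})

test_that("planted truth respects the declared feature geometry", {
  sim <- generate_genome(small_config(), "g1")
  tr <- sim$truth$ssr
  # member spans of one compound locus stay within dmax of each other;
  # independent features are separated by more than dmax
  ord <- order(tr$start)
  gap <- tr$start[ord][-1L] - tr$end[ord][-nrow(tr)] - 1L
  same <- tr$cssr_id[ord][-1L] == tr$cssr_id[ord][-nrow(tr)] &
    !is.na(tr$cssr_id[ord][-1L]) & !is.na(tr$cssr_id[ord][-nrow(tr)])
  expect_true(all(gap[same] >= 1L & gap[same] <= 10L))
  expect_true(all(gap[!same] > 10L))
  # planted counts follow the plan
  expect_equal(sum(!tr$in_cssr), sum(default_ssr_plan(40L)$count))
  expect_equal(nrow(sim$truth$cssr), 6L)
  expect_equal(sum(tr$in_cssr), sum(sim$truth$cssr$complexity))
})

test_that("deterministic plans apportion counts exactly", {
  plan <- default_ssr_plan(500L)
  expect_equal(sum(plan$count), 500L)
  expect_identical(plan, default_ssr_plan(500L))
  cplan <- default_cssr_plan(40L)
  expect_length(cplan, 40L)
  cx <- vapply(cplan, function(e) length(e$motifs), integer(1L))
  expect_equal(sum(cx == 2L), 38L)   # 95% of 40
  expect_equal(sum(cx == 3L), 2L)
  # adjacent members never share a motif; gaps always within 1..dmax
  for (e in cplan) {
    expect_true(all(e$motifs[-1L] != e$motifs[-length(e$motifs)]))
    expect_true(all(e$gaps >= 1L & e$gaps <= 10L))
  }
})

test_that("plant_config rejects impossible or undetectable plans", {
  expect_error(
    plant_config(genome_size = 3000,
                 ssr_plan = default_ssr_plan(200L),
                 cssr_plan = list()),
    "do not fit")
  expect_error(
    plant_config(ssr_plan = data.frame(standard_motif = "A",
                                       repeats = 5L, count = 1L),
                 cssr_plan = list()),
    "below the detection thresholds")
  expect_error(
    plant_config(ssr_plan = data.frame(standard_motif = "ACAC",
                                       repeats = 3L, count = 1L),
                 cssr_plan = list()),
    "minimal-period")
  expect_error(
    plant_config(cssr_plan = list(list(motifs = c("A", "AC"),
                                       repeats = c(7L, 3L),
                                       gaps = 0L))),
    "1..dmax")
  expect_error(
    plant_config(cssr_plan = list(list(motifs = "A", repeats = 7L,
                                       gaps = integer(0)))),
    ">= 2 motifs")
})

test_that("generate_cohort validates its arguments and reproduces itself", {
  expect_error(generate_cohort(n = 2), "at least 3")
  expect_error(generate_cohort(n = 3, gc_range = c(0.9, 1.2)),
               "degenerate")
  co <- generate_cohort(n = 3, size_range = c(4e4, 6e4),
                        ssr_per_kb = 0.3, cssr_per_kb = 0.04, seed = 5)
  expect_length(co$genomes, 3L)
  expect_equal(co$truth$planted$genome_id,
               c("synthetic_01", "synthetic_02", "synthetic_03"))
  co2 <- generate_cohort(n = 3, size_range = c(4e4, 6e4),
                         ssr_per_kb = 0.3, cssr_per_kb = 0.04, seed = 5)
  expect_identical(co$truth$ssr, co2$truth$ssr)
  # planted counts match the per-kb density model within rounding + noise
  expect_equal(co$truth$planted$n_ssr_planted,
               vapply(co$genomes, function(g) sum(!g$truth$ssr$in_cssr),
                      integer(1L)))
})
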