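test_that("scan_params validates thresholds and period range", {
  p <- scan_params()
  expect_s3_class(p, "scan_params")
  expect_identical(p$min_repeats, c(6L, 3L, 3L, 3L, 3L, 3L))
  expect_identical(p$max_period, 6L)
  expect_error(scan_params(max_period = 0), "1..6")
  expect_error(scan_params(max_period = 7), "1..6")
  expect_error(scan_params(c(6L, 3L), max_period = 3), "every period")
  expect_error(scan_params(c(6L, 1L, 3L, 3L, 3L, 3L)), ">= 2")
})

test_that("scanner reproduces the definitional examples", {
  scan1 <- function(s) scan_ssrs(genome_record("g", c(c1 = s)))

  r <- scan1("AAAAAA")                 # exactly six A's qualifies
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 1L)
  expect_equal(r$end, 6L)
  expect_equal(r$period, 1L)
  expect_equal(r$motif, "A")
  expect_equal(r$repeats, 6L)

  expect_equal(nrow(scan1("AAAAA")), 0L)  # five A's does not

  r <- scan1("ATATATATA")              # 9 bases: 4 whole copies, span 1-8
  expect_equal(r$start, 1L)
  expect_equal(r$end, 8L)
  expect_equal(r$period, 2L)
  expect_equal(r$repeats, 4L)

  r <- scan1("ACACAC")                 # reported once, with minimal period
  expect_equal(nrow(r), 1L)
  expect_equal(r$period, 2L)
  expect_equal(r$motif, "AC")

  r <- scan1("AAAAAANAAAAAA")          # runs never cross an ambiguity base
  expect_equal(nrow(r), 2L)
  expect_equal(r$start, c(1L, 8L))
  expect_equal(r$end, c(6L, 13L))

  r <- scan1("ACACACA")                # trailing partial copy truncated
  expect_equal(r$end, 6L)
  expect_equal(r$repeats, 3L)

  r <- scan1("GAAAAAAG")               # run embedded in other sequence
  expect_equal(r$start, 2L)
  expect_equal(r$end, 7L)
})

test_that("runs never cross a contig boundary", {
  g <- genome_record("g", c(c1 = "AAA", c2 = "AAA"))
  expect_equal(nrow(scan_ssrs(g)), 0L)
  g <- genome_record("g", c(c1 = "AAAAAA", c2 = "TTTTTT"))
  r <- scan_ssrs(g)
  expect_equal(nrow(r), 2L)
  expect_equal(r$contig_id, c("c1", "c2"))
  expect_equal(r$start, c(1L, 1L))
})

test_that("reported loci are mutually non-overlapping and sorted", {
  set.seed(42)
  s <- ref_random_seq(20000, 0.3)
  r <- scan_ssrs(genome_record("g", c(c1 = s)))
  expect_gt(nrow(r), 0L)
  expect_false(is.unsorted(r$start, strictly = TRUE))
  if (nrow(r) > 1L) {
    expect_true(all(r$start[-1L] > r$end[-nrow(r)]))
  }
  expect_equal(r$length, r$period * r$repeats)
  expect_equal(r$end - r$start + 1L, r$length)
  # the reported motif is literally the sequence at the locus start
  expect_equal(r$motif, substring(s, r$start, r$start + r$period - 1L))
})

test_that("scanner agrees with the naive reference on random sequences", {
  set.seed(7)
  for (gc in c(0.3, 0.5, 0.65)) {
    for (k in 1:12) {
      s <- ref_random_seq(1500, gc)
      got <- ssrsurvey:::.scan_string(s, scan_params())
      want <- ref_scan(s)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$period, want$period)
      expect_equal(got$copies, want$copies)
    }
  }
})

test_that("scanner honors non-default thresholds", {
  p <- scan_params(c(8L, 5L), max_period = 2L)
  s <- "AAAAAAA-ACACACACAC-GGGGGGGG-ATGATGATGATG"
  r <- ssrsurvey:::.scan_string(s, p)
  # (A)7 fails the 8-copy bar; (AC)5 and (G)8 pass; ATG is period 3 > max
  expect_equal(r$period, c(2L, 1L))
  expect_equal(r$copies, c(5L, 8L))
})

test_that("scanning is deterministic", {
  set.seed(99)
  s <- ref_random_seq(30000, 0.5)
  g <- genome_record("g", c(c1 = s))
  expect_identical(scan_ssrs(g), scan_ssrs(g))
})

test_that("isolated planted runs are found mirrored on the reverse strand", {
  sim <- generate_genome(
    plant_config(genome_size = 6e4, ssr_plan = default_ssr_plan(20L),
                 cssr_plan = default_cssr_plan(3L), seed = 5L),
    "fwd")
  s <- sim$genome$contigs[[1L]]
  n <- nchar(s)
  fwd <- scan_ssrs(sim$genome)
  rev <- scan_ssrs(genome_record("rev", c(c1 = ref_revcomp(s))))
  expect_equal(nrow(rev), nrow(fwd))
  # mirror the reverse-strand loci back into forward coordinates; where a
  # maximal run carries a partial trailing copy the two strands truncate
  # at opposite ends, so anchors may differ by up to one period
  o <- order(n - rev$end + 1L)
  expect_equal(rev$standard_motif[o], fwd$standard_motif)
  expect_equal(rev$repeats[o], fwd$repeats)
  expect_true(all(abs((n - rev$end[o] + 1L) - fwd$start) < fwd$period))
})
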