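make_loci <- function(starts, ends, motifs, contig = "c1", gid = "g1") {
  data.frame(genome_id = rep(gid, length(starts)),
             contig_id = rep(contig, length(starts)),
             start = as.integer(starts), end = as.integer(ends),
             period = nchar(motifs), motif = motifs,
             standard_motif = standardize_motif(motifs),
             repeats = as.integer((ends - starts + 1L) / nchar(motifs)),
             length = as.integer(ends - starts + 1L))
}

test_that("two SSRs compound iff their gap is at most dmax", {
  # gap = start2 - end1 - 1 = 10 with these coordinates
  loci <- make_loci(c(1L, 17L), c(6L, 22L), c("A", "AC"))
  res <- build_cssrs(loci, dmax = 10L)
  expect_equal(nrow(res$cssrs), 1L)
  expect_equal(res$cssrs$complexity, 2L)
  expect_equal(res$cssrs$compound_motif, "A-AC")
  expect_equal(res$cssrs$start, 1L)
  expect_equal(res$cssrs$end, 22L)
  expect_equal(res$cssrs$span_length, 22L)
  expect_true(all(res$loci$in_cssr))
  expect_equal(unique(res$loci$cssr_id), res$cssrs$cssr_id)

  # one base further apart (gap 11) and the chain breaks
  loci2 <- make_loci(c(1L, 18L), c(6L, 23L), c("A", "AC"))
  res2 <- build_cssrs(loci2, dmax = 10L)
  expect_equal(nrow(res2$cssrs), 0L)
  expect_false(any(res2$loci$in_cssr))
  expect_true(all(is.na(res2$loci$cssr_id)))

  # abutting repeats (gap 0) always chain
  loci3 <- make_loci(c(1L, 7L), c(6L, 12L), c("A", "AC"))
  expect_equal(nrow(build_cssrs(loci3, dmax = 0L)$cssrs), 1L)
})

test_that("a chain is maximal and complexity counts its members", {
  loci <- make_loci(c(1L, 10L, 20L, 60L), c(6L, 15L, 28L, 65L),
                    c("A", "AC", "AGC", "C"))
  res <- build_cssrs(loci, dmax = 10L)
  expect_equal(nrow(res$cssrs), 1L)
  expect_equal(res$cssrs$complexity, 3L)
  expect_equal(res$cssrs$compound_motif, "A-AC-AGC")
  expect_equal(res$loci$in_cssr, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(sum(res$cssrs$complexity), sum(res$loci$in_cssr))
})

test_that("chains never span contigs or genomes", {
  loci <- rbind(make_loci(1L, 6L, "A", contig = "c1"),
                make_loci(8L, 13L, "A", contig = "c2"))
  expect_equal(nrow(build_cssrs(loci, dmax = 10L)$cssrs), 0L)
  loci2 <- rbind(make_loci(1L, 6L, "A", gid = "g1"),
                 make_loci(8L, 13L, "A", gid = "g2"))
  expect_equal(nrow(build_cssrs(loci2, dmax = 10L)$cssrs), 0L)
})

test_that("compound assembly matches the interval-merging oracle", {
  set.seed(11)
  for (gc in c(0.25, 0.45)) {
    s <- ref_random_seq(40000, gc)
    loci <- scan_ssrs(genome_record("g", c(c1 = s)))
    for (dmax in c(0L, 1L, 10L, 50L)) {
      res <- build_cssrs(loci, dmax = dmax)
      groups <- ref_chain_groups(loci$start, loci$end, dmax)
      sizes <- table(groups)
      # same number of compound loci and same complexity spectrum
      expect_equal(nrow(res$cssrs), sum(sizes >= 2L))
      expect_equal(sort(res$cssrs$complexity),
                   sort(as.integer(sizes[sizes >= 2L])))
      # same membership: loci in groups of size >= 2 are exactly in_cssr
      expect_equal(res$loci$in_cssr,
                   as.integer(sizes[as.character(groups)]) >= 2L)
    }
  }
})

test_that("member totals grow monotonically with dmax", {
  set.seed(12)
  s <- ref_random_seq(30000, 0.3)
  loci <- scan_ssrs(genome_record("g", c(c1 = s)))
  ncssr <- vapply(c(0L, 2L, 5L, 10L, 25L), function(d) {
    sum(build_cssrs(loci, dmax = d)$loci$in_cssr)
  }, integer(1L))
  expect_false(is.unsorted(ncssr))
  # every compound locus has at least two members
  res <- build_cssrs(loci, dmax = 10L)
  if (nrow(res$cssrs) > 0L) {
    expect_true(all(res$cssrs$complexity >= 2L))
    expect_equal(res$cssrs$member_count, res$cssrs$complexity)
  }
})

test_that("build_cssrs enforces its input contract", {
  bad <- make_loci(c(10L, 1L), c(15L, 6L), c("A", "AC"))  # unsorted
  expect_error(build_cssrs(bad), "sorted")
  overlapping <- make_loci(c(1L, 4L), c(6L, 9L), c("A", "AC"))
  expect_error(build_cssrs(overlapping), "non-overlapping")
  empty <- build_cssrs(make_loci(integer(0), integer(0), character(0)))
  expect_equal(nrow(empty$cssrs), 0L)
})

test_that("complexity_spectrum tabulates counts and proportions", {
  cssrs <- data.frame(complexity = c(2L, 2L, 2L, 3L))
  sp <- complexity_spectrum(cssrs)
  expect_equal(sp$complexity, c(2L, 3L))
  expect_equal(sp$count, c(3L, 1L))
  expect_equal(sp$proportion, c(0.75, 0.25))
  expect_equal(sum(sp$proportion), 1)
  expect_equal(nrow(complexity_spectrum(data.frame(complexity = integer(0)))),
               0L)
})

test_that("unique compound motifs are those seen in exactly one genome", {
  cssrs <- data.frame(
    genome_id = c("g1", "g1", "g2", "g2", "g3"),
    compound_motif = c("A-AC", "AC-AG", "A-AC", "CG-AT", "CG-AT"))
  u <- unique_compound_motifs(cssrs, genome_ids = c("g1", "g2", "g3"))
  expect_equal(u$per_genome$n_unique_motifs, c(1L, 0L, 0L))
  expect_equal(u$total, 1L)
  # repetition within one genome does not disqualify a pattern
  cssrs2 <- data.frame(genome_id = c("g1", "g1"),
                       compound_motif = c("A-AC", "A-AC"))
  u2 <- unique_compound_motifs(cssrs2, genome_ids = c("g1", "g2"))
  expect_equal(u2$per_genome$n_unique_motifs, c(1L, 0L))
})
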