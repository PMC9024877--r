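# Largest-remainder apportionment of n items over weights
.apportion <- function(n, weights) {
  w <- weights / sum(weights)
  raw <- n * w
  base <- floor(raw)
  rem <- as.integer(round(n - sum(base)))
  if (rem > 0L) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

# Motif composition used by the default plans: AT-biased mono, di-dominated
# overall, the di/tri classes that dominate cyanobacterial genomes well
# represented, and a thin tail of period 4-6 motifs.
.default_motif_table <- function() {
  data.frame(
    standard_motif = c("A", "C",
                       "AG", "AC", "CG", "AT",
                       "AGC", "ACG", "ACC", "CCG", "AAG", "AAC",
                       "AAGC", "ACGC", "AACGG", "AACGCC"),
    repeats = c(7L, 6L, 4L, 4L, 3L, 3L,
                3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L),
    weight = c(0.10, 0.05, 0.20, 0.14, 0.08, 0.04,
               0.09, 0.07, 0.06, 0.05, 0.03, 0.03,
               0.02, 0.01, 0.02, 0.01))
}

#' Default plan of individual SSRs to plant
#'
#' Distributes `n_ssr` planted microsatellites over a fixed table of
#' standard motifs (periods 1-6, dinucleotides most abundant) by largest
#' remainder, so the plan is fully deterministic.
#'
#' @param n_ssr Total number of individual SSRs to plant.
#' @return data.frame with columns `standard_motif`, `repeats`, `count`.
#' @export
default_ssr_plan <- function(n_ssr = 500L) {
  tab <- .default_motif_table()
  tab$count <- .apportion(n_ssr, tab$weight)
  tab[tab$count > 0L, c("standard_motif", "repeats", "count")]
}

#' Default plan of compound SSRs to plant
#'
#' Builds `n_cssr` compound-locus templates: complexities allocated by
#' largest remainder over `complexity_probs` (default 95% complexity 2,
#' 5% complexity 3, the split typical of prokaryotic genomes), member
#' motifs cycled deterministically through a motif pool, and inter-member
#' gaps cycled through 1..`dmax`. No randomness is used, so the plan is a
#' pure function of its arguments.
#'
#' @param n_cssr Number of compound loci to plant.
#' @param dmax Maximum gap (bases) between adjacent members.
#' @param complexity_probs Named numeric vector: complexity -> proportion.
#' @return List of entries `list(motifs, repeats, gaps)`.
#' @export
default_cssr_plan <- function(n_cssr = 50L, dmax = 10L,
                              complexity_probs = c("2" = 0.95,
                                                   "3" = 0.05)) {
  cx <- as.integer(names(complexity_probs))
  if (any(is.na(cx)) || any(cx < 2L)) {
    stop("complexities must be integers >= 2")
  }
  counts <- .apportion(n_cssr, complexity_probs)
  pool <- c("A", "AC", "AG", "AGC", "C", "AT", "ACG", "CG", "ACC", "AAG")
  base_rep <- c(7L, 3L, 3L, 3L, 3L, 3L)  # by period, mono needs 6+
  plan <- vector("list", sum(counts))
  inst <- 0L
  for (j in seq_along(cx)) {
    for (i in seq_len(counts[j])) {
      inst <- inst + 1L
      idx <- ((inst - 1L + (seq_len(cx[j]) - 1L) * 3L) %% length(pool)) + 1L
      # never let two adjacent members share a motif
      for (k in seq_len(cx[j] - 1L)) {
        if (pool[idx[k + 1L]] == pool[idx[k]]) {
          idx[k + 1L] <- (idx[k + 1L] %% length(pool)) + 1L
        }
      }
      motifs <- pool[idx]
      reps <- base_rep[nchar(motifs)] + (inst + seq_along(motifs)) %% 2L
      gaps <- ((inst + seq_len(cx[j] - 1L)) %% dmax) + 1L
      plan[[inst]] <- list(motifs = motifs, repeats = as.integer(reps),
                           gaps = as.integer(gaps))
    }
  }
  plan
}

.feature_length <- function(entry) {
  sum(nchar(entry$motifs) * entry$repeats) + sum(entry$gaps)
}

#' Configuration for a synthetic genome with planted repeats
#'
#' Describes one synthetic genome: background size and GC target, the
#' individual SSRs and compound loci to plant, the gap rule, and an
#' optional CDS track. Validation — including whether all planted
#' features fit with at least `dmax + 1` bases of clearance between
#' independent features, so that no two planted features ever chain — runs
#' here, before any random sampling.
#'
#' @param genome_size Total assembly length in bases.
#' @param gc_content Target background GC fraction.
#' @param n_contigs Number of contigs (sizes split evenly).
#' @param ssr_plan data.frame `standard_motif`, `repeats`, `count`
#'   (see [default_ssr_plan()]).
#' @param cssr_plan List of `list(motifs, repeats, gaps)` entries
#'   (see [default_cssr_plan()]); all gaps must lie in 1..`dmax` (a gap of
#'   0 would let a member run extend into its neighbour, making the
#'   planted truth unrecoverable).
#' @param dmax Compound-locus gap threshold in bases.
#' @param cds_fraction Fraction of each contig covered by the planted CDS
#'   track (0 disables annotation; the track tiles each contig with one
#'   CDS block per kilobase).
#' @param seed Integer seed driving every random draw of the generator.
#' @param params [scan_params()] against which planted repeats must be
#'   detectable.
#' @return An object of class `plant_config`.
#' @export
plant_config <- function(genome_size = 2e6, gc_content = 0.60,
                         n_contigs = 1L,
                         ssr_plan = default_ssr_plan(500L),
                         cssr_plan = default_cssr_plan(50L),
                         dmax = 10L, cds_fraction = 0.85,
                         seed = 1L, params = scan_params()) {
  genome_size <- as.integer(genome_size)
  n_contigs <- as.integer(n_contigs)
  dmax <- as.integer(dmax)
  stopifnot(genome_size >= 1L, n_contigs >= 1L, dmax >= 0L,
            gc_content > 0, gc_content < 1,
            cds_fraction >= 0, cds_fraction <= 1,
            inherits(params, "scan_params"))
  stopifnot(is.data.frame(ssr_plan),
            all(c("standard_motif", "repeats", "count") %in%
                  names(ssr_plan)))
  for (i in seq_len(nrow(ssr_plan))) {
    m <- ssr_plan$standard_motif[i]
    p <- nchar(m)
    if (grepl("[^ACGT]", m) || !.is_minimal_period(m)) {
      stop("ssr_plan motif '", m, "' is not a minimal-period ACGT motif")
    }
    if (p > params$max_period ||
        ssr_plan$repeats[i] < params$min_repeats[p]) {
      stop("planted SSR (", m, ")", ssr_plan$repeats[i],
           " would fall below the detection thresholds")
    }
  }
  for (entry in cssr_plan) {
    if (length(entry$motifs) < 2L ||
        length(entry$repeats) != length(entry$motifs) ||
        length(entry$gaps) != length(entry$motifs) - 1L) {
      stop("each cssr_plan entry needs >= 2 motifs, matching repeats, ",
           "and one gap per adjacent pair")
    }
    if (any(entry$gaps < 1L) || any(entry$gaps > dmax)) {
      stop("cssr_plan gaps must lie in 1..dmax")
    }
    p <- nchar(entry$motifs)
    if (any(p > params$max_period) ||
        any(entry$repeats < params$min_repeats[p])) {
      stop("a planted compound member would fall below the detection ",
           "thresholds")
    }
  }
  # deterministic contig sizes and feature-to-contig allocation
  contig_len <- rep(genome_size %/% n_contigs, n_contigs)
  contig_len[1L] <- contig_len[1L] + genome_size %% n_contigs
  feat_len <- c(
    rep(nchar(ssr_plan$standard_motif) * ssr_plan$repeats,
        ssr_plan$count),
    vapply(cssr_plan, .feature_length, numeric(1L)))
  feat_kind <- c(rep.int(0L, sum(ssr_plan$count)),
                 rep.int(1L, length(cssr_plan)))
  clear <- dmax + 1L
  capacity <- contig_len - clear
  assignment <- integer(length(feat_len))
  o <- order(feat_len, decreasing = TRUE)
  for (i in o) {
    best <- which.max(capacity)
    if (capacity[best] < feat_len[i] + clear) {
      stop("planted features do not fit in a genome of ", genome_size,
           " bases with ", clear, " bases of clearance per feature")
    }
    capacity[best] <- capacity[best] - feat_len[i] - clear
    assignment[i] <- best
  }
  structure(list(genome_size = genome_size, gc_content = gc_content,
                 n_contigs = n_contigs, contig_len = contig_len,
                 ssr_plan = ssr_plan, cssr_plan = cssr_plan,
                 dmax = dmax, cds_fraction = cds_fraction,
                 seed = as.integer(seed), params = params,
                 feat_kind = feat_kind, assignment = assignment),
            class = "plant_config")
}

# Break every repeat not in `truth_keys` ("start:end:period") by point
# substitution at a non-protected position until a scan reproduces the
# truth exactly. Returns the repaired sequence and the number of passes.
.disrupt_repeats <- function(x, params, protect = NULL,
                             truth_keys = character(0L),
                             max_passes = 60L) {
  passes <- 0L
  repeat {
    hits <- .scan_chars(x, params)
    keys <- sprintf("%d:%d:%d", hits$start, hits$end, hits$period)
    extra <- which(!(keys %in% truth_keys))
    if (length(extra) == 0L) {
      if (length(keys) == length(truth_keys) &&
          all(truth_keys %in% keys)) break
      stop("a planted repeat was lost without any spurious locus to ",
           "repair; the plant configuration is internally inconsistent")
    }
    passes <- passes + 1L
    if (passes > max_passes) {
      stop("repeat disruption did not converge after ", max_passes,
           " passes")
    }
    fixed <- 0L
    for (i in extra) {
      span <- seq.int(hits$start[i], hits$end[i])
      free <- if (is.null(protect)) span else span[!protect[span]]
      if (length(free) == 0L) {
        # a locus shifted into a planted span by an upstream extra; it
        # resolves once that extra is broken, so skip it this pass
        next
      }
      fixed <- fixed + 1L
      # substitute densely enough that no remnant of the run can still
      # qualify: one change per p * min_repeats - 1 bases
      p <- hits$period[i]
      step <- max(p * params$min_repeats[p] - 1L, 2L)
      picks <- free[unique(pmin(seq.int(1L, length(free) + step - 1L,
                                        by = step), length(free)))]
      for (pos in picks) {
        hard <- unique(c(x[pos],
                         if (pos > 1L) x[pos - 1L],
                         if (pos < length(x)) x[pos + 1L]))
        choices <- setdiff(.DNA_BASES, hard)
        soft <- unique(c(if (pos > 2L) x[pos - 2L],
                         if (pos < length(x) - 1L) x[pos + 2L]))
        pref <- setdiff(choices, soft)
        if (length(pref)) choices <- pref
        x[pos] <- if (length(choices) == 1L) choices
                  else sample(choices, 1L)
      }
    }
    if (fixed == 0L) {
      stop("spurious loci lie entirely within planted spans and no ",
           "repair is possible; the plant configuration is ",
           "internally inconsistent")
    }
  }
  list(x = x, passes = passes)
}

.gc_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# Render one planted feature into sequence + relative-coordinate truth
.render_feature <- function(kind, spec, gc) {
  if (kind == 0L) {  # individual SSR: spec = list(motif, repeats)
    p <- nchar(spec$motif)
    seq <- strrep(spec$motif, spec$repeats)
    truth <- data.frame(offset = 1L, period = p, motif = spec$motif,
                        repeats = spec$repeats, length = p * spec$repeats,
                        in_cssr = FALSE)
    return(list(seq = seq, ssr = truth, complexity = NA_integer_))
  }
  # compound: members joined by random filler gaps
  pieces <- character(0L)
  offs <- integer(length(spec$motifs))
  at <- 1L
  for (j in seq_along(spec$motifs)) {
    mem <- strrep(spec$motifs[j], spec$repeats[j])
    offs[j] <- at
    pieces <- c(pieces, mem)
    at <- at + nchar(mem)
    if (j < length(spec$motifs)) {
      g <- spec$gaps[j]
      probs <- .gc_probs(gc)
      pieces <- c(pieces, paste(sample(names(probs), g, replace = TRUE,
                                       prob = probs), collapse = ""))
      at <- at + g
    }
  }
  truth <- data.frame(offset = offs, period = nchar(spec$motifs),
                      motif = spec$motifs, repeats = spec$repeats,
                      length = nchar(spec$motifs) * spec$repeats,
                      in_cssr = TRUE)
  list(seq = paste(pieces, collapse = ""), ssr = truth,
       complexity = length(spec$motifs))
}

#' Generate a synthetic genome with planted repeats and exact truth
#'
#' Samples a background sequence base-by-base at the target GC, then
#' "cleans" it: every run that would qualify as a microsatellite under the
#' scan thresholds is disrupted by a single substitution, iterating until
#' a scan of the background alone finds nothing. Planted features
#' (individual SSRs and compound loci) are then inserted at randomly
#' drawn, non-adjacent positions — every pair of independent features is
#' separated by more than `dmax` bases, so planted features never chain
#' accidentally — and a final repair pass guarantees that scanning the
#' finished genome returns exactly the planted truth. An optional CDS
#' track tiling each contig is emitted alongside. Identical seed and
#' configuration always produce the identical genome.
#'
#' @param config A [plant_config()].
#' @param genome_id Identifier given to the generated genome.
#' @return list with elements `genome` ([genome_record()]), `annotation`
#'   ([annotation_index()] or NULL), and `truth`: `ssr` and `cssr` tables
#'   in the exact shape of the pipeline outputs, plus `background_gc`
#'   (realized GC of non-planted positions) and `cleaning_passes`.
#' @export
generate_genome <- function(config, genome_id = "synthetic_1") {
  stopifnot(inherits(config, "plant_config"))
  set.seed(config$seed)
  params <- config$params
  probs <- .gc_probs(config$gc_content)
  # feature specs in the order used by the allocation in plant_config
  specs <- c(
    unlist(lapply(seq_len(nrow(config$ssr_plan)), function(i) {
      rep(list(list(motif = config$ssr_plan$standard_motif[i],
                    repeats = config$ssr_plan$repeats[i])),
          config$ssr_plan$count[i])
    }), recursive = FALSE),
    config$cssr_plan)
  clear <- config$dmax + 1L
  contigs <- character(config$n_contigs)
  names(contigs) <- paste0("contig_", seq_len(config$n_contigs))
  ssr_rows <- list(); cssr_rows <- list()
  total_passes <- 0L
  bg_gc_num <- 0; bg_gc_den <- 0
  for (ci in seq_len(config$n_contigs)) {
    len <- config$contig_len[ci]
    x <- sample(names(probs), len, replace = TRUE, prob = probs)
    cleaned <- .disrupt_repeats(x, params)
    x <- cleaned$x
    total_passes <- total_passes + cleaned$passes
    mine <- which(config$assignment == ci)
    if (length(mine)) {
      mine <- mine[sample.int(length(mine))]  # random placement order
      rendered <- lapply(mine, function(i) {
        .render_feature(config$feat_kind[i], specs[[i]],
                        config$gc_content)
      })
      flen <- vapply(rendered, function(r) nchar(r$seq), integer(1L))
      extra <- len - sum(flen) - (length(mine) + 1L) * clear
      parts <- as.vector(stats::rmultinom(1L, extra,
                                          rep(1, length(mine) + 1L)))
      gaps <- clear + parts
      starts <- cumsum(gaps[seq_along(mine)] +
                         c(0L, flen[-length(flen)])) + 1L
      protect <- logical(len)
      truth_keys <- character(0L)
      for (k in seq_along(mine)) {
        r <- rendered[[k]]
        s <- starts[k]
        chars <- strsplit(r$seq, "", fixed = TRUE)[[1L]]
        x[seq.int(s, s + length(chars) - 1L)] <- chars
        st <- r$ssr
        st$start <- s + st$offset - 1L
        st$end <- st$start + st$length - 1L
        # only the member repeats are protected; compound-gap filler bases
        # stay substitutable for the repair pass
        for (j in seq_len(nrow(st))) {
          protect[seq.int(st$start[j], st$end[j])] <- TRUE
        }
        cssr_id <- NA_character_
        if (!is.na(r$complexity)) {
          cssr_id <- sprintf("%s:%s:%d", genome_id, names(contigs)[ci],
                             st$start[1L])
          cssr_rows[[length(cssr_rows) + 1L]] <- data.frame(
            genome_id = genome_id, cssr_id = cssr_id,
            contig_id = names(contigs)[ci],
            start = st$start[1L], end = st$end[nrow(st)],
            complexity = r$complexity,
            compound_motif = paste(st$motif, collapse = "-"),
            span_length = st$end[nrow(st)] - st$start[1L] + 1L,
            member_count = r$complexity)
        }
        ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
          genome_id = genome_id, contig_id = names(contigs)[ci],
          start = st$start, end = st$end, period = st$period,
          motif = st$motif, standard_motif = st$motif,
          repeats = st$repeats, length = st$length,
          in_cssr = st$in_cssr, cssr_id = cssr_id)
        truth_keys <- c(truth_keys,
                        sprintf("%d:%d:%d", st$start, st$end, st$period))
      }
      repaired <- .disrupt_repeats(x, params, protect = protect,
                                   truth_keys = truth_keys)
      x <- repaired$x
      total_passes <- total_passes + repaired$passes
      bg <- x[!protect]
    } else {
      bg <- x
    }
    bg_gc_num <- bg_gc_num + sum(bg %in% c("G", "C"))
    bg_gc_den <- bg_gc_den + length(bg)
    contigs[ci] <- paste(x, collapse = "")
  }
  genome <- genome_record(genome_id, contigs)
  annotation <- .cds_track(genome, config$cds_fraction)
  ssr <- if (length(ssr_rows)) do.call(rbind, ssr_rows)
         else cbind(.empty_ssr_loci(),
                    data.frame(in_cssr = logical(0L),
                               cssr_id = character(0L)))
  cssr <- if (length(cssr_rows)) do.call(rbind, cssr_rows)
          else .empty_cssr_loci()
  o <- order(match(ssr$contig_id, names(contigs)), ssr$start)
  ssr <- ssr[o, , drop = FALSE]
  rownames(ssr) <- NULL
  o <- order(match(cssr$contig_id, names(contigs)), cssr$start)
  cssr <- cssr[o, , drop = FALSE]
  rownames(cssr) <- NULL
  ssr$region <- .track_region(ssr, config, genome)
  cssr$region <- .track_region(cssr, config, genome)
  list(genome = genome, annotation = annotation,
       truth = list(ssr = ssr, cssr = cssr,
                    background_gc = bg_gc_num / bg_gc_den,
                    cleaning_passes = total_passes),
       config = config)
}

.CDS_BLOCK <- 1000L

.cds_track <- function(genome, fraction) {
  if (fraction <= 0) return(NULL)
  coding_len <- round(.CDS_BLOCK * fraction)
  rows <- lapply(names(genome$contigs), function(cid) {
    len <- nchar(genome$contigs[[cid]])
    starts <- seq.int(1L, len, by = .CDS_BLOCK)
    ends <- pmin(starts + coding_len - 1L, len)
    keep <- ends >= starts
    data.frame(contig_id = cid, start = starts[keep], end = ends[keep])
  })
  annotation_index(genome$genome_id, do.call(rbind, rows),
                   nchar(genome$contigs))
}

# Region call of a locus against the tiled CDS track, by modular
# arithmetic (independent of the interval-overlap machinery of the
# pipeline, so recovery tests compare two separate routes).
.track_region <- function(loci, config, genome) {
  if (config$cds_fraction <= 0) return(rep(NA_character_, nrow(loci)))
  coding_len <- round(.CDS_BLOCK * config$cds_fraction)
  if (nrow(loci) == 0L) return(character(0L))
  off <- (loci$start - 1L) %% .CDS_BLOCK
  hit <- off < coding_len |
    (loci$end - loci$start) >= (.CDS_BLOCK - off)
  ifelse(hit, "coding", "noncoding")
}

#' Generate a cohort of synthetic genomes
#'
#' Draws `n` genomes with sizes and GC targets uniform over the given
#' ranges and plants repeats following a proportional density model: the
#' planted number of individual SSRs (and compound loci) in each genome is
#' `ssr_per_kb` (`cssr_per_kb`) times the genome size in kb, perturbed by
#' multiplicative Gaussian noise with relative standard deviation
#' `rel_noise`. Compound-locus complexities follow `complexity_probs`.
#' All randomness flows from `seed`; the same seed reproduces the
#' identical cohort.
#'
#' @param n Number of genomes (>= 3).
#' @param size_range,gc_range Ranges for genome size (bases) and GC
#'   fraction.
#' @param ssr_per_kb,cssr_per_kb Planted locus densities per kb.
#' @param rel_noise Relative noise on the planted counts.
#' @param complexity_probs Complexity mix of planted compound loci.
#' @param dmax Compound gap threshold.
#' @param cds_fraction CDS track coverage (see [plant_config()]).
#' @param n_contigs Contigs per genome.
#' @param seed Integer master seed.
#' @return list with `genomes` (list of [generate_genome()] results) and
#'   `truth` (pooled truth tables plus the per-genome planted counts).
#' @export
generate_cohort <- function(n = 54L,
                            size_range = c(1.68e6, 3.31e6),
                            gc_range = c(0.5245, 0.6444),
                            ssr_per_kb = 0.25, cssr_per_kb = 0.025,
                            rel_noise = 0.05,
                            complexity_probs = c("2" = 0.95, "3" = 0.05),
                            dmax = 10L, cds_fraction = 0.85,
                            n_contigs = 1L, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("a cohort needs at least 3 genomes")
  if (diff(range(size_range)) < 0 || size_range[1L] <= 0 ||
      diff(range(gc_range)) < 0 || gc_range[1L] <= 0 ||
      gc_range[2L] >= 1) {
    stop("degenerate size or GC range")
  }
  set.seed(as.integer(seed))
  sizes <- round(stats::runif(n, size_range[1L], size_range[2L]))
  gcs <- stats::runif(n, gc_range[1L], gc_range[2L])
  noise_ssr <- 1 + stats::rnorm(n, 0, rel_noise)
  noise_cssr <- 1 + stats::rnorm(n, 0, rel_noise)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  genomes <- vector("list", n)
  planted <- data.frame(genome_id = sprintf("synthetic_%02d", seq_len(n)),
                        genome_size = sizes, gc_target = gcs,
                        n_ssr_planted = NA_integer_,
                        n_cssr_planted = NA_integer_)
  for (i in seq_len(n)) {
    n_ssr <- max(0L, as.integer(round(ssr_per_kb * sizes[i] / 1000 *
                                        noise_ssr[i])))
    n_cssr <- max(0L, as.integer(round(cssr_per_kb * sizes[i] / 1000 *
                                         noise_cssr[i])))
    cfg <- plant_config(
      genome_size = sizes[i], gc_content = gcs[i], n_contigs = n_contigs,
      ssr_plan = default_ssr_plan(n_ssr),
      cssr_plan = default_cssr_plan(n_cssr, dmax = dmax,
                                    complexity_probs = complexity_probs),
      dmax = dmax, cds_fraction = cds_fraction, seed = seeds[i])
    genomes[[i]] <- generate_genome(cfg, genome_id = planted$genome_id[i])
    planted$n_ssr_planted[i] <- n_ssr
    planted$n_cssr_planted[i] <- n_cssr
  }
  truth_ssr <- do.call(rbind, lapply(genomes,
                                     function(g) g$truth$ssr))
  truth_cssr <- do.call(rbind, lapply(genomes,
                                      function(g) g$truth$cssr))
  list(genomes = genomes,
       truth = list(ssr = truth_ssr, cssr = truth_cssr,
                    planted = planted))
}

#' Write a synthetic cohort to FASTA/GFF3/TSV files
#'
#' Emits, for each genome, a FASTA assembly and (when a CDS track was
#' planted) a GFF3 annotation; plus pooled ground-truth tables and a
#' cohort manifest directly consumable by [run_survey()].
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_synthetic_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- data.frame(genome_id = character(0L),
                         fasta_path = character(0L),
                         gff_path = character(0L),
                         subclade = character(0L))
  for (g in cohort$genomes) {
    gid <- g$genome$genome_id
    fasta <- file.path(dir, paste0(gid, ".fasta"))
    seqs <- Biostrings::BStringSet(g$genome$contigs)
    Biostrings::writeXStringSet(seqs, fasta, width = 80L)
    gff <- NA_character_
    if (!is.null(g$annotation)) {
      gff <- file.path(dir, paste0(gid, ".gff3"))
      cds <- g$annotation$cds
      gr <- GenomicRanges::GRanges(
        seqnames = cds$contig_id,
        ranges = IRanges::IRanges(cds$start, cds$end),
        strand = "+",
        type = "CDS", source = "ssrsurvey", phase = 0L)
      rtracklayer::export(gr, gff, format = "gff3")
    }
    manifest <- rbind(manifest,
                      data.frame(genome_id = gid, fasta_path = fasta,
                                 gff_path = gff,
                                 subclade = NA_character_))
  }
  .write_tsv(cohort$truth$ssr, file.path(dir, "truth_ssr.tsv"))
  .write_tsv(cohort$truth$cssr, file.path(dir, "truth_cssr.tsv"))
  .write_tsv(cohort$truth$planted, file.path(dir, "truth_planted.tsv"))
  manifest_path <- file.path(dir, "manifest.tsv")
  .write_tsv(manifest, manifest_path)
  invisible(manifest_path)
}
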