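#' Cohort mean compound-repeat complexity
#'
#' The cohort average complexity is the mean over genomes of each genome's
#' ratio ncSSR / nCSSR (member SSRs per compound locus). Genomes without
#' any compound locus have an undefined ratio and are excluded with a
#' warning.
#'
#' @param summaries Genome-summary data.frame (columns `ncSSR`, `nCSSR`).
#' @return The cohort mean complexity, a number >= 2 whenever every
#'   retained genome has at least one CSSR.
#' @examples
#' s <- data.frame(ncSSR = c(400, 450), nCSSR = c(200, 150))
#' mean_complexity(s)  # (2.0 + 3.0) / 2 = 2.5
#' @export
mean_complexity <- function(summaries) {
  stopifnot(all(c("ncSSR", "nCSSR") %in% names(summaries)))
  zero <- summaries$nCSSR == 0L
  if (all(zero)) {
    stop("no genome in the cohort has any compound microsatellite; ",
         "mean complexity is undefined")
  }
  if (any(zero)) {
    warning("excluding ", sum(zero),
            " genome(s) without compound loci from mean complexity")
  }
  mean(summaries$ncSSR[!zero] / summaries$nCSSR[!zero])
}

#' Z index of compound-microsatellite representation
#'
#' Given the cohort mean complexity `c_bar`, the expected number of
#' compound loci in a genome is its member count divided by the cohort
#' mean, `nCSSR_exp = ncSSR / c_bar`: the count the genome would show if
#' it compounded its member SSRs at the cohort-average complexity. The Z
#' index standardizes the deviation of the observed count,
#' `Z = (nCSSR_obs - nCSSR_exp) / sqrt(nCSSR_exp)` (a Poisson-like
#' standardization); positive Z means more compound loci — i.e. less
#' aggregation per locus — than expected. A plain-ratio denominator
#' (`nCSSR_exp` itself) is available via `denominator = "linear"`.
#'
#' @param summaries Genome-summary data.frame (columns `genome_id`,
#'   `ncSSR`, `nCSSR`).
#' @param c_bar Cohort mean complexity from [mean_complexity()].
#' @param denominator `"sqrt"` (default) or `"linear"`.
#' @return data.frame with columns `genome_id`, `ncSSR`, `nCSSR_obs`,
#'   `nCSSR_exp`, `Z` (`Z` is NA where `nCSSR_exp` is 0).
#' @examples
#' s <- data.frame(genome_id = "g1", ncSSR = 400, nCSSR = 200)
#' z_scores(s, c_bar = 2.5)  # exp = 160, Z = 40 / sqrt(160)
#' @export
z_scores <- function(summaries, c_bar, denominator = c("sqrt", "linear")) {
  denominator <- match.arg(denominator)
  if (!is.numeric(c_bar) || length(c_bar) != 1L || is.na(c_bar) ||
      c_bar <= 0) {
    stop("`c_bar` must be a single positive number")
  }
  expd <- summaries$ncSSR / c_bar
  denom <- switch(denominator, sqrt = sqrt(expd), linear = expd)
  z <- ifelse(expd > 0, (summaries$nCSSR - expd) / denom, NA_real_)
  data.frame(genome_id = summaries$genome_id,
             ncSSR = summaries$ncSSR,
             nCSSR_obs = summaries$nCSSR,
             nCSSR_exp = expd,
             Z = z)
}

.default_pearson_pairs <- function() {
  data.frame(
    var1 = c("nSSR", "nSSR", "nSSR", "nCSSR", "nCSSR", "nCSSR", "nCSSR"),
    var2 = c("genome_size", "gc_content", "ncSSR",
             "genome_size", "gc_content", "nSSR", "ncSSR"))
}

#' Pearson correlations among genome and repeat statistics
#'
#' Computes, for each requested variable pair, the Pearson product-moment
#' correlation and its two-sided p-value (t transform with n - 2 degrees
#' of freedom, via [stats::cor.test()]). The default pairs relate nSSR and
#' nCSSR to genome size, GC content and each other / ncSSR, the standard
#' correlation panel of genome-wide repeat surveys. No multiple-testing
#' correction is applied.
#'
#' @param summaries Genome-summary data.frame; must contain every
#'   variable named in `pairs`. Needs at least 3 genomes.
#' @param pairs data.frame with columns `var1`, `var2`; default panel as
#'   described above.
#' @return data.frame with columns `pair`, `var1`, `var2`, `rho`,
#'   `p_value`, `n`. A variable with zero variance yields NA with a
#'   warning.
#' @export
pearson_table <- function(summaries, pairs = NULL) {
  if (is.null(pairs)) pairs <- .default_pearson_pairs()
  if (nrow(summaries) < 3L) {
    stop("at least 3 genomes are required for correlation analysis")
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    v1 <- pairs$var1[i]; v2 <- pairs$var2[i]
    x <- summaries[[v1]]; y <- summaries[[v2]]
    if (is.null(x) || is.null(y)) {
      stop("variable not found in summaries: ",
           if (is.null(x)) v1 else v2)
    }
    keep <- stats::complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero variance or too few observations for ", v1, " vs ",
              v2, "; correlation reported as NA")
      rho <- NA_real_; pv <- NA_real_
    } else {
      ct <- stats::cor.test(x, y, method = "pearson",
                            alternative = "two.sided")
      rho <- unname(ct$estimate); pv <- ct$p.value
    }
    data.frame(pair = paste(v1, "vs", v2), var1 = v1, var2 = v2,
               rho = rho, p_value = pv, n = length(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort-level report of a survey
#'
#' Aggregates a finished survey into cohort totals (sums of nSSR, nCSSR
#' and ncSSR), the cohort mean complexity, the tally of mono/di/tri
#' composition patterns, and the pooled complexity spectrum.
#'
#' @param summaries Genome-summary data.frame.
#' @param cssrs Pooled CSSR data.frame.
#' @return data.frame in long key/value form (written as
#'   `cohort_report.tsv`).
#' @export
cohort_report <- function(summaries, cssrs) {
  c_bar <- if (any(summaries$nCSSR > 0L)) {
    suppressWarnings(mean_complexity(summaries))
  } else NA_real_
  spec <- complexity_spectrum(cssrs)
  pat <- table(summaries$pattern)
  # paste0 maps zero-length inputs to "" rather than character(0)
  cx_keys <- if (nrow(spec) > 0L) {
    paste0("complexity_", spec$complexity, "_count")
  } else character(0L)
  pat_keys <- if (length(pat) > 0L) {
    paste0("pattern_", names(pat))
  } else character(0L)
  rows <- data.frame(
    key = c("n_genomes", "total_nSSR", "total_nCSSR", "total_ncSSR",
            "mean_complexity", pat_keys, cx_keys),
    value = c(nrow(summaries), sum(summaries$nSSR), sum(summaries$nCSSR),
              sum(summaries$ncSSR), c_bar,
              as.numeric(pat), spec$count))
  rows
}
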