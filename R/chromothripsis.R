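#' Parameters for the chromothripsis criteria
#'
#' Chromothripsis is inferred per chromosome from four hallmarks:
#' oscillating copy-number states (C1), spatial clustering of breakpoints
#' (C2), randomness of fragment-join orientations (C3), and randomness of
#' fragment order (C4).  A chromosome is called when at least two criteria
#' are satisfied.
#'
#' Note the inverted test logic of C3 and C4: chromothripsis predicts
#' *randomness*, so those criteria are satisfied when the test does NOT
#' reject its null (p >= alpha).  C2 is a conventional rejection test
#' (clustered = significantly non-uniform).
#'
#' @param alpha per-criterion significance level (no multiplicity
#'   correction: the >= 2-of-4 rule is the combiner).
#' @param min_segments minimum segments for C1 to be evaluable.
#' @param min_breakpoints minimum breakpoints for C2 to be evaluable.
#' @param min_joins_exact minimum intrachromosomal joins for C3 (exact
#'   multinomial form); at `chisq_joins` or more the chi-square form is
#'   used.
#' @param min_joins_order minimum joins for C4 to be evaluable.
#' @param osc_coverage fraction of segments the two dominant states must
#'   cover for C1.
#' @param osc_switches minimum switches between the two dominant states.
#' @param mc_resamples Monte-Carlo resamples for the C2 spacing test.
#' @param mc_seed seed for the C2 Monte-Carlo (criteria are deterministic
#'   given input + params).
#' @return parameter list.
#' @export
chromothripsis_params <- function(alpha = 0.05,
                                  min_segments = 10,
                                  min_breakpoints = 10,
                                  min_joins_exact = 4,
                                  chisq_joins = 8,
                                  min_joins_order = 8,
                                  osc_coverage = 0.8,
                                  osc_switches = 6,
                                  mc_resamples = 1000,
                                  mc_seed = 20210401) {
  stopifnot(alpha > 0, alpha < 1, min_segments >= 2, min_breakpoints >= 2)
  list(alpha = alpha, min_segments = min_segments,
       min_breakpoints = min_breakpoints, min_joins_exact = min_joins_exact,
       chisq_joins = chisq_joins, min_joins_order = min_joins_order,
       osc_coverage = osc_coverage, osc_switches = osc_switches,
       mc_resamples = mc_resamples, mc_seed = mc_seed)
}

criterion_result <- function(id, statistic = NA_real_, p_value = NA_real_,
                             satisfied = FALSE, evaluable = TRUE) {
  if (!evaluable) satisfied <- FALSE
  list(criterion = id, statistic = statistic, p_value = p_value,
       satisfied = satisfied, evaluable = evaluable)
}

# Evaluate an expression under a fixed seed, restoring the caller's RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Integer copy-number states from mean log2 ratios
#'
#' On a diploid baseline, the integer state of a segment with mean log2
#' ratio r is `round(2 * 2^r)`: 0.0 -> 2 copies, -1.0 -> 1 copy,
#' 0.585 -> 3 copies.
#'
#' @param seg_mean numeric vector of mean log2 ratios (or a segment data
#'   frame with a `seg_mean` column).
#' @return integer vector of copy-number states (>= 0).
#' @export
infer_cn_states <- function(seg_mean) {
  if (is.data.frame(seg_mean)) seg_mean <- seg_mean$seg_mean
  if (!length(seg_mean)) stop("infer_cn_states: no segments")
  as.integer(round(2 * 2^seg_mean))
}

#' C1: oscillating copy-number states
#'
#' Satisfied when the two most frequent states cover at least
#' `osc_coverage` of the segments AND the ordered state sequence,
#' restricted to those two states, switches between them at least
#' `osc_switches` times.  Requires `min_segments` segments to be
#' evaluable.  The statistic reported is the switch count.
#'
#' @param states ordered integer CN states along the chromosome.
#' @param params parameters from [chromothripsis_params()].
#' @return criterion result list (`criterion`, `statistic`, `p_value`,
#'   `satisfied`, `evaluable`).
#' @export
criterion_oscillation <- function(states, params = chromothripsis_params()) {
  n <- length(states)
  if (n < params$min_segments) {
    return(criterion_result("C1_oscillation", evaluable = FALSE))
  }
  tab <- sort(table(states), decreasing = TRUE)
  top2 <- as.integer(names(tab)[seq_len(min(2, length(tab)))])
  coverage <- sum(tab[seq_len(min(2, length(tab)))]) / n
  runs <- states[states %in% top2]
  switches <- if (length(runs) > 1) sum(diff(runs) != 0) else 0
  criterion_result("C1_oscillation", statistic = switches,
                   satisfied = coverage >= params$osc_coverage &&
                     switches >= params$osc_switches)
}

# Exact CDF of one inter-point spacing for n uniform points on [0, L]:
# s / L ~ Beta(1, n - 1).
spacing_cdf <- function(s, n, L) 1 - (1 - pmin(s / L, 1))^(n - 1)

# One-sided clustering statistic: KS-type excess of SMALL spacings.
# Spacings are probability-transformed through the exact null CDF; the
# statistic is the maximal excess of the empirical CDF over the uniform
# CDF, restricted to the lower half of the null spacing distribution so
# that over-regular spacing (a deficit of small spacings) cannot fire.
clustering_statistic <- function(positions, chrom_length) {
  s <- diff(sort(positions))
  n <- length(positions)
  u <- sort(spacing_cdf(s, n, chrom_length))
  keep <- u <= 0.5
  if (!any(keep)) return(0)
  i <- seq_along(u)
  max(0, max(i[keep] / length(u) - u[keep]))
}

#' C2: spatial clustering of breakpoints
#'
#' Monte-Carlo test of the inter-breakpoint spacing distribution against
#' uniform placement of the same number of breakpoints on the same
#' chromosome.  The statistic is a one-sided KS-type excess of small
#' spacings (see the methods vignette); the p-value is the fraction of
#' `mc_resamples` uniform placements with an equal or larger statistic.
#' Satisfied when p < alpha.  One-sided toward clustering: exactly
#' regularly spaced breakpoints do not satisfy the criterion.
#'
#' Duplicate positions are collapsed with a warning; unsorted input is
#' sorted.
#'
#' @param positions breakpoint positions (bp) on one chromosome.
#' @param chrom_length chromosome length (bp).
#' @param params parameters from [chromothripsis_params()].
#' @return criterion result list.
#' @export
criterion_breakpoint_clustering <- function(positions, chrom_length,
                                            params = chromothripsis_params()) {
  if (anyDuplicated(positions)) {
    warning("duplicate breakpoint positions collapsed")
    positions <- unique(positions)
  }
  positions <- sort(positions)
  n <- length(positions)
  if (n < params$min_breakpoints) {
    return(criterion_result("C2_clustering", evaluable = FALSE))
  }
  d_obs <- clustering_statistic(positions, chrom_length)
  d_null <- with_seed(params$mc_seed, {
    vapply(seq_len(params$mc_resamples), function(b) {
      clustering_statistic(stats::runif(n, 0, chrom_length), chrom_length)
    }, 0)
  })
  p <- (1 + sum(d_null >= d_obs)) / (params$mc_resamples + 1)
  criterion_result("C2_clustering", statistic = d_obs, p_value = p,
                   satisfied = p < params$alpha)
}

#' C3: randomness of fragment-join orientations
#'
#' Goodness of fit of the four orientation-class counts (deletion-type,
#' duplication-type, and the two inversion types) against equal
#' proportions.  With at least `chisq_joins` joins the chi-square form is
#' used (df 3); with `min_joins_exact` to `chisq_joins - 1` joins an exact
#' multinomial test (summing outcomes no more probable than the observed
#' one); below that the criterion is not evaluable.  Satisfied when the
#' test does NOT reject (p >= alpha): random religation predicts uniform
#' orientations.
#'
#' @param joins intrachromosomal joins (data frame with an `orientation`
#'   column, see [read_bedpe()]), or a length-4 count vector.
#' @param params parameters from [chromothripsis_params()].
#' @return criterion result list.
#' @export
criterion_join_randomness <- function(joins, params = chromothripsis_params()) {
  counts <- orientation_counts(joins)
  n <- sum(counts)
  if (n < params$min_joins_exact) {
    return(criterion_result("C3_join_randomness", evaluable = FALSE))
  }
  if (n >= params$chisq_joins) {
    expected <- n / 4
    stat <- sum((counts - expected)^2 / expected)
    p <- stats::pchisq(stat, df = 3, lower.tail = FALSE)
  } else {
    stat <- NA_real_
    p <- multinomial_uniform_p(counts)
  }
  criterion_result("C3_join_randomness", statistic = stat, p_value = p,
                   satisfied = p >= params$alpha)
}

orientation_counts <- function(joins) {
  lv <- orientation_levels()
  if (is.data.frame(joins)) {
    counts <- as.numeric(table(factor(joins$orientation, levels = lv)))
  } else {
    stopifnot(length(joins) == 4)
    counts <- as.numeric(joins)
  }
  names(counts) <- lv
  counts
}

# Exact multinomial uniformity test: p = total probability of outcomes no
# more probable than the observed one under p = (1/4, 1/4, 1/4, 1/4).
multinomial_uniform_p <- function(counts) {
  n <- sum(counts)
  p_obs <- stats::dmultinom(counts, prob = rep(0.25, 4))
  p <- 0
  for (a in 0:n) for (b in 0:(n - a)) for (c_ in 0:(n - a - b)) {
    pr <- stats::dmultinom(c(a, b, c_, n - a - b - c_), prob = rep(0.25, 4))
    if (pr <= p_obs * (1 + 1e-9)) p <- p + pr
  }
  min(1, p)
}

#' C4: randomness of fragment order
#'
#' The statistic is the Spearman rank correlation between the left
#' (smaller) breakend position of each intrachromosomal join and its
#' partner breakend position.  Because the smaller and larger member of
#' any random pair are structurally correlated, the naive correlation test
#' is not calibrated; the p-value is therefore computed conditionally on
#' the observed breakend positions, by repeatedly re-pairing the breakends
#' at random (seeded Monte-Carlo) and recomputing the statistic.  Ordered
#' rearrangement processes (joins pairing nearby, reference-ordered
#' positions) push the observed correlation above the re-paired null;
#' chromothriptic religation is itself a random pairing, so the test is
#' exact by construction.  One-sided toward positive order correlation;
#' satisfied when the test does NOT reject (p >= alpha).  Requires
#' `min_joins_order` joins.
#'
#' @param joins intrachromosomal joins data frame (`pos1`, `pos2`).
#' @param params parameters from [chromothripsis_params()].
#' @return criterion result list (statistic = observed Spearman rho).
#' @export
criterion_order_randomness <- function(joins, params = chromothripsis_params()) {
  n <- nrow(joins)
  if (is.null(n) || n < params$min_joins_order) {
    return(criterion_result("C4_order_randomness", evaluable = FALSE))
  }
  rho_of_pairs <- function(a, b) {
    stats::cor(rank(pmin(a, b)), rank(pmax(a, b)))
  }
  rho_obs <- rho_of_pairs(joins$pos1, joins$pos2)
  ends <- c(joins$pos1, joins$pos2)
  rho_null <- with_seed(params$mc_seed + 1L, {
    vapply(seq_len(params$mc_resamples), function(b) {
      perm <- sample(ends)
      rho_of_pairs(perm[seq_len(n)], perm[n + seq_len(n)])
    }, 0)
  })
  p <- (1 + sum(rho_null >= rho_obs)) / (params$mc_resamples + 1)
  criterion_result("C4_order_randomness", statistic = rho_obs,
                   p_value = p, satisfied = p >= params$alpha)
}

#' Call chromothripsis on one sample-chromosome
#'
#' Runs the four criteria on the chromosome's segments and
#' intrachromosomal joins and calls chromothripsis when at least two are
#' satisfied.  Non-evaluable criteria count as not satisfied.  A call
#' resting on exactly two criteria carries a `borderline` flag, the
#' machine-readable stand-in for manual review of marginal cases.
#'
#' Breakpoint positions for C2 are the breakends of the intrachromosomal
#' joins (both ends, deduplicated).
#'
#' @param segments segments of one sample on one chromosome (ordered by
#'   `start` internally).
#' @param joins SV joins of the same sample; only intrachromosomal joins
#'   on the segment chromosome are used.
#' @param genome genome model (for the chromosome length used by C2).
#' @param params parameters from [chromothripsis_params()].
#' @param chrom chromosome to evaluate; defaults to the single chromosome
#'   present in `segments` (or `joins`).
#' @return object of class `chromothripsis_eval`: list with `chrom`,
#'   `criteria` (list of 4 criterion results), `n_satisfied`, `call`,
#'   `borderline`.
#' @export
call_chromothripsis <- function(segments, joins, genome = genome_model(),
                                params = chromothripsis_params(),
                                chrom = NULL) {
  if (is.null(chrom)) {
    chrom <- unique(c(segments$chrom, joins$chrom1, joins$chrom2))
    if (length(chrom) != 1) {
      stop("chrom must be given when inputs span several chromosomes")
    }
  }
  chrom <- normalize_chrom(chrom)
  segs <- segments[segments$chrom == chrom, , drop = FALSE]
  segs <- segs[order(segs$start), , drop = FALSE]
  intra <- joins[joins$chrom1 == chrom & joins$chrom2 == chrom, , drop = FALSE]
  L <- genome$length[match(chrom, genome$chrom)]
  if (is.na(L)) stop("unknown chromosome: ", chrom)

  c1 <- if (nrow(segs)) {
    criterion_oscillation(infer_cn_states(segs$seg_mean), params)
  } else criterion_result("C1_oscillation", evaluable = FALSE)
  bp <- unique(c(intra$pos1, intra$pos2))
  c2 <- criterion_breakpoint_clustering(bp, L, params)
  c3 <- criterion_join_randomness(intra, params)
  c4 <- criterion_order_randomness(intra, params)

  criteria <- list(c1, c2, c3, c4)
  n_sat <- sum(vapply(criteria, `[[`, TRUE, "satisfied"))
  structure(list(chrom = chrom, criteria = criteria, n_satisfied = n_sat,
                 call = n_sat >= 2, borderline = n_sat == 2),
            class = "chromothripsis_eval")
}

#' @export
print.chromothripsis_eval <- function(x, ...) {
  cat("Chromothripsis evaluation for", x$chrom, "\n")
  for (cr in x$criteria) {
    cat(sprintf("  %-20s %s%s\n", cr$criterion,
                if (!cr$evaluable) "not evaluable"
                else if (cr$satisfied) "satisfied" else "not satisfied",
                if (is.na(cr$p_value)) "" else sprintf(" (p = %.3g)", cr$p_value)))
  }
  cat(sprintf("  call: %s (%d/4 criteria%s)\n",
              if (x$call) "CHROMOTHRIPSIS" else "negative", x$n_satisfied,
              if (isTRUE(x$borderline)) ", borderline" else ""))
  invisible(x)
}

#' Evaluate chromothripsis across a cohort
#'
#' Runs [call_chromothripsis()] for every sample x chromosome combination
#' present in the segmentation (restricted to chromosomes with any
#' intrachromosomal join, plus all segmented chromosomes).
#'
#' @param segments cohort segment data frame (with `sample`).
#' @param joins cohort join data frame (with a `sample` column).
#' @param genome genome model.
#' @param params parameters from [chromothripsis_params()].
#' @return data frame with one row per sample x chromosome: criterion
#'   satisfied flags, p-values, `n_satisfied`, `call`, `borderline`.
#' @export
evaluate_chromothripsis_cohort <- function(segments, joins,
                                           genome = genome_model(),
                                           params = chromothripsis_params()) {
  keys <- unique(rbind(segments[c("sample", "chrom")],
                       stats::setNames(joins[joins$chrom1 == joins$chrom2,
                                             c("sample", "chrom1")],
                                       c("sample", "chrom"))))
  rows <- lapply(seq_len(nrow(keys)), function(r) {
    s <- keys$sample[r]; ch <- keys$chrom[r]
    ev <- call_chromothripsis(segments[segments$sample == s, , drop = FALSE],
                              joins[joins$sample == s, , drop = FALSE],
                              genome, params, chrom = ch)
    crit <- ev$criteria
    data.frame(sample = s, chrom = ch,
               c1 = crit[[1]]$satisfied, c2 = crit[[2]]$satisfied,
               c3 = crit[[3]]$satisfied, c4 = crit[[4]]$satisfied,
               p_c2 = crit[[2]]$p_value, p_c3 = crit[[3]]$p_value,
               p_c4 = crit[[4]]$p_value,
               n_satisfied = ev$n_satisfied, call = ev$call,
               borderline = ev$borderline, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare chromothripsis frequency between two cohorts
#'
#' One-sided Fisher's exact test of the positive-call frequency, testing
#' enrichment in cohort A (the direction used when comparing the RIG
#' cohort against de novo pHGG comparison cohorts).
#'
#' @param calls_a,calls_b logical vectors of per-case calls.
#' @return `contingency_result` from [fisher_exact()].
#' @export
compare_cohort_frequency <- function(calls_a, calls_b) {
  if (!length(calls_a) || !length(calls_b)) stop("empty cohort")
  tab <- matrix(c(sum(calls_a), sum(!calls_a),
                  sum(calls_b), sum(!calls_b)), 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("positive", "negative")))
  fisher_exact(tab, sidedness = "greater")
}
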