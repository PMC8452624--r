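#' Configuration of the synthetic RIG cohort generator
#'
#' The generator plants, with known ground truth, exactly the statistical
#' structure the downstream stages test for: chromothriptic chromosomes
#' with two-state oscillating copy number, spatially clustered breakpoints
#' and orientation-random joins; progressive-rearrangement negative
#' controls with nested multi-state profiles and ordered joins; highly
#' amplified circular eccDNA amplicons; and two tumor subgroups with a
#' configurable (default ninefold) difference in somatic variant rate but
#' identical germline rates.
#'
#' Defaults encode the cohort the pipeline was designed around: 3 Group A
#' and 6 Group B tumors with paired germline data, a ninefold somatic
#' fold, a 34 Mb coding space, and chromothriptic events shattered inside
#' a window spanning 10% of the chromosome.
#'
#' @param seed master seed; every per-sample stream is derived from it.
#' @param n_samples_group_a,n_samples_group_b cohort sizes.
#' @param genome genome model (see [genome_model()]).
#' @param n_breakpoints breakpoints per chromothriptic event (>= 10).
#' @param cluster_window_bp span of the shattered region; `NULL` = 10% of
#'   the chromosome.
#' @param fragment_retention_prob probability a shattered fragment is
#'   retained (strictly inside (0,1); 0 or 1 cannot oscillate).
#' @param noise_sd segment-mean jitter (log2 units).
#' @param n_events,event_size_range_bp progressive-control parameters.
#' @param n_fragments,amplified_log2 eccDNA parameters (2-5 fragments;
#'   planted seg_mean is `amplified_log2` plus upward-truncated noise so
#'   the configured level is a guaranteed floor).
#' @param germline_rate_per_mb,somatic_rate_a_per_mb,somatic_fold_b,coding_mb
#'   mutation rates: germline rate identical in both groups; Group B
#'   somatic rate is `somatic_rate_a_per_mb * somatic_fold_b`.
#' @param depth_mean,qual_mean,qual_sd sequencing-depth and QUAL models.
#' @param spectrum named 6-class substitution spectrum (probabilities).
#' @param hypermutator_factor somatic-rate multiplier for samples
#'   simulated with `hypermutator = TRUE`.
#' @param age_median,latency_median,survival_median_months clinical
#'   distribution medians (years, years, months).
#' @return configuration list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_samples_group_a = 3, n_samples_group_b = 6,
                       genome = genome_model(),
                       n_breakpoints = 30, cluster_window_bp = NULL,
                       fragment_retention_prob = 0.5, noise_sd = 0.05,
                       n_events = 8, event_size_range_bp = c(1e6, 2e7),
                       n_fragments = 3, amplified_log2 = 2.5,
                       germline_rate_per_mb = 30,
                       somatic_rate_a_per_mb = 0.3,
                       somatic_fold_b = 9.0, coding_mb = 34,
                       depth_mean = 100, qual_mean = 80, qual_sd = 20,
                       spectrum = c("A>C" = 0.09, "A>G" = 0.17, "A>T" = 0.09,
                                    "C>A" = 0.10, "C>G" = 0.10, "C>T" = 0.45),
                       hypermutator_factor = 50,
                       age_median = 7, latency_median = 8,
                       survival_median_months = 9) {
  stopifnot(n_breakpoints >= 10,
            fragment_retention_prob >= 0, fragment_retention_prob <= 1,
            somatic_fold_b > 0, coding_mb > 0,
            n_fragments >= 2, n_fragments <= 5,
            n_events >= 1, length(event_size_range_bp) == 2,
            abs(sum(spectrum) - 1) < 1e-6)
  structure(list(seed = seed,
                 n_samples_group_a = n_samples_group_a,
                 n_samples_group_b = n_samples_group_b,
                 genome = genome,
                 n_breakpoints = n_breakpoints,
                 cluster_window_bp = cluster_window_bp,
                 fragment_retention_prob = fragment_retention_prob,
                 noise_sd = noise_sd,
                 n_events = n_events,
                 event_size_range_bp = event_size_range_bp,
                 n_fragments = n_fragments,
                 amplified_log2 = amplified_log2,
                 germline_rate_per_mb = germline_rate_per_mb,
                 somatic_rate_a_per_mb = somatic_rate_a_per_mb,
                 somatic_fold_b = somatic_fold_b,
                 coding_mb = coding_mb,
                 depth_mean = depth_mean,
                 qual_mean = qual_mean, qual_sd = qual_sd,
                 spectrum = spectrum,
                 hypermutator_factor = hypermutator_factor,
                 age_median = age_median,
                 latency_median = latency_median,
                 survival_median_months = survival_median_months),
            class = "sim_config")
}

chrom_length <- function(genome, chrom) {
  chrom <- normalize_chrom(chrom)
  L <- genome$length[match(chrom, genome$chrom)]
  if (is.na(L)) stop("unknown chromosome: ", chrom)
  L
}

#' Simulate a chromothriptic chromosome
#'
#' Plants all four chromothripsis hallmarks: `n_breakpoints` breakpoints
#' drawn uniformly inside a window of `cluster_window_bp` (clustered),
#' fragments independently retained (log2 ratio around 0) or lost (around
#' -1.0), giving a two-state oscillating profile; the retained fragments
#' are shuffled into a random derivative order with random orientations,
#' and the emitted joins are the derivative adjacencies, so join
#' orientations are uniform over the four classes and the partner order is
#' random.  Every join breakend coincides with a fragment boundary.
#'
#' @param config simulation configuration ([sim_config()]).
#' @param chrom chromosome to shatter.
#' @param seed RNG seed for this event (derived per sample by
#'   [simulate_cohort()]).
#' @param sample_id sample label on the emitted records.
#' @return list with `segments`, `joins` (both data frames) and `truth`
#'   (window, per-fragment retention, derivative order and orientations).
#' @export
simulate_chromothriptic_chromosome <- function(config, chrom, seed,
                                               sample_id = "S1") {
  p <- config$fragment_retention_prob
  if (p <= 0 || p >= 1) {
    stop("degenerate simulation: retention probability must be in (0, 1)")
  }
  chrom <- normalize_chrom(chrom)
  L <- chrom_length(config$genome, chrom)
  window <- if (is.null(config$cluster_window_bp)) 0.1 * L else config$cluster_window_bp
  window <- min(window, L)
  with_seed(seed, {
    region_start <- floor(stats::runif(1, 0, L - window))
    bp <- sort(unique(round(stats::runif(config$n_breakpoints,
                                         region_start, region_start + window))))
    bounds <- c(region_start, bp, region_start + window)
    n_frag <- length(bounds) - 1
    retained <- stats::rbinom(n_frag, 1, p) == 1
    base <- ifelse(retained, 0, -1)
    seg_mean <- stats::rnorm(n_frag, base, config$noise_sd)
    segments <- data.frame(sample = sample_id, chrom = chrom,
                           start = bounds[-length(bounds)], end = bounds[-1],
                           seg_mean = seg_mean, stringsAsFactors = FALSE)
    keep <- which(retained)
    joins <- empty_joins()
    order_idx <- integer(); orient <- character()
    if (length(keep) >= 2) {
      order_idx <- sample(keep)
      orient <- sample(c("+", "-"), length(keep), replace = TRUE)
      js <- lapply(seq_len(length(keep) - 1), function(i) {
        f1 <- order_idx[i]; o1 <- orient[i]
        f2 <- order_idx[i + 1]; o2 <- orient[i + 1]
        exit_pos <- if (o1 == "+") bounds[f1 + 1] else bounds[f1]
        exit_str <- if (o1 == "+") "+" else "-"
        entry_pos <- if (o2 == "+") bounds[f2] else bounds[f2 + 1]
        entry_str <- if (o2 == "+") "-" else "+"
        data.frame(chrom1 = chrom, pos1 = exit_pos, strand1 = exit_str,
                   chrom2 = chrom, pos2 = entry_pos, strand2 = entry_str,
                   name = sprintf("%s_ct_%d", sample_id, i),
                   stringsAsFactors = FALSE)
      })
      joins <- do.call(rbind, js)
      joins$orientation <- orientation_class(joins$strand1, joins$strand2)
    }
    list(segments = segments, joins = joins,
         truth = list(kind = "chromothripsis", chrom = chrom,
                      window = c(region_start, region_start + window),
                      bounds = bounds, retained = retained,
                      derivative_order = order_idx,
                      orientations = orient))
  })
}

#' Simulate a progressive-rearrangement chromosome (negative control)
#'
#' Sequential, independent deletion/duplication events produce a nested,
#' multi-state copy-number profile and joins whose partner positions are a
#' near-monotone function of the left breakends - the opposite of every
#' chromothripsis hallmark except segment count.
#'
#' @inheritParams simulate_chromothriptic_chromosome
#' @return as [simulate_chromothriptic_chromosome()].
#' @export
simulate_progressive_rearrangement <- function(config, chrom, seed,
                                               sample_id = "S1") {
  stopifnot(config$n_events >= 1)
  chrom <- normalize_chrom(chrom)
  L <- chrom_length(config$genome, chrom)
  with_seed(seed, {
    sz <- stats::runif(config$n_events, config$event_size_range_bp[1],
                       config$event_size_range_bp[2])
    st <- floor(stats::runif(config$n_events, 0, L - sz))
    en <- floor(st + sz)
    type <- sample(c("del", "dup"), config$n_events, replace = TRUE)
    joins <- data.frame(
      chrom1 = chrom, pos1 = st,
      strand1 = ifelse(type == "del", "+", "-"),
      chrom2 = chrom, pos2 = en,
      strand2 = ifelse(type == "del", "-", "+"),
      name = sprintf("%s_pr_%d", sample_id, seq_len(config$n_events)),
      stringsAsFactors = FALSE)
    joins$orientation <- orientation_class(joins$strand1, joins$strand2)
    bounds <- sort(unique(c(0, st, en, L)))
    mid <- (bounds[-length(bounds)] + bounds[-1]) / 2
    cn <- vapply(mid, function(m) {
      max(0, 2 + sum(m >= st & m < en & type == "dup") -
            sum(m >= st & m < en & type == "del"))
    }, 0)
    seg_mean <- ifelse(cn > 0, log2(cn / 2), -3) +
      stats::rnorm(length(cn), 0, config$noise_sd)
    segments <- data.frame(sample = sample_id, chrom = chrom,
                           start = bounds[-length(bounds)], end = bounds[-1],
                           seg_mean = seg_mean, stringsAsFactors = FALSE)
    list(segments = segments, joins = joins,
         truth = list(kind = "progressive", chrom = chrom,
                      events = data.frame(start = st, end = en, type = type),
                      cn_states = cn))
  })
}

#' Simulate an eccDNA amplicon
#'
#' Plants `n_fragments` disjoint, highly amplified segments (seg_mean =
#' `amplified_log2` plus upward-truncated noise) connected by exactly
#' `n_fragments` joins that close a single cycle traversing every fragment
#' once, in a random order with random orientations.  Background segments
#' at neutral copy number tile the rest of the chromosome so the
#' amplification selector has something to reject.
#'
#' @inheritParams simulate_chromothriptic_chromosome
#' @return as [simulate_chromothriptic_chromosome()]; `truth` carries the
#'   planted fragment coordinates, cycle order and orientations.
#' @export
simulate_eccdna <- function(config, chrom, seed, sample_id = "S1") {
  n <- config$n_fragments
  stopifnot(n >= 2, n <= 5)
  chrom <- normalize_chrom(chrom)
  L <- chrom_length(config$genome, chrom)
  with_seed(seed, {
    repeat {
      sz <- stats::runif(n, 1e5, 1e6)
      st <- floor(stats::runif(n, 0, L - sz))
      en <- floor(st + sz)
      o <- order(st)
      st <- st[o]; en <- en[o]
      if (all(st[-1] > en[-n])) break  # disjoint fragments guaranteed
    }
    frag_mean <- config$amplified_log2 + abs(stats::rnorm(n, 0, config$noise_sd))
    bg_bounds <- c(0, rbind(st, en), L)
    segs <- list()
    for (i in seq_len(n)) {
      segs[[length(segs) + 1]] <- data.frame(
        sample = sample_id, chrom = chrom, start = st[i], end = en[i],
        seg_mean = frag_mean[i], stringsAsFactors = FALSE)
    }
    gaps <- data.frame(start = c(0, en), end = c(st, L))
    gaps <- gaps[gaps$end > gaps$start, , drop = FALSE]
    if (nrow(gaps)) {
      segs[[length(segs) + 1]] <- data.frame(
        sample = sample_id, chrom = chrom, start = gaps$start, end = gaps$end,
        seg_mean = stats::rnorm(nrow(gaps), 0, config$noise_sd),
        stringsAsFactors = FALSE)
    }
    segments <- do.call(rbind, segs)
    segments <- segments[order(segments$start), , drop = FALSE]
    rownames(segments) <- NULL
    ord <- sample(n)
    orient <- sample(c("+", "-"), n, replace = TRUE)
    js <- lapply(seq_len(n), function(i) {
      a <- ord[i]; b <- ord[if (i == n) 1 else i + 1]
      oa <- orient[i]; ob <- orient[if (i == n) 1 else i + 1]
      data.frame(chrom1 = chrom,
                 pos1 = if (oa == "+") en[a] else st[a],
                 strand1 = if (oa == "+") "+" else "-",
                 chrom2 = chrom,
                 pos2 = if (ob == "+") st[b] else en[b],
                 strand2 = if (ob == "+") "-" else "+",
                 name = sprintf("%s_ecc_%d", sample_id, i),
                 stringsAsFactors = FALSE)
    })
    joins <- do.call(rbind, js)
    joins$orientation <- orientation_class(joins$strand1, joins$strand2)
    list(segments = segments, joins = joins,
         truth = list(kind = "eccdna", chrom = chrom,
                      fragments = data.frame(start = st, end = en,
                                             seg_mean = frag_mean),
                      cycle_order = ord, orientations = orient))
  })
}

sample_substitutions <- function(n, spectrum) {
  classes <- names(spectrum)
  cls <- sample(classes, n, replace = TRUE, prob = spectrum)
  ref <- substr(cls, 1, 1)
  alt <- substr(cls, 3, 3)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- stats::runif(n) < 0.5
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  list(ref = ref, alt = alt)
}

#' Simulate germline and somatic variant calls for one sample
#'
#' Germline variants are drawn at the same rate for both groups (Poisson
#' over the coding space), with heterozygous allele fractions and QUAL
#' scores from a truncated normal so a tail falls below the QUAL-50
#' filter.  Somatic counts are Poisson with rate
#' `somatic_rate_a_per_mb * coding_mb * fold`, fold = 1 for Group A and
#' `somatic_fold_b` for Group B (times `hypermutator_factor` when
#' `hypermutator`); somatic allele fractions are subclonal (uniform on
#' 0.05-0.5) and read support is binomial in a Poisson depth.
#' Substitution classes are drawn from the configured 6-class spectrum on
#' a random strand.
#'
#' @param config simulation configuration.
#' @param sample_id sample label.
#' @param group `"A"` or `"B"`.
#' @param seed RNG seed for this sample.
#' @param hypermutator logical; plants a mismatch-repair-deficient-like
#'   outlier for exercising the exclusion rule.
#' @return variant data frame in the [read_vcf()] layout.
#' @export
simulate_variant_calls <- function(config, sample_id, group = c("A", "B"),
                                   seed, hypermutator = FALSE) {
  group <- match.arg(group)
  stopifnot(config$germline_rate_per_mb > 0, config$somatic_rate_a_per_mb > 0)
  fold <- if (group == "B") config$somatic_fold_b else 1
  if (hypermutator) fold <- fold * config$hypermutator_factor
  with_seed(seed, {
    chroms <- config$genome$chrom
    lens <- config$genome$length
    gen_one <- function(n, compartment) {
      if (n == 0) return(empty_variants())
      ci <- sample(length(chroms), n, replace = TRUE, prob = lens)
      pos <- floor(stats::runif(n, 1, lens[ci]))
      sub <- sample_substitutions(n, config$spectrum)
      depth <- stats::rpois(n, config$depth_mean)
      if (compartment == "germline") {
        vaf_true <- rep(0.5, n)
        qual <- pmax(0, stats::rnorm(n, config$qual_mean, config$qual_sd))
      } else {
        vaf_true <- stats::runif(n, 0.05, 0.5)
        qual <- pmax(0, stats::rnorm(n, config$qual_mean / 2, config$qual_sd))
      }
      alt <- stats::rbinom(n, depth, vaf_true)
      data.frame(chrom = chroms[ci], pos = pos, ref = sub$ref, alt = sub$alt,
                 qual = round(qual, 1), alt_reads = alt, total_depth = depth,
                 vaf = ifelse(depth > 0, alt / depth, NA_real_),
                 compartment = compartment, coding = TRUE,
                 stringsAsFactors = FALSE)
    }
    n_germ <- stats::rpois(1, config$germline_rate_per_mb * config$coding_mb)
    n_som <- stats::rpois(1, config$somatic_rate_a_per_mb * config$coding_mb * fold)
    out <- rbind(gen_one(n_germ, "germline"), gen_one(n_som, "somatic"))
    rownames(out) <- NULL
    out
  })
}

#' Simulate a Table-1-shaped clinical table
#'
#' Ages and latencies are log-normal with configured medians, survival is
#' exponential with the configured median, vital status is mostly
#' deceased with a minority of unknowns, and a sprinkle of values is
#' missing, matching the dash convention of the printed table.
#'
#' @param config simulation configuration.
#' @param n number of cases.
#' @param seed RNG seed.
#' @return clinical data frame in the [read_clinical()] layout.
#' @export
simulate_clinical_table <- function(config, n, seed) {
  stopifnot(n >= 1)
  with_seed(seed, {
    age <- round(stats::rlnorm(n, log(config$age_median), 0.9), 1)
    age <- pmin(age, 20)
    latency <- round(stats::rlnorm(n, log(config$latency_median), 0.45), 1)
    survival <- round(stats::rexp(n, log(2) / config$survival_median_months), 1)
    status <- sample(c("deceased", "unknown"), n, replace = TRUE,
                     prob = c(0.81, 0.19))
    histology <- sample(c("M", "ALL", "A", "E", "Ge", "G,O", "other"), n,
                        replace = TRUE,
                        prob = c(0.38, 0.31, 0.09, 0.06, 0.06, 0.05, 0.05))
    field <- sample(c("Focal", "CSI", "CR", "TBI"), n, replace = TRUE,
                    prob = c(0.4, 0.3, 0.2, 0.1))
    dose <- as.character(round(stats::runif(n, 12, 60), 1))
    miss <- function(x, p = 0.1) {
      x[stats::runif(length(x)) < p] <- NA
      x
    }
    survival[status == "unknown"] <- NA
    data.frame(id = sprintf("SIM%02d", seq_len(n)),
               age = miss(age), histology = histology, dose_gy = miss(dose),
               field = field, latency_y = miss(latency), status = status,
               survival_months = survival, stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Generates the full multi-sample artifact: per-sample variant calls,
#' structural events (each sample carries a chromothriptic chromosome
#' with probability `chromothripsis_prob`, otherwise a
#' progressive-rearrangement control; an eccDNA amplicon is added with
#' probability `eccdna_prob`), and a clinical table.  One RNG stream per
#' sample is derived from the master seed, so per-sample outputs do not
#' depend on generation order.
#'
#' @param config simulation configuration.
#' @param chromothripsis_prob,eccdna_prob per-sample event probabilities
#'   (defaults 2/3 and 1/6, the event frequencies of the WGS cohort the
#'   generator emulates).
#' @return list with `segments`, `joins`, `variants` (list per sample),
#'   `clinical`, `samples` (sample/group table) and `truth` (per-sample
#'   planted ground truth).
#' @export
simulate_cohort <- function(config, chromothripsis_prob = 2 / 3,
                            eccdna_prob = 1 / 6) {
  n <- config$n_samples_group_a + config$n_samples_group_b
  groups <- rep(c("A", "B"), c(config$n_samples_group_a,
                               config$n_samples_group_b))
  ids <- sprintf("%s%d", groups, c(seq_len(config$n_samples_group_a),
                                   seq_len(config$n_samples_group_b)))
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1, n + 1))
  autosomes <- paste0("chr", 1:22)
  segments <- list(); joins <- list(); variants <- list(); truth <- list()
  for (i in seq_len(n)) {
    s <- seeds[i]
    draw <- with_seed(s, list(u = stats::runif(2),
                              chrom = sample(autosomes, 2)))
    ct <- draw$u[1] < chromothripsis_prob
    ev <- if (ct) {
      simulate_chromothriptic_chromosome(config, draw$chrom[1], s + 1, ids[i])
    } else {
      simulate_progressive_rearrangement(config, draw$chrom[1], s + 1, ids[i])
    }
    truth_i <- list(structural = ev$truth)
    seg_i <- ev$segments; join_i <- ev$joins
    if (draw$u[2] < eccdna_prob) {
      ecc <- simulate_eccdna(config, draw$chrom[2], s + 2, ids[i])
      seg_i <- rbind(seg_i, ecc$segments)
      join_i <- rbind(join_i, ecc$joins)
      truth_i$eccdna <- ecc$truth
    }
    if (nrow(join_i)) join_i$sample <- ids[i]
    segments[[i]] <- seg_i
    joins[[i]] <- join_i
    variants[[ids[i]]] <- simulate_variant_calls(config, ids[i], groups[i],
                                                 s + 3)
    truth[[ids[i]]] <- truth_i
  }
  clinical <- simulate_clinical_table(config, n, seeds[n + 1])
  clinical$id <- ids
  list(segments = do.call(rbind, segments),
       joins = do.call(rbind, joins),
       variants = variants,
       clinical = clinical,
       samples = data.frame(sample = ids, group = groups,
                            stringsAsFactors = FALSE),
       truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Emits the SEG, BEDPE, per-sample VCF, clinical TSV and a plain-text
#' ground-truth report into `outdir`.
#'
#' @param cohort output of [simulate_cohort()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_seg(cohort$segments, file.path(outdir, "cohort.seg"))
  jn <- cohort$joins
  write_bedpe(jn, file.path(outdir, "cohort.bedpe"))
  utils::write.table(jn["sample"], file.path(outdir, "cohort.bedpe.samples"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dir.create(file.path(outdir, "vcf"), showWarnings = FALSE)
  for (s in names(cohort$variants)) {
    write_vcf(cohort$variants[[s]], file.path(outdir, "vcf", paste0(s, ".vcf")),
              sample_name = s)
  }
  write_clinical(cohort$clinical, file.path(outdir, "clinical.tsv"))
  utils::write.table(cohort$samples, file.path(outdir, "groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_lines <- unlist(lapply(names(cohort$truth), function(s) {
    t <- cohort$truth[[s]]
    c(sprintf("sample=%s kind=%s chrom=%s", s, t$structural$kind,
              t$structural$chrom),
      if (!is.null(t$eccdna)) {
        sprintf("sample=%s kind=eccdna chrom=%s fragments=%d", s,
                t$eccdna$chrom, nrow(t$eccdna$fragments))
      })
  }))
  writeLines(truth_lines, file.path(outdir, "ground_truth.txt"))
  invisible(outdir)
}
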