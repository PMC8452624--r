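#' Germline mutation load
#'
#' The germline load of a sample is the total number of called germline
#' variants passing the QUAL filter (inclusive threshold, default 50).
#' Variants with missing QUAL are excluded.  Allele support is ignored.
#'
#' @param variants variant data frame (see [read_vcf()]); rows are assumed
#'   to be germline calls (filter by `compartment` upstream, or pass
#'   `compartment = "germline"` to filter here).
#' @param qual_threshold inclusive QUAL cutoff.
#' @param compartment optional compartment label to filter on.
#' @return integer count.
#' @export
germline_load <- function(variants, qual_threshold = 50,
                          compartment = "germline") {
  if (!is.null(compartment) && !is.null(variants$compartment)) {
    variants <- variants[!is.na(variants$compartment) &
                           variants$compartment == compartment, , drop = FALSE]
  }
  sum(!is.na(variants$qual) & variants$qual >= qual_threshold)
}

#' Somatic mutation load
#'
#' The somatic load is counted without QUAL filtering: tumor heterogeneity
#' means a subclonal variant can be real yet low-QUAL.  Instead each call
#' must be supported by at least `min_alt_reads` reads (inclusive, default
#' 4).
#'
#' @param variants variant data frame; rows are assumed somatic (or pass
#'   `compartment = "somatic"`).
#' @param min_alt_reads inclusive alt-read support cutoff.
#' @param compartment optional compartment label to filter on.
#' @return integer count.
#' @export
somatic_load <- function(variants, min_alt_reads = 4,
                         compartment = "somatic") {
  if (!is.null(compartment) && !is.null(variants$compartment)) {
    variants <- variants[!is.na(variants$compartment) &
                           variants$compartment == compartment, , drop = FALSE]
  }
  sum(!is.na(variants$alt_reads) & variants$alt_reads >= min_alt_reads)
}

#' Exome reporting filter
#'
#' Keeps variants supported by at least `min_alt_reads` mutant alleles AND
#' at least `min_vaf` variant allele fraction (both inclusive; defaults 5
#' and 0.30).  Variants flagged as curated-database matches (column
#' `database_match`, logical) bypass the filter.  Records whose VAF cannot
#' be computed (zero depth) are excluded with a warning.
#'
#' @param variants variant data frame.
#' @param min_alt_reads,min_vaf inclusive thresholds.
#' @return the reportable subset of `variants`.
#' @export
wes_report_filter <- function(variants, min_alt_reads = 5, min_vaf = 0.30) {
  db <- if (!is.null(variants$database_match)) {
    !is.na(variants$database_match) & variants$database_match
  } else rep(FALSE, nrow(variants))
  no_vaf <- is.na(variants$vaf)
  if (any(no_vaf & !db)) {
    warning(sum(no_vaf & !db), " variant(s) with undefined VAF excluded")
  }
  keep <- db | (!no_vaf & variants$alt_reads >= min_alt_reads &
                  variants$vaf >= min_vaf)
  variants[keep, , drop = FALSE]
}

#' Mutation load per megabase
#'
#' @param load variant count.
#' @param region_mb size of the interrogated region in Mb (> 0).
#' @return load / region_mb.
#' @export
load_per_mb <- function(load, region_mb) {
  if (!is.numeric(region_mb) || region_mb <= 0) {
    stop("region_mb must be > 0")
  }
  load / region_mb
}

#' The six substitution classes (purine/pyrimidine-collapsed, A/C reference)
#' @return character vector of class labels.
#' @export
substitution_classes <- function() {
  c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T")
}

#' Substitution spectrum of SNV calls
#'
#' Each single-nucleotide substitution is collapsed onto the strand whose
#' reference base is A or C: a T or G reference substitution is
#' reverse-complemented into its A/C-reference class (T>C becomes A>G,
#' G>T becomes C>A, and so on), giving the conventional 6-class spectrum.
#' Non-SNV records are skipped and counted.
#'
#' @param variants variant data frame with `ref` and `alt` columns.
#' @return list with `counts` (named length-6 vector), `proportions`
#'   (sums to 1 when any SNV present), `n_snv`, `n_skipped`.
#' @export
substitution_spectrum <- function(variants) {
  classes <- substitution_classes()
  ref <- toupper(variants$ref); alt <- toupper(variants$alt)
  is_snv <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  r <- ref[is_snv]; a <- alt[is_snv]
  flip <- r %in% c("T", "G")
  r[flip] <- comp[r[flip]]
  a[flip] <- comp[a[flip]]
  counts <- table(factor(paste0(r, ">", a), levels = classes))
  counts <- stats::setNames(as.numeric(counts), classes)
  n_snv <- sum(is_snv)
  list(counts = counts,
       proportions = if (n_snv > 0) counts / n_snv else counts * NA_real_,
       n_snv = n_snv, n_skipped = sum(!is_snv))
}

#' Per-sample mutation-load summary
#'
#' Applies the germline and somatic filters, computes somatic variants per
#' Mb of coding sequence and the 6-class somatic substitution spectrum,
#' and flags hypermutators (somatic coding rate above
#' `hypermutator_per_mb`, or membership in an explicit exclusion list).
#'
#' @param variants all variant calls of one sample (germline + somatic
#'   compartments).
#' @param sample_id sample identifier.
#' @param group subgroup label (e.g. "A"/"B").
#' @param coding_mb size of the coding space in Mb.
#' @param qual_threshold,min_alt_reads the two load filters.
#' @param hypermutator_per_mb somatic rate (variants/Mb) above which the
#'   sample is flagged.
#' @param known_hypermutators character vector of sample ids flagged by
#'   identity (e.g. known mismatch-repair-deficient cases).
#' @return one-row data frame with `sample`, `group`, `germline_load`,
#'   `somatic_load`, `somatic_per_mb`, `hypermutator` plus the six
#'   spectrum proportion columns.
#' @export
mutation_load_summary <- function(variants, sample_id, group = NA_character_,
                                  coding_mb = 34, qual_threshold = 50,
                                  min_alt_reads = 4,
                                  hypermutator_per_mb = 10,
                                  known_hypermutators = character()) {
  g <- germline_load(variants, qual_threshold)
  s <- somatic_load(variants, min_alt_reads)
  rate <- load_per_mb(s, coding_mb)
  som <- variants[!is.na(variants$compartment) &
                    variants$compartment == "somatic", , drop = FALSE]
  som <- som[!is.na(som$alt_reads) & som$alt_reads >= min_alt_reads, , drop = FALSE]
  spec <- substitution_spectrum(som)
  out <- data.frame(sample = sample_id, group = group,
                    germline_load = g, somatic_load = s,
                    somatic_per_mb = rate,
                    hypermutator = rate > hypermutator_per_mb ||
                      sample_id %in% known_hypermutators,
                    stringsAsFactors = FALSE)
  prop <- as.list(spec$proportions)
  names(prop) <- sub(">", "_to_", substitution_classes())
  cbind(out, as.data.frame(prop))
}

#' Compare somatic mutation loads between two groups
#'
#' Fold change of mean somatic load (B over A), a two-sided two-sample
#' t-test on the per-sample loads, and a chi-square test on the pooled
#' 6-class substitution-spectrum counts.  Hypermutator-flagged samples are
#' removed first (default on), mirroring the exclusion of a known
#' mismatch-repair-deficient case from load comparisons.
#'
#' @param summaries_a,summaries_b per-sample summary data frames from
#'   [mutation_load_summary()] (rbind-ed rows).
#' @param exclude_hypermutators logical, default `TRUE`.
#' @param value column compared (default `"somatic_per_mb"`; fold change
#'   and t-test are invariant to the per-Mb scaling).
#' @return list with `fold_change`, `t_test_p`, `spectrum_chisq_p`,
#'   `n_a`, `n_b`, `n_excluded`, and the germline comparison
#'   `germline_t_test_p`.
#' @export
compare_groups <- function(summaries_a, summaries_b,
                           exclude_hypermutators = TRUE,
                           value = "somatic_per_mb") {
  n_excl <- 0
  if (exclude_hypermutators) {
    n_excl <- sum(summaries_a$hypermutator) + sum(summaries_b$hypermutator)
    summaries_a <- summaries_a[!summaries_a$hypermutator, , drop = FALSE]
    summaries_b <- summaries_b[!summaries_b$hypermutator, , drop = FALSE]
  }
  if (nrow(summaries_a) < 2 || nrow(summaries_b) < 2) {
    stop("need >= 2 samples per group after hypermutator exclusion")
  }
  a <- summaries_a[[value]]; b <- summaries_b[[value]]
  if (mean(a) == 0) stop("zero mean load in group A: fold change undefined")
  tt <- stats::t.test(b, a, var.equal = FALSE)
  gt <- stats::t.test(summaries_b$germline_load, summaries_a$germline_load,
                      var.equal = FALSE)
  spec_cols <- sub(">", "_to_", substitution_classes())
  sp_p <- NA_real_
  if (all(spec_cols %in% names(summaries_a))) {
    pool <- function(df) colSums(df[spec_cols] * df$somatic_load, na.rm = TRUE)
    tab <- rbind(pool(summaries_a), pool(summaries_b))
    if (all(colSums(tab) > 0) && all(rowSums(tab) > 0)) {
      sp_p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    }
  }
  list(fold_change = mean(b) / mean(a), t_test_p = tt$p.value,
       germline_t_test_p = gt$p.value, spectrum_chisq_p = sp_p,
       n_a = nrow(summaries_a), n_b = nrow(summaries_b),
       n_excluded = n_excl)
}
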