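mk_variants <- function(qual, alt_reads, depth = 100,
                        compartment = "somatic", ref = "A", alt = "G") {
  n <- max(length(qual), length(alt_reads))
  qual <- rep_len(qual, n); alt_reads <- rep_len(alt_reads, n)
  data.frame(chrom = "chr1", pos = seq_len(n), ref = rep_len(ref, n),
             alt = rep_len(alt, n), qual = qual, alt_reads = alt_reads,
             total_depth = depth,
             vaf = alt_reads / depth, compartment = compartment,
             coding = TRUE, stringsAsFactors = FALSE)
}

test_that("germline load applies the inclusive QUAL-50 filter and nothing else", {
  v <- mk_variants(qual = c(49, 50, 51, NA), alt_reads = 0,
                   compartment = "germline")
  expect_equal(germline_load(v), 2L)
  expect_equal(germline_load(v[0, ]), 0L)
  # invariant to alt-read support
  v2 <- v; v2$alt_reads <- 999
  expect_equal(germline_load(v2), germline_load(v))
  # idempotent: filtering a filtered set changes nothing
  kept <- v[!is.na(v$qual) & v$qual >= 50, ]
  expect_equal(germline_load(kept), germline_load(v))
})

test_that("somatic load requires >= 4 reads and ignores QUAL entirely", {
  v <- mk_variants(qual = c(1, 1, 99), alt_reads = c(3, 4, 2))
  expect_equal(somatic_load(v), 1L)
  # QUAL invariance
  v2 <- v; v2$qual <- 0
  expect_equal(somatic_load(v2), somatic_load(v))
  expect_equal(somatic_load(v[0, ]), 0L)
  # compartments do not leak into each other
  mixed <- rbind(mk_variants(60, 10, compartment = "germline"),
                 mk_variants(1, 10, compartment = "somatic"))
  expect_equal(germline_load(mixed), 1L)
  expect_equal(somatic_load(mixed), 1L)
})

test_that("the exome reporting filter applies both thresholds with db bypass", {
  v <- mk_variants(qual = 60, alt_reads = c(5, 4, 10, 2), depth = c(16, 4, 100, 20))
  # VAFs: 5/16 = 0.3125, 4/4 = 1, 10/100 = 0.1, 2/20 = 0.1
  kept <- wes_report_filter(v)
  expect_equal(kept$alt_reads, 5)          # boundary case kept
  v$database_match <- c(FALSE, FALSE, TRUE, FALSE)
  kept <- wes_report_filter(v)
  expect_equal(kept$alt_reads, c(5, 10))   # database match bypasses
  # exact boundary VAF 0.30 with 5 reads is kept
  b <- mk_variants(qual = 60, alt_reads = 6, depth = 20)
  expect_equal(nrow(wes_report_filter(b)), 1L)
  # zero depth -> undefined VAF -> excluded with warning
  z <- mk_variants(qual = 60, alt_reads = 0, depth = 0)
  z$vaf <- NA_real_
  expect_warning(out <- wes_report_filter(z), "undefined VAF")
  expect_equal(nrow(out), 0L)
})

test_that("variants per Mb is plain normalization", {
  expect_equal(load_per_mb(68, 34), 2)
  expect_equal(load_per_mb(0, 34), 0)
  expect_equal(load_per_mb(40, 34), 2 * load_per_mb(20, 34))
  expect_error(load_per_mb(10, 0), "region_mb")
})

test_that("substitution spectrum collapses onto the A/C reference strand", {
  v <- mk_variants(qual = 60, alt_reads = rep(10, 4))
  v$ref <- c("A", "T", "G", "C")
  v$alt <- c("G", "C", "T", "T")
  # A>G, T>C -> A>G, G>T -> C>A, C>T
  sp <- substitution_spectrum(v)
  expect_equal(unname(sp$counts[c("A>G", "C>A", "C>T")]), c(2, 1, 1))
  expect_equal(sum(sp$proportions), 1)

  # strand-complement invariance
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v2 <- v; v2$ref <- unname(comp[v$ref]); v2$alt <- unname(comp[v$alt])
  expect_equal(substitution_spectrum(v2)$counts, sp$counts)

  # non-SNVs are skipped and counted
  v$alt[1] <- "GT"
  sp <- substitution_spectrum(v)
  expect_equal(sp$n_skipped, 1L)

  # a configured uniform spectrum generates ~1/6 per class
  cfg <- sim_config(seed = 2, somatic_rate_a_per_mb = 300,
                    germline_rate_per_mb = 1,
                    spectrum = setNames(rep(1 / 6, 6), substitution_classes()))
  v <- simulate_variant_calls(cfg, "S", "A", seed = 8)
  sp <- substitution_spectrum(v[v$compartment == "somatic", ])
  expect_gt(sp$n_snv, 5000)
  expect_true(all(abs(sp$proportions - 1 / 6) < 0.02))
})

test_that("group comparison recovers a planted fold and excludes hypermutators", {
  cfg <- sim_config(seed = 9)
  sa <- do.call(rbind, lapply(1:20, function(i) mutation_load_summary(
    simulate_variant_calls(cfg, paste0("A", i), "A", 300 + i),
    paste0("A", i), "A")))
  sb <- do.call(rbind, lapply(1:20, function(i) mutation_load_summary(
    simulate_variant_calls(cfg, paste0("B", i), "B", 600 + i),
    paste0("B", i), "B")))
  cmp <- compare_groups(sa, sb)
  expect_gt(cmp$fold_change, 5)
  expect_lt(cmp$fold_change, 13)
  expect_lt(cmp$t_test_p, 0.01)
  expect_gt(cmp$germline_t_test_p, 0.001)  # germline rates identical

  # a planted hypermutator is flagged and excluded (default on)
  hyper <- mutation_load_summary(
    simulate_variant_calls(cfg, "A99", "A", 999, hypermutator = TRUE),
    "A99", "A")
  expect_true(hyper$hypermutator)
  cmp2 <- compare_groups(rbind(sa, hyper), sb)
  expect_equal(cmp2$n_excluded, 1L)
  expect_equal(cmp2$n_a, 20L)
  expect_equal(cmp2$fold_change, cmp$fold_change)
  # with exclusion off the fold collapses toward 1
  cmp3 <- compare_groups(rbind(sa, hyper), sb, exclude_hypermutators = FALSE)
  expect_lt(cmp3$fold_change, cmp$fold_change)

  expect_error(compare_groups(sa[1, ], sb), "2 samples")
})
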