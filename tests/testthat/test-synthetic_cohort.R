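test_that("every generator is byte-identical under the same seed", {
  cfg <- sim_config(seed = 4)
  expect_identical(simulate_chromothriptic_chromosome(cfg, "chr7", 10),
                   simulate_chromothriptic_chromosome(cfg, "chr7", 10))
  expect_identical(simulate_progressive_rearrangement(cfg, "chr7", 10),
                   simulate_progressive_rearrangement(cfg, "chr7", 10))
  expect_identical(simulate_eccdna(cfg, "chr4", 10),
                   simulate_eccdna(cfg, "chr4", 10))
  expect_identical(simulate_variant_calls(cfg, "S", "B", 10),
                   simulate_variant_calls(cfg, "S", "B", 10))
  expect_identical(simulate_clinical_table(cfg, 27, 10),
                   simulate_clinical_table(cfg, 27, 10))
  expect_identical(simulate_cohort(sim_config(seed = 4, n_samples_group_a = 2,
                                              n_samples_group_b = 2)),
                   simulate_cohort(sim_config(seed = 4, n_samples_group_a = 2,
                                              n_samples_group_b = 2)))
})

test_that("chromothriptic chromosomes carry the planted two-state oscillation", {
  cfg <- sim_config(seed = 1, fragment_retention_prob = 0.5)
  switch_fracs <- vapply(1:100, function(i) {
    ct <- simulate_chromothriptic_chromosome(cfg, "chr7", 500 + i)
    st <- infer_cn_states(ct$segments$seg_mean)
    # exactly two states: retained baseline and one-copy loss
    expect_true(all(st %in% c(1L, 2L)))
    # segments tile the window without overlap
    o <- order(ct$segments$start)
    expect_true(all(diff(ct$segments$start[o]) > 0))
    expect_equal(ct$segments$start[o][-1],
                 ct$segments$end[o][-length(o)])
    # every join breakend coincides with a segment boundary
    bounds <- c(ct$segments$start, ct$segments$end)
    expect_true(all(c(ct$joins$pos1, ct$joins$pos2) %in% bounds))
    mean(diff(st[o]) != 0)
  }, 0)
  # adjacent-state switch fraction has binomial expectation 0.5
  expect_gte(mean(switch_fracs), 0.4)
})

test_that("degenerate retention probabilities and unknown chromosomes error", {
  expect_error(simulate_chromothriptic_chromosome(
    sim_config(seed = 1, fragment_retention_prob = 0), "chr7", 1),
    "degenerate")
  expect_error(simulate_chromothriptic_chromosome(
    sim_config(seed = 1, fragment_retention_prob = 1), "chr7", 1),
    "degenerate")
  expect_error(simulate_chromothriptic_chromosome(sim_config(seed = 1),
                                                  "chr99", 1), "unknown")
})

test_that("a maximal cluster window removes the clustering signal", {
  L <- genome_model()$length[7]  # chr7
  cfg <- sim_config(seed = 1, cluster_window_bp = L)
  fired <- vapply(1:40, function(i) {
    ct <- simulate_chromothriptic_chromosome(cfg, "chr7", 800 + i)
    bp <- unique(c(ct$joins$pos1, ct$joins$pos2))
    criterion_breakpoint_clustering(bp, L)$satisfied
  }, TRUE)
  expect_lte(mean(fired), 0.15)
})

test_that("progressive rearrangements are multi-state, ordered negative controls", {
  cfg <- sim_config(seed = 1, n_events = 8)
  multi <- vapply(1:20, function(i) {
    pr <- simulate_progressive_rearrangement(cfg, "chr7", 900 + i)
    expect_equal(nrow(pr$joins), 8L)
    # joins pair each event's own boundaries: partner order tracks left order
    expect_true(all(pr$joins$pos2 > pr$joins$pos1))
    length(unique(pr$truth$cn_states))
  }, 0L)
  expect_true(all(multi >= 3))

  one <- simulate_progressive_rearrangement(sim_config(seed = 1, n_events = 1),
                                            "chr7", 5)
  expect_equal(nrow(one$joins), 1L)
})

test_that("planted eccDNA fragments pass the amplification threshold by construction", {
  cfg <- sim_config(seed = 1, amplified_log2 = 2.0, n_fragments = 3)
  e <- simulate_eccdna(cfg, "chr4", 77)
  amp <- select_amplified_segments(e$segments, 2.0)
  expect_equal(nrow(amp), 3L)
  expect_equal(sort(amp$start), sort(e$truth$fragments$start))
  # background segments stay neutral
  bg <- e$segments[!(e$segments$start %in% e$truth$fragments$start), ]
  expect_true(all(abs(bg$seg_mean) < 0.3))
})

test_that("variant generator plants the somatic fold and a shared germline rate", {
  cfg <- sim_config(seed = 1)
  expect_error(sim_config(seed = 1, somatic_fold_b = 0), "somatic_fold_b")
  va <- simulate_variant_calls(cfg, "a", "A", 50)
  vb <- simulate_variant_calls(cfg, "b", "B", 51)
  # somatic counts reflect the 9x fold (A ~ 10, B ~ 92 before filtering)
  expect_gt(sum(vb$compartment == "somatic"),
            3 * sum(va$compartment == "somatic"))
  # germline counts are drawn from the same rate
  ga <- sum(va$compartment == "germline"); gb <- sum(vb$compartment == "germline")
  expect_lt(abs(ga - gb) / ga, 0.2)
  # hypermutator flag multiplies the somatic rate
  vh <- simulate_variant_calls(cfg, "h", "A", 52, hypermutator = TRUE)
  expect_gt(sum(vh$compartment == "somatic"),
            10 * sum(va$compartment == "somatic"))
  # read support is bounded by depth; VAF consistent
  expect_true(all(va$alt_reads <= va$total_depth))
  expect_equal(va$vaf, va$alt_reads / va$total_depth)
})

test_that("clinical tables have the Table-1 shape and configured medians", {
  cfg <- sim_config(seed = 1)
  cl <- simulate_clinical_table(cfg, 27, 99)
  expect_equal(nrow(cl), 27L)
  expect_true(all(cl$age >= 0, na.rm = TRUE))
  expect_true(all(cl$latency_y >= 0, na.rm = TRUE))
  expect_true(all(is.na(cl$survival_months[cl$status == "unknown"])))
  # latency median approaches the configured 8 years in a large draw
  big <- simulate_clinical_table(cfg, 4000, 100)
  expect_lt(abs(median(big$latency_y, na.rm = TRUE) - cfg$latency_median), 0.5)
  expect_lt(abs(median(big$age, na.rm = TRUE) - cfg$age_median), 1)
})

test_that("a simulated cohort is complete and closed over its ground truth", {
  cfg <- sim_config(seed = 8, n_samples_group_a = 3, n_samples_group_b = 3)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$samples), 6L)
  expect_setequal(names(co$variants), co$samples$sample)
  expect_equal(nrow(co$clinical), 6L)
  # every sample's planted structural event is scorable from the files alone
  for (s in co$samples$sample) {
    tr <- co$truth[[s]]$structural
    segs <- co$segments[co$segments$sample == s &
                          co$segments$chrom == tr$chrom, ]
    expect_gt(nrow(segs), 0)
    jn <- co$joins[co$joins$sample == s & co$joins$chrom1 == tr$chrom, ]
    if (tr$kind == "chromothripsis" && length(tr$derivative_order) >= 2) {
      expect_equal(nrow(jn), length(tr$derivative_order) - 1)
    }
  }
  # round-trips through the on-disk formats
  outdir <- withr::local_tempdir()
  write_cohort(co, outdir)
  segs <- read_seg(file.path(outdir, "cohort.seg"))
  expect_equal(nrow(segs), nrow(co$segments))
  joins <- read_bedpe(file.path(outdir, "cohort.bedpe"))
  expect_equal(nrow(joins), nrow(co$joins))
  expect_true(file.exists(file.path(outdir, "ground_truth.txt")))
})
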