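gm <- toy_genome()

test_that("segment direction and extent follow the inclusive thresholds", {
  # 2 Mb gain on the 60 Mb q arm: focal
  call <- classify_segment(toy_segment(50e6, 52e6, 0.5), gm)
  expect_equal(call$direction, "gain")
  expect_equal(call$extent, "focal")
  expect_equal(call$arm, "q")
  expect_equal(call$arm_fraction, 2 / 60)

  # neutral segment: extent not applicable
  call <- classify_segment(toy_segment(50e6, 52e6, 0.0), gm)
  expect_equal(call$direction, "neutral")
  expect_equal(call$extent, "not_applicable")

  # loss covering 80% of the q arm: broad
  call <- classify_segment(toy_segment(42e6, 90e6, -0.3), gm)
  expect_equal(call$direction, "loss")
  expect_equal(call$extent, "broad")

  # inclusive boundaries, both presets
  expect_equal(classify_segment(toy_segment(1, 100, 0.2), gm)$direction, "gain")
  expect_equal(classify_segment(toy_segment(1, 100, -0.2), gm)$direction, "loss")
  expect_equal(classify_segment(toy_segment(1, 100, 0.199), gm)$direction, "neutral")
  wgs <- cn_thresholds("wgs")
  expect_equal(classify_segment(toy_segment(1, 100, 0.22), gm, wgs)$direction,
               "neutral")
  expect_equal(classify_segment(toy_segment(1, 100, 0.25), gm, wgs)$direction,
               "gain")
})

test_that("the 3mb focal mode uses absolute length", {
  th <- cn_thresholds(focal_mode = "3mb")
  expect_equal(classify_segment(toy_segment(50e6, 52.9e6, 0.5), gm, th)$extent,
               "focal")
  expect_equal(classify_segment(toy_segment(50e6, 54e6, 0.5), gm, th)$extent,
               "broad")
  # same segment is focal under arm25 (4 Mb of a 60 Mb arm)
  expect_equal(classify_segment(toy_segment(50e6, 54e6, 0.5), gm)$extent,
               "focal")
})

test_that("centromere-spanning segments split per arm with consistent direction", {
  calls <- classify_segment(toy_segment(30e6, 70e6, -0.4), gm)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$arm, c("p", "q"))
  expect_equal(calls$end[1], 40e6)
  expect_equal(calls$start[2], 40e6)
  expect_equal(unique(calls$direction), "loss")
})

test_that("out-of-bounds and unknown-chromosome segments are rejected", {
  expect_error(classify_segment(toy_segment(90e6, 110e6, 0.1), gm), "bounds")
  expect_error(classify_segment(toy_segment(1, 10, 0.1, chrom = "chr9"), gm),
               "unknown")
})

test_that("classification properties: totality, monotonicity, split-invariance", {
  set.seed(21)
  for (rep in 1:20) {
    seg <- toy_segment(start <- runif(1, 0, 50e6),
                       start + runif(1, 1e5, 30e6),
                       rnorm(1, 0, 0.5))
    call <- classify_segment(seg, gm)
    expect_true(all(call$direction %in% c("gain", "loss", "neutral")))
    expect_true(all(call$extent %in% c("focal", "broad", "not_applicable")))

    # raising the gain threshold never converts neutral -> gain
    strict <- cn_thresholds(gain = 0.5)
    c2 <- classify_segment(seg, gm, strict)
    if (call$direction[1] == "neutral") expect_false(c2$direction[1] == "gain")

    # splitting at an interior point preserves direction
    mid <- floor((seg$start + seg$end) / 2)
    halves <- rbind(toy_segment(seg$start, mid, seg$seg_mean),
                    toy_segment(mid, seg$end, seg$seg_mean))
    ch <- classify_segment(halves, gm)
    expect_equal(unique(ch$direction), unique(call$direction))
  }
})

test_that("arm frequencies reproduce n/N percentages and match a brute-force scan", {
  # 25 samples, 10 with a broad p loss on chr1 -> 40.0%
  broad_loss <- do.call(rbind, lapply(1:10, function(i)
    toy_segment(0, 30e6, -0.5, sample = sprintf("S%02d", i))))
  quiet <- do.call(rbind, lapply(11:25, function(i)
    toy_segment(0, 30e6, 0.0, sample = sprintf("S%02d", i))))
  calls <- classify_segment(rbind(broad_loss, quiet), gm)
  freq <- arm_alteration_frequencies(calls)
  row <- freq[freq$chrom == "chr1" & freq$arm == "p" & freq$direction == "loss", ]
  expect_equal(row$n_altered, 10)
  expect_equal(row$n_samples, 25)
  expect_equal(row$frequency, 40.0)

  # permutation invariance
  shuffled <- calls[sample(nrow(calls)), ]
  expect_equal(arm_alteration_frequencies(shuffled)[
    order(freq$chrom, freq$arm, freq$direction), ], freq)

  # no non-neutral calls -> all frequencies 0
  freq0 <- arm_alteration_frequencies(classify_segment(quiet, gm))
  expect_true(all(freq0$frequency == 0))

  # brute-force oracle on a random small cohort
  set.seed(31)
  segs <- do.call(rbind, lapply(1:8, function(i) {
    k <- sample(3:6, 1)
    st <- sort(runif(k, 0, 99e6))
    toy_segment(st, st + runif(k, 5e5, 1e6), rnorm(k, 0, 0.4),
                sample = paste0("R", i))
  }))
  calls <- classify_segment(segs, gm)
  freq <- arm_alteration_frequencies(calls)
  for (r in seq_len(nrow(freq))) {
    hits <- 0
    for (s in unique(calls$sample)) {
      sub <- calls[calls$sample == s, ]
      if (any(sub$chrom == freq$chrom[r] & sub$arm == freq$arm[r] &
                sub$direction == freq$direction[r] & sub$extent == "broad")) {
        hits <- hits + 1
      }
    }
    expect_equal(freq$n_altered[r], hits)
  }
})

test_that("gene calls use the maximal-|seg_mean| overlapping segment", {
  genes <- data.frame(symbol = "PDGFRA", chrom = "chr1",
                      start = 10e6, end = 10.1e6, stringsAsFactors = FALSE)
  # fully inside an amplified segment
  g <- call_gene_cnv(toy_segment(9e6, 11e6, 2.5), genes)
  expect_equal(g$call, "amplification")
  # only neutral coverage
  g <- call_gene_cnv(toy_segment(9e6, 11e6, 0.0), genes)
  expect_equal(g$call, "neutral")
  expect_false(g$no_coverage)
  # spanning two segments: 0.1 vs -0.4 -> loss wins on |seg_mean|
  segs <- rbind(toy_segment(9e6, 10.05e6, 0.1), toy_segment(10.05e6, 11e6, -0.4))
  g <- call_gene_cnv(segs, genes)
  expect_equal(g$call, "loss")
  expect_equal(g$seg_mean, -0.4)
  # no overlap at all -> neutral + flag
  g <- call_gene_cnv(toy_segment(50e6, 60e6, 1.0), genes)
  expect_equal(g$call, "neutral")
  expect_true(g$no_coverage)
})

test_that("per-sample CNV counts equal a brute-force filter", {
  expect_equal(nrow(cnv_count_per_sample(
    classify_segment(toy_segment(1, 2, 0.5)[0, ], gm))), 0L)

  segs <- rbind(toy_segment(c(1e6, 5e6, 9e6), c(2e6, 6e6, 10e6), 0.5),
                toy_segment(c(50e6, 60e6), c(51e6, 61e6), -0.5))
  counts <- cnv_count_per_sample(classify_segment(segs, gm))
  expect_equal(counts$n_gain, 3)
  expect_equal(counts$n_loss, 2)
  expect_equal(counts$n_total, 5)

  set.seed(41)
  segs <- toy_segment(st <- sort(runif(30, 0, 90e6)), st + 1e5,
                      rnorm(30, 0, 0.3))
  calls <- classify_segment(segs, gm)
  counts <- cnv_count_per_sample(calls)
  expect_equal(counts$n_total, sum(calls$direction != "neutral"))
})

test_that("the bundled gene fixture is valid and on modeled chromosomes", {
  genes <- gene_loci()
  expect_setequal(genes$symbol,
                  c("PDGFRA", "CDK4", "CDKN2A", "BCOR", "NF1", "TP53", "MET"))
  gm19 <- genome_model()
  expect_true(all(genes$chrom %in% gm19$chrom))
  expect_true(all(genes$end <= gm19$length[match(genes$chrom, gm19$chrom)]))
})
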