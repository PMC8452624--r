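test_that("CN state inference rounds 2 * 2^seg_mean", {
  expect_equal(infer_cn_states(c(0, -1, 0.585)), c(2L, 1L, 3L))
  expect_equal(infer_cn_states(c(1, 2)), c(4L, 8L))
  expect_error(infer_cn_states(numeric()), "no segments")
})

test_that("C1 detects two-state oscillation and rejects monotone profiles", {
  perfect <- rep(c(2L, 1L), 5)
  r <- criterion_oscillation(perfect)
  expect_true(r$satisfied)
  expect_equal(r$statistic, 9)

  r <- criterion_oscillation(1:10)
  expect_false(r$satisfied)

  r <- criterion_oscillation(rep(c(2L, 1L), 4))  # 8 segments < min 10
  expect_false(r$evaluable)
  expect_false(r$satisfied)

  # two dominant states must cover >= 80%
  diluted <- c(rep(c(2L, 1L), 4), 3L, 4L, 5L, 6L)
  expect_false(criterion_oscillation(diluted)$satisfied)
})

test_that("C2 is one-sided toward clustering", {
  set.seed(5)
  # tight cluster on a long chromosome: strongly significant
  clustered <- sort(runif(100, 0, 1e6))
  r <- criterion_breakpoint_clustering(clustered, 100e6)
  expect_true(r$satisfied)
  expect_lt(r$p_value, 0.01)

  # exactly regular spacing is MORE regular than uniform, not clustered
  regular <- seq(1e6, 99e6, length.out = 100)
  r <- criterion_breakpoint_clustering(regular, 100e6)
  expect_false(r$satisfied)
  expect_equal(r$p_value, 1)

  # below the minimum count: not evaluable
  expect_false(criterion_breakpoint_clustering(c(1, 2, 3, 4, 5) * 1e6,
                                               100e6)$evaluable)

  # duplicates are collapsed with a warning
  expect_warning(
    criterion_breakpoint_clustering(c(clustered, clustered[1]), 100e6),
    "collapsed")
})

test_that("C2 fires at roughly alpha when breakpoints are genuinely uniform", {
  set.seed(11)
  fires <- vapply(1:60, function(i) {
    criterion_breakpoint_clustering(sort(runif(30, 0, 1e8)), 1e8)$satisfied
  }, TRUE)
  expect_lte(mean(fires), 0.15)
})

test_that("C3 matches hand-computed chi-square values and the exact oracle", {
  r <- criterion_join_randomness(c(10, 10, 10, 10))
  expect_equal(r$p_value, 1)
  expect_true(r$satisfied)

  r <- criterion_join_randomness(c(40, 0, 0, 0))
  expect_equal(r$statistic, 120)  # (40-10)^2/10 + 3 * 10
  expect_lt(r$p_value, 1e-3)
  expect_false(r$satisfied)

  r <- criterion_join_randomness(c(12, 8, 11, 9))
  expect_equal(r$statistic, 1.0)
  expect_equal(r$p_value, pchisq(1, 3, lower.tail = FALSE))
  expect_true(r$satisfied)

  # exact multinomial branch (4-7 joins) against independent enumeration
  for (counts in list(c(6, 0, 0, 0), c(2, 2, 2, 1), c(4, 1, 1, 1))) {
    expect_equal(criterion_join_randomness(counts)$p_value,
                 multinom_oracle(counts), tolerance = 1e-12)
  }

  expect_false(criterion_join_randomness(c(2, 1, 0, 0))$evaluable)
})

test_that("C4 rejects ordered joins and accepts random religation", {
  # partner a monotone function of the left breakend: perfectly ordered
  ordered <- data.frame(pos1 = (1:10) * 1e6, pos2 = (1:10) * 1e6 + 5e5)
  r <- criterion_order_randomness(ordered)
  expect_equal(r$statistic, 1)
  expect_false(r$satisfied)

  # random re-pairings of the same breakends: satisfied in the bulk of seeds
  set.seed(13)
  ok <- vapply(1:40, function(i) {
    ends <- runif(28, 0, 1e8)
    j <- data.frame(pos1 = ends[1:14], pos2 = ends[15:28])
    criterion_order_randomness(j)$satisfied
  }, TRUE)
  expect_gte(mean(ok), 0.9)

  expect_false(criterion_order_randomness(
    data.frame(pos1 = c(1, 2, 3), pos2 = c(4, 5, 6)))$evaluable)
})

test_that("the call combines criteria with the >= 2-of-4 rule", {
  cfg <- sim_config(seed = 3)
  ct <- simulate_chromothriptic_chromosome(cfg, "chr7", seed = 99)
  ev <- call_chromothripsis(ct$segments, ct$joins)
  expect_s3_class(ev, "chromothripsis_eval")
  expect_equal(ev$n_satisfied,
               sum(vapply(ev$criteria, `[[`, TRUE, "satisfied")))
  expect_equal(ev$call, ev$n_satisfied >= 2)
  expect_equal(ev$borderline, ev$n_satisfied == 2)
  # satisfied implies evaluable
  for (cr in ev$criteria) {
    if (cr$satisfied) expect_true(cr$evaluable)
  }

  # no segments and no joins: everything non-evaluable, no call
  ev0 <- call_chromothripsis(ct$segments[0, ], ct$joins[0, ], chrom = "chr7")
  expect_false(ev0$call)
  expect_true(all(!vapply(ev0$criteria, `[[`, TRUE, "evaluable")))
})

test_that("criterion results are deterministic given input and params", {
  cfg <- sim_config(seed = 3)
  ct <- simulate_chromothriptic_chromosome(cfg, "chr7", seed = 17)
  e1 <- call_chromothripsis(ct$segments, ct$joins)
  e2 <- call_chromothripsis(ct$segments, ct$joins)
  expect_identical(e1, e2)
})

test_that("cohort frequency comparison is a one-sided Fisher test", {
  # 8/12 vs 6/20 against the enumeration oracle
  r <- compare_cohort_frequency(rep(c(TRUE, FALSE), c(8, 4)),
                                rep(c(TRUE, FALSE), c(6, 14)))
  tab <- matrix(c(8, 4, 6, 14), 2, byrow = TRUE)
  expect_equal(r$p_value, fisher_oracle(tab, "greater"))

  # identical cohorts: observed at expectation, p = 1
  r <- compare_cohort_frequency(rep(c(TRUE, FALSE), 6), rep(c(TRUE, FALSE), 6))
  expect_gte(r$p_value, 0.5)

  # single most extreme table
  r <- compare_cohort_frequency(rep(TRUE, 12), rep(FALSE, 12))
  expect_equal(r$p_value, 1 / choose(24, 12), tolerance = 1e-10)

  expect_error(compare_cohort_frequency(logical(), c(TRUE)), "empty")
})
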