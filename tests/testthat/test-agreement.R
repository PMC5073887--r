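test_that("expected agreement, variance and tail bound match the formulas", {
  st <- agreement_stats(c(2, 2, 4), 3)
  expect_equal(st$mu, 1.25)
  expect_equal(st$sigma2, 0.6875)
  expect_equal(st$lambda, 1.75)
  expect_equal(st$p_bound, 0.6875 / 3.75)
  expect_equal(st$p_bound, 0.18333, tolerance = 1e-4)
  expect_false(st$below_expectation)

  # zero deviation: the bound is vacuous
  st0 <- agreement_stats(c(2, 2), 1)
  expect_equal(st0$lambda, 0)
  expect_equal(st0$p_bound, 1)

  # below expectation: same bound magnitude, flagged
  stn <- agreement_stats(c(2, 2, 4), 0)
  expect_true(stn$below_expectation)
  expect_equal(stn$p_bound, 0.6875 / (0.6875 + 1.25^2))

  # degenerate certain trials
  expect_equal(agreement_stats(c(1, 1), 2)$p_bound, 1)
})

test_that("the bound decreases monotonically in |lambda| for fixed sigma2", {
  n_i <- rep(2, 10)
  ps <- vapply(5:10, function(a) agreement_stats(n_i, a)$p_bound, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("summarize_agreement computes the report row from trials", {
  cx <- manual_complexity(c("L1", "L2", "L3"), c(2L, 2L, 4L))
  comparisons <- tibble::tibble(
    read_id = c("r1", "r2", "r3", "r4"),
    locus_id = c("L1", "L2", "L3", "L3"),
    allele_index = 1L,
    mapped_correctly = c(TRUE, TRUE, TRUE, FALSE),
    matched = c(TRUE, TRUE, TRUE, FALSE),
    flagged = FALSE,
    calls = replicate(4, tibble::tibble(), simplify = FALSE))
  s <- summarize_agreement(comparisons, cx, label = "toy")
  expect_equal(s$N, 3L)             # the unmapped read is not a trial
  expect_equal(s$agreeing, 3L)
  expect_equal(s$mu, 1.25)
  expect_equal(s$sigma2, 0.6875)
  expect_equal(s$correct_mapped_pct, 75)
  expect_equal(s$actual_pct, 100)
  expect_equal(s$expected_pct, 100 * 1.25 / 3)
  g <- glance(s)
  expect_equal(g$p_bound, s$p_bound)

  # expected percentage for trials {2, 4}
  cx2 <- manual_complexity(c("L1", "L2"), c(2L, 4L))
  cmp2 <- comparisons[c(1, 3), ]
  cmp2$locus_id <- c("L1", "L2")
  s2 <- summarize_agreement(cmp2, cx2, label = "toy2")
  expect_equal(s2$expected_pct, 37.5)
})

test_that("only multiple-optimal loci enter the agreement trials", {
  cx <- manual_complexity(c("L1", "L2"), c(1L, 3L))
  comparisons <- tibble::tibble(
    read_id = c("r1", "r2"), locus_id = c("L1", "L2"), allele_index = 1L,
    mapped_correctly = TRUE, matched = TRUE, flagged = FALSE,
    calls = replicate(2, tibble::tibble(), simplify = FALSE))
  s <- summarize_agreement(comparisons, cx, label = "toy")
  expect_equal(s$N, 1L)
  expect_equal(s$correct_mapped, 2L)   # mapping stats still cover all reads
})

test_that("policy simulation agrees/disagrees with the recorded convention", {
  gs <- fixture_synth_leftmost()
  reads <- make_reads(gs$reference, gs$profile)
  prof <- profile_complexity(gs$reference, gs$profile)

  left <- simulate_policy_alignments(reads, gs$reference, "leftmost")
  sL <- summarize_agreement(compare_calls(left, reads, gs$reference), prof,
                            label = "leftmost")
  expect_gte(sL$actual_pct, 95)
  expect_lt(sL$p_bound, 0.01)
  expect_false(sL$below_expectation)

  right <- simulate_policy_alignments(reads, gs$reference, "rightmost")
  sR <- summarize_agreement(compare_calls(right, reads, gs$reference), prof,
                            label = "rightmost")
  expect_lte(sR$actual_pct, 10)
  expect_lt(sR$p_bound, 0.01)
  expect_true(sR$below_expectation)

  # an equivalent-but-shifted gap is correctly mapped yet disagreeing
  cmpR <- compare_calls(right, reads, gs$reference)
  amb <- gs$truth$locus_id[gs$truth$ambiguous]
  shifted <- dplyr::filter(cmpR, .data$locus_id %in% amb)
  expect_true(all(shifted$mapped_correctly))
  expect_true(all(!shifted$matched))
})

test_that("the uniform policy is seed-reproducible and null-consistent", {
  gu <- fixture_synth_uniform()
  reads <- make_reads(gu$reference, gu$profile)
  prof <- profile_complexity(gu$reference, gu$profile)

  a1 <- simulate_policy_alignments(reads, gu$reference, "uniform", seed = 5)
  a2 <- simulate_policy_alignments(reads, gu$reference, "uniform", seed = 5)
  expect_equal(a1, a2, ignore_attr = TRUE)

  s <- summarize_agreement(compare_calls(a1, reads, gu$reference), prof,
                           label = "uniform")
  # agreement count within 3 binomial standard deviations of expectation
  expect_lte(abs(s$agreeing - s$mu), 3 * sqrt(s$sigma2))
})

test_that("unambiguous loci produce identical alignments under all policies", {
  gs <- fixture_synth_leftmost()
  unamb <- gs$truth$locus_id[!gs$truth$ambiguous]
  profile1 <- dplyr::filter(gs$profile, .data$locus_id %in% unamb[1:3])
  reads <- make_reads(gs$reference, profile1)
  outs <- lapply(c("leftmost", "rightmost", "uniform"), function(p) {
    simulate_policy_alignments(reads, gs$reference, p, seed = 9)
  })
  expect_equal(outs[[1]], outs[[2]], ignore_attr = TRUE)
  expect_equal(outs[[1]], outs[[3]], ignore_attr = TRUE)
})

test_that("externally supplied SAM files flow through the same comparison", {
  gs <- fixture_synth_leftmost()
  amb <- gs$truth$locus_id[gs$truth$ambiguous]
  profile1 <- dplyr::filter(gs$profile, .data$locus_id %in% amb[1:5])
  reads <- make_reads(gs$reference, profile1)
  aln <- simulate_policy_alignments(reads, gs$reference, "leftmost")
  sam <- withr::local_tempfile(fileext = ".sam")
  write_alignments_sam(aln, gs$reference, sam)
  back <- read_alignments_sam(sam)
  cmp1 <- compare_calls(aln, reads, gs$reference)
  cmp2 <- compare_calls(back, reads, gs$reference)
  expect_equal(cmp1$matched, cmp2$matched)
  expect_equal(cmp1$mapped_correctly, cmp2$mapped_correctly)
})
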