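test_that("equal-penalty fill matches hand-computed scores", {
  s <- scoring_scheme(match = 1, mismatch = -4, gap_open = 0,
                      gap_extend = -1)
  dp <- fill_simple("A", "A", s)
  expect_equal(dp$M[2, 2], 1)
  expect_error(fill_simple("", "A", s), "non-empty")
  # AA vs AAA: 2 matches + 1 gapped base (brute-force oracle agrees)
  dp2 <- fill_simple("AA", "AAA", s)
  expect_equal(dp2$score, 1)
  expect_equal(oracle_enumerate("AA", "AAA", s, "global")$score, 1)
})

test_that("affine fill matches hand-computed scores and degenerates at rho=0", {
  s <- scoring_scheme(match = 1, mismatch = -4, gap_open = -2,
                      gap_extend = -1)
  expect_equal(fill_affine("A", "A", s)$M[2, 2], 1)
  # 2 matches minus one gap of length 1: 2 - (2 + 1)
  expect_equal(fill_affine("AA", "AAA", s)$score, -1)
  expect_equal(oracle_enumerate("AA", "AAA", s, "global")$score, -1)

  s0 <- scoring_scheme(gap_open = 0)
  withr::with_seed(11, {
    for (k in 1:20) {
      x <- random_dna(sample(1:6, 1))
      y <- random_dna(sample(1:6, 1))
      expect_equal(dp_affine_score <- fill_affine(x, y, s0)$score,
                   fill_simple(x, y, s0)$score)
    }
  })
})

test_that("enumeration returns every co-optimal alignment and no more", {
  s0 <- scoring_scheme(gap_open = 0)
  e <- enumerate_optimal("AA", "AAA", s0, mode = "global")
  expect_equal(nrow(e), 3L)   # the deletion can sit at any of 3 offsets
  expect_setequal(e$cigar, c("1D2M", "1M1D1M", "2M1D"))

  x <- strrep("ACGTGTCATG", 1)
  e1 <- enumerate_optimal(x, x, scoring_scheme(), mode = "global")
  expect_equal(nrow(e1), 1L)
  expect_true(all(e1$columns[[1]] == "M"))

  fx <- fixture_acga()
  e2 <- enumerate_optimal(fx$read, fx$window, scoring_scheme(),
                          mode = "fitting")
  expect_equal(nrow(e2), 2L)  # CGA after the anchor A, or ACG before it
  expect_setequal(e2$cigar, c("25M3I26M", "26M3I25M"))
})

test_that("degenerate affine trace (rho = 0) returns the simple model's set", {
  s0 <- scoring_scheme(gap_open = 0)
  withr::with_seed(4, {
    for (k in 1:10) {
      x <- random_dna(sample(2:6, 1), c("A", "C"))
      y <- random_dna(sample(2:6, 1), c("A", "C"))
      for (mode in c("global", "fitting")) {
        e <- enumerate_optimal(x, y, s0, mode = mode, cap = 100000L)
        o <- oracle_enumerate(x, y, s0, mode)
        expect_setequal(enumerate_keys(e), o$keys)
      }
    }
  })
})

test_that("enumerated sets equal the brute-force oracle across schemes", {
  schemes <- list(scoring_scheme(),                      # affine, bwa-like
                  scoring_scheme(1, -4, 0, -1),          # equal-penalty
                  scoring_scheme(2, -1, -3, -2))         # mild mismatch
  withr::with_seed(21, {
    for (k in 1:8) {
      x <- random_dna(sample(1:6, 1), c("A", "C"))
      y <- random_dna(sample(1:6, 1), c("A", "C"))
      for (s in schemes) {
        for (mode in c("global", "fitting")) {
          e <- enumerate_optimal(x, y, s, mode = mode, cap = 100000L)
          o <- oracle_enumerate(x, y, s, mode)
          expect_setequal(enumerate_keys(e), o$keys)
          expect_equal(attr(e, "score"), o$score)
        }
      }
    }
  })
})

test_that("every enumerated alignment rescored column-wise hits the optimum", {
  fx <- fixture_acga()
  for (s in list(scoring_scheme(), scoring_scheme(gap_open = 0))) {
    e <- enumerate_optimal(fx$read, fx$window, s, mode = "fitting")
    for (k in seq_len(nrow(e))) {
      expect_equal(
        rescore_alignment(e$columns[[k]], fx$read, fx$window,
                          e$window_offset[[k]], s),
        attr(e, "score"))
    }
  }
})

test_that("affine optima are a subset of equal-scoring splits on repeat fixtures", {
  # the equal-penalty model also allows split gaps, so its co-optimal count
  # can only grow on tandem-repeat contexts
  pairs <- list(c("TCACAG", "TCACACAG"),      # (CA)3, one unit deleted
                c("AAAA", "AAAAAA"),          # homopolymer
                c("TCAGG", "TCACACAGG"))      # two units deleted
  for (p in pairs) {
    n_aff <- nrow(enumerate_optimal(p[1], p[2], scoring_scheme(),
                                    mode = "global", cap = 100000L))
    n_sim <- nrow(enumerate_optimal(p[1], p[2],
                                    scoring_scheme(gap_open = 0),
                                    mode = "global", cap = 100000L))
    expect_gte(n_sim, n_aff)
    expect_gte(n_aff, 1L)
  }
})

test_that("exceeding the alignment cap raises an ambiguity overflow", {
  expect_error(
    enumerate_optimal("AAAA", "AAAAAAAA", scoring_scheme(gap_open = 0),
                      mode = "global", cap = 3L),
    class = "indelbias_overflow")
  err <- tryCatch(
    enumerate_optimal("AAAA", "AAAAAAAA", scoring_scheme(gap_open = 0),
                      mode = "global", cap = 3L),
    indelbias_overflow = function(e) e)
  expect_equal(err$cap, 3L)
})

test_that("two-row text rendering is consistent with the columns", {
  fx <- fixture_acga()
  e <- enumerate_optimal(fx$read, fx$window, scoring_scheme(),
                         mode = "fitting")
  rows <- format_alignment(e$columns[[1]], fx$read, fx$window,
                           e$window_offset[[1]])
  expect_equal(nchar(rows[1]), nchar(rows[2]))
  expect_equal(gsub("-", "", rows[2]), fx$read)
  expect_equal(sum(strsplit(rows[1], "")[[1]] == "-"), 3L)  # 3 inserted bases
})
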