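test_that("the worked two-deletion alignment yields two anchored calls", {
  p <- 101L
  calls <- alignment_to_calls(c("M", "D", "D", "M", "M", "D", "D", "M", "M"),
                              x = "TCAGG", y = "TCACACAGG",
                              window_pos = p, chrom = "chr1")
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$pos, c(p, p + 4L))
  expect_equal(calls$ref, c("TCA", "ACA"))
  expect_equal(calls$alt, c("T", "A"))
  expect_equal(calls$type, c("del", "del"))
})

test_that("a single contiguous deletion run yields one call", {
  p <- 101L
  calls <- alignment_to_calls(c("M", "M", "M", "D", "D", "D", "D", "M", "M"),
                              x = "TCAGG", y = "TCACACAGG",
                              window_pos = p, chrom = "chr1")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, p + 2L)
  expect_equal(calls$ref, "ACACA")
  expect_equal(calls$alt, "A")
})

test_that("all-match alignments yield no calls; mismatches become SNVs", {
  expect_equal(nrow(alignment_to_calls(rep("M", 5), x = "ACGTA",
                                       y = "ACGTA")), 0L)
  calls <- alignment_to_calls(c("M", "X", "M", "I", "I", "M"),
                              x = "ATGCAG", y = "ACGG", window_pos = 10L)
  expect_equal(calls$type, c("snv", "ins"))
  expect_equal(calls$pos, c(11L, 12L))
  expect_equal(calls$ref, c("C", "G"))
  expect_equal(calls$alt, c("T", "GCA"))
})

test_that("a gap run with no anchor base is an error", {
  expect_error(
    alignment_to_calls(c("D", "M", "M"), x = "CA", y = "ACA",
                       window_pos = 1L),
    "no anchor")
  # with a skipped window prefix the preceding base anchors the run
  al <- tibble::tibble(alignment_id = 1L, window_offset = 1L,
                       columns = list(c("D", "M", "M")))
  calls <- alignment_to_calls(al, x = "CA", y = "TACA", window_pos = 1L)
  expect_equal(calls$ref, "TA")
  expect_equal(calls$alt, "T")
  expect_equal(calls$pos, 1L)
})

test_that("calls applied as edits to the window reconstruct the read", {
  withr::with_seed(31, {
    for (k in 1:12) {
      x <- random_dna(sample(3:8, 1))
      y <- random_dna(sample(3:8, 1))
      e <- enumerate_optimal(x, y, scoring_scheme(), mode = "global",
                             cap = 100000L)
      for (q in seq_len(min(nrow(e), 5L))) {
        # alignments opening with a gap at window position 1 cannot be
        # anchored and raise instead; they are exercised elsewhere
        calls <- tryCatch(
          alignment_to_calls(e[q, ], x = x, y = y, window_pos = 1L),
          error = function(cond) NULL)
        if (is.null(calls)) next
        expect_equal(apply_calls_to_seq(calls, y, 1L), x)
      }
    }
  })
})

test_that("SAM records convert to calls with soft clips and strand flags", {
  ref <- reference_from_seq(chr1 = "GGGGTCACACAGGTTTTTTT")
  # read TCAGG aligned at 5 with the two-deletion column layout
  aln <- tibble::tibble(read_id = "r1", flag = 0L, chrom = "chr1", pos = 5L,
                        end = 13L, mapq = 60L, cigar = "1M2D2M2D2M",
                        seq = "TCAGG")
  calls <- sam_to_calls(aln, ref)
  expect_equal(calls$pos, c(5L, 9L))
  expect_equal(calls$ref, c("TCA", "ACA"))
  expect_equal(calls$alt, c("T", "A"))

  # soft-clipped bases consume read but produce no calls
  aln2 <- tibble::tibble(read_id = "r2", flag = 16L, chrom = "chr1",
                         pos = 5L, end = 13L, mapq = 60L,
                         cigar = "2S1M2D2M2D2M1S", seq = "AATCAGGA")
  expect_equal(sam_to_calls(aln2, ref), calls)

  # leading deletion anchored on the base before POS
  aln3 <- tibble::tibble(read_id = "r3", flag = 0L, chrom = "chr1", pos = 6L,
                         end = 13L, mapq = 60L, cigar = "2D6M",
                         seq = "CACAGG")
  c3 <- sam_to_calls(aln3, ref)
  expect_equal(c3$pos, 5L)
  expect_equal(c3$ref, "TCA")
  expect_equal(c3$alt, "T")
})

test_that("left alignment shifts equivalent representations to one form", {
  # (CA)3 context: GG T CACACA GG, deletion of one CA
  seq <- "GGTCACACAGG"
  reps <- list(list(pos = 3L, ref = "TCA", alt = "T"),
               list(pos = 5L, ref = "ACA", alt = "A"),
               list(pos = 7L, ref = "ACA", alt = "A"),
               list(pos = 4L, ref = "CAC", alt = "C"),
               list(pos = 6L, ref = "CAC", alt = "C"))
  norm <- lapply(reps, function(r) left_align_call(r$pos, r$ref, r$alt, seq))
  for (n in norm) {
    expect_equal(n$pos, 3L)
    expect_equal(n$ref, "TCA")
    expect_equal(n$alt, "T")
  }
})
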