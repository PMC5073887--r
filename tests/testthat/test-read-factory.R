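test_that("a biallelic locus yields exactly 10 reads of length 2k + |alt|", {
  ref <- fixture_ca3_reference()
  loci <- fixture_ca3_locus()
  reads <- make_reads(ref, loci)
  expect_equal(nrow(reads), 10L)
  expect_equal(sort(unique(reads$flank_left)),
               c(25L, 28L, 31L, 33L, 36L, 39L, 42L, 44L, 47L, 50L))
  expect_equal(reads$read_len,
               reads$flank_left + nchar(reads$alt) + reads$flank_right)
  expect_true(all(reads$read_len >= 50 & reads$read_len <= 104))
  expect_equal(nchar(reads$sequence), reads$read_len)

  # k = 25 with a 4-base alt gives a 54-base read
  ref2 <- reference_from_seq(chr1 = strrep("GATTC", 40))
  loci2 <- tibble::tibble(locus_id = "L1", chrom = "chr1", pos = 99L,
                          ref = "T", alts = list("TACG"), n_alts = 1L)
  r2 <- make_reads(ref2, loci2, reads_per_locus = 1L, flank_min = 25L,
                   flank_max = 25L)
  expect_equal(r2$read_len, 54L)
})

test_that("reads are u + alt + v verbatim from the reference", {
  ref <- fixture_ca3_reference()
  loci <- fixture_ca3_locus()
  reads <- make_reads(ref, loci)
  g <- ref$sequence[[1]]
  for (k in seq_len(nrow(reads))) {
    r <- reads[k, ]
    u <- substr(g, r$pos - r$flank_left, r$pos - 1L)
    v <- substr(g, r$pos + nchar(r$ref),
                r$pos + nchar(r$ref) - 1L + r$flank_right)
    expect_equal(r$sequence, paste0(u, r$alt, v))
    expect_equal(r$truth_start, r$pos - r$flank_left)
    expect_equal(r$truth_end, r$pos + nchar(r$ref) - 1L + r$flank_right)
  }
})

test_that("multi-allelic loci get one read set per alternative allele", {
  ref <- fixture_ca3_reference()
  loci <- tibble::tibble(locus_id = "L1", chrom = "chr1", pos = 121L,
                         ref = "TCA", alts = list(c("T", "TCACA")),
                         n_alts = 2L)
  reads <- make_reads(ref, loci)
  expect_equal(nrow(reads), 20L)
  expect_equal(sort(unique(reads$allele_index)), c(1L, 2L))
})

test_that("REF mismatches, tight flank ranges and edge loci are handled", {
  ref <- fixture_ca3_reference()
  bad <- tibble::tibble(locus_id = "L1", chrom = "chr1", pos = 121L,
                        ref = "AAA", alts = list("A"), n_alts = 1L)
  expect_error(make_reads(ref, bad), "does not match reference")

  loci <- fixture_ca3_locus()
  expect_error(make_reads(ref, loci, flank_min = 25L, flank_max = 27L),
               "too short for 10 distinct")

  edge <- tibble::tibble(locus_id = "L2", chrom = "chr1", pos = 10L,
                         ref = "A", alts = list("AT"), n_alts = 1L)
  out <- suppressMessages(make_reads(ref, edge))
  expect_equal(nrow(out), 0L)
  expect_equal(nrow(attr(out, "skipped")), 1L)
})

test_that("correct mapping means >= 1 bp overlap with the locus interval", {
  reads <- tibble::tibble(read_id = "r1", chrom = "chr1", locus_id = "L1",
                          pos = 120L, ref = "TCA", alt = "T",
                          allele_index = 1L, flank_left = 25L,
                          flank_right = 25L, sequence = "N",
                          read_len = 51L, truth_start = 95L,
                          truth_end = 147L)
  aln <- tibble::tibble(read_id = "r1", chrom = "chr1", pos = 100L,
                        end = 153L)
  expect_true(is_correctly_mapped(aln, reads))
  aln$chrom <- "chr2"
  expect_false(is_correctly_mapped(aln, reads))
  aln$chrom <- "chr1"; aln$pos <- 100L; aln$end <- 119L  # adjacent only
  expect_false(is_correctly_mapped(aln, reads))
  aln$end <- 120L                                        # 1 bp overlap
  expect_true(is_correctly_mapped(aln, reads))
})

test_that("generated reads realign to their truth window with a locus call", {
  ref <- fixture_ca3_reference()
  reads <- make_reads(ref, fixture_ca3_locus())
  g <- ref$sequence[[1]]
  for (k in c(1L, 5L, 10L)) {
    r <- reads[k, ]
    window <- substr(g, r$truth_start, r$truth_end)
    e <- enumerate_optimal(r$sequence, window, scoring_scheme(),
                           mode = "fitting")
    expect_gte(nrow(e), 1L)
    calls <- alignment_to_calls(e[1, ], x = r$sequence, y = window,
                                window_pos = r$truth_start, chrom = r$chrom)
    locus_end <- r$pos + nchar(r$ref) - 1L
    expect_true(any(calls$pos <= locus_end &
                      calls$pos + nchar(calls$ref) - 1L >= r$pos))
  }
})

test_that("manifest write/read round trip is lossless", {
  ref <- fixture_ca3_reference()
  reads <- make_reads(ref, fixture_ca3_locus())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(reads, tsv)
  back <- read_manifest(tsv)
  expect_equal(as.data.frame(back), as.data.frame(reads),
               ignore_attr = TRUE)
})
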