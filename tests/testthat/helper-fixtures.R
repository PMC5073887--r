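# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# reference with the worked tandem-repeat context T(CA)3G embedded at 121
fixture_ca3_reference <- function() {
  reference_from_seq(
    chr1 = paste0(strrep("GATC", 30), "TCACACAG", strrep("CTGA", 30)))
}

fixture_ca3_locus <- function() {
  tibble::tibble(locus_id = "L1", chrom = "chr1", pos = 121L, ref = "TCA",
                 alts = list("T"), n_alts = 1L)
}

# non-repetitive flanks of the worked insertion example
fixture_acga <- function() {
  u <- "GATTACAGATTACAGATTACAGATT"
  v <- "GGCCTTGGCCTTGGCCTTGGCCTTG"
  list(read = paste0(u, "ACGA", v), window = paste0(u, "A", v), u = u, v = v)
}

# moderate synthetic dataset shared by agreement/synthetic tests
fixture_synth_leftmost <- function() {
  cached("synth_leftmost", function() {
    generate_synthetic(synthetic_spec(seed = 7, n_loci = 40,
                                      chrom_length = 15000L,
                                      fraction_ambiguous = 0.5))
  })
}

# full-scale all-ambiguous dataset (leftmost convention)
fixture_synth_leftmost100 <- function() {
  cached("synth_leftmost100", function() {
    generate_synthetic(synthetic_spec(seed = 31, n_loci = 100,
                                      fraction_ambiguous = 1))
  })
}

fixture_synth_uniform <- function() {
  cached("synth_uniform", function() {
    generate_synthetic(synthetic_spec(seed = 8, n_loci = 40,
                                      chrom_length = 15000L,
                                      fraction_ambiguous = 1,
                                      recording_convention = "uniform"))
  })
}

# minimal hand-rolled complexity_profile for formula-level tests
manual_complexity <- function(locus_ids, n_affine) {
  records <- tibble::tibble(
    locus_id = locus_ids, chrom = "chr1", pos = seq_along(locus_ids),
    ref = "A", alts = replicate(length(locus_ids), "AT", simplify = FALSE),
    n_simple = n_affine, n_affine = n_affine,
    per_alt = replicate(length(locus_ids), tibble::tibble(),
                        simplify = FALSE),
    note = NA_character_)
  structure(list(records = records,
                 by_chrom = dplyr::count(records, chrom, n_affine,
                                         name = "n_loci"),
                 n_total = nrow(records),
                 n_multi = sum(n_affine > 1),
                 scheme = scoring_scheme(), flank = 50L,
                 skipped = tibble::tibble()),
            class = "complexity_profile")
}
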