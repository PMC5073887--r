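#' Build alt-allele-bearing reads around each INDEL locus
#'
#' Reverse-engineers the construction of a variant profile: for every locus
#' and every alternative allele, builds reads \code{r = u + alt + v} where `u`
#' and `v` are flanking reference substrings taken verbatim from the genome,
#' at `reads_per_locus` symmetric flank lengths evenly spaced across
#' `[flank_min, flank_max]`.  With the defaults (10 lengths in 25..50) a
#' biallelic locus yields exactly 10 reads of length `|u| + |alt| + |v|`,
#' i.e. roughly 50-100 bp; a locus with two alternative alleles yields 20.
#' Loci closer than `flank_max + |ref|` to a chromosome end are skipped and
#' tallied in the `skipped` attribute.
#'
#' @param reference Reference tibble from [read_fasta()].
#' @param loci Profile tibble from [read_variant_profile()].
#' @param flank_min,flank_max Flank length range (bp).
#' @param reads_per_locus Number of distinct flank lengths per (locus, alt)
#'   pair; must not exceed the number of distinct integers in the range.
#' @return The read manifest: a tibble with columns `read_id`, `chrom`,
#'   `locus_id`, `pos`, `ref`, `alt`, `allele_index`, `flank_left`,
#'   `flank_right`, `sequence`, `read_len`, `truth_start`, `truth_end`
#'   (the 1-based genomic interval the read should map to).  Attribute
#'   `skipped`: tibble of loci too close to a chromosome end.
#' @examples
#' ref <- reference_from_seq(chr1 = strrep("ACGTT", 40))
#' loci <- tibble::tibble(locus_id = "locus00001", chrom = "chr1",
#'                        pos = 100L, ref = "TA", alts = list("T"),
#'                        n_alts = 1L)
#' nrow(make_reads(ref, loci))
#' @export
make_reads <- function(reference, loci, flank_min = 25L, flank_max = 50L,
                       reads_per_locus = 10L) {
  stopifnot(flank_min >= 1, flank_max >= flank_min, reads_per_locus >= 1)
  ks <- unique(round(seq(flank_min, flank_max, length.out = reads_per_locus)))
  if (length(ks) < reads_per_locus) {
    abort(sprintf(
      "flank range [%d, %d] is too short for %d distinct flank lengths",
      flank_min, flank_max, reads_per_locus))
  }
  skipped <- list()
  rows <- list()
  for (k in seq_len(nrow(loci))) {
    loc <- loci[k, ]
    chrom_len <- reference$length[[match(loc$chrom, reference$chrom)]]
    ref_len <- nchar(loc$ref)
    if (loc$pos - flank_max < 1L ||
        loc$pos + ref_len - 1L + flank_max > chrom_len) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        locus_id = loc$locus_id, chrom = loc$chrom, pos = loc$pos,
        reason = "too close to chromosome end")
      next
    }
    obs <- ref_sub(reference, loc$chrom, loc$pos, loc$pos + ref_len - 1L)
    if (!identical(obs, toupper(loc$ref))) {
      abort(sprintf("locus %s: REF '%s' does not match reference '%s' at %s:%d",
                    loc$locus_id, loc$ref, obs, loc$chrom, loc$pos))
    }
    alts <- loc$alts[[1]]
    for (a in seq_along(alts)) {
      alt <- alts[[a]]
      for (fl in ks) {
        u <- ref_sub(reference, loc$chrom, loc$pos - fl, loc$pos - 1L)
        v <- ref_sub(reference, loc$chrom, loc$pos + ref_len,
                     loc$pos + ref_len - 1L + fl)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          read_id = sprintf("%s_alt%d_k%02d", loc$locus_id, a, fl),
          chrom = loc$chrom, locus_id = loc$locus_id, pos = loc$pos,
          ref = loc$ref, alt = alt, allele_index = a,
          flank_left = fl, flank_right = fl,
          sequence = paste0(u, alt, v),
          read_len = fl + nchar(alt) + fl,
          truth_start = loc$pos - fl,
          truth_end = loc$pos + ref_len - 1L + fl)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  skipped <- dplyr::bind_rows(skipped)
  if (nrow(skipped) > 0) {
    inform(sprintf("make_reads: skipped %d locus/loci too close to a chromosome end",
                   nrow(skipped)))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write a read manifest as TSV
#'
#' @param reads Read manifest from [make_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(reads, path) {
  readr::write_tsv(reads, path)
  invisible(path)
}

#' Read a manifest written by [write_manifest()]
#'
#' @param path Path to the TSV manifest.
#' @return The read manifest tibble.
#' @export
read_manifest <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    read_id = "c", chrom = "c", locus_id = "c", pos = "i", ref = "c",
    alt = "c", allele_index = "i", flank_left = "i", flank_right = "i",
    sequence = "c", read_len = "i", truth_start = "i", truth_end = "i"))
}

#' Is a read mapped to its own INDEL locus?
#'
#' A read is correctly mapped when its mapped reference interval lies on the
#' locus chromosome and overlaps the locus interval
#' `[pos, pos + |ref| - 1]` by at least one base.
#'
#' @param alignments Alignment tibble (columns `read_id`, `chrom`, `pos`,
#'   `end`).
#' @param reads Read manifest from [make_reads()].
#' @return Logical vector along `alignments`.
#' @export
is_correctly_mapped <- function(alignments, reads) {
  man <- dplyr::select(reads, "read_id", locus_chrom = "chrom",
                       locus_pos = "pos", locus_ref = "ref")
  j <- dplyr::left_join(alignments, man, by = "read_id")
  if (anyNA(j$locus_pos)) {
    abort("some alignments have read ids absent from the manifest")
  }
  locus_end <- j$locus_pos + nchar(j$locus_ref) - 1L
  j$chrom == j$locus_chrom & j$pos <= locus_end & j$end >= j$locus_pos
}
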