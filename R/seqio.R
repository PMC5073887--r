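#' Read a reference genome from FASTA
#'
#' Loads a (multi-record) FASTA file into the tabular reference
#' representation used throughout the package: one row per chromosome with
#' its full upper-cased sequence.  Multi-line records are joined; the
#' alphabet is restricted to A, C, G, T, N.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `chrom`, `sequence`, `length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGT", ">chr2", "TT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  # invalid sequence codes only raise a warning in Biostrings; treat both
  # warnings and errors as format errors
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort(sprintf("malformed FASTA '%s': %s",
                                      path, conditionMessage(e))),
    warning = function(w) abort(sprintf("malformed FASTA '%s': %s",
                                        path, conditionMessage(w)))
  )
  if (length(set) == 0) abort(sprintf("FASTA '%s' contains no records", path))
  # header lines may carry descriptions after the first whitespace
  nm <- sub("\\s.*$", "", names(set))
  if (any(nm == "")) abort(sprintf("FASTA '%s' has an empty record name", path))
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate chromosome name in '%s': %s",
                  path, nm[duplicated(nm)][1]))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    abort(sprintf("FASTA '%s' has an empty sequence for record '%s'",
                  path, nm[nchar(seqs) == 0][1]))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf("record '%s' contains characters outside A/C/G/T/N",
                  nm[bad][1]))
  }
  tibble::tibble(chrom = nm, sequence = unname(seqs),
                 length = unname(nchar(seqs)))
}

#' Build a reference tibble from in-memory sequences
#'
#' @param ... Named DNA strings, one per chromosome.
#' @return A reference tibble as from [read_fasta()].
#' @examples
#' reference_from_seq(chr1 = "ACGTACGT")
#' @export
reference_from_seq <- function(...) {
  seqs <- c(...)
  stopifnot(length(seqs) > 0, !is.null(names(seqs)), all(names(seqs) != ""))
  if (anyDuplicated(names(seqs))) abort("duplicate chromosome names")
  seqs <- toupper(seqs)
  tibble::tibble(chrom = names(seqs), sequence = unname(seqs),
                 length = nchar(seqs))
}

#' Write a reference tibble to FASTA
#'
#' @param reference Reference tibble (`chrom`, `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reference, path) {
  set <- Biostrings::DNAStringSet(setNames(reference$sequence,
                                           reference$chrom))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

ref_sequence <- function(reference, chrom) {
  i <- match(chrom, reference$chrom)
  if (is.na(i)) abort(sprintf("chromosome '%s' not in reference", chrom))
  reference$sequence[[i]]
}

ref_sub <- function(reference, chrom, start, end) {
  s <- ref_sequence(reference, chrom)
  if (start < 1 || end > nchar(s) || start > end) {
    abort(sprintf("interval %s:%d-%d outside reference bounds", chrom,
                  start, end))
  }
  substr(s, start, end)
}

#' Read an INDEL variant profile from VCF
#'
#' Parses the CHROM/POS/REF/ALT columns of a VCF (other columns are
#' ignored), validates every REF allele against the reference sequence, and
#' keeps one locus per row that carries at least one length-changing ALT
#' allele.  SNV-only rows and same-length ALTs are dropped; the number of
#' rows dropped for having no INDEL allele is reported via a message and the
#' `n_skipped_snv` attribute.  Alleles are expected in the anchored (VCF)
#' convention where REF and ALT share their first base; rows not in that
#' form are re-anchored using the reference base before POS (with a
#' message).
#'
#' @param path Path to a VCF file.
#' @param reference Reference tibble from [read_fasta()].
#' @return A tibble with columns `locus_id`, `chrom`, `pos` (1-based anchor),
#'   `ref`, `alts` (list column of character vectors), `n_alts`.  Attribute
#'   `n_skipped_snv` counts rows without any length-changing ALT.
#' @export
read_variant_profile <- function(path, reference) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) {
    out <- tibble::tibble(locus_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alts = list(), n_alts = integer())
    attr(out, "n_skipped_snv") <- 0L
    return(out)
  }
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- toupper(as.character(fix[, "REF"]))
  alt_raw <- as.character(fix[, "ALT"])

  rows <- vector("list", length(pos))
  n_skipped <- 0L
  n_reanchored <- 0L
  for (k in seq_along(pos)) {
    alts <- toupper(strsplit(alt_raw[[k]], ",", fixed = TRUE)[[1]])
    alts <- alts[alts != ref[[k]] & !grepl("[^ACGTN]", alts)]
    # keep only length-changing (INDEL) alleles
    alts <- alts[nchar(alts) != nchar(ref[[k]])]
    if (length(alts) == 0) { n_skipped <- n_skipped + 1L; next }
    p <- pos[[k]]; r <- ref[[k]]
    obs <- ref_sub(reference, chrom[[k]], p, p + nchar(r) - 1L)
    if (!identical(obs, r)) {
      abort(sprintf(
        "REF mismatch at %s:%d: VCF has '%s', reference has '%s'",
        chrom[[k]], p, r, obs))
    }
    if (any(substr(alts, 1, 1) != substr(r, 1, 1))) {
      # re-anchor on the base preceding POS (VCF-style anchored form)
      if (p == 1L) abort(sprintf(
        "cannot re-anchor unanchored variant at %s:%d (no base before POS)",
        chrom[[k]], p))
      b <- ref_sub(reference, chrom[[k]], p - 1L, p - 1L)
      r <- paste0(b, r)
      alts <- paste0(b, alts)
      p <- p - 1L
      n_reanchored <- n_reanchored + 1L
    }
    rows[[k]] <- tibble::tibble(chrom = chrom[[k]], pos = p, ref = r,
                                alts = list(alts),
                                n_alts = length(alts))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out <- dplyr::mutate(out,
      locus_id = sprintf("locus%05d", dplyr::row_number()),
      .before = 1)
  } else {
    out <- tibble::tibble(locus_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alts = list(), n_alts = integer())
  }
  if (n_skipped > 0) {
    inform(sprintf("read_variant_profile: skipped %d row(s) without a length-changing ALT",
                   n_skipped))
  }
  if (n_reanchored > 0) {
    inform(sprintf("read_variant_profile: re-anchored %d unanchored row(s)",
                   n_reanchored))
  }
  attr(out, "n_skipped_snv") <- n_skipped
  out
}

#' Write an INDEL profile as VCF
#'
#' Minimal VCF 4.2 writer for profiles shaped like the output of
#' [read_variant_profile()] (columns `chrom`, `pos`, `ref`, `alts`).
#'
#' @param profile Profile tibble.
#' @param reference Reference tibble (for contig header lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_profile <- function(profile, reference, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", reference$chrom, reference$length),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  body <- vapply(seq_len(nrow(profile)), function(k) {
    paste(profile$chrom[[k]], profile$pos[[k]], ".",
          profile$ref[[k]],
          paste(profile$alts[[k]], collapse = ","),
          ".", ".", ".", sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write synthetic reads to FASTQ
#'
#' Writes the `sequence` column of a read manifest as FASTQ with a constant
#' quality string (`I`, i.e. Q40); the read ids carry the truth locus so a
#' downstream SAM can be matched back to the manifest.
#'
#' @param reads Read manifest tibble from [make_reads()] (columns `read_id`,
#'   `sequence`).
#' @param path Output path.
#' @return Number of reads written, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  if (nrow(reads) == 0) abort("no reads to write")
  set <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = qual)
  invisible(nrow(reads))
}

sam_cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(tibble::tibble(op = character(),
                                                          len = integer()))
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar, perl = TRUE)[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(cigar)) {
    abort(sprintf("malformed CIGAR '%s'", cigar))
  }
  parts <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  tibble::tibble(
    op = substr(parts, nchar(parts), nchar(parts)),
    len = as.integer(substr(parts, 1, nchar(parts) - 1L))
  )
}

cigar_read_len <- function(cigar) {
  ops <- sam_cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])
}

cigar_ref_len <- function(cigar) {
  ops <- sam_cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
}

#' Read alignments from a SAM text file
#'
#' Minimal parser for plain-text SAM: header lines are skipped, flags 0/4/16
#' are honored (bit 0x4 marks an unmapped record, bit 0x10 a reverse-strand
#' record whose SEQ is already stored in reference orientation).  Unmapped
#' records are excluded from the returned table but counted in the
#' `n_unmapped` attribute.  Soft clips are preserved in the CIGAR.  Each
#' record's CIGAR must consume exactly `nchar(seq)` read bases.
#'
#' @param path Path to a SAM file.
#' @return A tibble with columns `read_id`, `flag`, `chrom`, `pos`, `end`
#'   (1-based closed mapped reference interval), `mapq`, `cigar`, `seq`.
#'   Attribute `n_unmapped` counts excluded unmapped records.
#' @export
read_alignments_sam <- function(path) {
  if (!file.exists(path)) abort(sprintf("SAM file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  n_unmapped <- 0L
  rows <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) abort(sprintf("SAM line %d has fewer than 11 fields", k))
    flag <- as.integer(f[[2]])
    if (bitwAnd(flag, 4L) != 0L) { n_unmapped <- n_unmapped + 1L; next }
    cigar <- f[[6]]
    seq <- toupper(f[[10]])
    if (seq != "*" && cigar != "*") {
      consumed <- cigar_read_len(cigar)
      if (consumed != nchar(seq)) {
        abort(sprintf(
          "SAM record '%s': CIGAR '%s' consumes %d read bases but SEQ has %d",
          f[[1]], cigar, consumed, nchar(seq)))
      }
    }
    pos <- as.integer(f[[4]])
    rows[[k]] <- tibble::tibble(
      read_id = f[[1]], flag = flag, chrom = f[[3]], pos = pos,
      end = pos + cigar_ref_len(cigar) - 1L,
      mapq = as.integer(f[[5]]), cigar = cigar, seq = seq)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(read_id = character(), flag = integer(),
                          chrom = character(), pos = integer(),
                          end = integer(), mapq = integer(),
                          cigar = character(), seq = character())
  }
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Write alignments as SAM text
#'
#' @param alignments Alignment tibble as from [read_alignments_sam()] or
#'   [simulate_policy_alignments()].
#' @param reference Reference tibble (for `@SQ` header lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(alignments, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", reference$chrom, reference$length))
  body <- vapply(seq_len(nrow(alignments)), function(k) {
    a <- alignments[k, ]
    paste(a$read_id, a$flag, a$chrom, a$pos, a$mapq, a$cigar,
          "*", 0L, 0L, a$seq, "*", sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
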