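#' Convert alignments to anchored variant calls
#'
#' Walks the columns of each alignment and emits one anchored call per
#' maximal run of gap columns plus one SNV call per mismatch column, in the
#' VCF convention: a deletion run becomes `REF = anchor + deleted window
#' bases, ALT = anchor`; an insertion run becomes `REF = anchor, ALT =
#' anchor + inserted read bases`, where the anchor is the last window base
#' consumed before the run.  A run at the very start of the consumed span is
#' anchored on the preceding window base when the window provides one
#' (`window_offset > 0`), and is an error otherwise.
#'
#' @param alignments Tibble from [enumerate_optimal()] (columns
#'   `alignment_id`, `window_offset`, `columns`), or a bare character vector
#'   of columns for a single alignment.
#' @param x Read sequence (defaults to the `read` attribute of
#'   `alignments`).
#' @param y Window sequence (defaults to the `window` attribute).
#' @param window_pos 1-based genomic position of the first window base.
#' @param chrom Chromosome name for the emitted calls.
#' @return A tibble with columns `alignment_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `type` (`"del"`, `"ins"`, `"snv"`), sorted by `alignment_id`
#'   then `pos`.
#' @examples
#' calls <- alignment_to_calls(c("M", "D", "D", "M", "M", "D", "D", "M", "M"),
#'                             x = "TCAGG", y = "TCACACAGG",
#'                             window_pos = 101, chrom = "chr1")
#' calls
#' @export
alignment_to_calls <- function(alignments, x = NULL, y = NULL,
                               window_pos = 1L, chrom = "chr1") {
  if (is.character(alignments)) {
    alignments <- tibble::tibble(alignment_id = 1L, window_offset = 0L,
                                 columns = list(alignments))
  }
  if (is.null(x)) x <- attr(alignments, "read")
  if (is.null(y)) y <- attr(alignments, "window")
  if (is.null(x) || is.null(y)) {
    abort("read/window sequences must be supplied (or carried as attributes)")
  }
  out <- purrr::map(seq_len(nrow(alignments)), function(k) {
    cl <- calls_from_columns(alignments$columns[[k]], x, y,
                             offset = alignments$window_offset[[k]],
                             window_pos = window_pos, chrom = chrom)
    if (nrow(cl) > 0) cl$alignment_id <- alignments$alignment_id[[k]]
    cl
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(alignment_id = integer(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), type = character()))
  }
  dplyr::arrange(dplyr::relocate(out, "alignment_id"),
                 .data$alignment_id, .data$pos)
}

calls_from_columns <- function(columns, x, y, offset = 0L, window_pos = 1L,
                               chrom = "chr1") {
  xs <- toupper(x); ys <- toupper(y)
  i <- 0L                      # read bases consumed
  j <- as.integer(offset)      # window bases consumed (window index of last)
  runs <- rle(columns)
  calls <- list()
  anchor_or_die <- function() {
    if (j < 1L) {
      abort(paste0("gap run at the start of the window has no anchor base; ",
                   "extend the window left"))
    }
    substr(ys, j, j)
  }
  for (r in seq_along(runs$values)) {
    v <- runs$values[[r]]; l <- runs$lengths[[r]]
    if (v == "M") {
      i <- i + l; j <- j + l
    } else if (v == "X") {
      for (s in seq_len(l)) {
        i <- i + 1L; j <- j + 1L
        calls[[length(calls) + 1L]] <- tibble::tibble(
          chrom = chrom, pos = window_pos + j - 1L,
          ref = substr(ys, j, j), alt = substr(xs, i, i), type = "snv")
      }
    } else if (v == "D") {
      anchor <- anchor_or_die()
      calls[[length(calls) + 1L]] <- tibble::tibble(
        chrom = chrom, pos = window_pos + j - 1L,
        ref = paste0(anchor, substr(ys, j + 1L, j + l)),
        alt = anchor, type = "del")
      j <- j + l
    } else if (v == "I") {
      anchor <- anchor_or_die()
      calls[[length(calls) + 1L]] <- tibble::tibble(
        chrom = chrom, pos = window_pos + j - 1L,
        ref = anchor,
        alt = paste0(anchor, substr(xs, i + 1L, i + l)), type = "ins")
      i <- i + l
    } else {
      abort(sprintf("unknown alignment column '%s'", v))
    }
  }
  out <- dplyr::bind_rows(calls)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          type = character())
  }
  out
}

#' Extract anchored calls from a SAM record
#'
#' Applies the package's call conventions (see [alignment_to_calls()]) to an
#' externally produced alignment: the CIGAR is expanded against the
#' reference (M/=/X columns classified by base comparison, soft clips
#' trimmed from the read) and each gap run / mismatch becomes an anchored
#' call.  When the record starts after position 1 the window is extended one
#' base left so that a leading gap run can be anchored.
#'
#' @param alignment One row of an alignment tibble (see
#'   [read_alignments_sam()]).
#' @param reference Reference tibble.
#' @return A tibble of calls (`chrom`, `pos`, `ref`, `alt`, `type`).
#' @export
sam_to_calls <- function(alignment, reference) {
  stopifnot(nrow(alignment) == 1)
  ops <- sam_cigar_ops(alignment$cigar)
  bad <- setdiff(ops$op, c("M", "=", "X", "I", "D", "S"))
  if (length(bad) > 0) {
    abort(sprintf("unsupported CIGAR op '%s' in '%s'", bad[[1]],
                  alignment$cigar))
  }
  seq <- toupper(alignment$seq)
  lead <- if (nrow(ops) > 0 && ops$op[[1]] == "S") ops$len[[1]] else 0L
  trail <- if (nrow(ops) > 1 && ops$op[[nrow(ops)]] == "S") ops$len[[nrow(ops)]] else 0L
  core <- ops[ops$op != "S", , drop = FALSE]
  read <- substr(seq, lead + 1L, nchar(seq) - trail)
  ref_len <- sum(core$len[core$op %in% c("M", "=", "X", "D")])
  pos <- alignment$pos
  chrom <- alignment$chrom
  # pull one extra base on the left (when available) to anchor leading gaps
  wstart <- max(1L, pos - 1L)
  offset <- pos - wstart
  window <- ref_sub(reference, chrom, wstart, pos + ref_len - 1L)

  cols <- character(0)
  i <- 0L; j <- as.integer(offset)
  for (k in seq_len(nrow(core))) {
    op <- core$op[[k]]; l <- core$len[[k]]
    if (op %in% c("M", "=", "X")) {
      rb <- strsplit(substr(read, i + 1L, i + l), "")[[1]]
      wb <- strsplit(substr(window, j + 1L, j + l), "")[[1]]
      if (length(rb) != l || length(wb) != l) {
        abort(sprintf("CIGAR '%s' inconsistent with read/reference lengths",
                      alignment$cigar))
      }
      cols <- c(cols, ifelse(rb == wb, "M", "X"))
      i <- i + l; j <- j + l
    } else if (op == "I") {
      cols <- c(cols, rep("I", l)); i <- i + l
    } else {
      cols <- c(cols, rep("D", l)); j <- j + l
    }
  }
  calls_from_columns(cols, read, window, offset = offset,
                     window_pos = wstart, chrom = chrom)
}

#' Left-align an anchored INDEL call
#'
#' Standard left normalization: while REF and ALT end in the same base the
#' call is shifted left (trimming the shared last base and, when one allele
#' would empty, prepending the reference base before the anchor), then
#' shared leading bases beyond the anchor are trimmed.  Every member of a
#' set of equivalent INDEL representations normalizes to the same leftmost
#' anchored form.
#'
#' @param pos 1-based anchor position.
#' @param ref REF allele.
#' @param alt ALT allele.
#' @param chrom_seq Full chromosome sequence string.
#' @return A list with elements `pos`, `ref`, `alt`.
#' @export
left_align_call <- function(pos, ref, alt, chrom_seq) {
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  last <- function(s) substr(s, nchar(s), nchar(s))
  repeat {
    rn <- nchar(ref); an <- nchar(alt)
    if (rn == 0 || an == 0 || last(ref) != last(alt)) break
    if (rn > 1 && an > 1) {
      ref <- substr(ref, 1, rn - 1L); alt <- substr(alt, 1, an - 1L)
    } else if (pos > 1) {
      b <- substr(chrom_seq, pos - 1L, pos - 1L)
      ref <- paste0(b, substr(ref, 1, rn - 1L))
      alt <- paste0(b, substr(alt, 1, an - 1L))
      pos <- pos - 1L
    } else break
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1) &&
         substr(ref, 2, 2) == substr(alt, 2, 2)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}
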