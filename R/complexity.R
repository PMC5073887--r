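#' INDEL complexity of one locus
#'
#' The complexity of an INDEL locus is the number of optimal alignments
#' obtained when a read bearing the alternative allele is aligned (fitting,
#' i.e. read end to end inside a padded reference window) to the reference
#' at that location.  The count is computed under the affine-gap model of
#' `scheme` (`n_affine`, the headline quantity) and under its equal-penalty
#' companion (`n_simple`).  For a multi-allelic locus the per-locus count is
#' the maximum over alternative alleles -- an aligner faces each read
#' separately, so the maximum captures the worst-case ambiguity; per-allele
#' counts are kept in the `per_alt` list column.
#'
#' Windows containing `N` are not scored (match/mismatch for `N` is
#' undefined); such loci return `NA` counts with `note = "window contains N"`.
#'
#' @param reference Reference tibble.
#' @param locus One row of a profile tibble (`chrom`, `pos`, `ref`, `alts`).
#' @param scheme A [scoring_scheme()]; `gap_open` must be < 0 so that the
#'   affine and equal-penalty models differ.
#' @param flank Padding (bp) on each side of the locus; the window is the
#'   locus interval padded by `flank`, and the read carries flanks of the
#'   same length.  Complexity is invariant to `flank` once it exceeds the
#'   repeat context.
#' @param cap Passed to [enumerate_optimal()].
#' @return A one-row tibble: `locus_id`, `chrom`, `pos`, `ref`, `alts`,
#'   `n_simple`, `n_affine`, `per_alt` (tibble of per-allele counts),
#'   `note`.
#' @examples
#' ref <- reference_from_seq(chr1 = paste0(strrep("GATC", 30), "TCACACAG",
#'                                         strrep("CTGA", 30)))
#' locus <- tibble::tibble(locus_id = "L1", chrom = "chr1", pos = 121L,
#'                         ref = "TCA", alts = list("T"))
#' locus_complexity(ref, locus, flank = 20)$n_affine
#' @export
locus_complexity <- function(reference, locus, scheme = scoring_scheme(),
                             flank = 50L, cap = 1000L) {
  stopifnot(nrow(locus) == 1)
  scheme <- as_scoring_scheme(scheme)
  if (scheme$gap_open >= 0) {
    abort("locus_complexity() expects an affine scheme (gap_open < 0)")
  }
  chrom_len <- reference$length[[match(locus$chrom, reference$chrom)]]
  ref_len <- nchar(locus$ref)
  wstart <- locus$pos - flank
  wend <- locus$pos + ref_len - 1L + flank
  if (wstart < 1L || wend > chrom_len) {
    abort(sprintf("locus %s at %s:%d does not pass flank bounds",
                  locus$locus_id, locus$chrom, locus$pos))
  }
  window <- ref_sub(reference, locus$chrom, wstart, wend)
  id <- if ("locus_id" %in% names(locus)) locus$locus_id else NA_character_
  if (grepl("N", window, fixed = TRUE)) {
    return(tibble::tibble(
      locus_id = id, chrom = locus$chrom, pos = locus$pos, ref = locus$ref,
      alts = locus$alts, n_simple = NA_integer_, n_affine = NA_integer_,
      per_alt = list(tibble::tibble(alt = character(), n_simple = integer(),
                                    n_affine = integer())),
      note = "window contains N"))
  }
  u <- ref_sub(reference, locus$chrom, wstart, locus$pos - 1L)
  v <- ref_sub(reference, locus$chrom, locus$pos + ref_len, wend)
  simple <- simple_variant(scheme)
  per_alt <- purrr::map(locus$alts[[1]], function(alt) {
    read <- paste0(u, alt, v)
    n_aff <- tryCatch(
      nrow(enumerate_optimal(read, window, scheme, mode = "fitting",
                             cap = cap)),
      indelbias_overflow = function(e) {
        abort(sprintf("locus %s: %s", id, conditionMessage(e)),
              class = "indelbias_overflow", cap = cap)
      })
    n_sim <- nrow(enumerate_optimal(read, window, simple, mode = "fitting",
                                    cap = cap))
    tibble::tibble(alt = alt, n_simple = n_sim, n_affine = n_aff)
  })
  per_alt <- dplyr::bind_rows(per_alt)
  tibble::tibble(
    locus_id = id, chrom = locus$chrom, pos = locus$pos, ref = locus$ref,
    alts = locus$alts,
    n_simple = max(per_alt$n_simple), n_affine = max(per_alt$n_affine),
    per_alt = list(per_alt), note = NA_character_)
}

#' Profile-wide INDEL complexity
#'
#' Applies [locus_complexity()] to every locus of a variant profile and
#' summarizes the result: the per-locus record table, a per-chromosome
#' histogram of `n_affine`, and the count of loci with multiple optimal
#' alignments.  Per-locus failures (flank bounds, ambiguity overflow) are
#' logged and tallied, not fatal.
#'
#' @param reference Reference tibble.
#' @param loci Profile tibble from [read_variant_profile()].
#' @inheritParams locus_complexity
#' @return A `complexity_profile` object with elements `records` (tibble),
#'   `by_chrom` (chromosome x n_affine histogram tibble), `n_total`,
#'   `n_multi` (loci with `n_affine > 1`), `skipped` (tibble of failures).
#'   Methods: `print()`, `tidy()`, `glance()`, `autoplot()`.
#' @export
profile_complexity <- function(reference, loci, scheme = scoring_scheme(),
                               flank = 50L, cap = 1000L) {
  skipped <- list()
  recs <- vector("list", nrow(loci))
  for (k in seq_len(nrow(loci))) {
    recs[[k]] <- tryCatch(
      locus_complexity(reference, loci[k, ], scheme, flank = flank,
                       cap = cap),
      error = function(e) {
        skipped[[length(skipped) + 1L]] <<- tibble::tibble(
          locus_id = loci$locus_id[[k]], reason = conditionMessage(e))
        NULL
      })
  }
  records <- dplyr::bind_rows(recs)
  if (nrow(records) == 0) {
    records <- tibble::tibble(
      locus_id = character(), chrom = character(), pos = integer(),
      ref = character(), alts = list(), n_simple = integer(),
      n_affine = integer(), per_alt = list(), note = character())
  }
  skipped <- dplyr::bind_rows(skipped)
  if (nrow(skipped) > 0) {
    inform(sprintf("profile_complexity: %d locus/loci skipped", nrow(skipped)))
  }
  by_chrom <- if (nrow(records) > 0) {
    dplyr::count(dplyr::filter(records, !is.na(.data$n_affine)),
                 .data$chrom, .data$n_affine, name = "n_loci")
  } else {
    tibble::tibble(chrom = character(), n_affine = integer(),
                   n_loci = integer())
  }
  structure(
    list(records = records, by_chrom = by_chrom,
         n_total = nrow(records),
         n_multi = sum(records$n_affine > 1, na.rm = TRUE),
         scheme = scheme, flank = flank, skipped = skipped),
    class = "complexity_profile")
}

#' @export
print.complexity_profile <- function(x, ...) {
  cat(sprintf("<complexity_profile> %d loci, %d with multiple optimal alignments (affine model)\n",
              x$n_total, x$n_multi))
  if (nrow(x$by_chrom) > 0) {
    tab <- tidyr::pivot_wider(x$by_chrom, names_from = "n_affine",
                              values_from = "n_loci", values_fill = 0L,
                              names_prefix = "n=")
    print(tab)
  }
  if (nrow(x$skipped) > 0) cat(sprintf("(%d loci skipped)\n", nrow(x$skipped)))
  invisible(x)
}

#' @rdname profile_complexity
#' @param x A `complexity_profile`.
#' @param ... Unused.
#' @export
tidy.complexity_profile <- function(x, ...) x$records

#' @rdname profile_complexity
#' @export
glance.complexity_profile <- function(x, ...) {
  ok <- x$records$n_affine[!is.na(x$records$n_affine)]
  tibble::tibble(
    n_total = x$n_total,
    n_multi = x$n_multi,
    frac_multi = if (length(ok) > 0) x$n_multi / length(ok) else NA_real_,
    modal_n = if (x$n_multi > 0) {
      multi <- ok[ok > 1]
      as.integer(names(sort(table(multi), decreasing = TRUE))[1])
    } else NA_integer_,
    n_skipped = nrow(x$skipped))
}

#' @rdname profile_complexity
#' @param object A `complexity_profile`.
#' @export
autoplot.complexity_profile <- function(object, ...) {
  df <- dplyr::filter(object$records, !is.na(.data$n_affine))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n_affine))) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom)) +
    ggplot2::labs(x = "INDEL complexity (optimal alignments, affine model)",
                  y = "loci")
}

#' Write complexity records and histogram as TSV
#'
#' @param profile A `complexity_profile`.
#' @param prefix Output path prefix; writes `<prefix>_records.tsv` and
#'   `<prefix>_histogram.tsv`.
#' @return The two paths, invisibly.
#' @export
write_complexity <- function(profile, prefix) {
  rec <- dplyr::mutate(profile$records,
                       alts = vapply(.data$alts, paste, character(1),
                                     collapse = ","),
                       per_alt = NULL)
  p1 <- paste0(prefix, "_records.tsv")
  p2 <- paste0(prefix, "_histogram.tsv")
  readr::write_tsv(rec, p1)
  readr::write_tsv(profile$by_chrom, p2)
  invisible(c(p1, p2))
}
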