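#' Expected-agreement statistics and Chebyshev-Cantelli bound
#'
#' Given the per-trial complexities \eqn{n_i} (one trial per correctly
#' mapped read at a multiple-optimal locus) and the observed number of
#' agreeing trials, computes the expectation under a uniform choice among
#' co-optimal alignments, \eqn{\mu = \sum_i 1/n_i}, its variance
#' \eqn{\sigma^2 = \sum_i (1/n_i)(1 - 1/n_i)}, the deviation
#' \eqn{\lambda = X - \mu} (in counts), and the one-sided tail bound
#' \eqn{\sigma^2 / (\sigma^2 + \lambda^2)} used as a p-value bound for the
#' deviation in the observed direction.  A deviation below expectation
#' (\eqn{\lambda < 0}) is bounded the same way and flagged
#' `below_expectation`.  The degenerate case \eqn{\sigma^2 = 0, \lambda = 0}
#' is reported as 1.
#'
#' @param n_i Integer vector of per-trial complexities (all >= 1).
#' @param agreeing Observed number of agreeing trials.
#' @return A one-row tibble: `n_trials`, `agreeing`, `mu`, `sigma2`,
#'   `lambda`, `p_bound`, `below_expectation`.
#' @examples
#' agreement_stats(c(2, 2, 4), 3)
#' @export
agreement_stats <- function(n_i, agreeing) {
  stopifnot(is.numeric(n_i), all(n_i >= 1), length(agreeing) == 1,
            agreeing >= 0, agreeing <= length(n_i))
  p <- 1 / n_i
  mu <- sum(p)
  sigma2 <- sum(p * (1 - p))
  lambda <- agreeing - mu
  p_bound <- if (sigma2 == 0 && lambda == 0) 1 else sigma2 / (sigma2 + lambda^2)
  tibble::tibble(n_trials = length(n_i), agreeing = agreeing, mu = mu,
                 sigma2 = sigma2, lambda = lambda, p_bound = p_bound,
                 below_expectation = lambda < 0)
}

#' Compare aligner calls with the recorded variant profile
#'
#' For each alignment of a synthetic read, decides (1) whether the read is
#' correctly mapped (its mapped interval overlaps its own locus, see
#' [is_correctly_mapped()]) and (2) whether the alignment *agrees* with the
#' profile: some call extracted from its CIGAR equals the recorded
#' `(pos, REF, ALT)` of the read's locus and allele exactly.  A correctly
#' mapped read whose optimal alignment places the equivalent gap one repeat
#' unit away is therefore counted as a disagreement -- that distinction is
#' the subject of the analysis.  Records whose CIGAR cannot be reconciled
#' with the reference are flagged and excluded from trials.
#'
#' @param alignments Alignment tibble ([read_alignments_sam()] or
#'   [simulate_policy_alignments()]).
#' @param reads Read manifest from [make_reads()]; its `pos`/`ref`/`alt`
#'   columns are the recorded representation being tested.
#' @param reference Reference tibble.
#' @return A tibble with one row per alignment: `read_id`, `locus_id`,
#'   `allele_index`, `mapped_correctly`, `matched`, `flagged`, `calls`
#'   (list column of extracted call tibbles).
#' @export
compare_calls <- function(alignments, reads, reference) {
  man <- dplyr::select(reads, "read_id", "locus_id", "allele_index",
                       locus_chrom = "chrom", locus_pos = "pos",
                       locus_ref = "ref", locus_alt = "alt")
  j <- dplyr::inner_join(alignments, man, by = "read_id")
  if (nrow(j) < nrow(alignments)) {
    abort("some alignments have read ids absent from the manifest")
  }
  mapped <- is_correctly_mapped(alignments, reads)
  out <- purrr::map(seq_len(nrow(j)), function(k) {
    a <- j[k, ]
    flagged <- FALSE
    calls <- NULL
    matched <- FALSE
    if (mapped[[k]]) {
      calls <- tryCatch(sam_to_calls(a, reference), error = function(e) {
        flagged <<- TRUE
        NULL
      })
      if (!is.null(calls) && nrow(calls) > 0) {
        matched <- any(calls$chrom == a$locus_chrom &
                         calls$pos == a$locus_pos &
                         calls$ref == a$locus_ref &
                         calls$alt == a$locus_alt)
      }
    }
    tibble::tibble(read_id = a$read_id, locus_id = a$locus_id,
                   allele_index = a$allele_index,
                   mapped_correctly = mapped[[k]], matched = matched,
                   flagged = flagged,
                   calls = list(calls %||% tibble::tibble()))
  })
  out <- dplyr::bind_rows(out)
  # manifest reads with no alignment record (unmapped or skipped) still
  # count as trials for the correct-mapping percentage
  absent <- dplyr::anti_join(reads, alignments, by = "read_id")
  if (nrow(absent) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      read_id = absent$read_id, locus_id = absent$locus_id,
      allele_index = absent$allele_index,
      mapped_correctly = FALSE, matched = FALSE, flagged = FALSE,
      calls = replicate(nrow(absent), tibble::tibble(), simplify = FALSE)))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize agreement between an aligner and the variant profile
#'
#' Builds one report row per aligner/policy, shaped like a row of the
#' published comparison table: the correct-mapping percentage over all
#' reads, and -- restricted to loci with multiple optimal alignments
#' (`n_affine > 1`) -- the actual agreement, the agreement expected under a
#' uniform choice among co-optimal alignments, and the Chebyshev-Cantelli
#' p-value bound on their difference (see [agreement_stats()]).
#'
#' By default each correctly mapped read is one trial with success
#' probability `1/n_i` given by its locus complexity (`trial_unit =
#' "read"`, consistent with the 10-reads-per-locus design).  With
#' `trial_unit = "locus"` each locus with at least one correctly mapped
#' read is a single trial that agrees when more than half of its correctly
#' mapped reads agree.
#'
#' @param comparisons Tibble from [compare_calls()].
#' @param complexity A `complexity_profile` from [profile_complexity()]
#'   covering every locus in `comparisons`.
#' @param label Aligner/policy label for the report row.
#' @param trial_unit `"read"` (default) or `"locus"`.
#' @return An `agreement_summary` object.  Methods: `print()`, `tidy()`
#'   (per-locus breakdown), `glance()` (the report row as a one-row
#'   tibble).
#' @export
summarize_agreement <- function(comparisons, complexity, label = "aligner",
                                trial_unit = c("read", "locus")) {
  trial_unit <- match.arg(trial_unit)
  stopifnot(inherits(complexity, "complexity_profile"))
  cx <- dplyr::select(complexity$records, "locus_id", "n_affine")
  missing <- setdiff(unique(comparisons$locus_id), cx$locus_id)
  if (length(missing) > 0) {
    abort(sprintf("no complexity record for locus/loci: %s",
                  paste(utils::head(missing, 3), collapse = ", ")))
  }
  # loci with NA complexity (e.g. windows containing N) drop out below
  j <- dplyr::left_join(comparisons, cx, by = "locus_id")
  n_reads <- nrow(j)
  correct_mapped <- sum(j$mapped_correctly)

  # only multiple-optimal loci enter the agreement analysis
  multi <- dplyr::filter(j, .data$n_affine > 1, !.data$flagged)
  trials <- dplyr::filter(multi, .data$mapped_correctly)
  if (trial_unit == "locus") {
    trials <- dplyr::summarize(
      dplyr::group_by(trials, .data$locus_id, .data$n_affine),
      matched = mean(.data$matched) > 0.5, .groups = "drop")
  }
  N <- nrow(trials)
  agreeing <- sum(trials$matched)
  st <- if (N > 0) {
    agreement_stats(trials$n_affine, agreeing)
  } else {
    tibble::tibble(n_trials = 0L, agreeing = 0L, mu = NA_real_,
                   sigma2 = NA_real_, lambda = NA_real_, p_bound = NA_real_,
                   below_expectation = NA)
  }
  structure(
    list(label = label, trial_unit = trial_unit,
         n_reads = n_reads,
         correct_mapped = correct_mapped,
         correct_mapped_pct = if (n_reads > 0) 100 * correct_mapped / n_reads else NA_real_,
         N = N, agreeing = agreeing,
         actual_pct = if (N > 0) 100 * agreeing / N else NA_real_,
         mu = st$mu, sigma2 = st$sigma2,
         expected_pct = if (N > 0) 100 * st$mu / N else NA_real_,
         lambda = st$lambda, p_bound = st$p_bound,
         below_expectation = st$below_expectation,
         n_flagged = sum(j$flagged),
         trials = trials),
    class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement_summary> %s (trial unit: %s)\n", x$label,
              x$trial_unit))
  cat(sprintf("  reads: %d, correctly mapped: %d (%.1f%%)\n",
              x$n_reads, x$correct_mapped, x$correct_mapped_pct))
  if (x$N > 0) {
    cat(sprintf("  trials at multiple-optimal loci (N): %d\n", x$N))
    cat(sprintf("  actual agreement:   %d (%.1f%%)\n", x$agreeing,
                x$actual_pct))
    cat(sprintf("  expected agreement: %.2f (%.1f%%), sigma2 = %.3f\n",
                x$mu, x$expected_pct, x$sigma2))
    cat(sprintf("  lambda = %+.2f, Chebyshev-Cantelli p-value bound = %.3g%s\n",
                x$lambda, x$p_bound,
                if (isTRUE(x$below_expectation)) " (below expectation)" else ""))
  } else {
    cat("  no trials at multiple-optimal loci (N = 0)\n")
  }
  invisible(x)
}

#' @rdname summarize_agreement
#' @param x,object An `agreement_summary`.
#' @param ... Unused.
#' @export
tidy.agreement_summary <- function(x, ...) {
  if (x$trial_unit == "locus") return(x$trials)
  dplyr::summarize(dplyr::group_by(x$trials, .data$locus_id, .data$n_affine),
                   trials = dplyr::n(), agreeing = sum(.data$matched),
                   .groups = "drop")
}

#' @rdname summarize_agreement
#' @export
glance.agreement_summary <- function(x, ...) {
  tibble::tibble(
    label = x$label, trial_unit = x$trial_unit, n_reads = x$n_reads,
    correct_mapped = x$correct_mapped,
    correct_mapped_pct = x$correct_mapped_pct,
    N = x$N, agreeing = x$agreeing, actual_pct = x$actual_pct,
    mu = x$mu, sigma2 = x$sigma2, expected_pct = x$expected_pct,
    lambda = x$lambda, p_bound = x$p_bound,
    below_expectation = x$below_expectation)
}

#' @rdname summarize_agreement
#' @export
autoplot.agreement_summary <- function(object, ...) {
  df <- tibble::tibble(
    kind = factor(c("actual", "expected"), levels = c("actual", "expected")),
    pct = c(object$actual_pct, object$expected_pct))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kind, y = .data$pct)) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(title = object$label, x = NULL, y = "agreement (%)")
}

#' Simulate an aligner with a fixed tie-breaking policy
#'
#' Stands in for an external aligner: each read is aligned (fitting) to a
#' padded window around its own truth interval, all optimal alignments are
#' enumerated, and the policy picks one -- `"leftmost"` the alignment whose
#' first difference sits at the smallest genomic coordinate, `"rightmost"`
#' the largest, `"uniform"` a seeded uniform choice among all co-optimal
#' alignments.  At loci with a single optimum all three policies coincide.
#' Reads whose enumeration overflows `cap` are skipped and tallied in the
#' `n_skipped` attribute.
#'
#' @param reads Read manifest from [make_reads()].
#' @param reference Reference tibble.
#' @param policy `"leftmost"`, `"rightmost"` or `"uniform"`.
#' @param scheme A [scoring_scheme()].
#' @param seed Seed for the `"uniform"` policy (required for
#'   reproducibility; ignored otherwise).
#' @param pad Extra window padding (bp) beyond the truth interval, so that
#'   shifted gap placements near the interval edges stay in the window.
#' @param cap Passed to [enumerate_optimal()].
#' @return An alignment tibble (`read_id`, `flag`, `chrom`, `pos`, `end`,
#'   `mapq`, `cigar`, `seq`) suitable for [compare_calls()] or
#'   [write_alignments_sam()].
#' @export
simulate_policy_alignments <- function(reads, reference,
                                       policy = c("leftmost", "rightmost",
                                                  "uniform"),
                                       scheme = scoring_scheme(),
                                       seed = NULL, pad = 20L, cap = 1000L) {
  policy <- match.arg(policy)
  scheme <- as_scoring_scheme(scheme)
  run <- function() {
    n_skipped <- 0L
    rows <- vector("list", nrow(reads))
    for (k in seq_len(nrow(reads))) {
      r <- reads[k, ]
      chrom_len <- reference$length[[match(r$chrom, reference$chrom)]]
      wstart <- max(1L, r$truth_start - pad)
      wend <- min(chrom_len, r$truth_end + pad)
      window <- ref_sub(reference, r$chrom, wstart, wend)
      alns <- tryCatch(
        enumerate_optimal(r$sequence, window, scheme, mode = "fitting",
                          cap = cap),
        indelbias_overflow = function(e) NULL)
      if (is.null(alns)) { n_skipped <- n_skipped + 1L; next }
      # order candidates by the genomic coordinate of their first difference
      key <- vapply(seq_len(nrow(alns)), function(q) {
        cl <- calls_from_columns(alns$columns[[q]], r$sequence, window,
                                 offset = alns$window_offset[[q]],
                                 window_pos = wstart, chrom = r$chrom)
        if (nrow(cl) == 0) wstart + alns$window_offset[[q]] else min(cl$pos)
      }, numeric(1))
      ord <- order(key, alns$window_offset, alns$cigar)
      pick <- switch(policy,
                     leftmost = ord[[1]],
                     rightmost = ord[[length(ord)]],
                     uniform = ord[[sample.int(length(ord), 1L)]])
      a <- alns[pick, ]
      pos <- wstart + a$window_offset
      rows[[k]] <- tibble::tibble(
        read_id = r$read_id, flag = 0L, chrom = r$chrom, pos = pos,
        end = pos + (a$end - a$start), mapq = 60L, cigar = a$cigar,
        seq = r$sequence)
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "n_skipped") <- n_skipped
    out
  }
  if (policy == "uniform" && !is.null(seed)) {
    withr::with_seed(seed, run())
  } else {
    run()
  }
}
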