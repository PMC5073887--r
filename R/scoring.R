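#' Alignment scoring scheme
#'
#' Bundles the four parameters of the alignment model: the reward for an
#' identical base pair, the (negative) score of a substitution, and the two
#' gap costs of the affine model, under which a contiguous gap of length
#' \eqn{k} scores \eqn{\rho + k\,\epsilon} (`gap_open` \eqn{\rho} is the
#' extra cost of a gap's first base, `gap_extend` \eqn{\epsilon} the cost of
#' every gapped base).  Setting `gap_open = 0` selects the equal-penalty
#' model, in which every gapped base costs the same and split gaps are not
#' penalized relative to one contiguous gap.
#'
#' Defaults follow common short-read-aligner ratios (match 1, mismatch -4,
#' gap open -6, gap extend -1): gaps are expensive relative to matches, so at
#' tandem-repeat INDEL loci the co-optimal alignments differ only in where
#' the one gap is placed, which is the ambiguity this package quantifies.
#'
#' @param match Score of aligning two identical bases. Must exceed `mismatch`.
#' @param mismatch Score of aligning two different bases.
#' @param gap_open Extra cost \eqn{\rho \le 0} of a gap's first base.
#'   `0` selects the equal-penalty model.
#' @param gap_extend Cost \eqn{\epsilon \le 0} of every gapped base.
#'
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme()
#' scoring_scheme(gap_open = 0) # equal-penalty model
#' @export
scoring_scheme <- function(match = 1, mismatch = -4, gap_open = -6,
                           gap_extend = -1) {
  stopifnot(is.numeric(match), is.numeric(mismatch),
            is.numeric(gap_open), is.numeric(gap_extend),
            length(match) == 1, length(mismatch) == 1,
            length(gap_open) == 1, length(gap_extend) == 1)
  if (match <= mismatch) {
    abort("`match` must be greater than `mismatch`.")
  }
  if (gap_open > 0 || gap_extend > 0) {
    abort("`gap_open` and `gap_extend` must be <= 0 (scores are maximized).")
  }
  structure(
    list(match = match, mismatch = mismatch,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  model <- if (x$gap_open == 0) "equal-penalty" else "affine"
  cat(sprintf(
    "<scoring_scheme> match=%+g mismatch=%+g gap_open=%+g gap_extend=%+g (%s)\n",
    x$match, x$mismatch, x$gap_open, x$gap_extend, model))
  invisible(x)
}

as_scoring_scheme <- function(s) {
  if (inherits(s, "scoring_scheme")) return(s)
  abort("`scheme` must be created with scoring_scheme().")
}

# Equal-penalty companion of an affine scheme (same match/mismatch/extend).
simple_variant <- function(s) {
  scoring_scheme(s$match, s$mismatch, 0, s$gap_extend)
}
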