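#' Fill the equal-penalty alignment matrix
#'
#' Computes the single-matrix dynamic program in which every gapped base
#' costs `gap_extend` and there is no extra gap-opening cost:
#' \deqn{M[i,j] = \max(M[i-1,j-1] + match(x_i,y_j),\; M[i-1,j]+\epsilon,\;
#'   M[i,j-1]+\epsilon)}
#' with boundaries \eqn{M[i,0]=i\epsilon} and \eqn{M[0,j]=j\epsilon}
#' (`mode = "fitting"` instead sets \eqn{M[0,j]=0} so any window prefix may
#' be skipped for free).
#'
#' @param x Read sequence (non-empty string).
#' @param y Reference window sequence (non-empty string).
#' @param scheme A [scoring_scheme()] with `gap_open = 0`.
#' @param mode `"global"` (both sequences end to end) or `"fitting"` (read
#'   end to end, window overhangs free).
#' @return A `dp_state` object: matrices, model/mode tags and the optimal
#'   score (`$score`).
#' @examples
#' fill_simple("AA", "AAA", scoring_scheme(gap_open = 0))$score
#' @export
fill_simple <- function(x, y, scheme = scoring_scheme(gap_open = 0),
                        mode = c("global", "fitting")) {
  mode <- match.arg(mode)
  scheme <- as_scoring_scheme(scheme)
  if (scheme$gap_open != 0) {
    abort("fill_simple() requires scheme$gap_open == 0; use fill_affine().")
  }
  dp_fill(x, y, scheme, model = "simple", mode = mode)
}

#' Fill the affine-gap alignment matrices
#'
#' Computes the three-matrix (Gotoh) dynamic program in which a contiguous
#' gap of length \eqn{k} costs \eqn{\rho + k\epsilon}: `M` is the overall
#' optimum for each prefix pair, `X` the optimum for alignments whose last
#' column puts a read base against a gap, `Y` for alignments whose last
#' column puts a window base against a gap:
#' \deqn{X[i,j] = \max(M[i-1,j] + \rho + \epsilon,\; X[i-1,j] + \epsilon)}
#' \deqn{Y[i,j] = \max(M[i,j-1] + \rho + \epsilon,\; Y[i,j-1] + \epsilon)}
#' \deqn{M[i,j] = \max(M[i-1,j-1] + match(x_i,y_j),\; X[i,j],\; Y[i,j])}
#' Leading gaps cost \eqn{\rho + k\epsilon}; with `gap_open = 0` the model
#' degenerates to the equal-penalty one.
#'
#' @inheritParams fill_simple
#' @param scheme A [scoring_scheme()].
#' @return A `dp_state` object.
#' @examples
#' fill_affine("AA", "AAA",
#'             scoring_scheme(match = 1, mismatch = -4,
#'                            gap_open = -2, gap_extend = -1))$score
#' @export
fill_affine <- function(x, y, scheme = scoring_scheme(),
                        mode = c("global", "fitting")) {
  mode <- match.arg(mode)
  scheme <- as_scoring_scheme(scheme)
  dp_fill(x, y, scheme, model = "affine", mode = mode)
}

dp_fill <- function(x, y, scheme, model, mode) {
  if (!is.character(x) || length(x) != 1 || nchar(x) < 1 ||
      !is.character(y) || length(y) != 1 || nchar(y) < 1) {
    abort("`x` and `y` must be non-empty strings.")
  }
  x <- toupper(x); y <- toupper(y)
  mats <- gotoh_fill_cpp(x, y, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend,
                         model == "simple", mode == "fitting")
  n <- nchar(x); m <- nchar(y)
  score <- if (mode == "global") mats$M[n + 1L, m + 1L] else max(mats$M[n + 1L, ])
  structure(
    c(mats, list(x = x, y = y, scheme = scheme, model = model, mode = mode,
                 score = score)),
    class = "dp_state")
}

#' @export
print.dp_state <- function(x, ...) {
  cat(sprintf("<dp_state> %s model, %s mode, |x|=%d |y|=%d, optimal score %g\n",
              x$model, x$mode, nchar(x$x), nchar(x$y), x$score))
  invisible(x)
}

# condition signalled when the number of co-optimal alignments exceeds `cap`
overflow_error <- function(cap, n_found = NA_integer_) {
  abort(
    sprintf("ambiguity overflow: more than %d co-optimal alignments", cap),
    class = "indelbias_overflow", cap = cap, n_found = n_found)
}

NEG_VALID <- -1e29

#' Enumerate all optimal alignments
#'
#' Fills the dynamic-programming matrices for the model selected by the
#' scheme (`gap_open = 0` selects the equal-penalty single-matrix model,
#' otherwise the affine three-matrix model) and retraces *every* optimal
#' decision, returning the union of all distinct maximum-scoring alignments.
#' Ties are deliberately not broken -- they are the object of study.
#' Distinct traceback routes that produce an identical column sequence (this
#' can happen in the affine trace when `gap_open = 0`) are deduplicated.
#'
#' In `"fitting"` mode the read must be consumed end to end while the window
#' may overhang on either side at no cost; alignments are trimmed so that
#' their first and last column consume a read base.  In `"global"` mode both
#' sequences are consumed end to end.
#'
#' @param x Read sequence.
#' @param y Reference window sequence.
#' @param scheme A [scoring_scheme()].
#' @param mode `"fitting"` (default; read-in-window, the configuration used
#'   for complexity and agreement analyses) or `"global"`.
#' @param cap Maximum number of distinct optimal alignments; exceeding it
#'   raises an `indelbias_overflow` error rather than truncating.
#' @return A tibble with one row per optimal alignment: `alignment_id`,
#'   `window_offset` (window bases skipped before the first consumed one),
#'   `start`/`end` (1-based window positions of the consumed span), `score`,
#'   `columns` (list column over `"M"` match, `"X"` mismatch, `"I"`
#'   insertion of a read base, `"D"` deletion of a window base) and `cigar`.
#'   Attributes `score`, `model`, `mode`, `read`, `window`.
#' @examples
#' # three equal-scoring placements of a one-base deletion
#' enumerate_optimal("AA", "AAA", scoring_scheme(gap_open = 0),
#'                   mode = "global")
#' @export
enumerate_optimal <- function(x, y, scheme = scoring_scheme(),
                              mode = c("fitting", "global"), cap = 1000L) {
  mode <- match.arg(mode)
  scheme <- as_scoring_scheme(scheme)
  model <- if (scheme$gap_open == 0) "simple" else "affine"
  dp <- dp_fill(x, y, scheme, model, mode)
  n <- nchar(dp$x); m <- nchar(dp$y)
  xs <- strsplit(dp$x, "")[[1]]
  ys <- strsplit(dp$y, "")[[1]]
  M <- dp$M; X <- dp$X; Y <- dp$Y
  go <- scheme$gap_open; ge <- scheme$gap_extend
  tol <- 1e-6
  near <- function(a, b) (a > NEG_VALID) && (b > NEG_VALID) && abs(a - b) < tol
  subsc <- function(i, j) if (xs[[i]] == ys[[j]]) scheme$match else scheme$mismatch

  paths <- 0L
  budget <- max(cap * 10L, 10000L)
  add_col <- function(st, col) { st$cols <- c(st$cols, col); st }
  base_case <- function(j) {
    paths <<- paths + 1L
    if (paths > budget) overflow_error(cap)
    list(list(cols = character(0), start = j))
  }

  # --- affine trace: states are cells of M / X / Y; columns are built in
  # reverse and flipped at the end ---------------------------------------
  tM <- function(i, j, allow_del = TRUE) {
    if (i == 0L && (dp$mode == "fitting" || j == 0L)) return(base_case(j))
    out <- list()
    if (i > 0L && j > 0L && near(M[i + 1L, j + 1L], M[i, j] + subsc(i, j))) {
      col <- if (xs[[i]] == ys[[j]]) "M" else "X"
      out <- c(out, lapply(tM(i - 1L, j - 1L), add_col, col))
    }
    if (i > 0L && near(M[i + 1L, j + 1L], X[i + 1L, j + 1L])) {
      out <- c(out, tX(i, j))
    }
    if (allow_del && j > 0L && near(M[i + 1L, j + 1L], Y[i + 1L, j + 1L])) {
      out <- c(out, tY(i, j))
    }
    out
  }
  tX <- function(i, j) {
    out <- list()
    if (near(X[i + 1L, j + 1L], M[i, j + 1L] + go + ge)) {
      out <- c(out, lapply(tM(i - 1L, j), add_col, "I"))
    }
    if (i > 1L && near(X[i + 1L, j + 1L], X[i, j + 1L] + ge)) {
      out <- c(out, lapply(tX(i - 1L, j), add_col, "I"))
    }
    out
  }
  tY <- function(i, j) {
    out <- list()
    if (near(Y[i + 1L, j + 1L], M[i + 1L, j] + go + ge)) {
      out <- c(out, lapply(tM(i, j - 1L), add_col, "D"))
    }
    if (j > 1L && near(Y[i + 1L, j + 1L], Y[i + 1L, j] + ge)) {
      out <- c(out, lapply(tY(i, j - 1L), add_col, "D"))
    }
    out
  }

  # --- equal-penalty trace ----------------------------------------------
  tS <- function(i, j, allow_del = TRUE) {
    if (i == 0L && (dp$mode == "fitting" || j == 0L)) return(base_case(j))
    out <- list()
    if (i > 0L && j > 0L && near(M[i + 1L, j + 1L], M[i, j] + subsc(i, j))) {
      col <- if (xs[[i]] == ys[[j]]) "M" else "X"
      out <- c(out, lapply(tS(i - 1L, j - 1L), add_col, col))
    }
    if (i > 0L && near(M[i + 1L, j + 1L], M[i, j + 1L] + ge)) {
      out <- c(out, lapply(tS(i - 1L, j), add_col, "I"))
    }
    if (allow_del && j > 0L && near(M[i + 1L, j + 1L], M[i + 1L, j] + ge)) {
      out <- c(out, lapply(tS(i, j - 1L), add_col, "D"))
    }
    out
  }

  trace_from <- function(i, j, allow_del) {
    if (model == "simple") tS(i, j, allow_del) else tM(i, j, allow_del)
  }

  raw <- if (mode == "global") {
    trace_from(n, m, allow_del = TRUE)
  } else {
    opt <- dp$score
    terms <- which(abs(M[n + 1L, ] - opt) < tol) - 1L
    # trailing deletions are excluded from fitting alignments, so skip the
    # deletion branch at the terminal cell
    do.call(c, lapply(terms, function(j) trace_from(n, j, allow_del = FALSE)))
  }

  # columns accumulate deepest-first while the recursion unwinds, which is
  # already forward order
  cols_fwd <- lapply(raw, function(st) st$cols)
  starts <- vapply(raw, function(st) st$start, integer(1))
  keys <- paste0(starts, "|",
                 vapply(cols_fwd, paste, character(1), collapse = ""))
  keep <- !duplicated(keys)
  cols_fwd <- cols_fwd[keep]; starts <- starts[keep]
  if (length(cols_fwd) > cap) overflow_error(cap, length(cols_fwd))

  scores <- vapply(seq_along(cols_fwd), function(k) {
    rescore_alignment(cols_fwd[[k]], dp$x, dp$y, starts[[k]], scheme)
  }, numeric(1))
  if (!all(abs(scores - dp$score) < 1e-6)) {
    bad <- which(abs(scores - dp$score) >= 1e-6)[[1]]
    abort(sprintf(
      "internal error: traced alignment rescored %g != optimum %g (offset %d, cigar %s)",
      scores[[bad]], dp$score, starts[[bad]],
      columns_to_cigar(cols_fwd[[bad]])))
  }

  ref_span <- vapply(cols_fwd, function(cc) sum(cc %in% c("M", "X", "D")),
                     integer(1))
  cigars <- vapply(cols_fwd, columns_to_cigar, character(1))
  ord <- order(starts, cigars)
  out <- tibble::tibble(
    alignment_id = seq_along(ord),
    window_offset = starts[ord],
    start = starts[ord] + 1L,
    end = starts[ord] + ref_span[ord],
    score = scores[ord],
    columns = cols_fwd[ord],
    cigar = cigars[ord])
  attr(out, "score") <- dp$score
  attr(out, "model") <- model
  attr(out, "mode") <- mode
  attr(out, "read") <- dp$x
  attr(out, "window") <- dp$y
  out
}

#' Rescore an alignment column by column
#'
#' Independent of the dynamic program: walks the column sequence and sums
#' match/mismatch scores plus affine gap costs (each maximal run of one gap
#' type pays `gap_open` once plus `gap_extend` per base).  Used to verify
#' that every enumerated alignment attains the matrix optimum.
#'
#' @param columns Character vector over `"M"`, `"X"`, `"I"`, `"D"`.
#' @param x Read sequence.
#' @param y Window sequence.
#' @param offset Window bases skipped before the alignment starts.
#' @param scheme A [scoring_scheme()].
#' @return The alignment score.
#' @export
rescore_alignment <- function(columns, x, y, offset = 0L,
                              scheme = scoring_scheme()) {
  xs <- strsplit(toupper(x), "")[[1]]
  ys <- strsplit(toupper(y), "")[[1]]
  i <- 0L; j <- as.integer(offset); sc <- 0; prev <- ""
  for (col in columns) {
    if (col == "M" || col == "X") {
      i <- i + 1L; j <- j + 1L
      sc <- sc + if (xs[[i]] == ys[[j]]) scheme$match else scheme$mismatch
    } else if (col == "I") {
      i <- i + 1L
      sc <- sc + scheme$gap_extend + if (identical(prev, "I")) 0 else scheme$gap_open
    } else if (col == "D") {
      j <- j + 1L
      sc <- sc + scheme$gap_extend + if (identical(prev, "D")) 0 else scheme$gap_open
    } else {
      abort(sprintf("unknown alignment column '%s'", col))
    }
    prev <- col
  }
  if (i != length(xs)) abort("columns do not consume the whole read")
  sc
}

columns_to_cigar <- function(columns) {
  ops <- ifelse(columns %in% c("M", "X"), "M", columns)
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Format an alignment as two gapped text rows
#'
#' @param columns Alignment column vector.
#' @param x Read sequence.
#' @param y Window sequence.
#' @param offset Window bases skipped before the alignment starts.
#' @return Character vector of two strings (window row, read row).
#' @export
format_alignment <- function(columns, x, y, offset = 0L) {
  xs <- strsplit(toupper(x), "")[[1]]
  ys <- strsplit(toupper(y), "")[[1]]
  i <- 0L; j <- as.integer(offset)
  top <- character(0); bot <- character(0)
  for (col in columns) {
    if (col %in% c("M", "X")) {
      i <- i + 1L; j <- j + 1L
      top <- c(top, ys[[j]]); bot <- c(bot, xs[[i]])
    } else if (col == "I") {
      i <- i + 1L
      top <- c(top, "-"); bot <- c(bot, xs[[i]])
    } else {
      j <- j + 1L
      top <- c(top, ys[[j]]); bot <- c(bot, "-")
    }
  }
  c(paste(top, collapse = ""), paste(bot, collapse = ""))
}
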