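# Brute-force enumeration of all maximum-scoring monotone alignments.
# Independent of the package's dynamic program: explores every column
# sequence recursively with incremental affine scoring (each maximal run of
# one gap type costs gap_open + len * gap_extend; gap_open = 0 gives the
# equal-penalty model).  Alignments are canonicalized as
# "<window offset>|<column string>" so sets can be compared with the
# package's enumerate_optimal() output.

oracle_key <- function(offset, cols) {
  paste0(offset, "|", paste(cols, collapse = ""))
}

enumerate_keys <- function(alns) {
  vapply(seq_len(nrow(alns)), function(k) {
    oracle_key(alns$window_offset[[k]],
               alns$columns[[k]])
  }, character(1))
}

# mode "global": both strings consumed end to end.
# mode "fitting": the whole read consumed, any contiguous window block, and
# the first/last column must consume a read base (trimmed alignments).
oracle_enumerate <- function(x, y, scheme, mode = c("global", "fitting")) {
  mode <- match.arg(mode)
  xs <- strsplit(toupper(x), "")[[1]]
  ys <- strsplit(toupper(y), "")[[1]]
  n <- length(xs); m <- length(ys)
  go <- scheme$gap_open; ge <- scheme$gap_extend
  best <- -Inf
  keys <- character(0)
  cols <- character(n + m)

  finish <- function(offset, depth, sc) {
    if (sc > best + 1e-9) {
      best <<- sc
      keys <<- character(0)
    }
    if (abs(sc - best) < 1e-9) {
      keys <<- c(keys, oracle_key(offset, cols[seq_len(depth)]))
    }
  }

  recurse <- function(offset, i, j, depth, sc, prev) {
    # prune hopeless branches only on completed alignments: no pruning at
    # all keeps this a pure brute force
    if (i == n) {
      if (mode == "fitting") {
        finish(offset, depth, sc)
        return(invisible())
      }
      if (j == m) {
        finish(offset, depth, sc)
        return(invisible())
      }
      # global: only deletions remain
      add <- ge + if (identical(prev, "D")) 0 else go
      cols[depth + 1L] <<- "D"
      recurse(offset, i, j + 1L, depth + 1L, sc + add, "D")
      return(invisible())
    }
    if (j < m) {
      sub <- if (xs[[i + 1L]] == ys[[j + 1L]]) scheme$match else scheme$mismatch
      cols[depth + 1L] <<- if (xs[[i + 1L]] == ys[[j + 1L]]) "M" else "X"
      recurse(offset, i + 1L, j + 1L, depth + 1L, sc + sub, "S")
    }
    addI <- ge + if (identical(prev, "I")) 0 else go
    cols[depth + 1L] <<- "I"
    recurse(offset, i + 1L, j, depth + 1L, sc + addI, "I")
    if (j < m && !(mode == "fitting" && i == 0L)) {
      # fitting alignments may not start with a deletion
      addD <- ge + if (identical(prev, "D")) 0 else go
      cols[depth + 1L] <<- "D"
      recurse(offset, i, j + 1L, depth + 1L, sc + addD, "D")
    }
    invisible()
  }

  if (mode == "global") {
    recurse(0L, 0L, 0L, 0L, 0, "")
  } else {
    for (off in 0:m) {
      # window bases before `off` are skipped for free; the recursion walks
      # j relative to the full window
      recurse(off, 0L, off, 0L, 0, "")
    }
  }
  list(score = best, keys = sort(unique(keys)))
}

# Apply anchored calls (del/ins/snv) to a reference segment; used for the
# call round-trip property.
apply_calls_to_seq <- function(calls, seq, seq_pos = 1L) {
  if (nrow(calls) == 0) return(seq)
  # right to left; at equal positions apply indels before SNVs so the
  # anchored indel still sees the original reference base
  calls <- calls[order(-calls$pos, calls$type == "snv"), ]
  for (k in seq_len(nrow(calls))) {
    p <- calls$pos[[k]] - seq_pos + 1L
    ref <- calls$ref[[k]]; alt <- calls$alt[[k]]
    stopifnot(substr(seq, p, p + nchar(ref) - 1L) == ref)
    seq <- paste0(substr(seq, 1, p - 1L), alt,
                  substr(seq, p + nchar(ref), nchar(seq)))
  }
  seq
}

# deterministic random DNA
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
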