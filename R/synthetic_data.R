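#' Specification for the synthetic study inputs
#'
#' Describes a synthetic reference genome plus INDEL profile emulating the
#' structure of the real study inputs (a multi-chromosome reference with
#' tandem-repeat contexts, and a variant profile whose recorded INDEL
#' representation follows one alignment convention).  Generation is a pure
#' function of the spec: the same spec yields byte-identical files.
#'
#' Ambiguous loci embed an INDEL whose allele is one unit of a tandem
#' repeat: a deletion locus carries `c` reference copies of a unit of
#' length `L` and deletes one; an insertion locus carries `c - 1` copies
#' and inserts one.  Either way the locus has exactly `(c-1)*L + 1`
#' co-optimal alignments under the default affine scheme (verified at
#' generation time).  With the default ranges (`L` in 1..2, `c` in 2..3)
#' the ambiguous complexities are 2, 3, 3, 5 -- the distribution peaks
#' at 3.  Unambiguous loci are placed in repeat-free context and verified
#' to have a single optimal alignment.
#'
#' @param seed Integer seed; generation is deterministic given the spec.
#' @param n_chromosomes,chrom_length Shape of the reference.
#' @param n_loci Number of INDEL loci.
#' @param fraction_ambiguous Fraction of loci (rounded) placed in
#'   tandem-repeat context.
#' @param unit_len_range,copies_range Ranges (inclusive) for the repeat
#'   unit length `L` and copy number `c` of ambiguous loci.
#' @param n_snv Number of SNV-only rows added to the VCF (exercise for
#'   profile filtering; not part of the truth table).
#' @param recording_convention Which equivalent representation the VCF
#'   records: `"leftmost"`, `"rightmost"` or `"uniform"` (random per
#'   locus).
#' @return A `synthetic_spec` object.
#' @examples
#' synthetic_spec(seed = 7, n_loci = 20)
#' @export
synthetic_spec <- function(seed = 1L, n_chromosomes = 2L,
                           chrom_length = 25000L, n_loci = 100L,
                           fraction_ambiguous = 0.3,
                           unit_len_range = c(1L, 2L),
                           copies_range = c(2L, 3L),
                           n_snv = 5L,
                           recording_convention = c("leftmost", "rightmost",
                                                    "uniform")) {
  recording_convention <- match.arg(recording_convention)
  stopifnot(fraction_ambiguous >= 0, fraction_ambiguous <= 1,
            n_chromosomes >= 1, chrom_length > 0, n_loci >= 0, n_snv >= 0,
            length(unit_len_range) == 2, length(copies_range) == 2,
            unit_len_range[1] >= 1, copies_range[1] >= 2)
  structure(
    list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
         chrom_length = as.integer(chrom_length), n_loci = as.integer(n_loci),
         fraction_ambiguous = fraction_ambiguous,
         unit_len_range = as.integer(unit_len_range),
         copies_range = as.integer(copies_range),
         n_snv = as.integer(n_snv),
         recording_convention = recording_convention),
    class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> seed=%d, %d chromosome(s) x %d bp, %d loci (%.0f%% ambiguous), convention=%s\n",
    x$seed, x$n_chromosomes, x$chrom_length, x$n_loci,
    100 * x$fraction_ambiguous, x$recording_convention))
  invisible(x)
}

rot_unit <- function(unit, k) {
  L <- nchar(unit); k <- k %% L
  if (k == 0) unit else paste0(substr(unit, k + 1, L), substr(unit, 1, k))
}

#' Generate the synthetic reference, profile and ground truth
#'
#' Builds a seeded random reference, embeds `n_loci` INDEL loci
#' (tandem-repeat ambiguous or repeat-free unambiguous, see
#' [synthetic_spec()]), records each locus in the VCF representation
#' dictated by the recording convention, and returns the full ground truth:
#' the intended ambiguity, the number of co-optimal alignments, and the
#' complete set of equivalent anchored representations per locus.  Every
#' locus is verified at generation time by enumerating its optimal
#' alignments on a small window; surrounding bases are resampled if random
#' background accidentally creates extra optima.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory; when given, writes
#'   `reference.fa`, `profile.vcf` and `truth.tsv`.
#' @return A list: `reference` (tibble), `profile` (tibble shaped like
#'   [read_variant_profile()] output, ids matching what that function
#'   assigns on re-read), `truth` (tibble with `locus_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `type`, `ambiguous`, `true_n`, `rep_index`,
#'   `anchor_pos`, `equiv` list column of equivalent-representation
#'   tibbles), `spec`, and `paths` when `dir` was given.
#' @examples
#' gs <- generate_synthetic(synthetic_spec(seed = 7, n_loci = 10,
#'                                         chrom_length = 6000))
#' gs$truth[, c("locus_id", "type", "ambiguous", "true_n")]
#' @export
generate_synthetic <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  res <- withr::with_seed(spec$seed, generate_synthetic_impl(spec))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, "reference.fa")
    vcf <- file.path(dir, "profile.vcf")
    tsv <- file.path(dir, "truth.tsv")
    write_fasta(res$reference, fa)
    write_variant_profile(res$vcf_rows, res$reference, vcf)
    truth_flat <- dplyr::mutate(res$truth, equiv = vapply(
      .data$equiv,
      function(e) paste(sprintf("%d:%s>%s", e$pos, e$ref, e$alt),
                        collapse = ";"),
      character(1)))
    readr::write_tsv(truth_flat, tsv)
    res$paths <- c(fasta = fa, vcf = vcf, truth = tsv)
  }
  res
}

generate_synthetic_impl <- function(spec) {
  bases <- c("A", "C", "G", "T")
  flank_max <- 50L
  spacing <- 2L * flank_max + 12L
  margin <- flank_max + 20L
  vf <- 12L          # verification flank
  verify_scheme <- scoring_scheme()

  chroms <- sprintf("chr%d", seq_len(spec$n_chromosomes))
  seqs <- lapply(chroms, function(ch) {
    sample(bases, spec$chrom_length, replace = TRUE)
  })
  names(seqs) <- chroms

  # slot positions guarantee the minimum spacing between loci
  slots <- lapply(chroms, function(ch) {
    seq(margin, spec$chrom_length - margin, by = spacing)
  })
  total_needed <- spec$n_loci + spec$n_snv
  capacity <- sum(lengths(slots))
  if (total_needed > capacity) {
    abort(sprintf(
      "spec demands %d loci but only %d positions fit with %d bp spacing",
      total_needed, capacity, spacing))
  }
  # deal slots round-robin across chromosomes, then sample which get a locus
  slot_tbl <- dplyr::bind_rows(lapply(seq_along(chroms), function(i) {
    tibble::tibble(chrom = chroms[[i]], pos = slots[[i]])
  }))
  pick <- sort(sample.int(nrow(slot_tbl), total_needed))
  slot_tbl <- slot_tbl[pick, ]
  is_snv_row <- rep(FALSE, total_needed)
  if (spec$n_snv > 0) {
    is_snv_row[sample.int(total_needed, spec$n_snv)] <- TRUE
  }
  indel_idx <- which(!is_snv_row)
  n_amb <- round(spec$fraction_ambiguous * spec$n_loci)
  amb_flag <- rep(FALSE, spec$n_loci)
  if (n_amb > 0) amb_flag[sample.int(spec$n_loci, n_amb)] <- TRUE

  sample_base_not <- function(excl) sample(setdiff(bases, excl), 1L)
  sample_unit <- function(L) {
    if (L == 1L) sample(bases, 1L)
    else paste(sample(bases, L, replace = FALSE), collapse = "")
  }

  enum_n <- function(g, p, ref, alt) {
    # co-optimal fitting alignments of the alt-bearing read on a small window
    rl <- nchar(ref)
    u <- paste(g[(p - vf):(p - 1L)], collapse = "")
    v <- paste(g[(p + rl):(p + rl - 1L + vf)], collapse = "")
    window <- paste(g[(p - vf):(p + rl - 1L + vf)], collapse = "")
    nrow(enumerate_optimal(paste0(u, alt, v), window, verify_scheme,
                           mode = "fitting", cap = 2000L))
  }

  truth <- vector("list", spec$n_loci)
  amb_counter <- 0L
  for (q in seq_along(indel_idx)) {
    row <- slot_tbl[indel_idx[[q]], ]
    ch <- row$chrom; p <- row$pos
    g <- seqs[[ch]]
    ambiguous <- amb_flag[[q]]
    if (ambiguous) amb_counter <- amb_counter + 1L
    is_del <- (q %% 2L) == 1L

    ok <- FALSE
    for (attempt in seq_len(20L)) {
      if (ambiguous) {
        L <- sample(seq(spec$unit_len_range[1], spec$unit_len_range[2]), 1L)
        cc <- sample(seq(spec$copies_range[1], spec$copies_range[2]), 1L)
        unit <- sample_unit(L)
        copies_ref <- if (is_del) cc else cc - 1L
        reg_len <- copies_ref * L
        # redraw the neighbourhood, then install guard + repeat + guard
        lo <- p - vf; hi <- p + reg_len + 1L + vf
        g[lo:hi] <- sample(bases, hi - lo + 1L, replace = TRUE)
        uc <- strsplit(unit, "")[[1]]
        g[p] <- sample_base_not(uc[[L]])
        g[(p + 1L):(p + reg_len)] <- rep(uc, copies_ref)
        g[p + reg_len + 1L] <- sample_base_not(uc[[1]])
        true_n <- (cc - 1L) * L + 1L
        shifts <- 0L:((cc - 1L) * L)
        if (is_del) {
          equiv <- tibble::tibble(
            pos = p + shifts,
            ref = vapply(shifts, function(s) {
              paste(g[(p + s):(p + s + L)], collapse = "")
            }, character(1)),
            alt = g[p + shifts])
          type <- "del"
        } else {
          equiv <- tibble::tibble(
            pos = p + shifts,
            ref = g[p + shifts],
            alt = vapply(shifts, function(s) {
              paste0(g[p + s], rot_unit(unit, s))
            }, character(1)))
          type <- "ins"
        }
      } else {
        L <- sample(1:2, 1L)
        if (is_del) {
          lo <- p - vf; hi <- p + L + 1L + vf
          g[lo:hi] <- sample(bases, hi - lo + 1L, replace = TRUE)
          # block single-base slides in either direction
          g[p] <- sample_base_not(g[p + L])
          g[p + 1L] <- sample_base_not(g[p + L + 1L])
          equiv <- tibble::tibble(
            pos = p, ref = paste(g[p:(p + L)], collapse = ""), alt = g[p])
          type <- "del"
        } else {
          lo <- p - vf; hi <- p + 2L + vf
          g[lo:hi] <- sample(bases, hi - lo + 1L, replace = TRUE)
          ins <- paste(sample(bases, L, replace = TRUE), collapse = "")
          ic <- strsplit(ins, "")[[1]]
          g[p + 1L] <- sample_base_not(ic[[1]])
          g[p] <- sample_base_not(ic[[L]])
          equiv <- tibble::tibble(pos = p, ref = g[p],
                                  alt = paste0(g[p], ins))
          type <- "ins"
        }
        true_n <- 1L
      }
      n_obs <- enum_n(g, equiv$pos[[1]], equiv$ref[[1]], equiv$alt[[1]])
      if (n_obs == true_n) { ok <- TRUE; break }
    }
    if (!ok) {
      abort(sprintf(
        "could not realize a locus with %d optimal alignment(s) at %s:%d",
        true_n, ch, p))
    }
    seqs[[ch]] <- g
    rep_index <- switch(spec$recording_convention,
                        leftmost = 0L,
                        rightmost = nrow(equiv) - 1L,
                        uniform = sample.int(nrow(equiv), 1L) - 1L)
    rec <- equiv[rep_index + 1L, ]
    truth[[q]] <- tibble::tibble(
      chrom = ch, pos = rec$pos, ref = rec$ref, alt = rec$alt, type = type,
      ambiguous = ambiguous, true_n = true_n, rep_index = rep_index,
      anchor_pos = p, equiv = list(equiv))
  }
  truth <- dplyr::bind_rows(truth)

  # SNV rows exercise profile filtering; they carry no truth record
  snv_rows <- NULL
  if (spec$n_snv > 0) {
    snv_slots <- slot_tbl[is_snv_row, ]
    snv_rows <- dplyr::bind_rows(lapply(seq_len(nrow(snv_slots)), function(k) {
      ch <- snv_slots$chrom[[k]]; p <- snv_slots$pos[[k]]
      refb <- seqs[[ch]][[p]]
      tibble::tibble(chrom = ch, pos = p, ref = refb,
                     alts = list(sample(setdiff(bases, refb), 1L)))
    }))
  }

  reference <- tibble::tibble(
    chrom = chroms,
    sequence = unname(vapply(seqs, paste, character(1), collapse = "")),
    length = spec$chrom_length)

  chrom_rank <- match(truth$chrom, chroms)
  ord <- order(chrom_rank, truth$pos)
  truth <- truth[ord, ]
  truth$locus_id <- sprintf("locus%05d", seq_len(nrow(truth)))
  truth <- dplyr::relocate(truth, "locus_id")

  profile <- tibble::tibble(
    locus_id = truth$locus_id, chrom = truth$chrom, pos = truth$pos,
    ref = truth$ref, alts = lapply(truth$alt, identity),
    n_alts = 1L)

  vcf_rows <- dplyr::bind_rows(
    dplyr::select(profile, "chrom", "pos", "ref", "alts"),
    snv_rows)
  vcf_rows <- vcf_rows[order(match(vcf_rows$chrom, chroms), vcf_rows$pos), ]

  list(reference = reference, profile = profile, truth = truth,
       vcf_rows = vcf_rows, spec = spec)
}
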