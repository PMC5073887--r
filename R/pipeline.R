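#' Pipeline step: generate synthetic study inputs
#'
#' Thin wrapper over [generate_synthetic()] that always writes
#' `reference.fa`, `profile.vcf` and `truth.tsv` to `out_dir`.
#'
#' @param spec A [synthetic_spec()] (or a named list of its arguments).
#' @param out_dir Output directory.
#' @return The [generate_synthetic()] result, invisibly.
#' @export
run_generate <- function(spec, out_dir) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  res <- generate_synthetic(spec, dir = out_dir)
  inform(sprintf("wrote %s", paste(res$paths, collapse = ", ")))
  invisible(res)
}

#' Pipeline step: per-locus INDEL complexity
#'
#' Reads a reference and variant profile, computes [profile_complexity()],
#' and optionally writes the per-locus table and per-chromosome histogram
#' as TSV.
#'
#' @param fasta,vcf Input paths.
#' @param out_prefix Optional output path prefix (see [write_complexity()]).
#' @param scheme A [scoring_scheme()].
#' @param flank,cap Passed to [profile_complexity()].
#' @return The `complexity_profile`, invisibly.
#' @export
run_complexity <- function(fasta, vcf, out_prefix = NULL,
                           scheme = scoring_scheme(), flank = 50L,
                           cap = 1000L) {
  reference <- read_fasta(fasta)
  loci <- read_variant_profile(vcf, reference)
  prof <- profile_complexity(reference, loci, scheme, flank = flank,
                             cap = cap)
  if (!is.null(out_prefix)) write_complexity(prof, out_prefix)
  invisible(prof)
}

#' Pipeline step: build the read set
#'
#' Reads a reference and profile, builds the alt-bearing read set with
#' [make_reads()], and writes `<out_prefix>.fastq` plus
#' `<out_prefix>_manifest.tsv`.
#'
#' @param fasta,vcf Input paths.
#' @param out_prefix Output path prefix.
#' @param flank_min,flank_max,reads_per_locus Passed to [make_reads()].
#' @return The read manifest, invisibly.
#' @export
run_reads <- function(fasta, vcf, out_prefix, flank_min = 25L,
                      flank_max = 50L, reads_per_locus = 10L) {
  reference <- read_fasta(fasta)
  loci <- read_variant_profile(vcf, reference)
  reads <- make_reads(reference, loci, flank_min = flank_min,
                      flank_max = flank_max,
                      reads_per_locus = reads_per_locus)
  write_reads_fastq(reads, paste0(out_prefix, ".fastq"))
  write_manifest(reads, paste0(out_prefix, "_manifest.tsv"))
  inform(sprintf("wrote %d reads to %s.fastq", nrow(reads), out_prefix))
  invisible(reads)
}

#' Pipeline step: agreement report
#'
#' Scores alignments -- either simulated with a tie-breaking policy or
#' ingested from an external SAM file -- against the recorded variant
#' profile and produces one report row (correct-mapping %, actual and
#' expected agreement %, Chebyshev-Cantelli p-value bound).  Exactly one of
#' `policy` and `sam` must be given.
#'
#' @param fasta,vcf Input paths.
#' @param manifest Path to the read manifest written by [run_reads()].
#' @param policy `"leftmost"`, `"rightmost"` or `"uniform"`, or `NULL` when
#'   `sam` is given.
#' @param sam Path to a SAM file with alignments of the manifest reads, or
#'   `NULL` when `policy` is given.
#' @param label Report row label (defaults to the policy or SAM basename).
#' @param scheme A [scoring_scheme()].
#' @param seed Seed for the `"uniform"` policy.
#' @param flank,cap Passed to [profile_complexity()].
#' @param out Optional path for the TSV report row.
#' @return The `agreement_summary`, invisibly.
#' @export
run_agreement <- function(fasta, vcf, manifest, policy = NULL, sam = NULL,
                          label = NULL, scheme = scoring_scheme(),
                          seed = NULL, flank = 50L, cap = 1000L,
                          out = NULL) {
  if (is.null(policy) == is.null(sam)) {
    abort("give exactly one of `policy` or `sam`")
  }
  reference <- read_fasta(fasta)
  loci <- read_variant_profile(vcf, reference)
  reads <- read_manifest(manifest)
  alignments <- if (!is.null(policy)) {
    simulate_policy_alignments(reads, reference, policy, scheme,
                               seed = seed, cap = cap)
  } else {
    read_alignments_sam(sam)
  }
  label <- label %||% (policy %||% basename(sam))
  prof <- profile_complexity(reference, loci, scheme, flank = flank,
                             cap = cap)
  cmp <- compare_calls(alignments, reads, reference)
  summ <- summarize_agreement(cmp, prof, label = label)
  if (summ$N == 0) {
    inform("no correctly mapped reads at multiple-optimal loci (N = 0)")
  }
  if (!is.null(out)) readr::write_tsv(glance(summ), out)
  print(summ)
  invisible(summ)
}
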