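---
title: "Alignment ambiguity and aligner bias at INDEL loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment ambiguity and aligner bias at INDEL loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelbias)
```

## The problem

A variant profile records each INDEL as one anchored `(POS, REF, ALT)`
entry. Inside tandem repeats, however, a read carrying the alternative
allele often has several *equally* optimal alignments to the reference,
and each of them implies a different anchored call: deleting one `CA`
from `T(CA)3G` can be written as `TCA>T`, `CAC>C`, `ACA>A`, ... at five
different positions. All of these are the same biological event; the one
that reaches the catalog is decided by the aligner's tie-breaking rule.
`indelbias` measures how often this happens (per-locus *INDEL
complexity*), and tests whether a recorded profile carries the signature
of such a rule (the *agreement* statistic with a Chebyshev–Cantelli
p-value bound).

## Alignment models

Reads are aligned to reference windows by exact dynamic programming,
maximizing the score under a `scoring_scheme(match, mismatch, gap_open,
gap_extend)`:

* **Equal-penalty model** (`gap_open = 0`): a single matrix `M` with
  `M[i,j] = max(M[i-1,j-1] + match(x_i, y_j), M[i-1,j] + eps,
  M[i,j-1] + eps)`, boundaries `M[i,0] = i*eps`, `M[0,j] = j*eps`.
  Every gapped base costs `eps`; split gaps cost the same as one
  contiguous gap.
* **Affine model**: the three-matrix (Gotoh) recursion in which `X` holds
  alignments ending with a read base against a gap, `Y` alignments ending
  with a window base against a gap, and `M` the overall optimum, so that
  a contiguous gap of length *k* costs `rho + k*eps`. Because `M` takes
  the maximum over the diagonal case and both gap matrices, an insertion
  run directly adjacent to a deletion run is representable — each run
  pays its own opening. The column-wise rescoring used in tests and the
  brute-force oracle follow exactly this rule, so the two routes share
  one semantics.

Since scores are maximized, all penalties are non-positive; the
boundaries are gap-scored prefixes consistent with maximization. With
`gap_open = 0` the affine recursion degenerates to the equal-penalty
model (a tested invariant).

Two alignment *modes* are exposed. `"global"` consumes both sequences end
to end. `"fitting"` — the mode used throughout the analyses — consumes
the read end to end while the window may overhang on either side at no
cost; this matches aligning a short read into a padded genomic window.
Fitting alignments are *trimmed*: their first and last column must
consume a read base. Leading or trailing window deletions would only add
negative gap score next to a free overhang, so with `gap_extend < 0` they
are never optimal anyway; trimming makes the definition unambiguous for
degenerate schemes as well.

### Enumerating *all* optima

`enumerate_optimal()` retraces every cell decision that attains the
maximum, recursively, and returns the union of all distinct
maximum-scoring alignments. No ties are broken — ties are the quantity
being studied. Distinct traceback routes that yield an identical column
sequence (possible in the affine trace when `gap_open = 0`) are
deduplicated on the column string plus window offset. Every returned
alignment is rescored column by column and must hit the matrix optimum
exactly; a count above `cap` (default 1000) raises an explicit
"ambiguity overflow" condition rather than truncating silently.

The enumeration is validated against an independent brute-force oracle —
exhaustive recursion over every monotone column sequence with incremental
scoring — over all-pairs samples of short `{A,C}` strings, for both
models, both modes and several schemes.

### Scoring defaults

The analysis source does not pin scoring values, and published counts at
genome scale are parameter-sensitive. The package defaults to `match =
+1`, `mismatch = -4`, `gap_open = -6`, `gap_extend = -1` — the ratio
family used by mainstream short-read aligners — and every function takes
an explicit scheme. Under these defaults, co-optimal sets at
tandem-repeat INDELs consist of the distinct placements of one gap, which
is the ambiguity of interest.

## From alignments to calls

Each maximal run of deletion columns becomes one anchored deletion call
(`REF` = last consumed window base + deleted bases, `ALT` = that anchor
base), each insertion run one anchored insertion call, and each mismatch
column one SNV call; calls are sorted by position. A gap run at the very
start of the consumed span is anchored on the preceding window base when
one exists and is an error otherwise — callers therefore pad windows one
base left of any position where a gap can occur. The same conventions are
applied to external SAM records (CIGAR ops `M/=/X/I/D/S`; soft clips
consume read bases silently), so simulated and ingested alignments flow
through one call path.

## The read factory

For every locus and every alternative allele, reads `r = u·alt·v` are
built with `u`, `v` taken verbatim from the reference at
`reads_per_locus = 10` symmetric flank lengths evenly spaced across
`[25, 50]` bp, giving read lengths `|u| + |alt| + |v|` of roughly
50–100 bp and 10× coverage of each locus. How the original design arrived
at "exactly 10 reads" per locus is not stated; ten evenly spaced flank
lengths per (locus, allele) pair is the simplest deterministic reading,
makes the biallelic case exactly 10, and scales multi-allelic loci by
allele as intended. Reads carry no sequencing error: the question under
study is tie-breaking among exact co-optima, and error would only blur
it. A read is *correctly mapped* when its mapped interval overlaps the
locus interval `[POS, POS + |REF| - 1]` by at least one base.

## INDEL complexity

`locus_complexity()` aligns the alt-bearing read (fitting mode) against
the locus window padded by `flank` (default 50 bp) on each side and
counts co-optimal alignments under the affine scheme (`n_affine`) and its
equal-penalty companion (`n_simple`). Complexity is invariant to the
flank once it exceeds the repeat context (tested at 25 vs 50 bp). Two
conventions required a decision:

* **Multi-allelic loci**: complexity is the *maximum* over alternative
  alleles — an aligner faces each read separately, and the maximum is the
  worst-case ambiguity; per-allele counts are retained.
* **Counting unit**: distinct optimal *alignments*, not distinct
  resulting call sets, matching the expected-agreement arithmetic
  (`p_i = 1/n_i`).

Windows containing `N` are excluded (match scoring for `N` is undefined
in the model) and reported as such.

## The agreement statistic

Restricted to loci with multiple optima (`n_affine > 1`), every correctly
mapped read is one trial that *agrees* when its extracted call equals the
recorded `(POS, REF, ALT)` exactly. Under unbiased (uniform) tie-breaking
each trial agrees with probability `1/n_i`, so

* expected agreement `mu = sum(1/n_i)`,
* variance `sigma2 = sum((1/n_i) * (1 - 1/n_i))`,
* observed deviation `lambda = X - mu` (in counts; percentages are
  display-only),
* p-value bound `sigma2 / (sigma2 + lambda^2)` (Chebyshev–Cantelli).

The bound is applied to the deviation in the observed direction: an
aligner far *below* expectation (the high-disagreement group) receives
the same small bound, flagged `below_expectation`, which reproduces the
small p-values reported for both the high-agreement and the
high-disagreement aligner groups. The degenerate case `sigma2 = 0,
lambda = 0` is reported as 1.

Trials default to reads (`trial_unit = "read"`, consistent with the 10×
design); `trial_unit = "locus"` collapses each locus with at least one
correctly mapped read into a single majority-vote trial, for comparison.

## Synthetic data and what it does (not) show

`generate_synthetic()` builds the study inputs with full ground truth:
i.i.d. uniform background sequence; ambiguous loci embedding an INDEL
whose allele is one unit of a tandem repeat (a deletion locus carries `c`
copies and deletes one, an insertion locus `c-1` copies and inserts one,
giving exactly `(c-1)*L + 1` co-optimal alignments either way); guard
bases that stop the repeat from extending; unambiguous loci in repeat-free
context. Every locus is verified at generation time by enumeration on a
small window, with local resampling when random background accidentally
creates extra optima — so ambiguity exists exactly where intended. With
the default ranges (`L` in 1–2, `c` in 2–3) the ambiguous complexity
distribution is `{2, 3, 3, 5}`-valued with mode 3, mirroring the reported
peak at 3. Minimum locus spacing is `2*50 + 12` bp so no read or window
spans two loci. The recorded VCF representation follows the chosen
convention: `leftmost` (equals standard left-alignment normalization — a
tested invariant), `rightmost`, or `uniform`.

The generator emulates repeat-context ambiguity, not real genomes: no
SNV linkage, no allele-frequency structure, no sequencing error, no
chromosome-scale heterogeneity. Passing tests demonstrate the method's
correctness and the bias dichotomy mechanism, not genome-wide counts,
which depend on unstated scoring parameters and full-scale data and are
out of scope here.

Simulated aligner policies (`leftmost`, `rightmost`, seeded `uniform`)
stand in for external aligners; real aligner output can be supplied as
SAM instead. On a leftmost-recorded profile the leftmost policy agrees
~100 % and the rightmost ~0 %, both with tail bounds below 0.01 — the
high-agreement vs high-disagreement dichotomy — while the uniform policy
on a uniform-recorded profile stays within 3 binomial standard deviations
of `mu` (both are acceptance-tested).

## Numerical choices and problem sizes

* Score comparisons in the traceback use an absolute tolerance of 1e-6;
  all default scores are small integers, so ties are exact.
* The alignment cap is 1000 by default; overflow is an error carrying
  the cap, and profile-level drivers log and skip such loci.
* Coordinates are 1-based fully closed (VCF convention) everywhere; the
  single conversion happens at SAM ingestion/emission.
* Reverse-strand SAM records (flag 16) are handled by relying on SAM's
  convention that SEQ is stored in reference orientation.
* Test and acceptance runs use 100-locus profiles (1000 reads), where
  the full generate → reads → complexity → policies → agreement pipeline
  completes in well under a minute; the brute-force oracle is exercised
  on string pairs up to length 8 (global) and 6 (fitting), the largest
  sizes where exhaustive enumeration stays fast.

## Known limitations

* Genome-scale replication of multiple-optimal counts is inherently
  scoring-parameter-sensitive; the package reports counts for an explicit
  scheme rather than claiming universal numbers.
* The affine model does not score `N` bases; windows containing `N` are
  excluded rather than guessed.
* `enumerate_optimal()` is exact and exhaustive, not banded or
  vectorized; it is meant for locus windows (~100–200 bp), not
  chromosome-length alignments.
* The p-value is an upper *bound* (Chebyshev–Cantelli), not an exact
  tail probability; it is conservative by design.
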