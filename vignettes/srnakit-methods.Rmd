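---
title: "srnakit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srnakit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnakit)
```

## The problem

Small RNA sequencing of a species with sparse annotation (pig, and livestock
generally) poses two coupled problems. First, a small RNA library is not a
miRNA library: fragments of rRNAs, tRNAs and other non-coding RNAs fall in the
same 16–100 nt size window and, when annotation is thin, are easily
mislabelled as miRNAs. Second, mature miRNAs are expressed as families of end
variants (isomiRs) — 5'/3' additions and deletions arising from imprecise
hairpin cleavage (templated changes, explained by the precursor sequence) and
from post-transcriptional tailing (non-templated changes, classically 3'
adenylation or uridylation). Characterizing these requires exact, auditable
coordinate arithmetic against the precursor, not just a mapped/unmapped flag.

srnakit implements the whole path from raw FASTQ to isomiR tables:

1. **preprocess** — 3' adapter clipping that *keeps only clipped reads*
   (an unclipped 126 nt read cannot be a genuine small RNA insert), and
   removal of a single leading `N` (a first-cycle artifact of some
   Illumina instruments that affects on the order of 15% of reads).
2. **counttable** — collapsing reads to unique sequences per sample,
   joining samples on the sequence string, and a CPM low-evidence filter
   (retain a sequence iff CPM ≥ cutoff in ≥ *k* libraries).
3. **annotate** — exact full-length search of each unique sequence
   against a prioritized multi-species reference collection
   (mature/precursor miRNAs, rRNA, tRNA, piRNA clusters, mRNA, other
   ncRNA, across the target species plus human and cattle), with a
   false-miRNA exclusion rule: a candidate also occurring in a pig tRNA
   or a pig/human rRNA is removed from the miRNA class.
4. **isomir** — grouping sequences under their precursor and canonical
   mature, calling 5'/3' offsets and non-templated tails, ranking
   variants by expression, and producing the standard partition,
   length-histogram, base-composition and rank-1 summaries.
5. **report** — per-dataset expression profiles, top-N tables and
   cross-dataset enrichment comparison.
6. **synth** — a fully ground-truthed generator so all of the above can
   be tested without any external data.

## Annotation model

The reference search returns every ungapped, mismatch-free occurrence of the
**full query** inside a reference sequence. This is the effective acceptance
criterion that remains when a short-read BLAST search is post-filtered to
discard any alignment with a mismatch or gap, and it makes the matching
engine exactly testable: the test suite checks it hit-for-hit against a naive
substring scan. `Biostrings::matchPDict` provides the engine; a query
containing `N` never matches (no wildcard semantics), and queries shorter
than 16 nt are always reported unannotated to guard against spurious exact
matches of very short fragments.

Strand handling: mature and precursor miRNAs (and other transcript classes)
are directional and matched plus-strand only; for genomic-context classes
(piRNA clusters, mRNA loci) the reverse complement of the query is searched
too, reported with `strand == "-"`.

Class resolution applies the exclusion rule *first*: a sequence with both a
miRNA hit and a pig-tRNA or pig/human-rRNA hit is assigned the contaminant
class with `excluded_as` recording the reason. Remaining multi-class
sequences follow a fixed priority (miRNA > tRNA > rRNA > piRNA cluster >
mRNA > other ncRNA) — the exclusion rule is principled; the residual
priority is a deterministic labelling convention, not a biological claim.
miRNA labels follow the origin precedence pig-known > pig-predicted >
cattle-orthologue > human-orthologue, with one refinement: a *mature* hit
always outranks a precursor-only hit, so a sequence matching an orthologue
mature that happens to lie inside a pig precursor is labelled as a novel
mature of a known gene rather than as a pig precursor fragment. The strict
exclusion rule is exact occurrence; `annotate_sequences(edit1_exclusion =
TRUE)` additionally removes miRNA candidates within edit distance 1 of a
contaminant subsequence, off by default because "highly similar" has no
canonical definition.

A consequence worth stating plainly: a sequence carrying a non-templated
tail matches *no* reference exactly and therefore stays unannotated at this
stage. The isomiR caller is deliberately decoupled from annotation —
`call_isomir()` accepts any candidate sequence against any group — and the
generator's end-to-end check scores tail recovery through that route. In a
real study the practical recipe is to seed groups from exactly annotated
sequences and call remaining unannotated sequences against the groups of
their nearest exactly-matching prefix; automating that shortlist is future
work, not part of the tested surface.

## IsomiR calling

All coordinates are 0-based half-open, reported in the mature strand's 5'→3'
orientation. For a query and its group (precursor plus canonical mature at
`[mature_start, mature_end)`), the caller finds the **maximal contiguous
core** of the query occurring exactly in the precursor and overlapping the
canonical locus. Because annotation is mismatch-free, end offsets and
non-templated tails are the only degrees of freedom, so a deterministic
end-anchored extension resolves the alignment without a multiple-sequence
aligner and is exactly reproducible. Offsets read off the core coordinates
(`five_offset < 0`: templated 5' addition; `> 0`: 5' deletion;
`three_offset` symmetric at the 3' end) and the residual query prefix/suffix
are the non-templated tails — the maximal end runs that the precursor cannot
explain; an addition beyond the precursor boundary is always non-templated.
Every record satisfies the reconstruction invariant
`five_tail + precursor[aligned_start:aligned_end] + three_tail == query`,
asserted record-by-record in the tests.

Numerical choices:

* ambiguous placements (several maximal cores over the locus) resolve to
  the placement minimizing `|five_offset| + |three_offset|`, ties to the
  smaller `|five_offset|`, then leftmost — deterministic and
  order-independent;
* cores shorter than 16 nt are rejected; such sequences are reported as
  unassignable rather than force-fitted;
* expression ranks are dense with lexicographic tie-break on the
  sequence, so outputs diff cleanly between runs;
* a mature with no available precursor (an orthologue mature whose
  hairpin is not annotated) forms a *mature-only* group: offsets are
  computed against the mature's own ends and templating cannot be
  verified, so `templated` is `NA` and these records are reported
  separately, never merged into the main partition;
* multi-mapped sequences (matures contained in several precursors)
  contribute to every matching group and are flagged; the per-miRNA
  aggregation documents the resulting double counting instead of
  silently dropping reads.

## The CPM filter

CPM is `count / library_size x 1e6` with library sizes frozen at their
post-preprocessing values — filtering never re-normalizes, otherwise the
meaning of the cutoff would drift as rows are removed. The comparison is
inclusive (`>=`). `cutoff_from_reads()` converts an average per-library read
count into its CPM equivalent (20 reads in a 7.58 M-read library ≈ 2.64
CPM), which is the convenient way to set a cutoff before the mean library
size is known precisely.

## What the generator emulates — and what it does not

`sim_config()` defaults are a fixed statement of the world being emulated,
not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| mod-class probabilities | 3'-only 0.54, both 0.29, 5'-only 0.10, canonical 0.07 | observed read-class mix in deep blastocyst libraries |
| templated-addition probability | 5' 0.54, 3' 0.37 | derived from observed non-templated counts per end |
| tail base bias | A 0.35, C 0.20, G 0.20, T 0.25 | 3' adenylation dominates non-templated tailing |
| tail length | geometric (p = 0.6), max 4 | one- and two-base tails dominate |
| leading-N probability | 0.15 | HiSeq 4000 first-cycle artifact rate |
| read length / adapter | 126 nt / Illumina Universal Adapter | library chemistry being emulated |
| mature length | 16–27 nt, peak 23 (discretized normal, sd 1.5) | canonical mature length distribution |
| contaminant read fractions | rRNA 0.70, tRNA 0.10, piRNA 0.005, mRNA 0.005, other 0.06 | read-level class composition of un-size-selected libraries |
| group abundance | power law, exponent 1.2 | dominant miRNA ≈ 22% of miRNA reads |
| counts | negative binomial, size 5 | overdispersed biological replicates |
| scale | 200 precursors, 4 samples x 25 000 reads | desk-scale calibration used by the whole test suite |

Deliberate simplifications, hence what a green test does **not** establish:

* precursors are random sequences with the mature window placed at least
  `max_offset + max_tail` from each end; there is no hairpin folding and
  no thermodynamic realism (hairpin-based novel-gene prediction is out of
  scope);
* non-templated tail bases are sampled conditional on differing from the
  precursor base at that position, which makes truth labels unambiguous —
  real tailing has no such guarantee, so real recovery rates are an upper
  bound;
* the leading `N` is *prepended*, so trimming restores the true insert
  exactly. On the real instrument the artifact replaces the first base,
  and its removal genuinely shortens the read — one reason real libraries
  show an excess of apparent one-base 5' deletions that the generator
  will not reproduce;
* there is no sequencing-error model and no quality-score realism;
  quality strings are carried but never used;
* per-end deletions are capped so the remaining core stays ≥ 16 nt
  (shorter variants would be unassignable by construction); for the
  shortest matures this slightly converts deletions into additions;
* the full-scale design (36 libraries of 8–32 M reads) is not
  desk-reproducible; the defaults scale it down by roughly three orders
  of magnitude while keeping every rate parameter as stated above.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
report <- end_to_end_check(cfg)
glance(report)
#> # A tibble: 1 x 4
#>   class_accuracy exclusion_rate false_exclusions isomir_recovery
#> 1              1              1                0               1
```

On the default simulation the pipeline annotates every exactly-matchable
sequence to its true class, excludes all 17 planted miRNA/tRNA and
miRNA/rRNA dual hits with zero false exclusions, and recovers the planted
(offset, tail) labels for 100% of evaluable reads.

## Known limitations

* Exact full-length matching is a *post-filter model* of a short-read
  BLAST search; genuinely gapped or partial alignments are out of scope.
* Differential expression is intentionally not implemented; the package
  exports raw integer matrices (`as_edger_counts()`) for edgeR.
* The enrichment labels in `compare_profiles()` use a configurable fold
  threshold (default 3x, absence floored at 0.01%) — a reporting
  convention of this package, not an inferential procedure.
* Annotation of sequences with non-templated tails requires candidate
  shortlisting outside the exact-match engine, as discussed above.
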