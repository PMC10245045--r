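---
title: "Isoform-aware self-correction of transcriptome long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform-aware self-correction of transcriptome long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocorr)
```

## The model

Self-correction treats every long read in turn as a *template* and
recruits overlapping reads as *candidates*. After banded global alignment
and normalisation (each mismatch split into a deletion column followed by
an insertion column, so a column never holds two differing bases), the
evidence at each template position is a tally of four events per
candidate: it matches the template base, deletes it, inserts bases right
after it, or — after masking — is *skipped*.

The isoform problem enters through the masking step. Reads from two
isoforms of the same gene align well along shared exons and catastrophically
across a skipped exon. A sliding window over the alignment columns scores

$$\mathrm{identity} = \frac{\mathrm{match\_base\_num}}{\mathrm{window\_length}}$$

and when the window's identity is at or below the threshold (defaults:
window length 5, threshold 0.5), the candidate character at the window's
anchor column is replaced by `N` in a copy of the candidate row. A
low-identity stretch therefore masks every character whose window reaches
into it. Masked characters at template-consuming columns are counted as
*skips*; masked inserted characters are simply discarded.

Two consensus tables result: the *normal* table built from the unmasked
rows and the *modify* table built from the masked rows (the only one with
skip counts). Correction boundaries keep the template interval where
coverage, counted as `match + insert + skip`, reaches `min_coverage`; the
skip term matters because heavily masked positions are still covered.

A position is *structurally divergent* when `skip > coverage * scov`
(default `scov = 0.1`): most of its masked evidence is then interpreted as
reads from a different exon structure rather than random noise, and the
position's type is decided from the modify table — i.e. from
same-structure evidence only. Otherwise the normal table decides.

## Position typing

The type of each position (MAT, INS, DEL, UNDEFINE) drives the area
partition. The typing policy is deliberately isolated in one small
function so it can be swapped; the package uses observable-population
majorities:

* `INS` when the number of candidates inserting immediately after the
  position reaches half the uncensored covering support `m + d`. Insertion
  events are *censored* for masked candidates (their inserted characters
  were discarded), so skips do not belong in this denominator.
* otherwise `DEL` when deletions exceed half the full covering population
  `m + d + skip`. Deletions are observed for every candidate — gap
  characters are never masked — so here skips do count, and a thinned
  match count cannot hand deletions a spurious majority. Ties keep the
  template base.
* otherwise `MAT`; `UNDEFINE` when there is no evidence at all.

An earlier draft used a three-way strict majority between `m`, `i` and
`d`. That rule is structurally biased: a candidate can match a position
*and* insert after it, so at a true template deletion the match and
insertion counts are nearly equal and the position is typed MAT about half
the time, leaving the missing base unrepaired. Treating insertion support
as orthogonal to through-going support removes that failure mode.

## Areas and consensus

Maximal runs of MAT/DEL positions are *simple areas*: MAT positions emit
the majority-voted base (ties resolve to the template base, then
alphabetically; under normalised alignments the votes are in practice the
template base), DEL positions emit nothing. Runs containing INS or
UNDEFINE positions are *complex areas*, extended to their flanking MAT
anchors; the anchors belong to the complex area and are emitted exactly
once, which keeps area joins free of duplicated or dropped bases.

Complex areas are corrected on a directed acyclic alignment graph: every
candidate row (and the template row) contributes a chain of
`(position, insertion rank, base)` nodes; coincident nodes merge, parallel
edges sum their weights, and the consensus is the source-to-sink path of
maximum total weight, computed by dynamic programming in topological
order. Determinism is guaranteed by fixed tie-breaking: template-supporting
edges first, then the alphabetically smaller predecessor base, then the
smaller node id.

Two refinements matter in practice:

* **Masked-edge removal.** When any `N` appears in an area's rows, the
  area is a structural-change area: rows are split at masked characters,
  the fragments contribute internal edges only, and only fragments that
  reach their row's own ends attach to the source/sink sentinels. The
  majority isoform's exon-insertion path therefore falls out of the graph
  for a minor-isoform template.
* **Score centring.** The raw maximum-weight objective favours longer
  paths: a detour through an extra node collects an extra edge, so an
  insertion carried by only half the reads would always win. The
  complex-area corrector therefore scores each edge as
  `weight - spanning/2`, where `spanning` counts unmasked area-spanning
  rows — the population actually competing for the path. Minority detours
  then score negative while equal-length comparisons are unchanged. The
  exported `max_weight_consensus()` defaults to the pure objective
  (`center = 0`); the corrector passes the centring explicitly.

## Structural insertions across isoforms

One structural event cannot be handled per pairwise alignment: a candidate
from the exon-carrying isoform overlapping an exon-skipping template
carries a few hundred extra bases. Under edit-distance costs the optimal
pairwise alignment does not keep such an insertion contiguous -- it
threads the extra sequence through coincidental matches downstream (a
zigzag that is strictly cheaper than one long gap in random sequence), so
the insertion never appears as one block in any consensus table, and each
candidate's zigzag differs. Affine gap costs were evaluated and rejected:
they keep the block contiguous but merge nearby *noise* indels into
mismatch bridges, measurably degrading base-level correction.

The package instead detects the event where it is unambiguous: in the seed
chain. A candidate whose shared k-mers fall on two diagonal bands
separated by `min_struct_ins` or more bases (default 20) carries a
structural insertion (positive jump) or deletion (negative) relative to
the template, localised between the two seed blocks. During correction,
insertion-jump candidates are clustered by junction position; when a
majority of the junction-spanning candidates agree, their inserted
segments are polished by per-column majority voting and the consensus
segment replaces the short template interval between the seed blocks.
This is the package's stand-in for the partial-order merging a full POA
consensus would perform.

Crucially, the splice is *suppressed* whenever the junction positions are
flagged structurally divergent by the skip statistic. In the windowed
mode a cross-isoform junction is masked and skip-dominated, so the
majority isoform's exon is never forced into a minor-isoform read; in the
baseline mode (no masking, no skips) the splice goes through -- which is
precisely the isoform-erasing behaviour of structure-blind
self-correction that the windowed mode exists to prevent, and the
behaviour the retention benchmark measures.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `window_length` | 5 columns | sliding-window length for Eq. above |
| `identity_threshold` | 0.5 | window fires at identity ≤ threshold; 0 disables masking (baseline mode) |
| `scov` | 0.1 | structural test `skip > coverage * scov` |
| `min_coverage` | 4 reads | boundary filter on `match + insert + skip` |
| `min_output_size` | 100 bases | discard shorter corrected reads |
| `k` | 13 | seed k-mer size |
| `min_seed` | 4 | minimum shared seeds per candidate |
| `max_diag_spread` | 400 bases | seed diagonal spread; must exceed the longest skipped exon |
| `min_struct_ins` | 20 bases | minimum seed-diagonal jump treated as a structural insertion |
| `max_align_error` | 0.5 | drop candidates whose alignment edit rate exceeds this |

Masking edge cases are pinned down as follows: a window fires only when
its identity is at most the threshold *and* below 1, and a threshold of 0
disables masking entirely. This makes threshold 0 exactly the baseline
mode and keeps a perfect window from ever masking, while leaving the
default 0.5 behaviour untouched. The text description of the method masks
the traversed position rather than the whole fired window, and the package
follows that reading: full-window masking was tried and measurably erases
the insertion evidence needed to repair template deletions (each inserted
base sits in a locally noisier window, so its masking probability is far
above average), roughly tripling the residual deletion error.

## The overlapper stand-in

Candidate recruitment is a deterministic k-mer overlapper: exact 13-mer
hits binned onto alignment diagonals, one candidate per read from the
densest diagonal window, both strands tried via reverse complement, ties
broken by read id. This is an acknowledged simplification of
production-scale pairwise filters; it is exact at the package's scale
(thousands of reads) and fully reproducible. The diagonal window is wide
enough (400 bases by default) that cross-isoform overlaps spanning a
skipped exon still chain into a single candidate — without that, the
baseline mode could never be tempted to insert the exon and the
comparison would be vacuous.

## What the simulator emulates (and what it does not)

`simulate_genes()` builds multi-exon genes (5–7 exons of 150–300 bases,
targeting ~1.5 kb transcripts — the typical full-length mRNA scale) whose
isoforms differ by skipping one internal exon, with the minor isoform at a
configurable abundance (default 0.2, matching the low-relative-coverage
regime where isoform loss concentrates). Exons are uniform random
sequence with a 13-mer uniqueness guard so isoform assignment is never
trivially ambiguous. `simulate_reads()` draws reads per gene by isoform
abundance, truncates a fraction from the 5' end (imperfect full-length
capture; the 3' end is retained), and injects i.i.d. per-base errors,
default 4% mismatch / 5% insertion / 4% deletion — the indel-dominant
~13% profile of raw PacBio/Nanopore cDNA.

Deliberately not modelled: homopolymer-biased and signal-level error
structure, reverse-strand reads by default, expression count models beyond
per-isoform fractions, intron retention and alternative 5'/3' ends, and
sequence similarity *between* genes. Passing tests therefore demonstrate
the structural mechanism — that windowing protects exon-skipping isoforms
from majority overwrite under realistic error rates and coverage — not
performance on any particular instrument's bias profile.

## Evaluation choices

Corrected reads are evaluated against the simulator truth, not a genome:
each read is aligned (banded fitting alignment, transcript ends free) to
every isoform of its gene of origin and assigned to the nearest isoform if
the edit rate is within a threshold (0.30 for raw reads, 0.10 for
corrected) and the margin to the runner-up exceeds 20 edit units —
otherwise it stays unassigned. Per gene, the isoform set *before* is the
isoforms with at least one assigned raw read, *after* the same over
corrected reads; an isoform present before and absent after is *lost*.
Relative coverage bins `(0, 0.1], ..., (0.9, 1]` partition isoforms by
their share of the gene's raw reads. These thresholds are reported in
every output header; they are evaluation conveniences, not part of the
correction method.

## Numerical and degenerate-input conventions

Template coordinates are 0-based with half-open intervals throughout.
Alignment tie-breaking prefers match over deletion over insertion;
candidate order is by descending seed score, then read id. Reads with no
candidates, no position at `min_coverage`, or corrected length below
`min_output_size` are discarded with a logged reason. An all-masked
position types as UNDEFINE and its area falls back to the template
substring; a complex area with no graph path does the same. Window
identities are compared with a small epsilon so `2/5 <= 0.4` holds exactly
in floating point.

## Problem sizes

The shipped tests exercise the full pipeline at 50 single-isoform genes x
30x coverage for correction efficacy and 100 two-isoform genes x 30x for
the windowed-vs-baseline retention comparison; the acceptance script runs
40 two-isoform genes at 24x. These sizes give stable estimates (error
rates reproduce within ~0.1 percentage points across seeds) while keeping
a full run in the minutes range on one core.

## Known limitations

* The windowed mode trades a little per-base accuracy for isoform
  retention: masking thins the evidence around error clusters, so on
  structurally homogeneous (single-isoform) data its residual error sits
  above the baseline mode's. On multi-isoform data the ordering reverses,
  because the baseline's structural overwrites count as errors against
  each read's true transcript.
* Isoforms whose distinctive exon is shorter than the assignment margin
  (20 edit units) cannot be told apart by the evaluator.
* One correction pass only; no second-round correction of unmodified
  reads, no clique-based overlap cleaning, and no polishing with quality
  scores.
* The structural test keys on the skip statistic alone; isoform pairs
  differing by events that produce no masked stretch on either side (e.g.
  very short skipped exons within one window) fall back to ordinary
  consensus behaviour.
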