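# isocorr

Isoform-aware self-correction of transcriptome sequencing long reads.

## The problem

Third-generation (PacBio / Nanopore) cDNA reads can span full-length
transcripts (~1.5 kb), but carry 12–15% errors dominated by indels.
Self-correction tools built for genomic reads fix those errors by aligning
reads against each other and voting — implicitly assuming all overlapping
reads come from the *same* underlying sequence. In a transcriptome that
assumption fails: a gene's isoforms share most exons, so reads from the
major isoform dominate the evidence for a minor-isoform read and "correct"
its distinctive structure away (e.g. re-inserting a skipped exon). The
result is a measurable loss of isoform diversity, concentrated in weakly
expressed transcripts.

`isocorr` implements a consensus pipeline that keeps the error-correction
power of the overlap/consensus approach while protecting structural
differences between isoforms:

1. **Overlap + base alignment.** Each read serves once as the template;
   candidate reads sharing seed k-mers in a consistent diagonal band are
   globally aligned (banded edit distance) and the alignment is normalised
   so every mismatch becomes a deletion plus an insertion — rows `tstr`
   (template) and `qstr` (candidate).
2. **Sliding-window masking.** For every alignment column the identity of
   the window starting there is `match_base_num / window_length`
   (defaults: length 5, threshold 0.5). Characters in low-identity
   stretches are replaced by `N` in a copy `newqstr`: in transcriptome
   data these stretches are typically alignments across *different exon
   structures*.
3. **Consensus tables with a skip statistic.** Per template position the
   pipeline tallies match / insert / delete counts from `qstr` (the
   *normal* table) and additionally *skip* counts — masked candidates — from
   `newqstr` (the *modify* table). Correction boundaries keep positions
   with coverage `match + insert + skip >= min_coverage` (default 4).
4. **Structural test and position typing.** A position with
   `skip > coverage * scov` (default `scov` 0.1) is structurally
   divergent: its type (MAT / INS / DEL / UNDEFINE) is decided from the
   modify table, i.e. only from same-structure evidence; otherwise from
   the normal table.
5. **Area partitioning and consensus.** Runs of MAT/DEL positions are
   *simple areas*, corrected by fast list voting; areas containing INS or
   UNDEFINE positions are *complex areas*, corrected by the maximum-weight
   path through a directed acyclic alignment graph. In structural-change
   areas the edges derived from masked (`N`) evidence are removed first,
   so the majority isoform cannot overwrite the minority one.
6. **Merging.** Per-area consensus strings are concatenated; corrected
   reads shorter than `min_output_size` (default 100) are discarded.

Setting `identity_threshold = 0` (the `baseline` flag) disables masking and
yields the behaviour of a conventional DNA self-corrector — the package's
built-in comparison point.

The package also ships a multi-isoform read simulator with per-read ground
truth (exon-skipping isoforms, indel-dominant error profiles, uneven
isoform abundance) and evaluators for per-base error rates and isoform
retention, binned by *relative coverage* — the fraction of a gene's reads
belonging to an isoform (`isoform_num / transcript_num`).

## Worked example

```r
library(isocorr)

genes <- simulate_genes(n_genes = 2, isoform_range = c(2, 2),
                        minor_abundance = 0.2, seed = 1)
sim   <- simulate_reads(genes, depth = 15, seed = 2)   # ~13% error reads

cr <- correct_reads(sim$reads, correction_params())
glance(cr)
#> # A tibble: 1 x 7
#>   n_reads n_corrected pct_corrected n_bases mean_candidates median_complex_len baseline
#>     <int>       <int>         <dbl>   <int>           <dbl>              <dbl> <lgl>
#> 1      30          30           100   32526              14                  3 FALSE

compute_read_metrics(sim$reads, cr$corrected, genes, sim$truth)[
  , c("error_rate", "mismatch_rate", "insert_rate", "delete_rate")]
#> # A tibble: 1 x 4
#>   error_rate mismatch_rate insert_rate delete_rate
#>        <dbl>         <dbl>       <dbl>       <dbl>
#> 1     0.0238       0.00947     0.00409      0.0103
```

All 30 reads survive correction and the per-base error rate against the
known transcripts drops from ~13% to ~2.4% at this small 15x depth (it
falls below 2% at 30x). `isoform_retention()` then reports, per gene, the
isoform sets observed before and after correction and which isoforms were
lost in which relative-coverage bin; `autoplot()` on the result draws the
loss profile. `run_benchmark()` wires the whole windowed-vs-baseline
comparison together, and `exec/isocorr` exposes
`simulate` / `correct` / `evaluate` / `benchmark` subcommands for shell use.

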