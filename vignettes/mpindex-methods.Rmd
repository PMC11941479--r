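---
title: "Quantifying Microprocessor activity from chromatin RNA-seq coverage"
author: "mpindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Microprocessor activity from chromatin RNA-seq coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Most miRNA genes are transcribed as long primary transcripts (pri-miRNAs)
whose hairpins are cropped co-transcriptionally by the Microprocessor, the
nuclear complex of DGCR8 and the RNase III enzyme Drosha. Mature miRNA
abundance is therefore a poor readout of Microprocessor activity: it
convolves transcription, cropping, export, Dicer processing and turnover.
Chromatin-associated RNA-seq largely removes the downstream steps. The
chromatin fraction is enriched for nascent transcripts, so an efficiently
cropped hairpin appears as a local coverage trough: reads accumulate over
the flanking pri-miRNA sequence while the excised hairpin is exported and
lost from the fraction. A hairpin that escapes cropping — because the locus
is Microprocessor-independent (e.g. a mirtron) or because Microprocessor
dosage is reduced — shows flat coverage across hairpin and flanks.

The Microprocessor Processing Index (MPI) turns this picture into a
per-locus statistic:

$$\mathrm{MPI} = -\log_2 \frac{\bar d_{\mathrm{hairpin}} + 1}
                              {\bar d_{\mathrm{flank}} + 1}$$

where $\bar d$ denotes mean per-nucleotide read depth over the scoring
regions defined below. The pseudocount keeps the ratio defined at zero
coverage and shrinks low-coverage loci towards 0. MPI well above 0 means
efficient processing; MPI near 0 or negative means inefficient or absent
processing. Condition-level MPI is the arithmetic mean over replicate
samples, and differential processing between genotypes is

$$\Delta\mathrm{MPI} = \overline{\mathrm{MPI}}_{\mathrm{mutant}}
                     - \overline{\mathrm{MPI}}_{\mathrm{reference}},$$

negative when the locus is less processed in the mutant. Averaging
per-sample MPIs (rather than taking the MPI of averaged depths) is a
deliberate ordering: the two differ whenever replicates vary in library
depth, and the mean-of-ratios form weights replicates equally.

## Scoring regions

Each annotated hairpin is extended by `flank_len` (default 100 nt) on each
side, then the outer `trim` (default 5 nt) nucleotides of the hairpin *and*
of each flank are excluded. At defaults this leaves:

* a hairpin core of (hairpin length − 10) nt,
* two flank cores of 95 nt each (190 nt of scored flank in total),
* a 10 nt gap between the hairpin core and each flank core.

The gap absorbs uncertainty in annotated Drosha cleavage positions:
alternative cleavage a few nucleotides outside the annotated hairpin would
otherwise bleed hairpin-like coverage into the flank mean (or vice versa).
Both parameters are configurable; the 10 nt gap is emergent (`2 * trim`),
not hard-coded. Region coordinates depend only on hairpin start/end, never
on strand, so MPI is orientation-symmetric; strand only selects which
coverage track is read.

Two boundary policies are strict by design. Hairpins shorter than
`2 * trim + 1` nt have no defined core and raise an error naming the locus.
A locus whose left flank would run off the chromosome start also errors
rather than silently truncating, because a truncated flank biases the flank
mean; `run_mpi()` collects such loci in a `region_failures` table instead
of dropping them silently. Clustered miRNAs whose flanks overlap a
neighbouring hairpin are *not* excluded automatically — whether that is an
artifact depends on the cluster's processing — but
`flank_overlap_report()` lists them so they can be inspected, and the
flank-balance filter catches the strongly asymmetric cases.

## Depth extraction

Depth is strand-resolved: a hairpin on the minus strand must be scored
against minus-strand transcription. For BAM input, primary,
non-supplementary, non-duplicate-flagged alignments with `MAPQ >=
min_mapq` (default 0) are counted; existing duplicate flags are respected
but duplicates are never marked here. Each read is assigned to the
transcribed strand by the library chemistry: the default
`reverse_stranded` matches dUTP-based rRNA-depleted protocols (first mate
antisense to the transcript), and `forward_stranded` is available for the
opposite convention. Aligned reference positions (CIGAR `M`/`=`/`X` and
`D`) increment depth; intron skips (`N`), insertions and soft-clips do not
— standard depth-tool semantics, stated here for reproducibility.
BedGraph pairs (one file per strand, 0-based half-open, non-overlapping
intervals) are accepted as a lighter interchange format and are what the
simulator emits; `export_bedgraph()` round-trips any coverage for browser
inspection. MPI needs no between-sample normalisation: it is a ratio of
means within one sample.

## Locus-inclusion filters

Four filters remove loci whose MPI would be uninterpretable; all are
applied per locus and audited (`first_fail` and `all_fails` per excluded
locus, so `survivors + excluded = input`):

1. **Mirtrons** (and tailed mirtrons) bypass Drosha via splicing; their
   hairpin depletion is not a Microprocessor signal. Status comes from a
   curated ID list — no structural inference is attempted.
2. **Detected miRNAs**: the locus must produce a mature miRNA that was
   detected (e.g. included in small-RNA-seq statistics); undetected loci
   contribute annotation noise. Loci annotated without mature IDs (BED6
   input) are matched against the allowlist by locus ID instead.
3. **Reference flank depth** ≥ 2 (inclusive), averaged over
   reference-condition samples: below that, the MPI denominator is mostly
   pseudocount.
4. **Flank balance**: the two flank means must not differ more than
   4-fold, compared as $(\max + 1)/(\min + 1)$ so the rule is defined for
   a zero flank. Strong asymmetry indicates overlapping transcription
   units, neighbouring hairpins, or transcript ends inside a flank. The
   rule is applied in every sample by default (strictest reading);
   `flank_ratio_scope = "ref_mean"` relaxes it to reference means only.

The MPI equation uses a single flank mean; since both cores have equal
length, the pooled per-nucleotide mean equals the average of the two flank
means, which is how it is computed. Filter 4 is the only place the two
flanks are considered separately.

A fifth threshold, `ref_processed_threshold` (default 0.3 on the
reference-condition MPI), sets the `processed_in_ref` flag used to
restrict distribution summaries to loci actually processed in the
reference; it never removes records, because the four filters above are
the only exclusions applied.

Per-locus significance testing of ΔMPI is deliberately absent: with a
handful of replicates the informative outputs are the per-locus effect
sizes and the condition-level MPI distributions, both of which are
emitted (per-sample and per-condition MPI columns).

## The basal UG motif

Efficient Drosha recognition is associated with a UG dinucleotide at the
basal stem junction, anchored 14 nt upstream of the 5′ end of the 5p
mature miRNA. `basal_ug_present()` therefore tests whether positions
−14/−13 (counting −1 as the nucleotide immediately upstream of the 5p 5′
end) are `U` then `G`, case- and T/U-insensitively. The anchor follows the
standard basal-UG convention; because Drosha cleavage annotation can shift
by a nucleotide between databases, a `slack = 1` option widens the anchor
window by ±1 nt (off by default). An `N` in the window yields an
*indeterminate* call, distinct from absence; indeterminate loci are
excluded from the 2×2 motif-by-group table and reported separately.
Group-level depletion is tested two-sidedly with the exact test on the
2×2 table. Apical UGU, CNNC and mGHG motifs are out of scope.

## Category enrichment

`hypergeom_enrichment(N, K, n, k)` returns the exact upper-tail
probability $P(X \ge k)$ of drawing at least $k$ category members among
$n$ selected from a universe of $N$ containing $K$ — the standard
over-representation test for questions like "are primate-specific miRNAs
enriched among dysregulated miRNAs?". The universe is always supplied by
the caller (typically the miRNAs included in differential-expression
analysis); no default universe is baked in, because the result is
meaningless without an explicit sampling frame. The test suite verifies
the implementation against exhaustive enumeration of all draws for small
universes and against an independently coded closed form for all
$N \le 20$.

## The simulator and what it does (and does not) emulate

`simulate_dataset()` generates the full input bundle — BED6 annotations,
per-sample stranded bedGraph pairs, mirtron and detected ID lists, a
manifest, and a truth table — from a compact generative model:
unprocessed transcripts cover hairpin plus flanks uniformly at a
locus-specific transcription level λ; processed transcripts have lost
their hairpin. Per-nucleotide depth is thus Poisson(λ) over flanks and
Poisson(λ(1 − p)) over the hairpin, independently per nucleotide, where p
is the locus's processing efficiency in that condition. The expected MPI
has the closed form

$$E[\mathrm{MPI}] \approx -\log_2\frac{\lambda(1-p) + 1}{\lambda + 1},$$

which `estimate_efficiency()` inverts (clipped to [0, 1]) to back-estimate
p from observed MPI and flank depth — the basis of the
`run_recovery()` parameter-recovery loop.

Defaults encode the study design the pipeline targets: three genotypes
with graded Microprocessor dosage (efficiencies 0.8 / 0.5 / 0.2 for
WT / HET / KO), four replicates per condition, 85 nt hairpins (so the
trimmed core is 75 nt and each flank core 95 nt, matching real
pre-miRNA scale), and λ = 100 reads/nt, a well-covered chromatin library.
Small fractions of loci (5% each, drawn disjointly) are flagged as
mirtrons or omitted from the detected list purely to exercise filters 1–2.
Loci are placed non-overlapping, alternating strands, at least `flank_len`
from chromosome ends. Everything is reproducible byte-for-byte from the
seed.

The model is deliberately minimal. It does not emulate read-level
sampling (noise is per-nucleotide Poisson, slightly optimistic relative
to fragment-level correlation), transcription-unit structure (promoters,
splicing, transcript ends inside flanks), uneven coverage along the
transcript, GC bias, sequencing error, or partial hairpin retention on
chromatin (a `residual_retention` parameter exists, default 0). Passing
recovery tests therefore demonstrates that the estimator and plumbing are
correct and unbiased under flat transcription — not that MPI is unbiased
on real chromatin data, where flank coverage is not flat and the filters
carry real weight.

## Validation problem sizes and numerical choices

The test suite validates the formula against an independently coded
evaluation on 1000 random depth pairs (tolerance 1e−12); null and signal
simulations use 200 loci at λ = 100 (mean MPI within ±0.05 of the closed
form, the tolerance implied by Poisson error at that size); parameter
recovery uses 200 loci × 3 replicates at p ∈ {0.2, 0.5, 0.8} (mean
absolute error ≤ 0.05, bias within ±0.02); the differential check (0.8 vs
0.5) requires ΔMPI < 0 for ≥ 95% of surviving loci. Ties and boundaries:
filter 3 is inclusive at 2.0, filter 4 inclusive at 4.0, and the
`processed_in_ref` flag is strict (> 0.3). Output tables are ordered by
locus ID and numeric columns written at six significant digits, so equal
seeds give byte-identical files.

## Known limitations

* MPI conflates cropping efficiency with any other process that depletes
  hairpin-spanning chromatin reads (fast co-transcriptional cleavage by
  other nucleases would look identical).
* Loci transcribed from both strands, or antisense transcription through
  a hairpin, are not modelled; the stranded extraction merely keeps them
  from mixing.
* The efficiency back-estimate assumes flat transcription across the
  scored window and is intended for simulation recovery, not as a
  calibrated efficiency on real data.
* The filters treat condition labels asymmetrically (reference defines
  filters 3 and the `processed_in_ref` flag); swapping the reference
  changes the surviving set.
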