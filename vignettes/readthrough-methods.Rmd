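---
title: "Quantifying stop-codon readthrough from ribosome profiling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stop-codon readthrough from ribosome profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Stop-codon readthrough (SCR) is the decoding of a termination codon by a
near-cognate tRNA, after which the ribosome keeps elongating into the
3'UTR. In ribosome profiling data it appears as ribosome-protected
fragments (RPFs) mapping downstream of the annotated stop codon. Measuring
it per transcript requires care on three fronts, each of which shapes this
package:

1. **Isoform ambiguity.** A read 3' of one isoform's stop codon may lie
   inside another isoform's CDS. `riboscr` therefore analyses one
   transcript per gene, chosen so its stop codon is the 3'-most among the
   gene's isoforms, and discards genes whose selected transcript overlaps
   transcripts of the nearest same-strand neighbour or whose UTRs overlap
   pseudogenes (UTR exon intervals are used for the pseudogene check).
2. **Sub-codon positioning.** Each footprint is reduced to the nucleotide
   at the centre of its A-site codon via read-length-specific 5' offsets,
   calibrated per library from reads at start codons (initiating ribosomes
   hold the start codon in the P site, so the A-site codon centre sits at
   `cds_start + 4`; the offset for a length is the mode of
   `cds_start + 4 - five_prime` over its calibration reads). Ties resolve
   to the smaller shift, deterministically.
3. **Sparse signal.** Basal readthrough is rare, so the readthrough
   statistic is a ratio of densities with explicit windows and filters
   rather than a model fit, and zeros are retained as informative.

# The RRTS and its windows

All coordinates in the package are 1-based and closed — the R/Bioconductor
convention (`IRanges`, `substr`), adopted so that window arithmetic matches
the idiom of the surrounding ecosystem. `cds_end` is the last nucleotide of
the stop codon; the NTC starts at `cds_end - 2`; the first in-frame 3'UTR
stop codon ("3'TC") is found by scanning codons from `cds_end + 1` in steps
of 3.

For an included transcript,

* CDS window: `cds_start + 18 .. cds_end - 15` (removes the start- and
  stop-codon peaks);
* extension window: `cds_end + 7 .. tc3_pos - 1` (removes the 6 nt after
  the NTC, where the geometry of the terminating/readthrough transition
  distorts densities);
* RRTS = extension density / CDS density (counts per nt).

Exclusions, applied in a fixed order so each record carries exactly one
reason: fewer than 128 reads on the transcript; no 3'TC; fewer than 5
complete codons strictly between NTC and 3'TC (`tc3_pos - cds_end < 16`,
which leaves at least 9 informative nucleotides); zero CDS-window density.
The 128-read threshold counts reads assigned anywhere on the transcript.
RRTS is a ratio of raw densities, hence invariant to depth normalization.
For log-scale plots, zero scores are floored at 2^-15; correlation
statistics drop zeros instead.

# Metagene profiles and the 3'UTR/CDS ratio

Per transcript, density at every position is divided by the mean density
over the CDS; profiles are averaged position-wise with each transcript
weighted once (the per-transcript normalization already removes
expression). Position 0 is the first nucleotide of the stop codon. A
transcript contributes only if the full window (stop: -150..+100; start:
-100..+150) fits inside it. The 3'UTR/CDS ratio is 100 x the mean averaged
density over +5..+100 divided by the mean over -147..-16, computed on the
averaged profile by default (a per-transcript variant is available via
`per_transcript = TRUE`; the two agree under homogeneous readthrough but
weight transcripts differently when readthrough varies).

# Frames, 3'TC metagenes, codon occupancy

A count stored at codon-centre `c` has A-site codon start `p = c - 1` and
frame `(p - cds_start) mod 3`, with residue classes {0, 1, 2} reported as
{0, +1, -1}. Region totals use CDS-normalized densities, making fractions
invariant to expression. The CDS region spans the full CDS so a uniform
track splits exactly into thirds.

The frame-resolved 3'TC metagene classes transcripts by the frame of the
first stop codon found in their 3'UTR *in that frame*, searching the three
frames independently (the alternative — conditioning on the overall first
stop — couples the classes and was not adopted). Windows are +/-12 nt
around the stop; transcripts with an additional same-frame stop inside the
window are discarded (stops in other frames do not terminate the ribosome
flux under study and are ignored).

Codon occupancy divides the raw density in a codon's 3-nt window by the
transcript's CDS mean density computed excluding the first and last 15 nt,
skipping occurrences in the first or last two codons; the score for a codon
is the mean over all its occurrences.

# NTC versus 3'TC relative readthrough

For each eligible transcript the ratio of CDS-normalized density over the
27-nt flank downstream of a stop (positions +6..+32 from the stop's first
nucleotide) to the 27-nt flank upstream (-30..-4) is computed at both the
NTC and the first 3'TC. The flanks are codon-aligned: "30 nt either side
excluding the codon adjacent to the stop" yields 9 codons = 27 nt per
flank; the stop codon itself is never part of either flank. Transcripts are
excluded when the 3'TC is absent, lies within the first 30 nt of the
3'UTR, has fewer than 30 nt downstream, or has another in-frame stop in
those 30 nt; non-finite ratios (zero upstream density) are dropped with a
counter. With replicate libraries, a paired t-test compares per-replicate
mean TC3 and NTC ratios.

# Sequence-context statistics

The context is the 30-mer spanning a terminating ribosome's footprint:
15 nt upstream, the stop codon, 12 nt downstream, available when the 3'UTR
has at least 12 nt. Each context is weighted by its transcript's RRTS;
zero weights are retained (an option drops them).

*Positional tests.* For each of the 27 flanking positions and each
nucleotide, a pooled-variance two-sample Student's t-test compares weights
with versus without that nucleotide; the stop codon is tested as a 3-level
factor (each codon against the rest). The one-sided p-value is taken in the
observed direction and the signed statistic reported — the direction is
chosen post hoc, which is the reading that lets a single test report
"increases" or "decreases" per cell. Welch's test is available behind a
flag. Benjamini-Hochberg adjustment is applied jointly over all tested
cells, positional and stop together, matching how the full logo is
displayed. Degenerate cells (a side with fewer than 2 records, or zero
pooled variance with a non-zero mean difference) are reported untested;
when every weight is identical the test is defined as t = 0, p = 0.5.

*Ridge model.* RRTS is regressed on a 111-column binary design — 27
positions x 4 nucleotides plus 3 stop-codon indicators — with an
unpenalized intercept, no standardization (the design is binary), and
penalty alpha = 10^3 by default. Coefficients solve
`(Xc'Xc + alpha I) beta = Xc' yc` on the centred design, the same
semantics as scikit-learn's `Ridge`; at alpha = 0 on a full-rank design
this is ordinary least squares, which the tests exploit as an oracle.

*Nucleotide frequencies.* NTC windows span -40..+60 (requiring a 60-nt
3'UTR), 3'TC windows -12..+12 (requiring 12 nt downstream and no other
in-frame stop in the window); the stop is collapsed to one position whose
codon frequencies are reported separately, and downstream positions are
labelled from +4, treating the stop as a four-nucleotide signal.

# The synthetic generator

`simulation_spec()` fixes the study conditions; its defaults describe a
deeply sequenced mammalian library and are not tuned per analysis:
log-normal expression (sdlog 0.75), 28-35 nt reads peaking at 31 nt with
the canonical offset table {28-30: 16, 31-35: 17}, frame fidelity 0.95
(off-frame A-sites jittered +/-1 nt evenly — the jitter moves the A-site,
not the read length, so offset calibration stays clean), 5x dwell pauses at
initiation and termination, human-like stop-codon usage
(UAA 0.30, UAG 0.24, UGA 0.46), and a planted in-frame 3'TC at a
controlled codon distance with the intervening sequence guaranteed
stop-free. Readthrough is either a fixed per-transcript probability or a
logistic function of the transcript's own 111-feature context, so context
recovery tests compare like with like. Ribosome flux drops to `pi` past
the NTC and by `tc3_readthrough` past each in-frame 3'UTR stop.

What the generator does *not* emulate — sequencing errors, duplicated
reads, rRNA contamination, nuclease sequence bias, per-codon dwell
heterogeneity beyond explicit multipliers, and genuinely context-correlated
nucleotide composition — bounds what passing tests show: they demonstrate
that the estimators recover their targets under the stated generative
model, not that real libraries are free of these biases.

`simulate_rrts_weights()` emulates RRTS measurement noise directly
(truth x unit-mean log-normal noise) for context-statistics validation at
scales where read-level simulation adds nothing but runtime; read-level
recovery of RRTS itself is always validated separately.

# Numerical and design choices

* Coordinates 1-based closed throughout; GTF input converted at parse
  time; internal CDS bounds include the stop codon, extending GENCODE-style
  CDS features by the `stop_codon` feature or by a sequence-checked 3 nt.
* Isoform selection ties resolve to the lexicographically smallest
  transcript id, making selection deterministic and order-independent.
* Mann-Whitney U tests use exact enumeration when both groups have fewer
  than 8 untied observations, otherwise the normal approximation with
  continuity and tie correction.
* RPM normalization is per read length by default (each length scaled by
  its own mapped-read total), with a documented `global` mode; all ratio
  statistics are invariant to this choice within one library.
* Reads whose shifted A-site falls beyond the transcript 3' end are
  dropped, not clipped; every dropped class is counted, and
  included + excluded records always sum to the input.
* Only primary alignments are counted; a MAPQ threshold supports
  unique-only sensitivity analyses.

# Validation scales

The test suite and `scripts/acceptance.R` run desk-scale simulations chosen
so each check is decisive yet quick: 500 transcripts / 1M reads for RRTS
recovery (median within 15% of pi = 0.05, 0.2, 0.5), 300 / 5e5 for offset
and frame recovery, 500 / 2.5M x 2 replicates for the NTC 0.33 vs 3'TC
0.46 contrast, and 2000-transcript context sims over 10 seeds for the +4 C
effect and its false-positive control. Statistical primitives (BH, exact
U, ridge) are checked against brute-force oracles to 1e-8 on 100 random
small instances each.

# Known limitations

* The A-site "centre" convention reproduces the canonical offset table
  under start-codon calibration, but the centre-vs-P-site reading of
  offsets is an interpretation; offsets are data, so a different convention
  shifts all windows coherently.
* Multi-transcript assignment of a genomic 5' end keeps every matching
  transcript; after single-isoform selection with overlap filtering this is
  rare, but unfiltered transcript sets can double-count.
* The selection count and UTR statistics on a real GENCODE annotation
  depend on annotation release details (APPRIS/CCDS tag dialects);
  full-scale runs are supported but not part of the offline validation.
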