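---
title: "Quantifying differential splice-isoform abundance from barcoded long reads"
author: "nanopsi authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying differential splice-isoform abundance from barcoded long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanopsi)
```

## The problem

Long-read cDNA sequencing of oligo-dT-primed libraries reads entire
transcripts, so a single alignment carries both the gene a read came from
and the exon/intron structure of the isoform it represents. That makes it
possible to ask, per genomic base, how often a base is *retained* in the
transcript pool versus spliced out — and to compare that retention between
experimental conditions (for example, unstressed cells versus cells under
endoplasmic-reticulum stress, where both XBP1 splicing by IRE1 and broader
isoform-abundance shifts are expected). `nanopsi` implements this analysis
end to end: demultiplexing of barcoded raw reads, gene assignment of
spliced alignments, per-base percent-spliced-in (%SI) pileups, segmentation
of genes into regions of homogeneous %SI, and a negative-binomial
likelihood-ratio test for differential retention, together with a
synthetic-data generator that makes every stage testable against known
truth.

## Read architecture and demultiplexing

A library read, in its forward layout, is

```
[barcode][poly-T tract][revcomp(cDNA insert)][revcomp(common primer)]
```

or the reverse complement of the whole layout. Demultiplexing is anchored:

1. **Poly-T anchor.** `find_polyt()` finds the longest window that is at
   least 90% T and at least 10 bases long, on the read and its reverse
   complement, then trims the window to begin and end on a T. The trimming
   step matters: the literal "longest ≥90% window" may extend one or two
   non-T bases past the tract, and the trimmed interval is what marks the
   barcode boundary.
2. **Common-primer (CP) anchor.** `find_common_primer()` is a semi-global
   (infix) edit-distance search, reported within a tolerance of 3 edits.
   Edit distance — not Hamming distance — is used throughout because
   nanopore errors include indels.
3. **Barcode search.** The barcode is sought in a window of barcode length
   plus 8 bases immediately 5' of the poly-T tract (the oligo-dT primer
   places it there), extended 8 bases *into* the detected tract because a
   T-rich barcode tail can be absorbed by the tract window; the infix
   matcher is indifferent to trailing T context. When no tract is found,
   the window sits at the start of the CP-oriented read. A read is
   assigned only when **exactly one** barcode lies within 3 edits; zero
   matches, two or more matches, or poly-T/CP anchors implying conflicting
   orientations all exclude the read.

The bundled barcode set (`default_barcodes()`) has pairwise edit distance
at least 7, which is more than twice the tolerance: by the triangle
inequality no read can be within 3 edits of two barcodes, so cross-sample
misassignment is structurally impossible — errors can only cost recall.
Trimming (`trim_read()`) removes the barcode, tract and CP loci and
returns the insert in mRNA sense.

One deliberate coordinate convention: genomic coordinates are 0-based and
half-open everywhere inside the package (SAM and GTF emission convert at
the boundary), while positions *within a read string* use R's native
1-based inclusive indexing, since they only ever feed `substr()`.

## Gene assignment

Each alignment's reference footprint — the genomic span of its
`M`/`=`/`X`/`D`/`N` operations, i.e. including skipped introns — is scored
against every overlapping annotation as

```
score = overlap / max(annotation length, footprint length)
```

and the best-scoring annotation wins (`assign_genes()`). The footprint
includes `N` runs because the score compares against the annotation's
genomic span, not its exonic content. Ties break by larger overlap, then
lexicographic gene id; strand is ignored because double-stranded cDNA can
align to either strand. Only primary alignments are read from SAM/BAM.
The per-sample gene-count table (`build_counts()`) feeds an external
differential-expression engine; only the significance thresholds (BH FDR
≤ 0.05 and |log2 fold-change| ≥ 0.5, `de_threshold_filter()`) are applied
here.

## The %SI pileup

For each gene and sample, `accumulate_pileup()` maintains two per-base
counters: `spliced_in` (reads whose alignment includes the base,
mismatches included) and `spanning` (reads whose alignment crosses the
base). Their ratio is the percent-spliced-in. Three cleaning rules are
applied to each CIGAR first (`preprocess_cigar()`):

* insertions and soft clips are dropped (no reference footprint);
* runs shorter than 10 bases merge into the preceding run, adopting its
  class — this absorbs alignment noise, and in particular folds small
  deletions into their flanking matches so they cannot masquerade as
  splicing. A short *leading* run has no preceding run and merges forward
  (flagged when it happens);
* the first and last cleaned runs of every read contribute to neither
  counter, suppressing the noisy alignment of read ends. A read reduced
  to two or fewer runs contributes nothing.

Reads with aligned fraction (read bases in `M`/`=`/`X`/`I` over all read
bases) of 0.8 or less are dropped beforehand as short, spurious
alignments; the boundary is strict (exactly 0.8 is dropped).

The terminal-trim rule has a structural consequence worth knowing: a
retained intron is only *visible* when the matched run crossing it is
interior to the read, which requires a spliced-out run on both sides.
Retention of a gene's first or last intron, or retention observed by reads
truncated past the flanking exon, is censored. The synthetic generator
therefore places retained introns mid-gene (see below), and real-data
estimates near transcript ends should be read with this censoring in mind.

## Segmentation

Replicate pileups are pooled by summing counts — not by averaging
fractions — so positions are weighted by evidence. Positions are masked
out when any sample spans them fewer than 5 times or any condition's mean
spanning coverage falls below 20; "mean among replicates" is taken within
each condition, the stricter of the two readings, so that a condition
with systematically thin coverage cannot be carried by the other.

`segment_psi()` scans the pooled fraction left to right, keeping the
cumulative mean since the current region start and opening a new region
whenever a position deviates from that mean by more than 0.1. The
cumulative mean resets at each region start — the only reading under which
a long gene with several splicing states yields multiple clean regions.
Masked positions are skipped without closing the region. A step larger
than 0.1 therefore produces a boundary exactly at the step, and
deviations of 0.1 or less never split (alternating 0.95/0.90 stays one
region).

Regions whose pooled fraction reaches 0.05 in no condition are dropped as
never-retained. Each surviving region is summarised per sample as
`k = round(mean spliced_in)`, `n = round(mean spanning)` over its masked
positions, with round-half-to-even fixed as the rounding convention for
bit-reproducibility.

## The retention model and test

Per region and condition, replicate counts are modelled as

```
k_i ~ NegBin(mean = p * n_i, dispersion = phi)
```

with `p` the retention probability and one dispersion shared across
replicates (`variance = mu + mu^2/phi`). `nb_fit()` minimises the negative
log likelihood with bounded quasi-Newton (L-BFGS-B) over `p` in
`[1e-6, 1]` and `log(phi)` with `phi` in `[1e-3, 1e3]`, from the fixed
start `p0 = sum(k)/sum(n)`, `phi0 = 1` — deterministic, no seed involved.
With three replicates `phi` is weakly identified, hence the bounds, and a
fit landing on a bound is flagged. The objective clamps its parameters
inside the bounds so that finite-difference gradient probes at the
boundary stay finite.

Differential retention between conditions A and B is scored by the
likelihood ratio

```
lambda = L_joint / (L_A * L_B)
```

where the joint fit shares a single `p` across all replicates of both
conditions but refits its own dispersion, keeping the comparison a
genuine nested-model contrast; consequently `lambda <= 1`, with small
values indicating differential retention. `lambda` is treated as the
region's significance value and adjusted across all tested regions with
Benjamini-Hochberg (`fdr_correct()`), transcriptome-wide rather than per
gene. An optional calibrated mode (`calibrate = TRUE` in `diff_splice()`)
additionally maps `-2 log lambda` through a 1-df chi-square; it is an
extension and off by default.

A numerical detail with a visible consequence: the NB objective is the
*weighted mean* negative log likelihood over unique `(k, n)` pairs. For
two conditions carrying identical data, the joint objective is then
bitwise identical to each separate objective, the optimiser follows the
identical path, and `lambda` is exactly 1 — the identical-data null holds
in floating point, not merely approximately. Tiny positive `log lambda`
from optimiser slop in other configurations is capped at `lambda = 1`.

## Targeted fractions

`intron_spanning_fraction()` reproduces the targeted splicing readout used
for the XBP1 unconventional intron: among reads whose raw footprint covers
the intron plus a 10-base flank, the fraction whose alignment carries an
`N` run covering at least 90% of the interval. Exact splice-boundary
matching would be brittle to splice-site wobble in long reads; both
tolerances are declared defaults. Uncertainty is the binomial
delta-method standard error on the logit scale, `sqrt(1/k + 1/(n-k))`,
back-transformed to a 2-SE interval; at `k = 0` or `k = n` a +0.5
continuity correction is applied and flagged. `gel_splicing_fraction()`
implements the gel-band formula `(s + h/2)/(u + s + h)`, the hybrid
heteroduplex carrying one strand of each product.

## What the generator emulates — and what it does not

`simulate_transcriptome()` produces a reference chromosome, multi-exon
genes (4–6 exons by default; all introns at least 20 bases, detectable
under the 10-base merge rule), a fully spliced isoform per gene plus an
isoform retaining one middle intron, two conditions with three biological
replicates each, and per-read truth. Defaults encode the study design the
analysis targets: 20 genes, 200 reads per gene per replicate, a regulated
gene whose retention shifts 0.95 → 0.35 between conditions while the
remaining genes hold a 0.30 background in both (null regions), 2%
substitution errors, equal forward/reverse read orientation, and
5'-truncation drawn as a Beta(8, 2) fraction of the transcript retained
from its 3' end — oligo-dT priming anchors the 3' end, so loss is from
the 5' side. Barcode count and length are free choices (16 nt, up to 24),
as the primer design itself does not fix them.

Emulated deliberately: the barcode/poly-T/CP read layout in both
orientations, substitution errors at a configurable rate (indels
configurable, default 0 so mismatch counts are exactly predictable —
the matcher still uses edit distance), isoform mixtures with
condition-specific proportions, truncation, and spliced alignments built
directly from isoform structure (`M` over blocks, `N` over spliced-out
introns).

Not emulated: basecalling error profiles (homopolymer-biased errors),
chimeric reads, PCR duplicates, aligner-specific artefacts (the simulator
stands in for the aligner, so alignment errors are absent by
construction), polyadenylation tails, and multi-isoform mixtures beyond
one retained intron per gene. Passing tests therefore demonstrate the
correctness of the *analysis rules* under the statistical structure the
method assumes — not robustness to every failure mode of real nanopore
data.

In recovery simulations for the NB fit, generated counts are clamped at
the spanning coverage (`k <= n` is a model precondition); with dispersion
50 — moderate biological overdispersion — the clamp is rare and shifts
the mean by well under the 0.03 bias budget.

## Problem sizes used in the checks

The shipped tests and the acceptance script size their simulations to be
informative while staying lightweight: 10,008 reads at 2% error for
demultiplexing recall and misassignment; 500 random CIGARs against a
naive per-base oracle; six genes of noise-free, full-length reads for
boundary recovery; 200 Monte-Carlo repeats per retention level for bias;
a 20-gene, 2-condition, 3-replicate end-to-end run (24,000 reads) for
detection; 1,000 intron-spanning reads for the targeted fraction.

## Known limitations

* The segmentation scan is the analysis rule itself, not a changepoint
  method; it is order-dependent by design and is not upgraded to binary
  segmentation or HMMs.
* `lambda` is used directly as a significance value, as the analysis
  defines it; it is not a calibrated p-value unless the chi-square
  extension is enabled.
* Retention of terminal introns is censored by the terminal-trim rule
  (see above).
* No UMI handling, dual barcodes, quality-aware matching, beta-binomial
  alternative, covariate adjustment, or more-than-two-condition omnibus
  test.
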