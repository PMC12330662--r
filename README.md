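# nanopsi

Demultiplexing and differential splice-isoform analysis for barcoded
long-read cDNA sequencing.

## What it does, and for whom

Long-read (e.g. Oxford Nanopore) sequencing of oligo-dT-primed cDNA reads
whole transcripts, so each spliced alignment reveals which introns a
transcript retained and which it spliced out. `nanopsi` is for
transcriptomics researchers who multiplex samples with barcoded oligo-dT
primers and want to ask, beyond gene-level expression, **where and how
strongly intron retention changes between conditions** — the kind of
question that arises when ER stress or an activated RNase (IRE1 acting on
XBP1) shifts the balance of splice isoforms.

The package covers the full path from raw reads to tested regions:

1. **Demultiplexing** — anchored, mismatch-tolerant barcode assignment
   around the poly-T tract and common primer (edit distance ≤ 3; reads
   with zero or multiple matching barcodes are excluded), plus trimming.
2. **Gene assignment** — each alignment goes to the annotation maximising
   `overlap / max(annotation length, footprint length)`; per-sample gene
   counts feed an external differential-expression engine, with the usual
   significance thresholds (BH FDR ≤ 0.05, |log2FC| ≥ 0.5) applied here.
3. **%SI pileup** — per base, the number of spliced-in reads `k` and
   spanning reads `n` from cleaned CIGARs (runs < 10 bp merged,
   insertions ignored, terminal runs of each read discarded, reads ≤ 80%
   aligned dropped). The ratio is the percent-spliced-in (%SI).
4. **Segmentation** — replicates pooled by summing counts, low-coverage
   positions masked (any sample < 5, any condition mean < 20), then a
   cumulative-average scan opens a new region whenever %SI deviates from
   the running mean by more than 0.1; never-retained regions (< 0.05
   everywhere) are dropped and each region summarised as rounded
   per-sample `(k, n)`.
5. **Differential splicing** — per region and condition, retention is
   estimated by maximum likelihood under `k_i ~ NB(mean = p·n_i,
   dispersion φ)`; conditions are compared by the nested likelihood
   ratio `λ = L_joint / (L_A · L_B)` (λ ≤ 1, identical data ⇒ λ = 1
   exactly), adjusted across regions by Benjamini–Hochberg.
6. **Targeted fractions** — the XBP1-style intron-spanning readout with
   logit-space standard errors, and the gel-band formula
   `(s + h/2)/(u + s + h)`.

A first-class synthetic-data module (`simulate_transcriptome()`,
`emit_raw_reads()`, `emit_alignments()`, `write_simulation()`) generates
genes, isoform mixtures, barcoded reads and spliced alignments with known
truth, so every stage is verifiable without external data. See the
methods vignette (`vignettes/nanopsi-methods.Rmd`) for the model details
and design choices.

## Worked example

Simulate a six-gene study — two conditions, three replicates, 200 reads
per gene per replicate, 2% substitution error — in which `gene001`'s
middle intron shifts retention 0.95 → 0.35 while the other genes hold a
0.30 background, then run the analysis:

```r
library(nanopsi)

sim <- simulate_transcriptome(n_genes = 6, seed = 11,
  design = condition_design(reads_per_gene = 200),
  arch = read_architecture(barcodes = default_barcodes(6)))
sim
#> <sim_transcriptome> 6 genes, 12 isoforms, 6 samples, 7200 reads (seed 11)

reads <- emit_raw_reads(sim)
demux <- demux_reads(reads, sim$arch$barcodes, cp = sim$arch$cp)
table(demux$status)
#>       assigned multiple_found
#>           7199              1

sheet <- sim$truth$sample_sheet
keep  <- demux$status == "assigned"
aln   <- emit_alignments(sim)
aln   <- aln[match(demux$read_id[keep], aln$read_id), ]
aln$sample_id <- sheet$sample_id[match(demux$barcode_id[keep],
                                       sheet$barcode_id)]

pl  <- gene_pileups(aln, sim$genes)
seg <- segment_genes(pl, sheet)
res <- diff_splice(seg$counts, "ctrl", "stress")
head(res[order(res$lambda),
         c("region_id", "p_a", "p_b", "delta_psi", "lambda", "fdr")], 4)
#>              region_id   p_a   p_b delta_psi   lambda      fdr
#> 2    gene001:1344-1463 0.962 0.318   -0.6445 1.44e-05 0.000389
#> 20   gene005:8383-8518 0.223 0.267    0.0441 3.34e-01 1.000000
#> 11   gene003:4882-4944 0.291 0.259   -0.0327 5.85e-01 1.000000
#> 25 gene006:10216-10323 0.265 0.292    0.0269 7.09e-01 1.000000
```

The top region is the regulated gene's retained intron: its boundaries
(1344–1463) match the intron, the per-condition retention estimates
(0.96, 0.32) recover the simulated probabilities, Δ%SI ≈ −0.64, and its
likelihood ratio is orders of magnitude below every null region. The
`fdr` column is the BH-adjusted λ; `-log10(fdr)` and `delta_psi` are the
volcano-plot axes.

The same analysis runs file-to-file (FASTQ/SAM/GTF/TSV in, TSV/BED/JSON
out) through `run_pipeline(pipeline_config(...))`, or from a shell via
`inst/scripts/nanopsi-pipeline.R`; every threshold above is a named,
overridable parameter whose default is the standard analysis, and the run
manifest records the configuration and the MD5 of every output.

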