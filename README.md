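# apaseq

Cleavage-site calling and alternative-polyadenylation (APA) analysis for
3'-end sequencing (3'-Seq) data, with a fully deterministic synthetic-data
generator that makes every stage testable without any external dataset.

## What it does

3'-Seq reads span the transcript cleavage site and carry the start of the
untemplated poly(A) tail. `apaseq` implements the complete analysis path:

1. **Untemplated-tail detection** — a read supports a cleavage-site (CS)
   call iff, in transcript orientation, it ends in a run of ≥ 8 As of which
   ≥ 5 of the first 8 mismatch the reference (rejecting internal-priming
   artifacts at genomic A-tracts). The cleavage coordinate is the first
   base of the run. Both SAM tail dialects (3' soft-clips and
   mismatch-aligned tails) are handled.
2. **CS calling** — per-gene poly(A) CS profiles (reads supporting
   cleavage at each position); sites are profile local maxima with ≥ 50 nt
   spacing (the stronger site wins below that) and ≥ 10 pooled supporting
   reads; genomic categories assigned by priority
   3'UTR > CDS > 5'UTR > intron > downstream extension > intergenic.
3. **PAS positional enrichment** — exact scans for the canonical AAUAAA
   (DNA: AATAAA) and 11 variants in ±100 nt around each CS; correctly
   mapped sites peak sharply at ≈ 20 nt upstream (offset −20).
4. **Differential CS usage** — per multi-CS 3'UTR, Pearson chi-square on
   the CS × condition count table with Benjamini–Hochberg FDR control;
   the Proximal Usage Index PUI = proximal reads / UTR total; direction of
   shift from ΔPUI; global shortening/lengthening trend via an exact
   binomial test of the direction split against 50/50 plus a paired
   Wilcoxon test on per-UTR PUIs.
5. **Auxiliary omics** — RNA-seq fold-change (RPKM → quantile
   normalization → log2 ratio with a 1.0 expression floor) and the IP-MS
   interactor filter (> 2-fold in ≥ 2 of 3 replicates, strict) with
   edge-list export.

The synthetic generator (`sim_config()`, `simulate_transcriptome()`,
`simulate_reads()`, `simulate_usage_tables()`, `simulate_aux_matrices()`)
emits FASTA/GTF/SAM with planted CSs, PAS hexamers, cleavage jitter,
untemplated tails, internal-priming decoys and per-condition usage
proportions, plus ground-truth tables for parameter-recovery testing.

## Worked example

```r
library(apaseq)

cfg <- sim_config(
  n_genes = 12, n_cs_per_utr = 2, reads_per_utr = 150,
  usage_props = list(control = c(0.5, 0.5),
                     treated = c(0.7, 0.3)),   # proximal usage +0.2
  seed = 42)
report <- run_end_to_end(cfg, out_dir = "apaseq_demo")
str(report[c("n_cs_called", "cs_recovery_rate", "pas_modal_offset",
             "n_multi_cs_utrs", "n_significant", "n_enhanced", "n_reduced",
             "binomial_p_vs_half")])
#> $ n_cs_called       : int 24
#> $ cs_recovery_rate  : num 1
#> $ pas_modal_offset  : int -21
#> $ n_multi_cs_utrs   : int 12
#> $ n_significant     : int 12
#> $ n_enhanced        : int 12
#> $ n_reduced         : int 0
#> $ binomial_p_vs_half: num 0.000488
```

All 24 planted sites are recovered (`cs_recovery_rate` 1); the PAS modal
offset lands at −21, one off the planted −20, because the called site
absorbs residual cleavage jitter; all 12 UTRs show the planted proximal
shift (12 enhanced / 0 reduced), and the direction split differs from the
50/50 chance expectation with p = 2·0.5¹² ≈ 4.9e−4. `apaseq_demo/`
contains `genome.fa`, `genes.gtf`, per-sample SAM files, `cs_sites.bed`,
`cs_counts.tsv`, `apa_results.tsv`, `pas_profile.tsv`, `report.json` and a
`manifest.json` recording parameters, seed and file digests.

## Scope notes

Comparisons are pairwise (treated vs control) on pooled condition counts;
dispersion-aware models, UMI handling and isoform quantification are out
of scope. See `vignettes/apaseq-methods.Rmd` for the model, parameter
defaults, simulator assumptions and known limitations.
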