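---
title: "apaseq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{apaseq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

3'-end sequencing (3'-Seq) captures the 3' termini of polyadenylated
transcripts and maps cleavage-and-polyadenylation sites (CSs) at nucleotide
resolution. Because read counts at a CS quantify its usage, 3'-Seq detects
alternative cleavage and polyadenylation (APA): condition-dependent shifts
between the proximal and distal CSs of a 3'UTR, which shorten or lengthen
the UTR. `apaseq` implements the complete analysis path from aligned
3'-Seq reads to per-3'UTR differential-usage calls, together with a
deterministic synthetic-data generator that makes every stage verifiable at
desk scale, and two auxiliary utilities (RNA-seq fold-change and an IP-MS
interactor filter) that belong to the same experimental programme.

## The analysis model

### Untemplated-tail detection and the internal-priming guard

A read supports a cleavage event only if it carries the *start of the
untemplated poly(A) tail*: in transcript orientation its 3' end must show a
terminal run of at least 8 As, of which at least 5 of the first 8 mismatch
the genome at the positions they align (or, for soft-clipped tails,
extrapolate) to. The mismatch requirement is the internal-priming guard: in
oligo-dT-primed libraries the primer can anneal to genomic A-rich tracts
inside transcripts, producing reads that end in *templated* As. Those match
the reference and are rejected. The cleavage coordinate is the genomic
position of the first base of the run, equivalently one past the last
templated base, reported in transcript orientation.

Two SAM "tail dialects" are handled through the CIGAR: modern aligners
soft-clip the untemplated tail, while permissive mismatch settings
(Bowtie-era alignments) place it as aligned mismatching bases.
`detect_tails()` reconstructs the read/reference pairing across both, and
across runs that straddle the clip boundary.

The A-run is strict: a sequencing error inside the tail truncates the run
at that point. With tail lengths of 10-30 nt and per-base error rates well
below 1%, a genuine tail still presents >= 8 clean As with high
probability; the simulator's defaults keep this regime.

### CS profiles and site selection

Tail calls are assigned to genes by position and strand, with gene spans
extended 1 kb downstream (configurable) because cleavage past the annotated
3' end is routine in 3'-Seq; such sites are categorised
`downstream_extension`. Per gene, the pooled **CS profile** records the
number of supporting reads at each position. Because per-read cleavage
scatters around a major site, sites are called as profile local maxima
under two rules:

* **spacing** -- accepted sites must lie >= 50 nt apart; when two
  candidates are closer, the stronger (higher-support) one is kept. This
  pairwise rule is generalised to many close peaks by a greedy pass:
  candidates ranked by support (ties broken toward the more proximal
  position) are accepted iff no already-accepted site lies within 50 nt.
  Greedy ranking is deterministic and reduces to the pairwise description
  for two peaks; tests verify it against an independent brute-force
  implementation of the same rule.
* **support** -- after selection, profile counts are re-aggregated onto the
  nearest accepted site within +/-25 nt (half the spacing; ties toward the
  proximal site) and sites with pooled support below 10 reads are dropped.
  The support threshold is applied to the *pooled* (all-sample) profile,
  maximising sensitivity; per-sample thresholding is available by running
  the caller per sample.

Localisation accuracy of the profile-argmax estimator is depth-limited:
with cleavage jitter of sd 3 nt, the empirical mode of n supporting reads
falls within +/-2 nt of the true major site roughly 80% of the time at
n = 20, 92% at n = 60, and 99% at n = 200. The package's verification runs
therefore use the default depth of 200 reads per UTR per sample; at very
low depth, sub-2-nt localisation is not attainable by any argmax-based
rule, which is a property of mode estimation rather than of the
implementation.

Genomic categories are assigned by priority
`3UTR > CDS > 5UTR > intron > downstream_extension > intergenic`, so a site
falling in one gene's 3'UTR and another's intron is counted as 3'UTR.

### PAS positional enrichment

As a precision check on CS mapping, the +/-100 nt window around every
called site (transcript sense; reverse-complemented for minus-strand
sites) is scanned for exact polyadenylation-signal hexamers: canonical
AATAAA plus eleven common variants (ATTAAA, TATAAA, AGTAAA, AAGAAA,
AATATA, AATACA, CATAAA, GATAAA, AATGAA, TTTAAA, ACTAAA), configurable.
Offsets are measured at the hexamer 3' end relative to the CS, negative
upstream, so correctly mapped sites produce a sharp peak near -20.
Enrichment is reported descriptively (peak/background ratio and a
one-sided binomial test against a uniform-offset null); no specific
significance test is canonical for this display, so the choice is
documented rather than asserted.

### Differential usage, PUI and the global trend

For every 3'UTR with >= 2 called CSs, replicate samples are pooled within
condition into a CS x 2 contingency table and tested with Pearson's
chi-square (no continuity correction), df = nCS - 1; tables with any
expected count below 5 are flagged, not substituted, since the chi-square
test is the prescribed method. P-values are adjusted by Benjamini-Hochberg
across UTRs, significance at FDR < 5% by default.

The **Proximal Usage Index (PUI)** is defined here as the plain fraction
`reads at the most proximal CS / total reads over the UTR's CSs`, bounded
in [0, 1]; log-ratio variants exist in the literature but the bounded
fraction is the most interpretable summary and is what the direction
classification needs. `delta_pui` is treated minus control of
condition-pooled PUIs; its sign classifies a UTR as `proximal_enhanced`
(3'UTR shortening) or `proximal_reduced`, with exact zeros recorded as
`none` and excluded from direction counts.

The global trend is assessed two ways: (i) a two-sided exact binomial test
of the enhanced/reduced split among significant UTRs against the 50/50
ratio expected by chance, and (ii) a two-sided Wilcoxon signed-rank test
on paired per-UTR PUIs over *all* multi-CS UTRs, which would detect a
global drift in proximal usage even below per-UTR significance.

### Behaviour of BH under a complete null

One calibration property deserves a note. Under a complete null with
independent (continuous) p-values, the BH step-up procedure makes at least
one false discovery per experiment with probability equal to the FDR level
(Simes' equality) -- i.e. about 1 in 20 null datasets at FDR 5% will show
a spurious call, by design. On discrete chi-square p-values at 200 reads
per condition we measure this per-dataset probability at roughly 5-9%
(the Pearson approximation is mildly anti-conservative in the far tail of
2x2 lattices). Consequently "no false FDR calls" cannot be expected in
more than ~95% of null simulations *in expectation*, and any fixed small
set of replicates will fluctuate around that value; the test suite
documents one such fluctuation rather than masking it. The bulk
calibration (fraction of raw p < 0.05 equal to 0.05) is exact to within
binomial noise.

## The synthetic-data generator

`simulate_transcriptome()` and `simulate_reads()` generate the structure
the analysis assumes, with ground truth for parameter recovery:

* Single-exon genes (60-nt 5'UTR, 300-nt CDS, 3'UTR of 300-400 nt by
  default) laid in tandem on one chromosome with 300-nt gaps and 200-nt
  chromosome flanks; genes alternate strands so both orientations are
  always exercised.
* One to three CSs per 3'UTR, the first 40 nt into the UTR, spaced 150 nt
  by default; a configuration whose CSs cannot fit the UTR is rejected.
  Each CS carries the PAS hexamer ending 20 nt upstream (transcript
  sense).
* Per-read cleavage jitter is a discretised normal (sd 3 nt by default)
  truncated to +/-10 nt, reproducing the observed fluctuation of cleavage
  around a major site while keeping the major site well-defined.
* Untemplated tails of 10-30 nt; reads are 50 nt; 200 reads per UTR per
  sample; per-base substitution errors at 0.001. Read length and depth are
  not reported for the motivating experiments, so these defaults are
  explicit configuration, chosen as typical of short-read 3'-Seq.
* Tails are written as terminal soft-clips in half the records and as
  aligned mismatching bases in the other half, so both SAM dialects are
  always exercised.
* Background sequence is A-depleted (p(A) = 0.12) and a +/-12-nt zone
  around each CS is kept A-free: genuine cleavage sites do not sit inside
  genomic A-tracts (reads there would be indistinguishable from
  internal-priming artifacts by construction), and the zone guarantees the
  first 8 reference bases under a jittered tail are informative for the
  mismatch rule.
* When `internal_priming_rate > 0`, a 12-nt templated A-tract is planted
  in each UTR at least 25 nt from every CS and clear of every PAS, and
  artifact reads ending in that tract are emitted. These must yield zero
  tail calls -- the exactness check of the 5-of-8 guard.

`simulate_usage_tables()` generates multi-CS usage tables directly at the
count level (multinomial) for statistical calibration at hundreds of UTRs,
where read-level simulation adds nothing but runtime.
`simulate_aux_matrices()` plants expression fold-changes and IP-MS
interactors with known truth.

What the generator does **not** emulate: realistic transcriptome-wide
expression distributions, instrument-specific error profiles, multi-exon
gene structure (introns are exercised through hand-written GTFs in the
test suite), UMI duplicates, or paired-end reads. Passing tests therefore
demonstrate correctness of the rules and statistics, not performance on
the full complexity of real libraries.

## Numerical and convention choices

* **Coordinates** are 1-based closed everywhere internally (the
  GRanges/IRanges convention); GTF is native, BED is converted to 0-based
  half-open only at the write/read boundary. A single internal convention
  avoids off-by-one drift; the 1-based choice matches the host ecosystem.
* **"Uniquely mapped"** is approximated at the flag level: unmapped,
  secondary (0x100) and supplementary (0x800) records and MAPQ = 0 records
  are dropped. Aligner-specific uniqueness flags are not portable; the
  count of dropped records is always reported.
* **Tie-breaks** are all deterministic and proximal-first: candidate
  ranking in site selection, support aggregation, and per-sample tail-call
  assignment (a call equidistant between two sites goes to the more
  proximal).
* **Degenerate inputs**: empty profiles yield empty site lists; a zero
  count total makes PUI undefined (NA, skipped with a log note); a
  condition with zero total counts is an error; PAS windows truncated at
  chromosome edges are scanned over the available part and flagged.
* **Interactor filter**: ">2-fold" is read strictly (`log2` difference
  > 1), configurable to `>=`; a protein missing in a replicate fails that
  replicate (conservative; no imputation).
* **Determinism**: every simulation consumes a single integer seed;
  identical configuration and seed give byte-identical FASTA/GTF/SAM/TSV
  and report JSON. Stage seeds are derived from the config seed by fixed
  offsets.

## Problem sizes used in verification

The shipped verification runs use 200 genes x 200 reads/UTR/sample for CS
recovery, 50 genes at internal-priming rate 0.2 for the artifact guard,
20 x 500 null UTR tables and 20 x 200 planted-shift tables (200 reads per
condition) for calibration and power, and 1000 random profiles for the
selection-rule equivalence check. These sizes give stable estimates of the
binary pass properties while keeping a full run in the order of a minute.

## Limitations

Dispersion-aware differential usage (beta-binomial), isoform-level
quantification, UMI handling, de-novo annotation correction and
time-course modelling are out of scope; comparisons are pairwise per
condition. The chi-square test treats replicate pooling as exact, which is
anti-conservative when biological replicate variability is large --- with
one sample per condition (the design the pipeline defaults emulate) the
point is moot, but users with replicates should interpret borderline calls
accordingly.

## Worked example

```{r example}
library(apaseq)

cfg <- sim_config(
  n_genes = 12, n_cs_per_utr = 2, reads_per_utr = 150,
  usage_props = list(control = c(0.5, 0.5),
                     treated = c(0.7, 0.3)),   # proximal shift of +0.2
  seed = 42)
report <- run_end_to_end(cfg, out_dir = "apaseq_demo")
str(report[c("n_cs_called", "cs_recovery_rate", "pas_modal_offset",
             "n_significant", "n_enhanced", "n_reduced",
             "binomial_p_vs_half")])
```

On this configuration the pipeline calls all 24 planted sites
(`cs_recovery_rate` 1), places the PAS peak at -21 (one off the planted
-20 because the modal called site absorbs residual jitter), finds all 12
UTRs significantly shifted with 12 enhanced / 0 reduced, and the binomial
test against the 50/50 expectation gives p = 2 * 0.5^12 ~= 4.9e-4.
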