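# molmeth

Single-molecule analysis of targeted enzymatic methyl-seq (EM-seq) long
reads for plant genomes.

Population-averaged methylation assays (WGBS-style) can miss regulatory
events that occur in a *subpopulation* of molecules: a locus where 15% of
cells gain a block of consecutively methylated CG sites, or where a bound
factor leaves an unmethylated footprint over a cis-element, may show almost
no change in per-site average levels. Targeted single-strand capture of a
panel of loci followed by enzymatic conversion and long-read sequencing
phases every cytosine of a target along one DNA molecule, so those
subpopulations become directly countable. `molmeth` is the analysis side of
that experiment, for anyone with a reference panel and converted long reads
(plus an optional WGBS-style table for concordance checks).

## What it computes

For each captured target (coding strand only), cytosines are enumerated and
classified into the three plant contexts — CG, CHG (H ∈ {A,C,T}) and CHH —
from the two downstream bases. Reads are assigned to targets with
conversion-independent terminal anchors (C/T-collapsed alphabet), globally
aligned with T-over-C treated as a match, and turned into per-molecule
ternary call vectors (C → methylated, T → unmethylated, else missing).
Reads with more than three consecutively methylated CHH sites are removed
as conversion failures, and conversion efficiency is estimated from an
unmethylated internal-control region as the pooled fraction of C→T calls.

On the filtered molecules the package computes:

* **mPPM** — methylation proportion per molecule: for read *i* and context
  *c*, `mPPM_i = (# methylated sites of c on read i) / (# sites of c)`,
  on filtered full-length reads.
* **DmPPM** — between-condition shifts in the mPPM distribution, tested at
  molecule level with the Kruskal–Wallis rank test (pairwise across
  conditions; replicates pooled).
* Per-site mean levels and regional means per replicate, compared across
  conditions by one-way ANOVA with post-hoc Tukey HSD.
* Within-molecule context co-methylation: per-read
  (mPPM_CG, mPPM_CHG, mPPM_CHH) triples, strict-ordering fractions and
  pairwise correlations.
* Run-length signatures and footprints: maximal runs of consecutive
  (un)methylated sites per molecule, declarative footprint specs
  ("first 2 CG sites unmethylated", "≥ 6 consecutively methylated CG"),
  their per-condition prevalences with replicate-level ANOVA/Tukey, and
  footprint-conditioned mPPM comparisons.
* QC: on-target fractions, per-target coverage (log2(reads + 1)),
  percentage of targets detected by ≥ 1 / ≥ 10 pooled filtered reads, and a
  logarithmic regression `reads = a + b·ln(GC)` of capture yield on target
  GC content.
* Single-molecule heatmaps: intervals between adjacent sites colored red
  (both flanking calls methylated), black (both unmethylated) or gray
  (transition); rows are molecules, hierarchically clustered on CG calls by
  Kendall's τ (binary τ-b) or Euclidean distance; display capped at a
  seeded subsample of 1,000 reads (statistics always run pre-subsampling).

A seeded simulator generates epiallele mixtures (per-context two-state
Markov chains with stationary probability p and persistence ρ, a shared
molecule-level propensity coupling contexts, and footprint-bearing
classes), converts them into reads under an explicit conversion model, and
keeps ground truth, so every stage is testable without sequencing data.

## Worked example

```r
library(molmeth)

dir <- tempfile("demo")
cfg <- toy_experiment(dir, seed = 7, reads_per_sample = 30)  # writes ref + reads
res <- run_pipeline(cfg, file.path(dir, "out"))

res$qc$per_sample
#>   sample total_reads on_target on_target_fraction
#> 1  cond1         120       120                  1
#> 2  cond2         120       120                  1

res$qc$conversion_rate
#> [1] 0.9946101

subset(res$dmppm, target_id == "T1")
#>   target_id context sample_a sample_b statistic      p_value median_diff significant
#> 1        T1      CG    cond1    cond2  79.02761 6.124787e-19 -0.41666667        TRUE
#> 2        T1     CHG    cond1    cond2  49.21523 2.293630e-12 -0.20000000        TRUE
#> 3        T1     CHH    cond1    cond2  25.43549 4.574250e-07 -0.02739726        TRUE

res$prevalence
#>         spec_id sample n_reads n_matching  fraction
#> 1 first2cg_open  cond1      57         42 0.7368421
#> 2 first2cg_open  cond2      56         12 0.2142857
#> 3   run2cg_meth  cond1      57         48 0.8421053
#> 4   run2cg_meth  cond2      56         56 1.0000000
```

The toy scenario simulates two conditions whose CG stationary methylation
differs (0.2 vs 0.6): every read is on target, the internal control reports
the simulated ~99.5% conversion, the CG DmPPM test flags the shift
(median mPPM difference −0.42), and the "first 2 CG unmethylated" footprint
is correspondingly commoner in the low-methylation condition. Output tables
(mppm.tsv, dmppm.tsv, footprint_prevalence.tsv, qc.json, per-sample
heatmap PNGs with row-order sidecars, manifest.json) land in `out/`.

A thin CLI lives at `inst/scripts/molmeth`
(`molmeth run --config config.yaml --outdir out`,
`molmeth sim --outdir dir --seed 1`).

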