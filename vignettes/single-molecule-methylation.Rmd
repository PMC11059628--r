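---
title: "Methods: single-molecule targeted methylation analysis with molmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule targeted methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molmeth)
```

# The measurement model

`molmeth` analyses targeted enzymatic methyl-seq (EM-seq) long reads: a
panel of single-stranded regions is captured from the coding strand of each
gene, unmethylated cytosines are enzymatically converted (C → U, read as
T), 5mC is retained as C, and each sequenced molecule reports the joint
methylation state of every cytosine along one original DNA strand. Only
the captured strand is analysed; opposite-strand cytosines do not exist in
the library.

Three assumptions follow the chemistry and drive every design choice:

1. **A read base at a cytosine site is ternary evidence.** C means
   methylated, T means converted (unmethylated), anything else —
   substitution, N, gap, uncovered — is *missing*, never coerced to a
   state.
2. **Conversion state must not affect read-to-target assignment.** Both a
   fully methylated and a fully converted molecule must map to their
   target, so assignment and alignment collapse C and T into one symbol
   (anchors) or score T against reference C as a full match (global
   alignment).
3. **Conversion failure is a per-molecule, run-like event.** A molecule
   that escaped conversion shows long runs of apparently methylated CHH
   sites; reads with more than three consecutively methylated CHH sites
   (run length ≥ 4 over the CHH subsequence, in site order) are removed.
   A missing call breaks a run, so a molecule is never discarded on
   unobserved evidence.

## Cytosine contexts

Contexts are classified from the two bases downstream of each C on the
captured strand: CG when the next base is G (only one downstream base is
required), else CHG (C-H-G) or CHH (C-H-H) with H ∈ {A, C, T}. At the 3'
edge of a target a C whose context cannot be resolved inside the target is
dropped, as is any C whose window contains N (with a warning). Coordinates
are 0-based in the site catalog (`index` over sites, `offset` into the
target) and 0-based half-open in the target table, matching BED; element
annotations in the target table are 1-based inclusive because they are
written and read by people.

# Statistics

Two statistical layers mirror how single-molecule data are actually
compared:

* **Molecule level, replicates pooled.** The methylation proportion per
  molecule (mPPM) of a context is the fraction of that context's sites
  methylated on one filtered, *full-length* read (a read with an
  informative call at every site, so phasing is complete; a target without
  sites of a context yields no record rather than a zero). Condition
  differences in the mPPM distribution (DmPPM) are tested with the
  Kruskal–Wallis rank test with tie correction — with two groups this is
  the rank-sum test up to the chi-square approximation. Pairwise p-values
  are reported raw with an optional Benjamini–Hochberg column; the default
  significance level is 0.05. When every pooled value is identical the
  statistic is defined as 0 and p as 1 (the tie-corrected formula is 0/0
  there).
* **Replicate level.** Regional mean levels (mean over a subregion's sites
  of the per-site mean, molecules pooled within replicate) and signature
  prevalences give one value per condition × replicate; conditions are
  compared by one-way ANOVA with post-hoc Tukey HSD (studentized range).
  Per-site mean levels use all filtered reads with an informative call at
  the site, not only full-length reads. Subregions are explicit site-index
  windows supplied by the user, not auto-detected.

Within-molecule co-methylation is summarised by per-read
(mPPM_CG, mPPM_CHG, mPPM_CHH) triples, the fractions of reads with
*strictly* mPPM_CG > mPPM_CHG and mPPM_CHG > mPPM_CHH (ties count toward
neither), and pairwise Pearson correlations (method switchable to
Spearman). Capture-yield dependence on base composition is fitted as
`reads = a + b·ln(GC)`; with a constant response R² is reported as 0 and
the slope p as NA.

Conversion efficiency is estimated on the internal control region as the
pooled fraction of unmethylated calls over all reads and all three
contexts. The control is assumed essentially free of 5mC; truly methylated
control cytosines, if any, bias the estimate down slightly, which is the
conservative direction for QC.

# Signatures and footprints

All "consecutive" statements operate on the *context subsequence* in site
order (adjacent CG sites, for example, regardless of their genomic
spacing), consistently between the CHH filter, the run encoder, footprint
matching and heatmap coloring. Footprints are declarative: either an
explicit site-index set that must carry a state ("first 2 CG sites both
unmethylated") or a minimum run length within one or more windows, with
several windows meaning the run must occur in each (the two-flanks case).
Spec files are validated against the target's context subsequence at load;
out-of-range indices are fatal. Prevalence denominators are filtered
full-length reads only.

# Visualization

Heatmap rows are molecules, identical across the CG/CHG/CHH panels; the
interval between adjacent sites is red when both flanking calls are
methylated, black when both are unmethylated, gray for a transition and
blank when either is missing, with white verticals at the true site
offsets. Rows are ordered by agglomerative clustering of the CG calls
(configurable context), with distance 1 − τ (Kendall) or Euclidean;
since the calls are binary, τ-b reduces to the phi coefficient and is
computed in closed form. A constant row has no defined τ: a
constant-vs-nonconstant pair gets distance 1, two identical constant rows
distance 0. Linkage defaults to average (the distance, not the linkage, is
the meaningful choice here); missing calls are imputed as unmethylated for
distances only; rows are pre-sorted by read id so leaf order is
reproducible under input permutation. Displays are capped at 1,000
molecules by a seeded uniform subsample; statistics are always computed
before subsampling, so the display seed can never change a number.

# The simulator

The generator emulates the statistical structure the analysis assumes, at
the study's design scale: `simulate_panel()` draws ~108 targets of 509–704
nt spanning roughly 19–52% GC plus one unmethylated 558 nt internal
control, and `simulate_experiment()` produces 4 conditions × 4 biological
replicates with per-target read depth Poisson-distributed around a mean
increasing in ln(GC). Each target is given at least two CG sites near its
5' end so first-k-CG footprint definitions are always resolvable.

Each molecule draws an epiallele class (mixture weight w), then a shared
propensity z ~ N(0, propensity_sd) on the logit scale; per context, site
states follow a two-state Markov chain with stationary probability
`plogis(qlogis(p) + z)` and transitions `p(1→1) = p + ρ(1−p)`,
`p(0→1) = p(1−ρ)`, which keep the stationary probability exactly while ρ
tunes run lengths. Footprint-class masks are applied afterwards.
Conversion is modelled per site: unmethylated read as T with probability
`conv_eff` (default 0.995 — the assay's controls convert above 99%),
methylated retained as C with `meth_retention` (default 0.995), missing
with `miss_rate` (default 5 × 10⁻⁴, leaving the large majority of ~600 nt
molecules full length, as observed for real captures where 93–100% of
mapped reads are full length). Defaults are fixed once and documented
here; tests never tune them.

One behaviour of this model is worth stating plainly: increasing
`propensity_sd` raises the *correlation* between per-read context
proportions (shared z moves all contexts together) but *lowers* the
strict-ordering fractions P(mPPM_CG > mPPM_CHG) and
P(mPPM_CHG > mPPM_CHH), because extreme propensities push molecules toward
all-unmethylated or all-methylated triples where the inequalities tie or
invert. The ordering tendency itself comes from
p_meth(CG) > p_meth(CHG) > p_meth(CHH), not from the coupling.

**What the simulator does not model:** sequencing errors outside cytosine
sites (HiFi consensus error is negligible at this scale), indels, PCR
duplicates, chimeric capture, and any true per-site rate heterogeneity
within a context. Passing tests therefore demonstrate correctness of the
computations under the declared generative model, not robustness to every
artefact of real libraries; the conversion-aware aligner path is exercised
by indel fixtures, but genuinely noisy long-read alignment is delegated to
the alignment scoring, not re-validated against real data here.

# Numerical and degenerate-input choices

* Read assignment uses 30 nt terminal anchors with at most 5 mismatches on
  the better anchor (C/T-collapsed); equal-length reads map 1:1, others go
  through global alignment (gap open 5, extend 2, T≡C match). Reads with
  missing calls at more than 20% of sites are discarded as low quality
  (configurable).
* Degenerate class probabilities p ∈ {0, 1} are kept exact under the logit
  shift (no NaN leakage from infinite logits).
* `qlogis`/`plogis` give `plogis(qlogis(p)) = p` exactly for interior p,
  so ρ = 0 reduces to independent Bernoulli sites.
* All seeds are explicit arguments; identical seeds give byte-identical
  outputs end-to-end (FASTA, tables, heatmap sidecars).

# Problem sizes used in the shipped checks

The test-suite and the acceptance script run the generator at sizes chosen
to make Monte-Carlo bounds tight while staying quick on a laptop: 10,000
molecules for round-trip fidelity, ≥ 12,000 pooled calls per
conversion-rate recovery, 2,500 random cases per brute-force-oracle
comparison, 2,000 null replicates (n = 100 per group) for type-I error and
100 replicates (n = 200 per group) for power, n = 2,000 for
footprint-mixture recovery, n = 5,000 for coupling correlations, and a
24-target, 4 × 2 pipeline run for the end-to-end QC quantities. The full
108-target, 4 × 4 design is the generator default and runs the same code
paths.

# Known limitations

* Assignment assumes reads are oriented like the captured strand (the
  capture chemistry fixes orientation); reverse-complemented input reads
  are off-target.
* The DmPPM test inherits the chi-square approximation of Kruskal–Wallis;
  for very small groups (< ~5 molecules) an exact test would be
  preferable.
* Footprint windows must be supplied as site indices; the package does not
  discover footprints de novo.
* The per-site mean level uses an unweighted mean over molecules, which is
  the natural estimator here but ignores any read-quality covariates.
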