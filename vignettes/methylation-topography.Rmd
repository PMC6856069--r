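---
title: "Methods: functional and topographic methylation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional and topographic methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methtopo)
```

## The problem and the model

IDH1/2-mutant tumors accumulate the oncometabolite 2-hydroxyglutarate,
which inhibits TET demethylases and produces a genome-wide CpG
hypermethylator phenotype. `methtopo` asks where that phenotype lands:
which functional elements and which chromosomal territories are
consistently hyper- or hypomethylated across IDH-mutant cancers of very
different tissue origin.

The unit of observation is the array probe. Methylation per probe and
sample is a beta value $\beta \in [0,1]$ (fraction methylated signal);
statistics are done on the M scale, $M = \log_2(\beta/(1-\beta))$, which is
closer to homoscedastic and makes the state cutoffs symmetric:
$\beta = 0.8 \Leftrightarrow M = +2$ and $\beta = 0.2 \Leftrightarrow
M = -2$. A probe is **hyper**methylated in a group when its group-mean
$M \ge +2$, **hypo**methylated when mean $M \le -2$, otherwise neither.
Boundary values are included; the three states partition the universe, and
negating M swaps hyper and hypo exactly (a property the tests exercise).

Two calling paths exist, used for different questions:

* the six-way *common-probe* path calls states on **all** probes of the
  harmonized universe per group, then intersects across groups;
* the two-group *differential* path first selects probes at BH FDR < 0.05
  (per-probe two-sided Welch t on M), and applies the $\pm 2$ cutoffs
  within the significant list.

## Pipeline order and preprocessing

QC → sex-probe removal → platform harmonization → quantile normalization →
M conversion. Samples are kept when their mean detection p-value is
strictly below 0.01. Harmonization intersects the probe sets of the two
array platforms; whether normalization should precede or follow that
subsetting is not decidable from first principles, and this package
normalizes **after** harmonization so that the quantile reference is built
on exactly the analysis universe; the run log records the universe size.

Quantile normalization is plain per-universe (each column mapped onto the
mean quantile vector, ties sharing their slot mean, delegated to
`limma::normalizeQuantiles`). Infinium chemistry-stratified normalization
is available through the `stratify` argument when a probe-type column is
supplied; without one, stratification would be guesswork. Background
adjustment is an intensity-level correction and cannot be applied to
beta-level inputs; the run log says so rather than silently pretending.

The beta→M clamp is $\varepsilon = 10^{-6}$ (keeps $\beta \in \{0,1\}$
finite at $|M| \approx 19.9$, far outside any decision boundary).

## Statistics

* **Differential methylation**: per-probe Welch (unequal-variance) t with
  Welch–Satterthwaite degrees of freedom, two-sided, vectorized over rows
  and verified against `t.test` to 1e-12 in the tests. Probes with zero
  variance in both groups and equal means get $p = 1$ and a degeneracy
  flag. FDR is step-up Benjamini–Hochberg (Benjamini–Yekutieli switchable);
  the suite checks it against a quadratic brute-force implementation of the
  step-up definition.
* **Top-K selection** (default K = 10,000) orders by ascending q, breaking
  ties by larger $|\Delta M|$ then probe id, so heatmap input is
  deterministic. Heatmap leaf orders use Euclidean distance with complete
  linkage — the clustering the field's heatmap defaults use; the choice is
  declared in the config rather than hidden. `run_pipeline` caps the probe
  dendrogram at 2,000 probes (a report-size choice; `hierarchical_order`
  itself is uncapped).
* **Region comparisons** (genome-wide): the per-arm ratio vectors of two
  regions are compared by a two-sided paired t-test pairing on chromosome
  arm. A constant per-arm difference makes the paired t undefined; such
  comparisons are returned flagged `degenerate` with NA statistics, using
  the same numerical guard `t.test` applies.
* **Arm vs genome**: the printed per-arm ratio is a single number, so a
  test needs replicate structure. Replicates are generated by bootstrap
  resampling probes within the arm (and within the genome-wide region
  pool), B = 200 by default, seeded; the two replicate sets are compared by
  Welch t and BH-adjusted across arms within each region × state. This
  construction is package-defined — the bootstrap is over probes, so it
  captures sampling noise of the probe complement, not biological
  between-sample variance.
* **ORA**: upper-tail hypergeometric $P(X \ge k)$ with
  $X \sim \mathrm{Hypergeom}(N, K, n)$, BH across sets. The universe is
  all genes on the harmonized manifest (not all genes in the collection):
  the array, not the database, defines what could have been observed.
  Checked against exhaustive enumeration of draws on small instances.

## Probe algebra and the specificity table

Common probes are the intersection of a state's per-group sets over **all**
groups; unique probes are one group's set minus the union of the others;
Venn counts tally all $2^k - 1$ membership patterns (guarded at $k \le 7$).
Percent tumor-specific is $100 \cdot \mathrm{unique}/\mathrm{total}$
rounded **half-up** to one decimal — half-up, not banker's, because only
half-up reproduces all twelve published percents (1,752/100,100 = 1.75025
must print 1.8). Column averages: totals half-up to integer, unique
averages unrounded, percent averages half-up to one decimal, matching the
published table's own conventions.

## Topography

Coordinates: UCSC-style gap/cytoband text tables are 0-based half-open and
stay so internally; Illumina-style probe positions are 1-based and
converted once at lookup. A position is on the p arm strictly before the
centromere gap, on the q arm at or past its end, and unassigned inside it.
Band lookup is half-open $[start, end)$. BED/bedGraph exports are 0-based
half-open, tab-separated, headerless — bit-exact round-trips are tested.

Arm ratios exclude the acrocentric p-arms (13p, 14p, 15p, 21p, 22p), which
carry essentially no array probes; the exclusion list is configurable since
synthetic genomes name their arms differently. Probes without any region
annotation stay in "all probes" universes but never enter region-specific
denominators; multi-region probes count once per region.

A **desert** is operationalized as: zero common hyper and zero common hypo
probes in all three regions, with annotated-probe coverage ≥ `min_probes`
(default 50). The coverage guard prevents calling a desert where the array
simply has no probes; detection is monotone in the threshold. Track export
clips $|M|$ into $[1.9, 7]$ sign-preserving — a display convention only;
analysis always uses unclipped M.

## What the generator emulates — and what it does not

`synth_spec()` defaults define the study conditions used throughout the
tests and the acceptance script: a 6-chromosome genome (one acrocentric),
20,000 probes, six tumor groups × 8 samples, two platforms with 80% probe
overlap, noise sd 0.5 on the M scale. Generation is fully seeded and
byte-reproducible.

Baseline methylation is a three-mode beta mixture (unmethylated ≈ 0.1,
intermediate ≈ 0.5, methylated ≈ 0.85) with **region-dependent weights**:
promoters mostly unmethylated, gene bodies and enhancers mostly methylated
— the CpG-island asymmetry real arrays show, and the mechanism that makes
the common sets reproduce the functional headline (body/enhancer
hypermethylation, promoter hypomethylation). The intermediate mode exists
because group-specific effects need a neutral launch point: a ±3 ΔM shift
planted on an intermediate probe lands at $M = \pm 3$ and cleanly decides
the state, giving each group its own unique probes. Effects are planted on
the M scale (where the cutoffs live), per region (promoter −3, gene body
and enhancer +3), on a fraction (default 0.3) of each group's
intermediate-baseline probes, independently per group. One arm (chr1q gene
bodies by default) gets its methylated-mode weight multiplied by 1.35 —
the planted topographic enrichment the arm statistics must find. Desert
bands keep their annotations but are pinned to the neutral baseline with
no effects, so they are call-free by construction. The smallest decision
margin anywhere is 0.5 M (the methylated mode at 2.50 vs the +2 cutoff);
with 8 samples at sd 0.5 the group-mean SE is 0.18, which is why ≥95%
recovery is the expected regime and not a tuned outcome.

Not emulated: Infinium type I/II chemistry and dye bias, batch and FFPE
effects, spatially correlated methylation blocks, CNV-distorted betas, and
biological within-group heterogeneity beyond i.i.d. Gaussian M noise.
Passing recovery tests therefore demonstrates the pipeline's correctness
on clean planted structure, not robustness to every artifact of clinical
array data.

## Problem sizes and runtime choices

The default scenario (20,000 probes × 48 samples) runs the full pipeline
in a few seconds; the test-suite's null simulation uses 2,000 probes × 20
samples; enumeration oracles stay at $N \le 11$. These sizes make the suite
quick while keeping every estimate's Monte-Carlo error far from its
decision threshold.

## Known limitations

* The differential engine is per-probe Welch + BH, deliberately simple and
  fully oracle-testable; moderated-variance (empirical Bayes) statistics
  are out of scope, as are surrogate-variable/batch corrections.
* Quantile normalization assumes comparable global methylation
  distributions across samples — reasonable within a tumor cohort, not
  across radically different tissue mixtures.
* The arm-vs-genome bootstrap quantifies probe-sampling uncertainty only.
* Real-data genome-scale counts depend on the actual Illumina manifests
  and cohorts; the package reproduces published *arithmetic* and planted
  *structure*, not cohort-specific probe counts.
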