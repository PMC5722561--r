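---
title: "Methods behind biomepair: paired two-kingdom microbiome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind biomepair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

`biomepair` analyzes paired tumor / adjacent-normal tissue microbiomes
profiled in two kingdoms: a bacteriome (16S amplicons) and a mycobiome (ITS
amplicons), each summarized as a taxon-by-sample count table with lineage
annotations. The questions it answers are the standard ones for this design:

* Do tumor communities differ from their matched normal tissue in diversity
  (Shannon index), richness, and composition (Bray-Curtis, unweighted
  UniFrac, PCoA, dendrograms)?
* Which taxa differ in relative abundance between groups (Kruskal-Wallis
  with Bonferroni-Dunn adjustment), and which taxa covary within and across
  kingdoms (rank-correlation screens)?
* Can a random forest on the combined genus-level relative abundances
  distinguish tumor from normal tissue, how reliable is its error estimate
  (out-of-bag and 0.632+ bootstrap), which variables carry the signal
  (permutation importance against a random-grouping null, backward
  elimination), and does the per-patient *vote-fraction difference* — a
  field-cancerization statistic — associate with clinical covariates such
  as T-stage?

Because no public dataset accompanies this design, the package ships a
synthetic cohort generator that emulates the study conditions and gives
every downstream stage a testable ground truth.

## Data model

An `abundance_table` holds non-negative integer counts (taxa x samples)
with lineage columns (`kingdom`, `phylum`, `genus`, optional `species`) and
a declared row granularity (`rank`). A `paired_cohort` bundles one table
per kingdom, sample metadata (patient, tissue, T-stage, N-stage, smoking,
age, sex; unknowns are `NA`), and the patient pairing map. Key contracts:

* `aggregate_to_rank()` sums rows sharing a lineage at the coarser rank and
  conserves per-sample totals exactly (integer arithmetic).
* `to_relative_abundance()` normalizes within sample; columns sum to 1
  within 1e-9. Relative abundances are always computed *per kingdom*:
  bacterial and fungal reads come from separate amplicon libraries with
  incomparable depths, so pooling them into one denominator would let
  library chemistry masquerade as biology. A `joint = TRUE` switch exists
  for sensitivity analyses.
* `filter_low_depth_pairs()` removes a pair — both samples, both kingdoms —
  when either member has fewer than `min_reads` (default 50) *bacterial*
  reads. Filtering on the bacterial library only mirrors the practice of
  treating 16S depth as the quality gate; removing whole pairs preserves
  the paired design.
* Taxa with zero total count over the retained samples are dropped and
  logged; analyses only ever see taxa observed at least once.

## The synthetic cohort generator

`simulate_cohort()` draws counts from a Dirichlet-multinomial (DM) model,
the standard overdispersed count model for compositional microbiome data.
Per kingdom, a baseline log-composition follows a power-law abundance
decay (exponent 1.05 for bacteria, 0.9 for fungi), so the dominant
bacterial genus sits near 23% of the community — the regime in which one
abundant genus (a *Streptococcus* analog) can plausibly double in tumors.
The generative path per patient is:

1. a patient-level log-scale offset (SD `patient_effect_sd`, default 0.7)
   perturbs the baseline: both of a patient's samples share it, creating
   realistic within-pair correlation;
2. the tumor expected composition adds the planted log2 fold-changes and
   renormalizes. The default plants a 10-genus signal (8 bacterial, 2
   fungal) led by a doubling of the dominant bacterial genus; concentrating
   tumor mass onto fewer genera is what drives the recoverable drop in
   tumor Shannon diversity;
3. for high-T-stage patients (default fraction 0.54) the *normal* sample's
   expected composition is interpolated toward the tumor composition on
   the log scale: `normal' = tumor + (1 - a) * (normal - tumor)` with
   `a = field_attenuation_high` (default 0.3). `a = 0` leaves pairs
   untouched; `a = 1` makes the pair difference pure sampling noise. One
   knob therefore reproduces the phenomenon of tumor-like dysbiosis in
   normal-appearing tissue of patients with larger tumors;
4. library depth is log-normal per tissue and kingdom. Defaults match a
   cohort whose tumor libraries are shallower and far more variable than
   non-tumor libraries (bacterial medians 6,294 vs 13,561 reads; the
   spread parameters are matched to interquartile ratios, and the long
   lower tail of tumor depths is what makes the `min_reads = 50` pair
   filter occasionally fire, as it should);
5. counts are multinomial draws from a Dirichlet perturbation of the
   expected composition with concentration `overdispersion` (default 150:
   a genus at 2% abundance has roughly 57% coefficient of variation before
   counting noise, which is moderate overdispersion for tissue biopsies).
   Column sums equal the drawn depths exactly.

Optional `covarying_pairs` add a shared per-sample latent log-normal
factor to two genera, planting a positive correlation for the screen's
recovery tests. A `GroundTruth` object records the planted fold-changes,
per-patient T-stage and attenuation.

What the generator does *not* emulate: taxonomic misassignment, chimeras,
PCR and extraction bias, sparsity structure beyond DM, and real phylogeny
(trees are random within the genus-in-phylum nesting). Tests passing on
synthetic cohorts therefore demonstrate that the *machinery* recovers
planted effects under realistic noise — not that any biological claim
holds in real tissue.

## Community metrics

* **Shannon index** `H = -sum p_i log p_i` in natural log (nats), the
  convention of the ecology toolchain this field uses; `base` switches to
  log2/log10. `H <= log(richness)` always, with equality at uniformity.
* **Richness** counts taxa with positive abundance and is invariant to
  depth rescaling — but not to depth itself. No rarefaction is applied
  anywhere; with tumor libraries systematically shallower, richness
  contrasts partially reflect depth. This is deliberate (the pipeline
  reproduces the field's common practice) and documented rather than
  hidden; the depth medians are reported alongside.
* **Bray-Curtis** via `vegan::vegdist`; **unweighted UniFrac** is computed
  in-package on the tree's edge incidence (fraction of branch length
  leading to taxa present in exactly one of two samples, over branch
  length present in either), because the established implementations
  refuse multifurcating topologies such as star trees. On binary rooted
  trees it agrees with `picante::unifrac` to machine precision (tested).
  The ITS side of real studies rarely has a defensible phylogeny; UniFrac
  therefore requires an explicit tree input and is skipped without one.
* **PCoA** is classical scaling (`stats::cmdscale`): double-center
  `-D^2/2`, eigendecompose. Negative eigenvalues (routine for Bray-Curtis)
  are reported, never silently dropped, and excluded from the
  variance-explained denominator by default (switchable).
* **Dendrograms** use average linkage (UPGMA): deterministic, ultrametric,
  and exactly the exhaustive closest-pair-merge procedure (tested against
  a brute-force oracle). Samples are ordered lexicographically first so
  merge ties resolve deterministically; complete linkage is available.

## Group-wise testing

Per-taxon screens compute relative abundance per kingdom at the requested
rank and run an *unpaired* Kruskal-Wallis test per taxon — mid-ranks, tie
correction, chi-square reference — deliberately ignoring the pairing, as
is common in this literature; a paired Wilcoxon signed-rank variant is
available behind `paired = TRUE` as a clearly labeled extension. For two
groups the Bonferroni-Dunn post hoc reduces to the single comparison, so
the multiplicity family is the set of taxa tested within a kingdom at that
rank: `p_adj = min(1, p * m)`. An exact permutation p-value
(`p_method = "exact"`, exhaustive enumeration) exists for small two-group
problems where the chi-square approximation is poor.

Correlation screens default to Spearman rank correlation (robust for
compositional, zero-inflated abundances; Pearson switchable) with
Benjamini-Hochberg adjustment across all pairs in a scope — thousands of
exploratory pairs make family-wise control hopeless and these screens feed
network displays, not confirmatory claims. Constant taxa have undefined
coefficients and are reported as missing.

Two caveats shape the type-I-error checks in the test suite. Under the
generator's *default* conditions the unpaired test's null is never exactly
true even with no planted effects: tumor and normal samples differ in
depth (different dispersion of proportions) and share patient offsets
(within-pair correlation, which makes the unpaired test conservative). The
suite therefore verifies nominal type-I behavior on an *exchangeable* null
cohort — no planted effects, no attenuation, `patient_effect_sd = 0`,
tissue-symmetric depths — where the tested hypothesis actually holds, and
verifies *power* (planted fold-change recovery) under the realistic
defaults.

## The random-forest layer

`fit_rf()` wraps `randomForest` (ntree = 2001 trees, odd to avoid vote
ties; mtry = 10 candidate variables per split) on the merged 112-genus
relative-abundance matrix. Tumor and normal samples of one patient enter
as independent rows — the pairing enters only later, through the
vote-difference statistic. The exposed quantities are:

* **vote fraction**: fraction of trees, *among those where the sample was
  out of bag*, voting "tumor". Full-ensemble votes would be optimistically
  biased. A vote fraction above 0.5 predicts tumor; the OOB error is the
  misclassification rate at that threshold and is recomputable exactly
  from the exposed votes.
* **importance**: permutation mean decrease in accuracy, compared against
  `n_random_models = 20` refits on label permutations that preserve class
  sizes exactly (the "random groupings" null band).
* **backward elimination**: variables are ranked once by the full model's
  importance and never re-ranked after drops (re-ranking inside the search
  biases selection); each step removes the least important 20%
  (`drop_fraction`) of survivors down to 2 variables, recording OOB error
  per subset size. With `c_sd = 0` the smallest subset attaining the
  minimum error is selected — parsimony as the tie-break; `c_sd > 0`
  admits any subset within that many binomial SDs of the minimum.
* **0.632+ bootstrap**: per resample, patients' samples drawn with
  replacement train the model (optionally with in-bootstrap backward
  selection, whose selected sets yield per-variable selection
  frequencies); never-drawn samples are predicted. With apparent error
  `err_bar` (full-data forest predicting its own training data with all
  trees — the standard apparent-error definition), leave-one-out bootstrap
  error `Err1` (mean over samples of each sample's mean held-out error),
  and no-information rate `gamma = sum_k p_k (1 - q_k)`:
  `Err1' = min(Err1, gamma)`;
  `R = (Err1' - err_bar) / (gamma - err_bar)` (0 when degenerate, clipped
  to [0, 1]); `w = 0.632 / (1 - 0.368 R)`;
  `err632+ = (1 - w) err_bar + w Err1'`. The estimate is a convex
  combination of apparent and bootstrap error with `w` in [0.632, 1].
* **field effect**: per patient, `d = vote(tumor) - vote(nontumor)`;
  `d > 0` means the pair trends correctly even if one member is
  misclassified. Differences are compared across a clinical grouping
  (default T-stage) with a Welch test on the per-patient `d` values —
  algebraically the between-group test of the tissue-by-group interaction
  in a two-level repeated-measures design, which is the transparent
  operationalization of a repeated-measures MANOVA on two levels; a
  rank-sum variant is switchable. The vote-difference analysis uses the
  full 112-variable model by default (the selected-subset model can be
  passed instead).

## Determinism and numerical choices

One master seed derives a named sub-stream for every stochastic component
(taxonomy, cohort sampling, forest fits, label permutations, each
bootstrap resample), so any figure-analog is independently reproducible
and two pipeline runs with the same configuration are byte-identical
(hash-verified in the tests). Degenerate inputs fail loudly: zero-total
samples, asymmetric distance matrices, NaN distances, all-pairs-removed
filters, single-class training sets, samples never out of bag or never
held out all raise errors naming the offender rather than propagating
silently. Welch tests on zero-variance groups return p = 1 (identical) or
p = 0 (separated) instead of NaN.

## Problem sizes in the test suite

The simulation-based checks run at the cohort scale they make claims
about: 39-40 pairs and 112 genus features for recovery of planted
fold-changes, covariances and the T-stage attenuation (20 replicate
cohorts each); 200 patients for generator-calibration checks; forests of
501 trees inside the heavy resampling loops and 2001 trees elsewhere; 50
to 100 bootstrap iterations in the estimator checks, against a
straight-line oracle at n = 12. `scripts/acceptance.R` reruns the full
pipeline on a default 39-pair cohort with 2001-tree forests and a 100-fold
bootstrap.

## Interfaces

The R functions are the primary interface; `scripts/acceptance.R`
reproduces the headline numbers and `inst/cli/biomepair.R` is a thin
`simulate`/`run` wrapper for shell use. All artifacts are plain TSV, JSON
and newick.

## Known limitations

* Unpaired per-taxon tests under depth asymmetry are not exactly nominal
  (see above); the paired variant is provided but not the default.
* No rarefaction or compositional transforms (CLR); no mixed-effects
  abundance models; no PERMANOVA; weighted UniFrac is out of scope.
* The generator's trees are simulated, so UniFrac results on synthetic
  cohorts exercise the machinery, not real phylogenetic signal.
* Selection frequencies from in-bootstrap backward elimination are
  reported descriptively; no stability-selection inference is attached.
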