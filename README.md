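# biomepair

Paired tumor / non-tumor tissue microbiome analysis across two kingdoms
(bacteriome + mycobiome), for studies in which each patient contributes a
tumor sample and a matched adjacent-normal sample profiled by 16S and ITS
amplicon sequencing.

## What it computes

Given taxon-by-sample count tables (one per kingdom), sample metadata and
optional rooted trees, the pipeline runs:

* **Community structure** — per-sample Shannon diversity
  `H = -Σ pᵢ ln pᵢ` and richness; Bray-Curtis dissimilarity
  `BC(a,b) = 1 - 2 Σ min(aᵢ,bᵢ) / (Σaᵢ + Σbᵢ)`; unweighted UniFrac
  (unique branch length over observed branch length); PCoA by classical
  scaling; UPGMA dendrograms.
* **Differential abundance** — per-taxon Kruskal-Wallis tests on relative
  abundances with Bonferroni-Dunn adjustment; intra- and inter-kingdom
  Spearman correlation screens with Benjamini-Hochberg control.
* **Random-forest classification** — a 2001-tree forest on the merged
  genus-level relative abundances (per-kingdom normalized), exposing
  out-of-bag *vote fractions* per sample; permutation importance against a
  20-fold random-grouping null; backward variable elimination over OOB
  error; the 0.632+ bootstrap error estimate
  `err632+ = (1-ŵ)·err̄ + ŵ·min(Err₁, γ̂)`, `ŵ = 0.632/(1 - 0.368·R̂)`;
  and the per-patient vote-fraction difference
  `d = vote(tumor) - vote(nontumor)`, tested across clinical groups
  (e.g. T-stage) as a field-cancerization statistic.
* **Synthetic cohorts** — a Dirichlet-multinomial generator that plants
  tumor/normal fold-changes, patient effects, tissue-asymmetric sequencing
  depths and a tunable T-stage "field effect", with ground truth, so every
  stage is testable without sequencing data.

## Worked example

```r
library(biomepair)

sim    <- simulate_cohort(generator_config(seed = 42))
cohort <- filter_low_depth_pairs(sim$cohort)   # <50 bacterial reads rule
cohort
#> <paired_cohort> 39 patients (78 samples); 90 bacterial + 22 fungal taxa at rank genus/genus

diversity_comparison(cohort, rank = "genus", metric = "shannon")
#>    kingdom  metric  rank mean_nontumor mean_tumor sd_nontumor sd_tumor statistic        p
#> 1 bacteria shannon genus          3.06       2.78       0.257    0.371    11.647 0.000643
#> 2    fungi shannon genus          2.44       2.46       0.142    0.194     0.713 0.398423

m   <- merge_genus_tables(cohort)              # 112 genus features
fit <- fit_rf(m$features, cohort$metadata$tissue, rf_config(seed = 42))
fit
#> <rf_fit> 78 samples, 112 variables, ntree=2001, OOB error 0.269

vd <- vote_fraction_differences(fit, cohort)
ft <- field_effect_test(vd, "t_stage")
sprintf("mean d: low T-stage %.3f, high T-stage %.3f (p = %.3g)",
        ft$means[["low"]], ft$means[["high"]], ft$p_value)
#> "mean d: low T-stage 0.158, high T-stage 0.100 (p = 0.121)"
```

Reading: bacterial Shannon diversity is significantly lower in tumors
(the generator concentrates tumor communities onto fewer genera) while
fungal diversity is unchanged; the forest separates tumor from normal
tissue well above chance; and the tumor-vs-normal vote gap is smaller in
high-T-stage patients, whose normal tissue has been pulled toward the
tumor profile (the planted field effect, attenuation 0.3 at default — at
stronger attenuation the gap difference becomes significant).

`run_pipeline(pipeline_config(...))` chains all stages, writes every
artifact (TSV/JSON/newick) plus a markdown report, and is byte-identical
under a fixed seed. A thin CLI lives at `inst/cli/biomepair.R`
(`simulate` / `run` subcommands).

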