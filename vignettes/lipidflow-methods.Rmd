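---
title: "Methods: class-level lipid profiling and reaction-activation scoring"
author: "lipidflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: class-level lipid profiling and reaction-activation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidflow)
```

# Scope and model

`lipidflow` implements the downstream analysis of a two-group untargeted
lipidomics study of nervous-system tissue — wild-type (WT) versus a
homozygous disease model (HOM) — starting from an annotated feature table
(lipid molecular species x samples, peak areas) as exported by alignment
software. The pipeline covers:

1. **Nomenclature.** Shorthand names (`PC 16:0_18:1`, `PE O-16:1_18:1`,
   `SM 18:1;O2/16:0`) are parsed into a class code and a list of chains
   `(carbons, doubleBonds, oxidation, etherLinked)`. The registry holds the
   19 classes observed in nervous tissue plus psychosine (PSY). Ether
   subclasses (PC-O/PE-O/PI-O) are distinct class codes because the
   class-level statistics treat them separately. A plasmalogen `P-` prefix
   is normalized to `O-` with one extra double bond (the standard shorthand
   equivalence); the `d18:1` sphingoid dialect is normalized to `18:1;O2`.
   Unknown class tokens fail loudly by default — silent drops would corrupt
   class totals — with an opt-in skip-with-warning mode.

2. **Semi-quantification.** Concentrations are computed per analyte as
   `area / IS area x spike x extract volume / protein amount`
   (ug lipid / ug protein), with the class-matched deuterated internal
   standard as denominator; psychosine is quantified against PSY-d5
   (default spike 125 ng/mL) in ng/ug protein. The effective in-extract IS
   concentration is configurable per class (default 100 ug/mL with an
   exposed dilution factor), as is a per-class response factor to model
   classes quantified against a chemically different standard (HexCer and
   sulfatide default to the ceramide standard). A zero IS area invalidates
   the sample rather than being imputed: an IS failure is an acquisition
   failure. Missing-value handling is pass-through by default; half-minimum
   imputation and a presence filter are opt-in.

3. **Class profile.** Species are summed to class totals; the grand total
   per sample equals the sum over species (a conservation law asserted in
   the tests). Groups are compared with a two-sided Welch t-test on the raw
   concentration scale by default (Student and log-scale options), stars at
   p < 0.05 / 0.01 / 0.001, no multiple-testing correction by default
   (matching the per-class raw-p convention of such summary tables;
   Benjamini–Hochberg available). Error bars are the standard error of the
   mean by default. One-way ANOVA is provided for three or more groups; its
   two-group special case reproduces the squared-t identity.

4. **Multivariate.** Median normalization divides each sample by its median
   and rescales by the median of medians; Pareto scaling divides centered
   species by the square root of their standard deviation (autoscaling by
   the standard deviation). PCA treats samples as observations and species
   as variables, with a deterministic sign convention (the
   largest-magnitude loading of each component is positive) so runs are
   reproducible. Group confidence ellipses use the chi-squared(2) quantile
   on the group's 2-D score covariance. The heatmap stage selects the top-k
   (default 50) species by ascending p, breaking ties by descending
   |log2 fold change| and then by name, and clusters rows and columns with
   complete linkage on Euclidean distances; correlation distance is a flag.
   The default order is normalize -> Pareto -> PCA.

5. **Reaction networks.** For each catalogued transformation
   reactant -> product the per-sample *weight* is the ratio of the product
   pool's total to the reactant pool's total. Statistics are computed on
   log2 weights so activation and suppression are symmetric; the Z-score is
   the signed probit of the two-sided p-value (sign = direction of the
   case-minus-control mean), a deterministic monotone-in-p summary. The
   default class catalog covers the CDP-DAG synthase routes from PA,
   phospholipase D routes to PA, PS synthases, PG synthesis from PC and
   cardiolipin, and phospholipase A (PC -> LPC); it is user-extensible via
   CSV. The call threshold defaults to 0.05, with a stricter 0.02
   "highlight" tier exposed in the pipeline output.

6. **Building blocks.** Chain abundance is the multiplicity-weighted sum of
   species concentrations over species containing the chain
   (`PA 18:1_18:1` contributes twice to 18:1); sphingoid long-chain bases
   are excluded by default so the profile reflects fatty-acid chains, and
   ether chains count with their `(c, d)` signature. Elongation
   `(c,d)->(c+2,d)`, desaturation `(c,d)->(c,d+1)` and beta-oxidation
   `(c,d)->(c-2,d)` edges are generated only between observed chains;
   beta-oxidation only from substrates with >= 20 carbons to keep the
   network from saturating with short-chain edges. Enzyme labels come from
   a lookup keyed by (type, substrate): SCD1 for 16:0/18:0 desaturation,
   D6D (FADS2) for 18:1/18:2, D5D (FADS1) for 22:2, ELOVL1/3/6 for 16:x
   and 22:0 elongation, generic family labels elsewhere.

7. **Psychosine correlation.** Pearson correlation on log concentrations
   by default (Spearman available), pooled across both groups, with a sign
   label (positive/negative/none) at a configurable alpha.

# Synthetic data and what it does (and does not) emulate

The generator is first-class, tested code: it defines the study conditions
under which every calibration and recovery claim is made.

* **Baselines and effects.** Per-class WT baselines and HOM/WT ratios
  default to the published per-tissue class means bundled as
  `referenceClassMeans()`; a null design sets every ratio to 1. Species
  within a class share the class baseline through a Dirichlet split
  (gamma shape 2), so class totals are controlled while species vary.
* **Noise.** Log-normal with CV 20% by default (typical combined
  technical and biological variability for tissue lipidomics), mean-
  corrected so expected class totals equal the design targets; `cv = 0`
  reproduces the targets exactly.
* **Chains.** Sampling weight is concentrated on C16/C18 chains with 0–1
  double bonds, with low-weight longer and polyunsaturated chains through
  24:6 so that elongation/desaturation/beta-oxidation edges are
  observable.
* **Group sizes.** Defaults n = 5 WT / 4 HOM, the profile-stage sizes of
  the study the defaults are patterned on.
* **Psychosine.** WT baselines 0.02/0.02/0.05/0.08 ng/ug for B/C/SC/SN
  with HOM/WT ratios 8/10/22/27. The SC and SN ratios are the published
  approximate values; the B/C values are package choices (the source
  prints no numbers for them) placed well below SC/SN.
* **Feature tables.** Peak areas are constructed by inverting the
  semi-quantification formula around log-normally varying IS areas, so
  `semiQuantify()` recovers the planted concentrations to float precision
  — a generator/inverter round-trip asserted at 1e-10 relative error.

What passing tests on these data do **not** show: real acquisitions have
missing values, class-dependent response factors, correlated
species-level noise, isotope and in-source artifacts, and retention-time
drift — none of which the generator emulates. Calibration and power
results are statements about the model above, not about any particular
instrument.

# Numerical and design choices

* **Planted-effect harness.** Planting a product-pool fold change
  necessarily shifts the weight of *every* catalog edge incident to that
  pool (they share the scaled total), so the false-call criterion in the
  recovery harness is evaluated over edges sharing no node with the
  planted edge. Chain effects are realized through *pure carrier*
  species — species whose acyl chains all equal the product chain —
  scaled by a compensating factor, so the product pool moves by exactly
  the planted fold while chains that merely co-occur with it inside mixed
  species are not dragged along; the generator forces a single-chain
  carrier (a CE species) when the random draw produced none.
* **Type-I accounting.** Edges within one replicate share class totals and
  are therefore correlated; the binomial interval for the null call rate
  is computed with n = number of replicates, not replicates x edges.
* **Psychosine recovery.** A single n = 5 replicate has roughly 13%
  sampling error on a ratio of group means at CV 20%; the recovery check
  therefore averages the estimated HOM/WT ratio over 50 independent
  replicates at the same n and CV.
* **Degenerate inputs.** Zero variance in both groups yields p = NA (no
  stars, no call) rather than an error; constant rows scale to zero and
  are logged; constant correlation vectors yield NA with a warning (or an
  error when psychosine itself is constant); k larger than the item count
  clamps with a message; sample medians of zero abort median
  normalization.
* **Tie-breaks and determinism.** Heatmap selection orders by (p,
  -|log2FC|, name); PCA signs are fixed by the largest loading; all
  generator randomness flows from one integer seed; pipeline runs with
  the same config and seed produce byte-identical CSVs.
* **Problem sizes.** The calibration suite uses 1000 null replicates for
  the type-I check and 200 replicates per planted-effect recovery, at the
  default design (18 classes, ~216 species, n = 5/4, CV 20%) — sizes at
  which the binomial intervals above are meaningful while the suite stays
  quick to run.
* **Interfaces.** This is an R analysis package in the Bioconductor
  style: the exported functions (`runPipeline()` and the per-stage
  functions) and this vignette are the interface; `runPipeline()` accepts
  a YAML/JSON config with one seed and writes per-stage CSVs plus a
  machine-readable JSON report.

# Known limitations

* Class-level weights use pool totals, not species-matched
  reactant/product pairs; a species-matched mode is a possible extension.
* Shorthand parsing covers the species-level dialects above, not full
  structural nomenclature (stereochemistry, sn-resolved ether bonds,
  oxidized species beyond the `;O` suffix).
* The t-test on log2 weights assumes approximate log-normality of pool
  totals; with very few species per class the approximation degrades.
* Published per-class p-values cannot be reproduced exactly without the
  raw per-sample data, which is not deposited; the worked example
  reproduces the printed grand totals and significance counts, and all
  sample-level claims are calibration/recovery properties on synthetic
  data.

# A worked example

```{r example, eval = FALSE}
d <- syntheticDesign("SN", seed = 1)
ft <- generateFeatureTable(d)
le <- semiQuantify(ft$areas, defaultISMap(), ft$sampleData)
tot <- classTotals(le)
compareGroups(tot, sampleGroups(le))
scores <- annotateReactions(
  scoreReactions(computeReactionWeights(tot, defaultClassCatalog()),
                 sampleGroups(le)),
  defaultClassCatalog())
head(scores)
```
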