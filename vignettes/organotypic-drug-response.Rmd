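---
title: "Methods: stratifying organotypic tumor drug response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratifying organotypic tumor drug response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgslice)
```

## The problem

Fresh tumor tissue can be kept alive for a few days as thin organotypic
slices and exposed to a drug ex vivo. Serial slices are fixed at baseline
(T0) and at 24-h intervals, stained for a proliferation marker (Ki-67),
an apoptosis marker (cleaved caspase-3) and p53-pathway proteins, and the
tumor is then classed as drug-sensitive or -resistant from how far its
proliferative compartment collapses relative to a vehicle-treated sister
slice. `orgslice` implements that quantitative chain — scoring,
trajectory normalization, classification, gene-card expression analysis
and two-drug synergy analysis — together with seeded generators that
emulate each data type, so every stage is testable without tissue.

## Scores and trajectories

* **Ki-67 score**: positive tumor cells over all tumor cells, as a
  percent. Same statistic for the gammaH2AX phosphorylation index
  (DNA-damage marker; 100 cells scored per sample by default).
* **Two-score composite**: markers graded for both percent positivity
  and staining intensity (0 = absent to 3 = strong). The field does not
  agree on a single way to combine the two; `orgslice` reports the pair
  and quantifies with their product, the standard 0-300 H-score, which
  is what every downstream ratio uses.
* **Baseline normalization**: each (case, marker, arm) series is
  expressed as percent of its own T0 value, so T0 is exactly 100.
* **Growth index (GI)**: the Ki-67/caspase-3 ratio renormalized to T0
  (GI(T0) = 1); a falling GI means the balance is tipping from
  proliferation to apoptosis.

*Zero floor.* A composite score of 0 would make ratios and T0
normalization undefined. Zero scores are therefore lifted to 0.5 — half
the minimal nonzero H-score unit (1% positivity at intensity 1) — before
any division. The floor is a configurable argument of
`normalize_to_baseline()` and `growth_index()`; trajectories with
missing timepoints are analyzed on observed times only, never imputed.

## The response rule

Relative Ki-67 is the drug arm's baseline-normalized Ki-67 divided by
the vehicle arm's at the final shared timepoint (72 h in the standard
design), times 100. A tumor is a **Responder** when this is at most 50
(proliferation fell by half or more against control), else a
**Non-Responder**; the boundary value 50 is a Responder. Using the
same-time vehicle arm as denominator, rather than T0 alone, corrects for
culture drift; a `mode = "t0"` switch gives the uncorrected form. The
rule is stamped into every calls table as a `rule_version` string.

Group association statistics follow the conventions of the source
analyses: a classical pooled-variance unpaired t test (Welch by flag)
for means, and an exact 2x2 Fisher test — implemented by full
hypergeometric enumeration with the standard 1e-7 relative tie
tolerance — for categorical features. Multi-level features are collapsed
to their conventional dichotomies (IDC vs other histotype, pT1 vs
larger, node-negative vs positive with unknowns dropped, G3 vs G1-G2,
receptor positive vs negative, p53 mutant vs wild-type); diagnostic
Ki-67 is additionally dichotomized at 15% positive cells.

## Gene-card expression analysis

Cards measure ~92 apoptosis-related targets plus three reference genes
(ACTB, TBP, HMBS) in duplicate wells. The chain is:

1. **Relative quantity**: replicate Ct values are averaged per (gene,
   sample); RQ = E^(Ctmin − Ct) with amplification efficiency E = 2
   (perfect doubling; configurable), so each gene's best-expressed
   sample has RQ = 1.
2. **Reference stability**: for reference j, M_j is the mean SD across
   samples of its pairwise log2 ratios with the other references;
   constant-ratio references have M = 0. An iterative worst-reference
   exclusion (`genorm_select()`) is provided but off by default — the
   standard card design fixes the three references.
3. **Normalization factor**: geometric mean of the reference RQs per
   sample; dividing by it absorbs any per-sample scale (loading,
   RNA input).
4. **Median-centering**: target RQ/NF values are log2-transformed and
   each gene centered on its median across samples. Centering is done
   *on the log scale* (subtracting the median of logs rather than
   dividing by the median RQ before the log): for an odd number of
   samples the two are identical, for an even number only the log-scale
   form keeps the per-gene median exactly zero, which is the invariant
   the rest of the pipeline relies on.
5. **Differential ranking**: per-gene two-sided pooled-variance t on the
   log2 values with Benjamini-Hochberg FDR, genes sorted by p. The
   original platform's supervised analysis tool is not specified
   precisely enough to reimplement, so the *ranking* is the comparable
   output, not the p-values. A zero-variance, zero-difference gene gets
   p = 1 by convention. Genes undetermined in more than half the samples
   (configurable) are dropped and counted.

Validation-style single-reference quantification is the plain 2^-dCt
statistic (`delta_ct_quant()`), with missing Ct propagating as NA.

## Bliss synergy analysis

Viability plates carry a 7x7 two-drug concentration grid plus dose-0
single-agent wells, duplicate assay wells, and 12 + 12 maximal-kill /
untreated control wells. Fractional growth inhibition rescales
fluorescence linearly between the aggregated control means (0 =
untreated, 1 = full kill); replicates are averaged after that
transformation. Under assay noise, inhibitions can leave [0, 1]; since
the Bliss formula is only defined on probabilities, values are clamped
into [0, 1] for the expectation E = A + B − A·B and excess X = O − E,
while raw values are retained in the output and the clamp count is
logged. `combination_summary()` calls the plate by the sign of the mean
excess. The default margin `delta = 0` is the strict sign rule; with
noisy plates a finite-sample mean excess is almost never exactly zero,
so calls intended to separate real interaction from noise should use a
positive margin. The package's acceptance checks use delta = 0.01,
chosen a priori as roughly twice the standard deviation of the
plate-mean excess under the generator's stated noise (2% of dynamic
range, duplicate wells), not fitted to any observed outcome.

## The synthetic world

The generators state one fixed world; their defaults are the conditions
the study design implies, and they were not revisited after seeing test
results.

* **Cohort** (`cohort_params()`): 33 cases, responder fraction 19/33;
  baseline Ki-67 normal around 16% (Responders) / 26% (Non-Responders),
  SD 8% (chosen: matches the spread of a typical diagnostic Ki-67
  distribution), clipped to [1, 100] and rounded. Drug-arm final
  relative Ki-67 uniform on 0-50% (Responders) or 70-180%
  (Non-Responders), values below 0.5% floored so the trajectory stays
  positive; the path from 100% at T0 is log-linear (monotone and
  parameter-free — per-timepoint shapes are not otherwise constrained).
  Vehicle arms fluctuate around baseline with multiplicative lognormal
  noise of CV 10% (the drift magnitude is not stated anywhere; 10% is a
  typical slide-to-slide scoring variability and is flagged as a free
  choice). The caspase-3 composite starts at 10 H-score units and rises
  4-fold by 72 h in drug-treated Responders only (a clear but not
  saturating induction; the true fold is not stated).
  Clinicopathological covariates are drawn independently of class.
  The true labels are hidden behind `reveal_true_class()` so recovery
  tests cannot leak them through the ordinary tables.
* **Gene card** (`expression_params()`): 92 targets named from the
  packaged panel roster (only BIRC5, BIRC3 and TNF are documented card
  members; the rest are labelled synthetic placeholders), references at
  Ct 19/22/25, targets laddered over Ct 24-34, well SD 0.25 cycles,
  duplicate wells, and a planted +2 log2 fold-change on BIRC5 in
  Non-Responders by default (higher expression = lower Ct).
* **Plate** (`plate_params()`): 7-point geometric ladders over
  0.0004-0.1 and 0.004-1 umol/L, Hill slope 1 with EC50 at the
  geometric mid-dose (so the mid single-agent inhibition is exactly
  0.5), fluorescence 10000 (untreated) to 1000 (killed) with Gaussian
  noise SD at 2% of that range. A planted interaction deforms the
  combination truth to E ± strength·sqrt(A·B)·(1−E), clipped to [0, 1]:
  symmetric, vanishing when either agent is inactive, and weighted by
  the remaining head-room. (The geometric-mean coupling is this
  package's choice of interaction model; it reproduces the reference
  worked value 0.875 at A = B = 0.5, strength 1.)

**What a green test establishes — and what it does not.** The synthetic
world has clean class structure: disjoint relative-Ki-67 ranges,
independent covariates, homoscedastic Gaussian Ct noise, no plate edge
effects or drift, no missing timepoints, no inter-observer scoring
disagreement. Recovery and detection rates measured on it certify the
*pipeline's* correctness under its stated assumptions, not performance
on real tissue, where class overlap, nested measurement error and
informative missingness all occur. In particular, the ~96% label
recovery at CV 10% noise reflects genuinely ambiguous draws near the
50% boundary, which is a property of the stated world, not a defect of
the rule.

## Numerical choices

* Fisher enumeration works in log-choose space and clamps the two-sided
  sum at 1 (the tie tolerance can push it to 1 + 1e-16).
* `unpaired_t_test()` refuses samples whose pooled variance is zero
  unless the means are equal too (then t = 0, p = 1).
* All artifact tables are comma-separated text written at full
  precision; a run's manifest echoes the resolved configuration, and
  per-module seeds derive from the single top-level seed as
  `seed * 10 + stage index`, so the whole bundle is reproducible from
  the manifest alone.
* Tie at the classification boundary resolves to Responder, recorded in
  the `rule_version` string.

## Known limitations

* Only 2x2 Fisher tests are provided; full r-x-c exact tests are out of
  scope, so multi-level features are analyzed through their standard
  dichotomies.
* No dose-response curve fitting, Loewe/ZIP/HSA models, or plate-effect
  correction; the Bliss layer starts and ends at the excess grid.
* No pathway enrichment downstream of the differential ranking.
* The published 92-gene card roster is not public; the packaged panel
  beyond the documented members is an explicitly labelled placeholder,
  adequate for generator naming but not for biological interpretation.
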