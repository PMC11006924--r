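---
title: "Methods: evolutionary QSPR design of rhamnolipid biosurfactants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary QSPR design of rhamnolipid biosurfactants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modelling problem

Two regression problems sit at the core of the package:

* **Biosynthesis model** — `logP_RL = f(conc_C, logP_C, conc_N, C:N, pH,
  temperature, shaking, time)`: which feedstock and cultivation conditions
  produce a rhamnolipid (RL) of a given hydrophobicity. Higher logP_RL means
  a mono-rhamnolipid-rich product; lower means di-rhamnolipid-rich.
* **Solubilization model** — `logMSR = f(impurity, logP_RL, logP_SOL,
  MV_SOL, CMC, temperature, pH)`: how efficiently a given
  biosurfactant/solubilizate pairing solubilizes, expressed as the base-10
  log of the molar solubilization ratio.

Both are fitted by gene expression programming (GEP), a symbolic-regression
flavor of evolutionary computation: models are short algebraic expressions
rather than black boxes, which is what makes the downstream sign/importance
analysis and the inverse "recipe" calculators meaningful.

Units are fixed package-wide: concentrations and CMC in mg/L, molecular
volumes in cubic angstroms (a nm³ convention occasionally seen for
solubilizate volumes is treated as a typo; all reference values used here
are on the Å³ scale), temperature in °C, shaking in rpm, time in hours; logP,
pH, C:N (w/w) and MSR (mol/mol) are dimensionless.

## Harmonization rules

Literature rows rarely report everything. The rules implemented are:

* Mixture descriptors (`weighted_descriptor`): mass-fraction weighted
  arithmetic means of component logP and MV. Fractions must be positive and
  sum to 1 (tolerance 1e-6 on input, exact renormalization on output).
* Composition resolution (`resolve_composition`): when only a mono/di split
  is known it is carried by the two representative congeners Rha-C10-C10 and
  Rha-Rha-C10-C10; when congeners are listed without shares a default 35/65
  mono/di mass split is assumed and divided *equally within each class* —
  the equal split is a maximum-entropy choice where the source is silent.
  Zero-share components are dropped.
* C:N (`derive_cn_ratio`, `reconcile_cn_ratio`): derived as conc_C/conc_N;
  an explicitly reported ratio that disagrees with the derived one by more
  than 5% is kept (the explicit value wins) with a logged warning, on the
  view that reported ratios may reflect feed details the concentrations do
  not capture.
* The built-in congener table ships **synthetic stand-in** logP/MV values
  (real per-congener descriptors come from cheminformatics software and are
  *inputs* to this package). Only their qualitative structure — the mono
  congener smaller and more hydrophobic than the di — is relied upon
  anywhere.

## Imputation

`mice_impute` is a single-completion (m = 1) chained-equations imputer:
column means initialize, then per-column ordinary least squares on all other
descriptors, visiting columns in order of increasing missingness, for 10
cycles. Targets are never imputed and never used as predictors. Three
deliberate choices:

* **10% gate**: imputation is refused outright when descriptor-cell
  missingness exceeds `max_missing_fraction` (default 0.10) — beyond that
  the completed table would be substantially model output.
* **Deterministic predictions** (no posterior noise): the downstream use is
  a single completed table, so between-imputation variance is not
  propagated; determinism buys exact reproducibility.
* **Range clamping and ordinal rounding**: imputed cells are clamped to the
  observed range of their column, and columns whose observed values are all
  whole numbers (the 0–5 impurity scale) are rounded — so a completed table
  can never violate the record invariants.

## The GEP engine

Chromosomes are `genes` (default 3) fixed-length strings in Karva
(breadth-first) notation: a head of length `head` (default 8) that may hold
functions or terminals, and a computed tail of length `head × (max arity −
1) + 1` holding terminals only, which guarantees every head decodes to a
complete tree. Genes are joined by an additive linking function. Terminals
are the descriptor names plus 5 random-numerical-constant slots per gene,
drawn uniformly from [−10, 10].

All primitives are protected so any chromosome yields finite fitness:
division by zero returns 1, `ln` of a non-positive argument returns
`log(1+|x|)`, `exp` is clipped at ±50, square root acts on |x|. Remaining
double overflow (long products) is clamped at ±1e100 at evaluation time.

Evolution is generational with elitism (the best-so-far individual survives
unmodified, so the fitness trace is non-increasing), size-3 tournament
selection on training RMSE, and the classical operator set: per-symbol point
mutation (rate 0.044), IS/RIS/gene transposition (0.1 each), one-point and
two-point recombination (0.3 each), gene recombination (0.1), and constant
mutation (0.01). Constant mutation mixes 50% uniform redraws with 50% local
multiplicative perturbations (`c · 10^N(0, 0.25)` plus a small additive
term): pure uniform redraws almost never land on the small coefficients real
descriptor scales require, and the local move is what lets the engine tune
weak but genuine effects. All operators preserve head/tail discipline by
construction, which the suite checks on thousands of random applications.
QSPR work of this kind has typically relied on a commercial GEP tool whose
internal schedule is not documented; the defaults here are conventional GEP
settings and every one of them is exposed in `gep_config()`.

## Fitting protocol and reporting

`fit_protocol` runs `n_splits` random 80:20 train/validation splits ×
`n_runs` evolution seeds (default 3 × 10 = 30 candidates). Every candidate
is a frozen expression scored on its own split — there is no refitting
between train and validation. Selection minimizes validation RMSE with ties
broken by training RMSE and then run order, making selection stable under
candidate reordering. The ensemble report keeps train/validation R² for all
candidates; the selected model stores both its validation R² and the pooled
(train + validation) R², since published headline values of this kind are
often pooled scatter statistics — both are reported rather than guessing.
The "general" biosynthesis model uses all rows; producer-specific models are
row subsets (`subset_by_producer`). `MV_C` is excluded from the default
biosynthesis descriptor set and available behind the `include_MV_C` flag,
because the protocol's canonical descriptor list omits it while some
analyses include it.

## Sensitivity analysis

* **Contribution signs**: at every data point the partial derivative of the
  prediction with respect to the descriptor is estimated by a central finite
  difference with step `1e-4 × sd(descriptor)` — scale-aware and small
  enough to be robust for the piecewise-smooth protected primitives. The
  report is the percentage of points with positive / negative / zero
  derivative. The derivative of interest is always taken with respect to the
  model's own target (logP_RL or logMSR).
* **Importance**: permutation importance — the mean relative RMSE increase
  over 30 permutations of the descriptor column, clipped to [0, 1];
  descriptors absent from the expressed genes score exactly 0. The
  commercial tool's importance formula is proprietary, so magnitudes are not
  comparable and only the *ranking* is treated as reproducible.
* In tests that compare a refit model's sign structure with a generating
  truth, a descriptor with permutation importance below 0.05 is read as "no
  sign claim": symbolic-regression fits generically carry tiny spurious
  terms whose derivative sign is noise, and a 5% relative-RMSE floor
  separates claimed effects from that noise symmetrically for the truth and
  the refit.

## Applicability domain

The domain is the componentwise [min, max] of the training descriptors,
inclusive at the bounds (training extremes are in-domain by definition).
Forward calculators **warn** on out-of-domain queries but still answer;
inverse design **refuses** to search outside the domain (exit code 4 at the
CLI). The reasoning: a scientist reading a single extrapolated prediction
can weigh it, but an optimizer left free to extrapolate will actively seek
the regions where the model is least trustworthy. Domain bounds are always
recomputed from the training data actually used, and where a published
bound disagrees with the data the recomputed bound is authoritative.

## Laboratory data reduction

* **CMC** (`cmc_from_isotherm`): two-segment least squares on (log10 c, γ)
  with exhaustive breakpoint search (≥ 3 points per segment), minimizing
  total SSE; the CMC is the intersection abscissa, back-transformed. The
  plateau slope is left free (post-CMC tension drifts slightly in real
  isotherms); SSE ties break toward the flatter plateau. A non-descending
  pre-micellar branch or an intersection outside the data range is an error,
  not a number. Replicate isotherms may be pooled into one fit or averaged
  first — both enter as plain (concentration, tension) pairs.
* **MSR** (`msr_from_curve`): OLS slope of solubilizate vs surfactant molar
  concentrations restricted to points above the CMC (≥ 3 required);
  non-positive slopes are "no measurable solubilization". mg/L inputs with
  molar masses are converted first, making the result invariant to
  consistent unit changes.

## The synthetic world

The generators emulate the two curated databases so every stage is testable
offline: 213 cultivation rows at 9.6% MCAR descriptor-cell missingness and
74 solubilization rows at 1.99% (missing cell counts are exact, not
Bernoulli, so small tables still hit the nominal rate). Descriptor ranges
are anchored to published anchor values where available — feedstock logP
from −2.64 (glucose) to 10.84 (brassica oil), solubilizate logP 2.7–10.8
and MV 94–985 ų, logMSR clamped to the literature span [−5, 0.9] — and to
plausible cultivation practice otherwise (pH 5–8, 25–37 °C, 0–250 rpm,
24–240 h, log-uniform concentrations).

Default noise levels are chosen once to mirror the explained variance of
the real modelling exercise (≈ 1.0 on logP_RL giving R² ≈ 0.6; ≈ 0.6 on
logMSR giving R² ≈ 0.8) and are overridden downward in recovery tests,
which state so explicitly.

`MV_C` is drawn collinear with `logP_C` (linear trend, residual sd 40 ų).
This mirrors chemistry — across real feedstocks, from sugars to plant oils,
molecular volume and hydrophobicity rise together — and it matters
methodologically: with fully independent descriptors, chained-equations
imputation degenerates to mean imputation and a 9.6% missing rate on an
informative descriptor caps achievable validation R² well below what any
fit can recover. The solubilization generator keeps independent marginals
(at 1.99% missingness imputation quality is immaterial). The generators do
**not** emulate: reporting biases, non-MCAR missingness, inter-laboratory
systematic offsets, discrete popular values (e.g. pH exactly 7), or
correlated measurement error — so a green pipeline test establishes that
the machinery recovers a known signal under stated noise, not that the
method conquers real literature heterogeneity.

Truth functions (`truth_registry`) include linear and monotone-saturating
biosynthesis forms and linear/interaction solubilization forms whose sign
structure matches the qualitative experimental picture: logMSR strictly
decreasing in solubilizate molecular volume and increasing in solubilizate
hydrophobicity and biosurfactant impurity (micellar swelling by
impurities). The solubilization truths' relative effect sizes are anchored
to published importance magnitudes for the corresponding descriptors
(molecular volume : hydrophobicity : impurity : CMC ≈ 0.384 : 0.312 :
0.252 : 0.013), scaled so the noiseless target fills the literature logMSR
span — so the emulated world reproduces not just the signs but the
approximate ordering strength of the real one.

## Numerical choices and degenerate inputs

* Protected-operator conventions as above; empty datasets, constant
  observation vectors (R² undefined), sub-5-row splits, zero-nitrogen C:N,
  all-below-CMC curves and flat isotherms are all hard errors with named
  rows/fields rather than silent NaNs.
* Model JSON serialization writes doubles at full precision; reloading a
  model reproduces predictions to 1e-12 and rerunning a pipeline with the
  same config reproduces model files byte-identically.
* All randomness flows from explicit integer seeds; protocol run seeds are
  derived as `(master %% 1e5) × 1000 + split × 100 + run`, keeping every
  derived seed far below 2³¹.

## Known limitations

* The GEP engine is a faithful re-implementation of the protocol-level
  description (RMSE fitness, 80:20 splits, 3 × 10 repeats), not of any
  commercial tool's internals; published R² values can only be matched in
  the aggregate, and importance magnitudes not at all (ranking only).
* The real curated databases are not bundled; the structural acceptance checks
  run on the synthetic emulation, and the R² replication test stays red in
  offline builds by design (see the repository's decisions ledger).
* At the 74-row scale of the solubilization database, the permutation
  importances of the second- and third-ranked descriptors are statistically
  tied in a single emulated sample: their strict ordering is not a
  reproducible quantity at that sample size, only the top rank and the
  rank-2/3 membership are.
* Single-completion imputation understates uncertainty in downstream fits.
* The applicability domain is a bounding box: it cannot flag interior holes
  in descriptor space.
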