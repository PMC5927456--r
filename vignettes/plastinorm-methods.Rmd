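---
title: "Methods: reaction norms, plasticity indices and phylogenetic contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reaction norms, plasticity indices and phylogenetic contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastinorm)
```

`plastinorm` estimates how strongly zooplankton life-history traits
respond to seasonal gradients of temperature and food, and compares the
magnitude of that thermal plasticity across latitudes and across a
phylogeny. This vignette documents the models, the tunable parameters,
the numerical conventions, and what the synthetic-data generators do and
do not emulate.

## The environmental summary

A vertically migrating calanoid experiences neither the lake surface nor
the anoxic hypolimnion. The monthly environment is therefore the
arithmetic mean (and sample SD) of the temperature measurements at
depths strictly below `surface_exclusion` (default 1 m) and, when an
anoxic layer is present, strictly above its top. Assumptions:

* **Anoxia is a single expanding hypolimnetic block.** The anoxic top is
  the shallowest depth at which oxygen falls below `oxygen_threshold`
  *and stays below it to the bottom of the cast*. A transient dip that
  recovers deeper is treated as a sensor artefact, not anoxia. The
  threshold defaults to 1.0 mg/L; there is no universal convention, and
  it is configurable.
* **Surface exclusion is a depth rule**, not a sample-count rule: depths
  strictly greater than 1 m are used, whatever the cast spacing.

Phytoplankton counts become biomass through geometric cell volumes
(sphere, cylinder, prolate spheroid; any other shape label is rejected
loudly) at a cellular density of 1 (1 cm³ = 1 g). The package adopts the
convention that 1 μm³ per cell at a density of 1 cell/mL contributes
1 × 10⁻⁹ mg/L, which puts a 50-μm centric diatom at 2 × 10⁴ cells/mL at
≈1.3 mg/L — the scale of a winter diatom bloom in an oligotrophic
tropical lake.

Thermal covariates of any monthly series are `t_min`, `t_max`,
`tar = t_max − t_min` and the seasonality `ts`, the sample standard
deviation of the monthly means. All SDs in the package are sample
(n − 1) SDs; for a single observation the SD is reported as missing,
never as 0.

## Individual traits and monthly means

Dry weight follows the allometric power law `W = 7.9 × 10⁻⁷ · L^2.33`
(W in μg, L the total length in μm, furcal rami excluded); wet weight is
10 × dry weight. Egg wet weight is the sphere volume `(π/6)d³` (one
axis) or prolate-spheroid volume `(π/6)ab²` (two axes) at density 1.
Reproductive effort is `RE = EW × CS` and its relative form
`RRE = 100 · RE / W_wet`.

Every derived quantity is computed **per individual before averaging**:
the monthly mean of RE is `mean(EW·CS)`, not `mean(EW)·mean(CS)`. This
ordering matters because the weight–length map is convex
(`mean(W(L)) ≥ W(mean(L))`), and it is what makes a monthly mean length
and its paired mean weight mutually consistent. Months with no carrier
of a trait are emitted as gaps and never interpolated. When a female
carries several measured eggs, her egg weight is the mean of her own
eggs.

## Reaction norms and the plasticity call

The population reaction norm of a trait is the relation between its
monthly means and the monthly environment means, over months where both
exist (n ≥ 3 required). The association is Pearson's correlation when
both vectors pass a Shapiro–Wilk screen at α = 0.05; otherwise a log₁₀
transform is tried once (only if all values are positive), and failing
that a Spearman rank-order correlation (mid-ranks for ties) is used. A
trait is classified *plastic* along a gradient when the two-sided
p-value is ≤ α (default 0.05). The trait × environment grid applies no
multiple-testing correction — each cell is a separate question, reported
with its own p — and the chosen method is recorded per cell.

The amplitude of a plastic response is the Phenotypic Plasticity Index,

```
PPI = 100 · (max monthly mean − min monthly mean) / max monthly mean ,
```

always computed from the extreme *monthly population means*, never from
per-individual extremes. PPI is scale-invariant, lives in [0, 100) for
positive traits, and is undefined for non-positive means (rejected as an
input error). Because the extremes of noisy means widen with noise, the
estimated PPI is biased upward relative to the generating PPI — a
property the test suite verifies by simulation and users should keep in
mind when comparing series of very different lengths or precisions.

The **intensity** of thermal plasticity is `PPI / TAR` (% change per
°C). Note the structural consequence of this ratio: across populations,
intensity correlates negatively with TAR *even when PPI is generated
independently of TAR*. The package treats this as a property to be
demonstrated (the test suite shows the negative Spearman sign arises in
≥95% of simulated databases with independent PPI), not as evidence of a
biological link.

One documented numerical wrinkle: for the reference lake series, the
printed extreme monthly mean temperatures differ by 3.2 °C, which is the
TAR the package computes; a companion rounding of the same series
elsewhere gives 3.3 °C. `thermal_covariates()` always returns the
arithmetic difference of its inputs.

## The latitudinal meta-analysis

Populations with fewer than `min_months` monthly records (default 5;
series of 3–4 months are the canonical exclusions) are set aside with a
reason. Length-unit series are bridged to dry biomass with the nearest
length–weight model from a registry, resolved species → genus →
`default` rank; the model used is recorded per population so every row
traces to either a named model or "native biomass". Size and temperature
must come from the same month record; months missing either are dropped
from both the PPI and the thermal covariates.

Zones split at |latitude| = 23.5° (the Tropic line; tropical is strictly
below). The report gives Spearman correlations of PPI against
|latitude|, T_min, T_max, TAR and TS, and of intensity against TAR;
Mann–Whitney comparisons (min-U statistic; exact two-sided p by complete
enumeration of group labelings when `choose(n, n_a)` ≤ 20 000, otherwise
a tie-corrected normal approximation with continuity correction) of TAR,
PPI and intensity between zones; and per-zone means ± SD. Species-level
analysis keeps the maximum-PPI population per species, with ties broken
deterministically (more months, then lexicographic id) and flagged.
Absolute latitude is used throughout; the sign is retained in the input
schema.

## Independent contrasts with soft polytomies

Composite trees assembled from heterogeneous sources carry no meaningful
branch lengths, so `assign_convention_lengths()` overwrites them with a
punctuational convention: daughters of polytomies get length 1, all
other branches length 2. Contrasts then follow the classic post-order
recurrence — standardize the daughter difference by `√(v_i + v_j)`,
replace the node by the 1/v-weighted daughter mean, and lengthen the
node's own branch by `v_i·v_j/(v_i + v_j)`.

A soft polytomy contributes exactly **one** contrast: its daughters are
partitioned about the unweighted mean of their *predictor* values (the
split statistic is a design choice — the predictor drives the grouping,
and this is logged in the output via `n_daughters` and `valid`), each
group is collapsed to its 1/v-weighted mean with effective length
`1/Σ(1/v)`, and the two aggregates are contrasted. When all daughter
predictor values are equal the split is degenerate: the contrast is
flagged invalid with a reason, excluded from regression but still
reported — which is exactly why the number of *valid* contrasts can be
smaller than n − 1. The parent branch is always incremented by
`1/Σ(1/v)` over all daughters (for two daughters this reduces to the
classic `v_i·v_j/(v_i+v_j)`), consistent with the variance of the
weighted mean. Every contrast is positivized on the predictor with the
response sign flipped in tandem; positivization leaves |r| of any
subsequent regression unchanged.

Association between contrasts is estimated by least squares **through
the origin** (contrasts have expectation zero): `slope = Σuw/Σu²`,
`r = Σuw/√(Σu²Σw²)`, two-sided p from the t transform on
`n_valid − 1` df. Trees are used as supplied — no ultrametricization, no
automatic polytomy resolution.

## What the generators emulate — and what they do not

`simulate_lake_year()` encodes a warm-monomictic tropical lake year:

* a piecewise-cosine temperature cycle from 14.9 °C (January) to
  18.1 °C (September peak) — the generator's extremes are hit exactly,
  so TAR_gen = 3.2 °C;
* phytoplankton biomass cycling 0.2 → 3.5 mg/L (March minimum, November
  maximum; a 17.5-fold fluctuation), emitted as spherical 50-μm diatom
  counts whose densities invert the biomass conversion exactly;
* an anoxic top appearing at 57 m in April, shallowest at 27 m in
  September, deepening afterwards, absent during winter mixing;
* 50 ovigerous females per month: length `1975 − 63.75·T + N(0, 40²)` μm
  (spanning ≈1025 μm cold to ≈821 μm warm), spherical egg diameter
  `324.5 − 13·T + N(0, 5²)` μm (≈1.17 down to ≈0.37 μg), clutch size
  Poisson with `log λ = 1.579 + 0.520·log(phyto)` (≈2.1 at the food
  minimum to ≈9.3 at the maximum), hatching Bernoulli at 0.9 per egg by
  default (optionally logit-linked to clutch size to produce a positive
  clutch–hatching association).

The coefficient choices pin the noise-free monthly means to the realistic
trait ranges for a small diaptomid; the noise SDs are of the order of the
published monthly SDs (tens of μm for length). What the generator does
**not** emulate: within-month environmental variation beyond profile
noise, food *quality* (decaying-bloom effects on hatching), size-selective
predation, development-time dynamics, or autocorrelated sampling error.
Passing recovery tests therefore demonstrates that the estimators are
correct and well-calibrated under these generating assumptions — not that
field data meet them.

`simulate_population_database()` generates 85 populations over 50
species (5 tropical, 80 extratropical by default), tropical TARs uniform
on 3.2–5.0 °C and extratropical on 2.3–24.5 °C, coldest-month
temperatures N(22.2, 5.0²) and N(7.2, 5.2²) by zone (truncated at 0),
and generating PPIs N(46, 18²) truncated to [5, 90], independent of TAR
by default (a latitude-linked option exists). Monthly sizes are a
seasonal cycle antiphase to temperature (temperature–size rule) whose
extremes realise the generating PPI exactly; multiplicative lognormal
noise (CV 3% by default) is then applied, so zero-noise runs recover the
generating PPI to machine precision.

`simulate_bm_tree()` grows a random topology, collapses a requested
fraction of internal edges into soft polytomies, assigns the convention
lengths, and evolves the predictor by Brownian motion *on those same
lengths*, with the response `y = β·x + independent Brownian noise`. This
makes β the exact estimand of the through-origin contrast regression.

## Problem sizes and tolerances in the test suite

The suite validates exact arithmetic to machine precision and uses
fixed-seed Monte Carlo for the statistical properties: 200 replicate
lake years for the plasticity-classification power check (≥95% required
for the generated-plastic traits), 500 replicate databases for the
intensity–TAR sign property (≥95% negative required), 500 replicate
16-tip trees for slope recovery (|mean β̂ − β| within 3 Monte-Carlo
standard errors), and 1000 replicates for the type-I-rate check of the
plasticity call (binomial band around α). Exact Mann–Whitney p-values
are compared against complete enumeration for all group sizes ≤ 5, and
binary-tree contrasts against the classic recurrence as implemented
independently in `ape`.

## Known limitations

* The plasticity call is correlational; it cannot separate direct
  thermal effects from covarying seasonal drivers.
* PPI compares only the two extreme months and therefore inherits their
  sampling error (upward bias under noise, see above); it also says
  nothing about the shape of the reaction norm between the extremes.
* The exact Mann–Whitney enumeration is combinatorial; above the
  configurable `exact_limit` the normal approximation takes over.
* Polytomy contrasts depend on the chosen split statistic (predictor
  mean); other operationalizations of the single-contrast method exist
  and can give different valid-contrast counts.
* The length–weight bridge applies one model per population; ontogenetic
  or seasonal allometry changes are not modelled.
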