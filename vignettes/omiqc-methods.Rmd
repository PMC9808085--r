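---
title: "Scoring pre-analytical quality of plasma and serum omics: methods"
author: "omiqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pre-analytical quality of plasma and serum omics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omiqc)
```

## The problem

Blood samples sit on a bench between draw and freezing. During that sitting
time, metabolites interconvert (hypoxanthine accumulates, lactate rises) and
blood cells leak or activate (hemolysis releases erythrocyte proteins such
as CA2 and CAT; coagulation in serum consumes fibrinogen and releases
platelet granule proteins such as PPBP and THBS1). Sitting time, holding
temperature and, to a much smaller extent, centrifugation force therefore
leave systematic fingerprints on plasma and serum metabolomes and proteomes.
In clinical cohorts these fingerprints are confounders: a biomarker panel
that partly measures bench time is not a biomarker panel.

`omiqc` implements a complete analysis chain to (a) identify which analytes
are unstable under controlled handling conditions, (b) condense the
instability fingerprint of each condition into a weighted signature, and
(c) score new samples for quality and blood-cell contamination with a
permutation-normalized enrichment score (NES). Because studies of this kind
rarely deposit raw quantitation tables, the package ships a synthetic cohort
generator with full ground truth, so every stage is testable end to end.

## The emulated study design

The generator's defaults emulate a typical controlled pre-analytical
experiment: six healthy donors, plasma held at 4°C and at room temperature
(RT) and serum at RT only (serum is, by construction, an RT product of
coagulation), sitting times of 0, 2, 4 and 8 hours, a targeted metabolome
panel of 497 analytes and a DIA plasma proteome of 572 proteins.
Centrifugation (2000 g) is carried in the metadata but given no effect:
controlled comparisons consistently fail to attribute signal to it.

Per feature $g$ and sample $s$ (individual $i$, time $t$, temperature
$\tau$) the generator draws

$$\log_2 y_{gs} = \mu_g + a_{gi} + \mathbb{1}[g\ \mathrm{affected}]\,
\delta_g\, t\, m_g(\tau) + \varepsilon_{gs},\qquad
a_{gi}\sim N(0,\sigma_\mathrm{ind}^2),\ \
\varepsilon\sim N(0,\sigma_\varepsilon^2),$$

and stores $2^{\log_2 y}$ as the raw value. Key default choices, and why:

* **10% of metabolites and 3% of proteins are time-sensitive** — the
  stable-majority structure repeatedly reported for blood under controlled
  handling (roughly nine in ten metabolites and nearly all proteins change
  only slightly).
* **Individual effects dominate, more so in the metabolome**
  ($\sigma_\mathrm{ind} = 1.0$ log2 units for metabolites, 0.3 for
  proteins, residual $\sigma_\varepsilon = 0.25$): between-donor separation
  is the strongest signal in such cohorts and is visibly weaker at the
  proteome level.
* **Slopes** $|\delta_g| \sim U(0.05, 0.5)$ log2/h with random sign. No
  study quantifies per-feature effect sizes beyond qualitative "absolute
  change" displays, so this range is a modelling choice: at 8 h it spans
  barely-detectable (0.4 log2) through dramatic (4 log2) changes.
* **Temperature asymmetry**: metabolite degradation is amplified at RT,
  protein deregulation at 4°C (hemolysis on ice), via a per-layer favored
  temperature and a multiplier (default 2). Each affected feature draws a
  sensitivity class — favored-only (50%), opposite-only (30%), both (20%) —
  so that signatures derived at one temperature are enriched for features
  that genuinely degrade mostly at that temperature. Without
  condition-specific feature sets, a single shared set would make every
  derived signature peak in the globally strongest condition and the
  per-condition scoring structure seen in real data could not arise.
* **Serum degrades its own, independently drawn feature set** (same
  fraction): coagulation chemistry differs from plasma bench chemistry.
  The truth object records plasma and serum flags separately.
* **Detection-limit censoring is analyte-specific**: each feature censors
  values below its own `lodQuantile` (default 5%) marginal quantile,
  mimicking per-analyte LOD semantics of targeted kits; the implied LOD
  table (threshold/10) is attached to the assay metadata.

What the generator does *not* emulate: ionization suppression, batch drift,
lipid-class chemistry, missingness that is not left-censoring, and
non-linear degradation kinetics. Passing tests on synthetic cohorts
demonstrate that the statistical machinery behaves as specified under the
model's assumptions — not that any particular real cohort satisfies them.

## Preprocessing

**Detection-limit filter.** A feature is kept iff the fraction of samples
where it is reliably quantified (value $> 10\times$LOD *or* $\ge$ LLOQ, a
disjunction) strictly exceeds 0.66. "More than 66%" is read as a strict
inequality; features lacking limits fall back to a completeness rule. The
rule is evaluated on whatever sample set is passed in, so plasma and serum
can be filtered jointly or separately; the removal report records every
feature's qualifying fraction either way.

**Variance stabilization.** Raw intensities are heteroskedastic: SD grows
with the mean. The package uses a two-step transform: per-sample
median-of-ratios scaling followed by a generalized log,
$\mathrm{glog}_2(x; c) = \log_2\!\big((x + \sqrt{x^2 + c^2})/2\big)$, with a
single dataset-level $c$ set to the 5th percentile of the scaled non-missing
values. This is a deliberate, documented approximation: downstream stages
need only approximate homoskedasticity, and a fixed-$c$ glog is exactly
reproducible without iterative maximum-likelihood calibration. One
implementation detail matters: the size-factor median is taken over each
sample's *observed* features against a feature-wise geometric-mean
reference. Restricting to globally complete features sounds cleaner but is
fragile under analyte-specific censoring — almost no feature is complete
everywhere, and the surviving subset is enriched for time-sensitive,
high-abundance analytes, which leaks handling effects into the size factors
and inflates false positives downstream. The observed-feature median is
dominated by the stable ~90% of the panel.

**Left-censored imputation.** Missing values are assumed censored at the
detection limit and replaced deterministically by the 1% linear-interpolation
quantile of the observed values of the same sample. A sample with no
observed values is an error (named in the message), not a guess.

Technical duplicate injections, when present, are averaged per feature
(`collapseReplicates`) before analysis.

## Stability statistics

Two model families, matching the two questions asked of such data:

**Moderated fixed-effects models** (`fitLinearEbayes`). For each feature,
ordinary least squares on a shared design (individual as a categorical
term; time numeric in hours; temperature categorical, reference 4°C). The
per-feature residual variances $s_g^2$ (df $d_g$) are shrunk toward a
global prior estimated by moment matching on $\log s_g^2$ (digamma /
trigamma equations, prior df $d_0$ and scale $s_0^2$):

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
\tilde t_g = \frac{\hat\beta_g}{\tilde s_g \sqrt{v_g}}
\sim t_{d_0 + d_g}.$$

Multi-column terms (individual) get a moderated F. Arbitrary linear
contrasts are supported; the 8 h vs 0 h sitting-time contrast used for
signature derivation is $8\times$ the time slope. When the observed
variance spread is no larger than chi-square sampling noise the prior df is
infinite and all features share $s_0^2 = \overline{s^2}$; with $d_0 = 0$
the fit reduces exactly to per-feature OLS t-tests (both limits are tested,
and the whole machinery is cross-checked against an independent
reference implementation in the unit tests).

Time is numeric by default — degradation displays as a trend along sitting
time, and a slope test is the matching hypothesis; a categorical-time
analysis can be had by passing a custom design.

**Per-feature linear mixed models** (`fitMixedStability`). Fixed effects
time, temperature and their interaction (plasma) or time only (serum), plus
a random intercept per individual; REML with Satterthwaite denominator df.
A fit is deemed singular when the random-intercept variance estimate sits
at the boundary (below $10^{-8}\times$ the residual variance, or the
optimizer fails); the feature is then refit as a fixed-effects-only linear
model and flagged `anova_fallback`. Note that when the true individual
variance is zero the REML estimate is strictly positive by sampling noise
for a sizeable minority of features, so the attainable fallback fraction
under forced singularity is a clear majority, not 100%.

Benjamini–Hochberg adjustment is applied per factor, per matrix type and
per omics layer — each analysis corrects its own family. Missing p-values
(degenerate features) are excluded from the FDR universe and reinserted.

## Signatures

A quality signature for a handling condition is the top-20 features by
**raw** p-value of the 8 h vs 0 h contrast within that condition's samples,
weighted by their moderated t-values. Raw rather than adjusted p is used
for ranking: within one contrast BH is monotone, so the selected set is
identical, but raw p avoids ties at capped adjusted values; ties are broken
by larger $|t|$, then feature id, making derivation fully deterministic.
Positive weight always means "increases under the degraded condition".

Contamination panels (erythrocyte, platelet, coagulation) are data, not
algorithm: the bundled TSV carries the literature-named driver proteins
plus a curated synthetic stand-in for the remaining membership (unit
weights for erythrocyte/platelet, signed weights for coagulation — clotting
consumes fibrinogen and F13A1 while releasing PPBP and THBS1), and any user
panel can replace it via `loadSignatures()`.

## Scoring

Values are first z-scored per feature across the cohort
(`scalePerFeature`): every measurement becomes "how unusual is this sample,
for this analyte, relative to the cohort". A signature's raw score in a
sample is the weighted mean over measured members,
$\sum w_i x_i / \sum |w_i|$ (minimum overlap 3 — smaller intersections are
noise-dominated and refused). The empirical null permutes the sample's
values across the full measured universe, keeping the weights on the
signature's slots, and

$$\mathrm{NES} = \frac{\mathrm{raw} - \mathrm{mean}(\mathrm{null})}
{\mathrm{sd}(\mathrm{null})}$$

is the number of null SDs the observed score sits away from chance. NES 0
means cohort-average degradation; the score is relative, not absolute —
which is why a reference-sample mechanism (`referenceDeltaNes`) is
provided and why including at least one sample of known quality in any
scored batch is good practice. Numerical notes: the default 1000
permutations give a null-mean Monte-Carlo error of about 3% of the null SD;
the same permutation index set is shared across samples (each sample's
marginal null is unchanged, computation is vectorized and deterministic
given the seed); a zero null SD (degenerate universe) yields a missing NES
with a warning rather than an infinity; scores are reported signed, and
focusing on positive values is a display choice left to the user.

## Design decisions that were genuinely open

* **Per-feature z-scoring** as the cohort normalization (an alternative
  would be rank-based scaling): z-scores keep effect magnitudes and make
  the weighted mean interpretable as an average standardized shift.
* **Null over values, not weights**: permuting the sample's values over the
  universe matches the "empirical null distribution of scores for this
  sample" reading of NES and keeps signatures of different sizes
  comparable.
* **Serum handled as its own group** with temperature fixed to RT
  everywhere (design specification, generator, model validity checks).
* **Signature derivation per temperature subset** (individual + numeric
  time model within one temperature) rather than one joint model with
  interaction contrasts: equivalent tests for the 8 h endpoint, simpler
  provenance per condition label.

## Problem sizes used in the packaged checks

The automated checks run, by choice, at desk scale: cohorts of 500
features for parameter-recovery checks (sensitivity and false-positive
rate of the mixed-model pipeline at BH $\alpha = 0.05$), the full default
panel (497 + 572 features, 72 samples per layer) for the condition-signature
and contamination checks, $10^5$ permutations against an exhaustively
enumerable 5-feature universe for the null oracle, and 500 samples × 300
features for NES calibration. The reproduction script
(`scripts/acceptance.R`) recomputes all of these from scratch from a single
seed.

## Known limitations

* The glog calibration is a fixed-quantile approximation, not a
  maximum-likelihood fit; extremely skewed intensity distributions may
  leave residual mean-variance trend at the low end.
* NES is cohort-relative; scoring a cohort that is uniformly degraded will
  not flag anything without reference samples.
* The bundled contamination membership beyond the named drivers is a
  synthetic stand-in and should be replaced with measured panels where
  available.
* Mixed-model p-values rely on Satterthwaite approximations; with six
  individuals the random-intercept variance itself is estimated with
  little precision (the per-feature fit flags make the fallback visible).
* The generator's linear-in-time log-scale kinetics are a first-order
  caricature; saturating or lagged degradation will be mis-specified by
  the slope test, though usually still detected.

## A minimal worked example

```{r example, eval = FALSE}
sim <- simulateCohort(simulationParams(seed = 1))
imp <- imputeMinDet(glogTransform(filterLowAbundance(sim$metabolome)$assay))
sig <- qualitySignatureFromCohort(imp, "plasma", "RT")
sc  <- nesScores(scalePerFeature(imp), sig, nPerm = 1000, seed = 2)
groupAverage(sc, as.data.frame(sim$metadata))
```
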