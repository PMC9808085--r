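# omiqc — pre-analytical quality scoring for plasma and serum omics

Blood samples degrade between draw and freezing: sitting time and holding
temperature leave systematic fingerprints on the plasma/serum metabolome
(e.g. hypoxanthine and lactate accumulation, stronger at room temperature)
and proteome (e.g. erythrocyte proteins such as CA2 and CAT leaking into
plasma on ice, coagulation remodelling in serum). In clinical omics these
fingerprints are confounders. `omiqc` is an R package for quantifying them
and for scoring the quality and blood-cell contamination of individual
samples.

The package implements, for both metabolomics and proteomics quantitation
matrices:

* **Preprocessing** — detection-limit filtering (keep a feature iff
  quantified above 10×LOD or ≥LLOQ in more than 66% of samples),
  median-of-ratios scaling with a generalized-log transform
  `glog2(x; c) = log2((x + √(x² + c²))/2)`, and deterministic left-censored
  ("MinDet"-style) imputation at a low per-sample quantile.
* **Stability statistics** — per-feature linear models with empirical-Bayes
  variance moderation (`s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)`, moderated
  t/F on `d₀ + d_g` df) for individual effects and sitting-time contrasts,
  and per-feature linear mixed models (random intercept per donor,
  Satterthwaite df, fixed-effects fallback on singular fits), with
  Benjamini–Hochberg FDR per factor.
* **Signatures** — condition fingerprints as the top-20 features of the
  8 h-vs-0 h contrast weighted by moderated t-values, plus bundled
  (user-replaceable) erythrocyte / platelet / coagulation contamination
  panels.
* **Scoring** — the weighted-mean signature score
  `Σ wᵢxᵢ / Σ|wᵢ|` on per-feature z-scaled data, normalized against an
  empirical permutation null: `NES = (raw − null_mean)/null_sd`, the number
  of null standard deviations a sample sits away from cohort-average
  degradation.
* **A synthetic cohort generator** with ground truth (6 donors, plasma at
  4°C/RT and serum at RT, sitting times 0/2/4/8 h, dominant individual
  random effects, ~10% time-sensitive metabolites / ~3% proteins,
  analyte-specific LOD censoring, contamination spike-ins), so the whole
  chain is testable without external data.

See `vignettes/omiqc-methods.Rmd` for the model, parameter rationale and
limitations.

## Worked example

```r
library(omiqc)

sim <- simulateCohort(simulationParams(seed = 1))
sim$metabolome
#> OmicsAssay [raw]: 497 features x 72 samples
#>   missing: 5.6%
#>   colData: sample_id, individual, matrix, time_h, temperature, centrifugation_g

imp <- imputeMinDet(glogTransform(filterLowAbundance(sim$metabolome)$assay))
sig <- qualitySignatureFromCohort(imp, "plasma", "RT")   # top-20, t weights
sig
#> OmicsSignature 'plasma_RT_8h' (derived_quality): 20 features
#>   metab_0466=33.9, metab_0422=28.3, metab_0484=-23.7, metab_0329=23.4, ...

sc <- nesScores(scalePerFeature(imp), sig, nPerm = 1000, seed = 2)
groupAverage(sc, as.data.frame(sim$metadata))
#>  matrix temperature time_h    signature mean_nes n
#>  plasma          4C      0 plasma_RT_8h    -2.12 6
#>  plasma          4C      2 plasma_RT_8h    -1.16 6
#>  plasma          4C      4 plasma_RT_8h    -0.33 6
#>  plasma          4C      8 plasma_RT_8h     1.18 6
#>  plasma          RT      0 plasma_RT_8h    -1.98 6
#>  plasma          RT      2 plasma_RT_8h     0.81 6
#>  plasma          RT      4 plasma_RT_8h     3.34 6
#>  plasma          RT      8 plasma_RT_8h     7.61 6
#>   serum          RT      0 plasma_RT_8h    -2.00 6
#>   serum          RT      2 plasma_RT_8h    -2.08 6
#>   serum          RT      4 plasma_RT_8h    -1.80 6
#>   serum          RT      8 plasma_RT_8h    -2.11 6
```

The `plasma_RT_8h` signature — derived from samples left 8 h at room
temperature — climbs monotonically with sitting time in the RT plasma
groups (mean NES −1.98 at 0 h to 7.61 at 8 h), rises only weakly in the
4°C groups, and stays flat and negative in serum: samples matching the
signature's own handling condition score highest, which is exactly what
makes the NES usable as a quality metric. Contamination is scored the same
way with `bundledContaminationSignatures()`; `runPipeline()` executes the
whole chain (simulate/load → preprocess → signatures → scores) and writes
TSV artifacts plus a provenance log, and `inst/scripts/omiqc.R` exposes it
on the command line.

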