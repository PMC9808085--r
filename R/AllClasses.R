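#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

.STAGES <- c("raw", "transformed", "imputed", "scaled")

#' Feature-by-sample quantitation container
#'
#' `OmicsAssay` extends [SummarizedExperiment::SummarizedExperiment] with a
#' `stage` tag recording where the matrix sits in the preprocessing chain
#' (`raw` -> `transformed` -> `imputed` -> `scaled`). Raw matrices hold
#' non-negative intensities/concentrations with `NA` marking values censored
#' below the detection limit; later stages hold generalized-log values.
#' Sample metadata (individual, matrix type, sitting time, temperature,
#' centrifugation) lives in `colData`.
#'
#' @slot stage character(1), one of `"raw"`, `"transformed"`, `"imputed"`,
#'   `"scaled"`.
#' @aliases OmicsAssay-class
#' @exportClass OmicsAssay
setClass("OmicsAssay",
    contains = "SummarizedExperiment",
    slots = c(stage = "character"),
    prototype = prototype(stage = "raw"))

setValidity("OmicsAssay", function(object) {
    msg <- NULL
    if (length(object@stage) != 1L || !object@stage %in% .STAGES)
        msg <- c(msg, sprintf("stage must be one of: %s",
                              paste(.STAGES, collapse = ", ")))
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "feature ids (rownames) must be present and unique")
    if (identical(object@stage, "raw")) {
        v <- SummarizedExperiment::assay(object)
        if (any(v < 0, na.rm = TRUE))
            msg <- c(msg, "raw values must be non-negative")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct an OmicsAssay
#'
#' @param values numeric matrix, features in rows, samples in columns; both
#'   dimnames required. `NA` marks missing (censored) cells.
#' @param colData optional `DataFrame`/`data.frame` of per-sample metadata;
#'   rownames must match `colnames(values)`.
#' @param stage processing stage tag, see [OmicsAssay-class].
#' @param ... further arguments passed to
#'   [SummarizedExperiment::SummarizedExperiment], e.g. `metadata`.
#' @return an [OmicsAssay-class] object.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
#' OmicsAssay(m)
#' @export
OmicsAssay <- function(values, colData = NULL, stage = "raw", ...) {
    if (!is.matrix(values) || !is.numeric(values))
        stop("'values' must be a numeric matrix")
    if (is.null(colData))
        colData <- S4Vectors::DataFrame(row.names = colnames(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = values), colData = colData, ...)
    new("OmicsAssay", se, stage = stage)
}

#' Stability statistics for a feature panel
#'
#' Long-format results of a feature-wise stability analysis: one row per
#' (feature, model term), with the coefficient estimate, the (moderated) t or
#' F statistic, degrees of freedom, raw and BH-adjusted p-values and a fit
#' flag (`ols`, `mixed`, `anova_fallback` or `degenerate`). For the
#' empirical-Bayes route the estimated prior `(d0, s02)` is kept alongside.
#'
#' @slot results `DataFrame` with columns `feature_id`, `factor`, `estimate`,
#'   `statistic`, `df`, `p`, `p_adj`, `fit_flag`.
#' @slot prior numeric, named `d0` and `s02` (NA for the mixed-model route).
#' @slot method character(1), `"ebayes"` or `"mixed"`.
#' @aliases StabilityResult-class
#' @exportClass StabilityResult
setClass("StabilityResult",
    slots = c(results = "DataFrame", prior = "numeric", method = "character"))

setValidity("StabilityResult", function(object) {
    need <- c("feature_id", "factor", "estimate", "statistic", "df",
              "p", "p_adj", "fit_flag")
    msg <- NULL
    if (!all(need %in% colnames(object@results)))
        msg <- c(msg, paste("results must contain columns:",
                            paste(need, collapse = ", ")))
    ok <- !is.na(object@results$p) & !is.na(object@results$p_adj)
    if (any(object@results$p_adj[ok] < object@results$p[ok] - 1e-12))
        msg <- c(msg, "adjusted p-values may not be smaller than raw p-values")
    if (any(object@results$p_adj[ok] > 1 | object@results$p_adj[ok] < 0))
        msg <- c(msg, "adjusted p-values must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Weighted feature signature
#'
#' A named set of features with signed weights encoding direction and strength
#' of change under a condition. Positive weight means the feature increases
#' under the degraded or contaminated condition.
#'
#' @slot name label of the signature (e.g. `"plasma_RT_8h"` or
#'   `"erythrocyte"`).
#' @slot source one of `"derived_quality"` (learned from a sitting-time
#'   contrast) or `"contamination"` (blood-cell panel).
#' @slot weights named numeric vector, feature id -> signed weight.
#' @slot provenance free-text origin note (condition label, k, citation tag).
#' @aliases OmicsSignature-class
#' @exportClass OmicsSignature
setClass("OmicsSignature",
    slots = c(name = "character", source = "character",
              weights = "numeric", provenance = "character"))

setValidity("OmicsSignature", function(object) {
    msg <- NULL
    w <- object@weights
    if (length(w) == 0L)
        msg <- c(msg, "signature must contain at least one feature")
    if (is.null(names(w)) || anyDuplicated(names(w)))
        msg <- c(msg, "weights must be uniquely named by feature id")
    if (any(!is.finite(w)))
        msg <- c(msg, "all weights must be finite")
    if (length(w) > 0L && all(w == 0))
        msg <- c(msg, "weights may not all be zero")
    if (!object@source %in% c("derived_quality", "contamination"))
        msg <- c(msg, "source must be 'derived_quality' or 'contamination'")
    if (is.null(msg)) TRUE else msg
})

#' Construct an OmicsSignature
#'
#' @param name signature label.
#' @param weights named numeric vector (feature id -> signed weight).
#' @param source `"derived_quality"` or `"contamination"`.
#' @param provenance free-text origin note.
#' @return an [OmicsSignature-class] object.
#' @examples
#' OmicsSignature("coagulation", c(PPBP = 1, THBS1 = 1, F13A1 = -1),
#'                source = "contamination")
#' @export
OmicsSignature <- function(name, weights, source = "derived_quality",
                           provenance = NA_character_) {
    new("OmicsSignature", name = name, source = source,
        weights = weights, provenance = as.character(provenance))
}

#' Sample-by-signature enrichment scores
#'
#' Holds, for every (sample, signature) pair, the raw weighted-mean score, the
#' mean and SD of the permutation null and the normalized enrichment score
#' NES = (raw - null_mean) / null_sd.
#'
#' @slot table `DataFrame` with columns `sample_id`, `signature`, `raw_score`,
#'   `null_mean`, `null_sd`, `nes`.
#' @slot nPerm number of permutations used for the null.
#' @slot seed RNG seed used (NA if none supplied).
#' @aliases ScoreTable-class
#' @exportClass ScoreTable
setClass("ScoreTable",
    slots = c(table = "DataFrame", nPerm = "integer", seed = "integer"))

setValidity("ScoreTable", function(object) {
    need <- c("sample_id", "signature", "raw_score", "null_mean",
              "null_sd", "nes")
    if (!all(need %in% colnames(object@table)))
        return(paste("table must contain columns:", paste(need, collapse = ", ")))
    TRUE
})

#' Simulation parameters for the synthetic blood cohort
#'
#' Defaults emulate the profiled study design: 6 individuals, plasma at 4C and
#' room temperature (RT) and serum at RT only, sitting times 0/2/4/8 h, 497
#' metabolites and 572 proteins, about 10% of metabolites and 3% of proteins
#' sensitive to sitting time, dominant individual random effects (stronger in
#' the metabolome), and 5% detection-limit censoring. Metabolite degradation
#' is amplified at RT and protein deregulation at 4C via
#' `tempInteractionMultiplier`.
#'
#' @slot nIndividuals number of blood donors (>= 2).
#' @slot nMetabolites,nProteins panel sizes.
#' @slot timePointsH sitting times in hours.
#' @slot temperatures temperature levels for plasma (serum is always RT).
#' @slot fracTimeSensitiveMetab,fracTimeSensitiveProt proportion of features
#'   with a genuine sitting-time effect.
#' @slot deltaRange range of |slope| in log2-units per hour for affected
#'   features.
#' @slot tempInteractionMultiplier amplification of the slope at the
#'   layer-favored temperature (RT for metabolites, 4C for proteins).
#' @slot sdIndividualMetab,sdIndividualProt SD of the per-individual random
#'   intercept, log2 units.
#' @slot sdNoise residual SD, log2 units.
#' @slot lodQuantile per-feature fraction of the intensity distribution
#'   censored to missing.
#' @slot seed default RNG seed (overridable in [simulateCohort()]).
#' @aliases SimulationParams-class
#' @exportClass SimulationParams
setClass("SimulationParams",
    slots = c(nIndividuals = "integer", nMetabolites = "integer",
              nProteins = "integer", timePointsH = "numeric",
              temperatures = "character",
              fracTimeSensitiveMetab = "numeric",
              fracTimeSensitiveProt = "numeric",
              deltaRange = "numeric",
              tempInteractionMultiplier = "numeric",
              sdIndividualMetab = "numeric", sdIndividualProt = "numeric",
              sdNoise = "numeric", lodQuantile = "numeric",
              seed = "integer"))

setValidity("SimulationParams", function(object) {
    msg <- NULL
    if (object@nIndividuals < 2L)
        msg <- c(msg, "nIndividuals must be >= 2")
    if (object@nMetabolites < 1L || object@nProteins < 1L)
        msg <- c(msg, "panel sizes must be positive")
    if (length(object@timePointsH) == 0L)
        msg <- c(msg, "timePointsH may not be empty")
    if (any(object@timePointsH < 0))
        msg <- c(msg, "timePointsH must be non-negative")
    props <- c(object@fracTimeSensitiveMetab, object@fracTimeSensitiveProt,
               object@lodQuantile)
    if (any(props < 0 | props > 1))
        msg <- c(msg, "proportions must lie in [0, 1]")
    sds <- c(object@sdIndividualMetab, object@sdIndividualProt,
             object@sdNoise)
    if (any(sds < 0))
        msg <- c(msg, "standard deviations must be >= 0")
    if (length(object@deltaRange) != 2L || any(object@deltaRange < 0) ||
        diff(object@deltaRange) < 0)
        msg <- c(msg, "deltaRange must be an increasing pair of non-negatives")
    if (object@tempInteractionMultiplier <= 0)
        msg <- c(msg, "tempInteractionMultiplier must be positive")
    if (!all(object@temperatures %in% c("4C", "RT")) ||
        length(object@temperatures) == 0L)
        msg <- c(msg, "temperatures must be a non-empty subset of {4C, RT}")
    if (is.null(msg)) TRUE else msg
})

#' Construct simulation parameters
#'
#' See [SimulationParams-class] for the meaning and scientific rationale of
#' each field.
#'
#' @param nIndividuals,nMetabolites,nProteins,timePointsH,temperatures,
#'   fracTimeSensitiveMetab,fracTimeSensitiveProt,deltaRange,
#'   tempInteractionMultiplier,sdIndividualMetab,sdIndividualProt,sdNoise,
#'   lodQuantile,seed see [SimulationParams-class].
#' @return a validated [SimulationParams-class] object.
#' @examples
#' simulationParams(nMetabolites = 100, nProteins = 50)
#' @export
simulationParams <- function(nIndividuals = 6, nMetabolites = 497,
                             nProteins = 572, timePointsH = c(0, 2, 4, 8),
                             temperatures = c("4C", "RT"),
                             fracTimeSensitiveMetab = 0.10,
                             fracTimeSensitiveProt = 0.03,
                             deltaRange = c(0.05, 0.5),
                             tempInteractionMultiplier = 2,
                             sdIndividualMetab = 1.0,
                             sdIndividualProt = 0.3,
                             sdNoise = 0.25, lodQuantile = 0.05,
                             seed = 1L) {
    new("SimulationParams",
        nIndividuals = as.integer(nIndividuals),
        nMetabolites = as.integer(nMetabolites),
        nProteins = as.integer(nProteins),
        timePointsH = as.numeric(timePointsH),
        temperatures = as.character(temperatures),
        fracTimeSensitiveMetab = fracTimeSensitiveMetab,
        fracTimeSensitiveProt = fracTimeSensitiveProt,
        deltaRange = as.numeric(deltaRange),
        tempInteractionMultiplier = tempInteractionMultiplier,
        sdIndividualMetab = sdIndividualMetab,
        sdIndividualProt = sdIndividualProt,
        sdNoise = sdNoise, lodQuantile = lodQuantile,
        seed = as.integer(seed))
}

#' Ground truth of a simulated cohort
#'
#' @slot metabolites,proteins `DataFrame`s with one row per feature:
#'   `feature_id`, `affected` (plasma sitting-time effect), `delta` (signed
#'   slope, log2/h), `m_4C`, `m_RT` (temperature multipliers),
#'   `affected_serum`, `delta_serum`.
#' @slot contamination `DataFrame` of injected contamination:
#'   `sample_id`, `signature`, `strength` (empty until
#'   [injectContamination()] is used).
#' @aliases SyntheticTruth-class
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
    slots = c(metabolites = "DataFrame", proteins = "DataFrame",
              contamination = "DataFrame"))
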