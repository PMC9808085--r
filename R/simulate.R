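## Synthetic plasma/serum cohort generation.
##
## Model per feature g and sample s (individual i, sitting time t, temperature
## tau): log2 y_gs = mu_g + a_gi + affected_g * delta_g * t * m_g(tau) + eps,
## a_gi ~ N(0, sd_ind^2), eps ~ N(0, sd_noise^2); the raw scale is 2^log2 y
## and values below the per-feature LOD quantile are censored to NA.
## Affected features carry a temperature-sensitivity class so that signatures
## derived at one temperature are enriched for features degrading mostly at
## that temperature (favored-only / opposite-only / both), with overall
## degradation amplified at RT for metabolites and at 4C for proteins.

# class mixture over affected features; favored = layer-favored temperature
.CLASS_PROBS <- c(favored = 0.5, opposite = 0.3, both = 0.2)
.OPPOSITE_ATTENUATION <- 0.2

.runWithSeed <- function(seed, expr) {
    if (!is.null(seed) && !is.na(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

.featureTruth <- function(n, prefix, frac, deltaRange, favoredTemp, mult,
                          featureIds) {
    nAff <- round(frac * n)
    affected <- logical(n)
    if (nAff > 0)
        affected[sample.int(n, nAff)] <- TRUE
    delta <- numeric(n)
    m4 <- numeric(n)
    mRT <- numeric(n)
    cls <- rep(NA_character_, n)
    if (nAff > 0) {
        delta[affected] <- stats::runif(nAff, deltaRange[1], deltaRange[2]) *
            sample(c(-1, 1), nAff, replace = TRUE)
        cls[affected] <- sample(names(.CLASS_PROBS), nAff, replace = TRUE,
                                prob = .CLASS_PROBS)
        mFav <- c(favored = mult, opposite = .OPPOSITE_ATTENUATION, both = 1)
        mOpp <- c(favored = .OPPOSITE_ATTENUATION, opposite = 1, both = 1)
        if (identical(favoredTemp, "RT")) {
            mRT[affected] <- mFav[cls[affected]]
            m4[affected] <- mOpp[cls[affected]]
        } else {
            m4[affected] <- mFav[cls[affected]]
            mRT[affected] <- mOpp[cls[affected]]
        }
    }
    # serum degrades its own (independently drawn) feature set, all at RT
    affSerum <- logical(n)
    if (nAff > 0)
        affSerum[sample.int(n, nAff)] <- TRUE
    deltaSerum <- numeric(n)
    deltaSerum[affSerum] <- stats::runif(sum(affSerum), deltaRange[1],
                                         deltaRange[2]) *
        sample(c(-1, 1), sum(affSerum), replace = TRUE)
    S4Vectors::DataFrame(feature_id = featureIds, affected = affected,
                         delta = delta, m_4C = m4, m_RT = mRT,
                         sensitivity_class = cls,
                         affected_serum = affSerum,
                         delta_serum = deltaSerum)
}

.simulateLayer <- function(truth, meta, mu, sdInd, sdNoise, lodQuantile,
                           nIndividuals) {
    n <- nrow(truth)
    aInd <- matrix(stats::rnorm(n * nIndividuals, 0, sdInd), n, nIndividuals)
    log2y <- matrix(mu, n, nrow(meta))
    for (j in seq_len(nrow(meta))) {
        i <- meta$individual[j]
        t <- meta$time_h[j]
        if (meta$matrix[j] == "plasma") {
            m <- if (meta$temperature[j] == "RT") truth$m_RT else truth$m_4C
            eff <- ifelse(truth$affected, truth$delta * t * m, 0)
        } else {
            eff <- ifelse(truth$affected_serum, truth$delta_serum * t, 0)
        }
        log2y[, j] <- log2y[, j] + aInd[, i] + eff
    }
    log2y <- log2y + matrix(stats::rnorm(n * nrow(meta), 0, sdNoise),
                            n, nrow(meta))
    raw <- 2^log2y
    dimnames(raw) <- list(truth$feature_id, meta$sample_id)
    # analyte-specific detection limit: per-feature lower quantile
    thr <- apply(raw, 1, stats::quantile, probs = lodQuantile, names = FALSE)
    raw[sweep(raw, 1, thr, "<")] <- NA
    list(raw = raw,
         limits = S4Vectors::DataFrame(feature_id = truth$feature_id,
                                       lod = thr / 10, lloq = NA_real_))
}

#' Simulate a plasma/serum metabolomics + proteomics cohort
#'
#' Generates raw quantitation matrices for both omics layers over the full
#' factorial design (individuals x plasma temperatures x sitting times, plus
#' serum at RT only), together with sample metadata and ground truth. The
#' proteome panel starts with the bundled blood-cell contamination marker
#' genes so that contamination spike-ins target measured features, as they
#' would on a real plasma DIA panel. Centrifugation is carried in the
#' metadata at a single level (2000 g) and has no effect on the values.
#'
#' @param params a [SimulationParams-class] object.
#' @param seed integer RNG seed; defaults to `params@seed`. Identical
#'   parameters and seed give bit-identical output.
#' @return a list with elements `metabolome` and `proteome` (raw
#'   [OmicsAssay-class] objects with detection limits in
#'   `metadata(x)$detectionLimits`), `metadata` (a `DataFrame`, also the
#'   `colData` of both assays) and `truth` ([SyntheticTruth-class]).
#' @examples
#' sim <- simulateCohort(simulationParams(nMetabolites = 50, nProteins = 40))
#' sim$metabolome
#' @export
simulateCohort <- function(params = simulationParams(), seed = params@seed) {
    stopifnot(is(params, "SimulationParams"))
    validObject(params)
    .runWithSeed(seed, {
        times <- params@timePointsH
        inds <- seq_len(params@nIndividuals)
        plasma <- expand.grid(individual = inds,
                              temperature = params@temperatures,
                              time_h = times, stringsAsFactors = FALSE)
        plasma$matrix <- "plasma"
        serum <- expand.grid(individual = inds, temperature = "RT",
                             time_h = times, stringsAsFactors = FALSE)
        serum$matrix <- "serum"
        meta <- rbind(plasma, serum)
        meta$centrifugation_g <- 2000L
        meta$sample_id <- sprintf("ind%02d_%s_%s_%gh", meta$individual,
                                  meta$matrix, meta$temperature, meta$time_h)
        meta <- meta[, c("sample_id", "individual", "matrix", "time_h",
                         "temperature", "centrifugation_g")]
        rownames(meta) <- meta$sample_id

        metabIds <- sprintf("metab_%04d", seq_len(params@nMetabolites))
        panel <- sort(unique(unlist(lapply(bundledContaminationSignatures(),
                                           function(s) names(s@weights)))))
        nProt <- params@nProteins
        protIds <- if (nProt <= length(panel)) panel[seq_len(nProt)] else
            c(panel, sprintf("prot_%04d",
                             seq_len(nProt - length(panel))))

        truthM <- .featureTruth(params@nMetabolites, "metab",
                                params@fracTimeSensitiveMetab,
                                params@deltaRange, "RT",
                                params@tempInteractionMultiplier, metabIds)
        truthP <- .featureTruth(nProt, "prot",
                                params@fracTimeSensitiveProt,
                                params@deltaRange, "4C",
                                params@tempInteractionMultiplier, protIds)

        muM <- stats::rnorm(params@nMetabolites, 4, 1.5)
        muP <- stats::rnorm(nProt, 15, 2)
        layerM <- .simulateLayer(truthM, meta, muM, params@sdIndividualMetab,
                                 params@sdNoise, params@lodQuantile,
                                 params@nIndividuals)
        layerP <- .simulateLayer(truthP, meta, muP, params@sdIndividualProt,
                                 params@sdNoise, params@lodQuantile,
                                 params@nIndividuals)

        cd <- S4Vectors::DataFrame(meta)
        truth <- new("SyntheticTruth", metabolites = truthM,
                     proteins = truthP,
                     contamination = S4Vectors::DataFrame(
                         sample_id = character(), signature = character(),
                         strength = numeric()))
        list(metabolome = OmicsAssay(layerM$raw, colData = cd, stage = "raw",
                 metadata = list(detectionLimits = layerM$limits)),
             proteome = OmicsAssay(layerP$raw, colData = cd, stage = "raw",
                 metadata = list(detectionLimits = layerP$limits)),
             metadata = cd, truth = truth)
    })
}

.conditionLabels <- function(cd) {
    paste(cd$matrix, cd$temperature, cd$time_h, sep = "_")
}

#' Spike a contamination signature into samples
#'
#' Shifts the log2 value of every signature feature by
#' `strength * w / max(|w|)` in the targeted samples (on raw matrices the
#' values are multiplied by `2^shift`). Targets are named by the schedule:
#' names may be condition labels of the form `"<matrix>_<temperature>_<time>"`
#' (e.g. `"plasma_4C_8"`), a matrix type (`"plasma"`, `"serum"`) or explicit
#' sample ids; unknown keys are an error.
#'
#' @param assay an [OmicsAssay-class] whose features include all signature
#'   features.
#' @param signature an [OmicsSignature-class].
#' @param schedule named numeric vector of non-negative strengths (log2 units
#'   at `|w| = max|w|`).
#' @param truth optional [SyntheticTruth-class]; when given, the injection is
#'   recorded in its `contamination` slot.
#' @return a list with elements `assay` (modified) and `truth` (updated, or
#'   `NULL` if none was supplied).
#' @examples
#' sim <- simulateCohort(simulationParams(nMetabolites = 20, nProteins = 40))
#' ery <- bundledContaminationSignatures()[["erythrocyte"]]
#' spiked <- injectContamination(sim$proteome, ery, c(plasma = 1),
#'                               truth = sim$truth)
#' @export
injectContamination <- function(assay, signature, schedule, truth = NULL) {
    stopifnot(is(assay, "OmicsAssay"), is(signature, "OmicsSignature"))
    if (any(schedule < 0))
        stop("contamination strengths must be >= 0")
    if (is.null(names(schedule)) || any(!nzchar(names(schedule))))
        stop("'schedule' must be a named vector")
    w <- signature@weights
    miss <- setdiff(names(w), rownames(assay))
    if (length(miss))
        stop("signature features absent from the matrix: ",
             paste(utils::head(miss, 5), collapse = ", "))
    cd <- SummarizedExperiment::colData(assay)
    labels <- .conditionLabels(cd)
    v <- SummarizedExperiment::assay(assay)
    events <- list()
    for (key in names(schedule)) {
        sel <- if (key %in% c("plasma", "serum")) cd$matrix == key
               else if (key %in% labels) labels == key
               else if (key %in% colnames(assay)) colnames(assay) == key
               else stop("unknown schedule key: ", key)
        strength <- schedule[[key]]
        if (strength == 0 || !any(sel)) next
        shift <- strength * w / max(abs(w))
        idx <- match(names(w), rownames(assay))
        if (identical(assay@stage, "raw"))
            v[idx, sel] <- v[idx, sel] * 2^shift
        else
            v[idx, sel] <- v[idx, sel] + shift
        events[[key]] <- S4Vectors::DataFrame(
            sample_id = colnames(assay)[sel],
            signature = signature@name, strength = strength)
    }
    SummarizedExperiment::assay(assay) <- v
    if (!is.null(truth) && length(events))
        truth@contamination <- rbind(truth@contamination,
                                     do.call(rbind, unname(events)))
    list(assay = assay, truth = truth)
}
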