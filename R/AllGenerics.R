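#' Processing stage of an OmicsAssay
#'
#' @param x an [OmicsAssay-class].
#' @return character(1), the stage tag.
#' @examples
#' m <- matrix(1:4, 2, 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
#' stage(OmicsAssay(m))
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))

#' @rdname stage
#' @export
setMethod("stage", "OmicsAssay", function(x) x@stage)

#' Extract the results table of a StabilityResult
#'
#' @param x a [StabilityResult-class].
#' @return the long-format `DataFrame` of per-feature per-factor statistics.
#' @export
setGeneric("stabilityTable", function(x) standardGeneric("stabilityTable"))

#' @rdname stabilityTable
#' @export
setMethod("stabilityTable", "StabilityResult", function(x) x@results)

#' Variance prior of an empirical-Bayes fit
#'
#' @param x a [StabilityResult-class] produced by [fitLinearEbayes()].
#' @return named numeric `c(d0 = ..., s02 = ...)`.
#' @export
setGeneric("variancePrior", function(x) standardGeneric("variancePrior"))

#' @rdname variancePrior
#' @export
setMethod("variancePrior", "StabilityResult", function(x) x@prior)

#' Extract the score table of a ScoreTable object
#'
#' @param x a [ScoreTable-class].
#' @return `DataFrame` with columns `sample_id`, `signature`, `raw_score`,
#'   `null_mean`, `null_sd`, `nes`.
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname scoreTable
#' @export
setMethod("scoreTable", "ScoreTable", function(x) x@table)

#' Signature weights
#'
#' @param x an [OmicsSignature-class].
#' @return named numeric vector of signed weights.
#' @export
setGeneric("signatureWeights", function(x) standardGeneric("signatureWeights"))

#' @rdname signatureWeights
#' @export
setMethod("signatureWeights", "OmicsSignature", function(x) x@weights)

#' Signature name
#'
#' @param x an [OmicsSignature-class].
#' @return character(1).
#' @export
setGeneric("signatureName", function(x) standardGeneric("signatureName"))

#' @rdname signatureName
#' @export
setMethod("signatureName", "OmicsSignature", function(x) x@name)

setMethod("show", "OmicsAssay", function(object) {
    cat(sprintf("OmicsAssay [%s]: %d features x %d samples\n",
                object@stage, nrow(object), ncol(object)))
    v <- SummarizedExperiment::assay(object)
    cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(v))))
    if (ncol(SummarizedExperiment::colData(object)) > 0)
        cat("  colData:", paste(colnames(SummarizedExperiment::colData(object)),
                                collapse = ", "), "\n")
})

setMethod("show", "OmicsSignature", function(object) {
    w <- object@weights
    cat(sprintf("OmicsSignature '%s' (%s): %d features\n",
                object@name, object@source, length(w)))
    n <- min(5L, length(w))
    cat("  ", paste(sprintf("%s=%.3g", names(w)[seq_len(n)], w[seq_len(n)]),
                    collapse = ", "),
        if (length(w) > n) ", ..." else "", "\n", sep = "")
})

setMethod("show", "StabilityResult", function(object) {
    cat(sprintf("StabilityResult (%s): %d rows, factors: %s\n",
                object@method, nrow(object@results),
                paste(unique(object@results$factor), collapse = ", ")))
    if (identical(object@method, "ebayes"))
        cat(sprintf("  prior: d0 = %.3g, s02 = %.3g\n",
                    object@prior[["d0"]], object@prior[["s02"]]))
})

setMethod("show", "ScoreTable", function(object) {
    cat(sprintf("ScoreTable: %d samples x %d signatures (nPerm = %d)\n",
                length(unique(object@table$sample_id)),
                length(unique(object@table$signature)), object@nPerm))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf(paste0("SyntheticTruth: %d metabolites (%d affected), ",
                       "%d proteins (%d affected), %d contamination events\n"),
                nrow(object@metabolites), sum(object@metabolites$affected),
                nrow(object@proteins), sum(object@proteins$affected),
                nrow(object@contamination)))
})
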