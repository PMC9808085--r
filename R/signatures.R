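## Weighted feature signatures: derivation from sitting-time contrasts,
## TSV persistence, and the bundled blood-cell contamination panels.

#' Derive a pre-analytical quality signature
#'
#' Selects the `k` features with the smallest raw p-value for the named
#' contrast (ties: larger |statistic| first, then lexicographic feature id)
#' and uses their moderated t-values as signed weights, so that a positive
#' weight means the feature increases under the degraded condition.
#'
#' @param result a [StabilityResult-class] containing the contrast (e.g. an
#'   8 h vs 0 h sitting-time contrast from [fitLinearEbayes()]).
#' @param contrast name of the contrast/factor in the result.
#' @param conditionLabel label recorded as the signature name, conventionally
#'   `<matrix>_<temperature>_<time>` (e.g. `"plasma_RT_8h"`).
#' @param k signature size; if fewer features have finite p, all are used
#'   with a warning.
#' @return an [OmicsSignature-class] with `source = "derived_quality"`.
#' @export
deriveQualitySignature <- function(result, contrast, conditionLabel,
                                   k = 20) {
    stopifnot(is(result, "StabilityResult"))
    tab <- as.data.frame(result@results)
    tab <- tab[tab$factor == contrast, , drop = FALSE]
    if (nrow(tab) == 0L)
        stop("contrast not present in result: ", contrast)
    tab <- tab[is.finite(tab$p), , drop = FALSE]
    if (nrow(tab) == 0L)
        stop("no finite p-values for contrast: ", contrast)
    if (nrow(tab) < k) {
        warning(sprintf("only %d features with finite p (< k = %d); using all",
                        nrow(tab), k))
        k <- nrow(tab)
    }
    ord <- order(tab$p, -abs(tab$statistic), tab$feature_id)
    top <- tab[ord[seq_len(k)], ]
    w <- stats::setNames(top$statistic, top$feature_id)
    OmicsSignature(conditionLabel, w, source = "derived_quality",
                   provenance = sprintf("contrast=%s; k=%d", contrast, k))
}

#' Derive a quality signature directly from a cohort
#'
#' Convenience wrapper: subsets the samples to one matrix type (and, for
#' plasma, one temperature), fits per-feature models with `individual` and
#' numeric `time` as fixed effects, forms the `8 h vs 0 h` sitting-time
#' contrast (`8 * time` slope) with moderated statistics, and extracts the
#' top-`k` signature.
#'
#' @param assay an imputed [OmicsAssay-class] with design factors in
#'   `colData`.
#' @param matrixType `"plasma"` or `"serum"`.
#' @param temperature temperature level to subset to (`"4C"`/`"RT"`);
#'   ignored for serum (always RT).
#' @param k signature size (default 20).
#' @param hours sitting time of the contrast endpoint (default 8).
#' @return an [OmicsSignature-class] named `<matrix>_<temperature>_<hours>h`.
#' @examples
#' sim <- simulateCohort(simulationParams(nMetabolites = 60, nProteins = 40))
#' imp <- imputeMinDet(glogTransform(sim$metabolome))
#' qualitySignatureFromCohort(imp, "plasma", "RT", k = 5)
#' @export
qualitySignatureFromCohort <- function(assay, matrixType,
                                       temperature = "RT", k = 20,
                                       hours = 8) {
    cd <- SummarizedExperiment::colData(assay)
    sel <- cd$matrix == matrixType
    if (matrixType == "serum") temperature <- "RT"
    sel <- sel & cd$temperature == temperature
    if (!any(sel)) stop("no samples match the requested condition")
    sub <- assay[, sel]
    spec <- designSpec(matrixType, fixed = c("individual", "time"))
    X <- buildDesign(SummarizedExperiment::colData(sub), spec)
    cv <- numeric(ncol(X))
    cv[colnames(X) == "time_h"] <- hours
    cname <- sprintf("time%g_vs_0", hours)
    fit <- fitLinearEbayes(sub, X, contrasts = stats::setNames(list(cv),
                                                               cname))
    deriveQualitySignature(fit, cname,
                           sprintf("%s_%s_%gh", matrixType, temperature,
                                   hours), k = k)
}

#' Read signatures from a TSV file
#'
#' Expected columns: `signature`, `feature_id`, `weight` (tab-separated,
#' `#` comment lines allowed). Optional `source` and `provenance` columns are
#' honoured; `source` defaults to `"derived_quality"`.
#'
#' @param path file path.
#' @return named list of [OmicsSignature-class] objects.
#' @export
loadSignatures <- function(path) {
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("signature", "feature_id", "weight")
    if (!all(need %in% colnames(tab)))
        stop("signature file must have columns: ",
             paste(need, collapse = ", "))
    w <- suppressWarnings(as.numeric(tab$weight))
    if (anyNA(w))
        stop("non-numeric weight in rows: ",
             paste(utils::head(which(is.na(w)), 5), collapse = ", "))
    tab$weight <- w
    if (anyDuplicated(tab[, c("signature", "feature_id")]))
        stop("duplicate (signature, feature_id) rows")
    sigs <- lapply(split(tab, tab$signature), function(d) {
        src <- if ("source" %in% colnames(d)) d$source[1] else
            "derived_quality"
        prov <- if ("provenance" %in% colnames(d)) d$provenance[1] else
            NA_character_
        OmicsSignature(d$signature[1],
                       stats::setNames(d$weight, d$feature_id),
                       source = src, provenance = prov)
    })
    sigs[unique(tab$signature)]
}

#' Write signatures to a TSV file
#'
#' @param signatures a list of [OmicsSignature-class] objects (or a single
#'   one).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSignatures <- function(signatures, path) {
    if (is(signatures, "OmicsSignature")) signatures <- list(signatures)
    tab <- do.call(rbind, lapply(signatures, function(s)
        data.frame(signature = s@name, feature_id = names(s@weights),
                   weight = s@weights, source = s@source,
                   provenance = s@provenance, row.names = NULL)))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Bundled blood-cell contamination signatures
#'
#' Returns the packaged erythrocyte, platelet and coagulation panels used to
#' score blood-cell contamination of plasma/serum proteomes. Erythrocyte and
#' platelet members carry unit weights (+1); the coagulation panel is signed
#' (platelet-released factors such as PPBP and THBS1 increase on coagulation,
#' clotting-consumed factors such as F13A1 and the fibrinogens decrease).
#' Beyond the literature-named driver proteins (CAT, CA2, BLVRB, PRDX2,
#' ALDOA; PPBP, THBS1, F13A1) the bundled membership is a curated synthetic
#' stand-in for externally published panels and is fully user-replaceable via
#' [loadSignatures()].
#'
#' @return named list of three [OmicsSignature-class] objects:
#'   `erythrocyte`, `platelet`, `coagulation`.
#' @examples
#' bundledContaminationSignatures()[["erythrocyte"]]
#' @export
bundledContaminationSignatures <- function() {
    path <- system.file("extdata", "contamination_signatures_synthetic.tsv",
                        package = "omiqc", mustWork = TRUE)
    loadSignatures(path)
}
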