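## Preprocessing: detection-limit filtering, variance stabilization by a
## median-ratio-scaled generalized log, and deterministic left-censored
## imputation. Stages advance raw -> transformed -> imputed.

.advanceStage <- function(assay, to) {
    from <- assay@stage
    ok <- switch(to,
        transformed = from == "raw",
        imputed = from == "transformed",
        scaled = from == "imputed",
        FALSE)
    if (!ok)
        stop(sprintf("illegal stage transition %s -> %s", from, to))
    assay@stage <- to
    assay
}

#' Remove low-abundance features by the detection-limit rule
#'
#' A feature is retained iff the fraction of samples in which it is reliably
#' quantified exceeds `minFrac`. A cell qualifies when its value is above
#' 10 x LOD or at/above the LLOQ (a disjunction; either limit may be absent).
#' Features without any limit fall back to a completeness rule: the fraction
#' of non-missing cells must exceed `minFrac`.
#'
#' @param assay a raw [OmicsAssay-class].
#' @param limits `data.frame`/`DataFrame` with columns `feature_id`, `lod`,
#'   `lloq` (either limit may be `NA`). Defaults to the limits stored in
#'   `metadata(assay)$detectionLimits`, if any; with no limits at all the
#'   completeness rule applies everywhere.
#' @param minFrac retention threshold, in (0, 1]; the qualifying fraction
#'   must be strictly greater. Default 0.66.
#' @return a list with `assay` (filtered, still stage `raw`) and `report`
#'   (`data.frame` of all features: `feature_id`, `qualifying_fraction`,
#'   `retained`, `rule`).
#' @examples
#' m <- matrix(c(100, 100, 100, 1, 1, 100), 2, 3, byrow = TRUE,
#'             dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
#' lims <- data.frame(feature_id = c("f1", "f2"), lod = 1, lloq = NA)
#' filterLowAbundance(OmicsAssay(m), lims)$report
#' @export
filterLowAbundance <- function(assay, limits = NULL, minFrac = 0.66) {
    stopifnot(is(assay, "OmicsAssay"))
    if (!identical(assay@stage, "raw"))
        stop("filterLowAbundance expects a raw matrix")
    if (minFrac <= 0 || minFrac > 1)
        stop("'minFrac' must lie in (0, 1]")
    if (is.null(limits))
        limits <- S4Vectors::metadata(assay)$detectionLimits
    v <- SummarizedExperiment::assay(assay)
    lod <- lloq <- rep(NA_real_, nrow(v))
    if (!is.null(limits)) {
        limits <- as.data.frame(limits)
        idx <- match(rownames(v), limits$feature_id)
        lod <- limits$lod[idx]
        if ("lloq" %in% colnames(limits)) lloq <- limits$lloq[idx]
    }
    hasLimit <- !is.na(lod) | !is.na(lloq)
    qual <- matrix(FALSE, nrow(v), ncol(v))
    obs <- !is.na(v)
    okLod <- !is.na(lod)
    qual[okLod, ] <- obs[okLod, , drop = FALSE] &
        v[okLod, , drop = FALSE] > 10 * lod[okLod]
    okLloq <- !is.na(lloq)
    qual[okLloq, ] <- qual[okLloq, , drop = FALSE] |
        (obs[okLloq, , drop = FALSE] & v[okLloq, , drop = FALSE] >= lloq[okLloq])
    frac <- ifelse(hasLimit, rowMeans(qual, na.rm = FALSE), rowMeans(obs))
    keep <- frac > minFrac
    report <- data.frame(feature_id = rownames(v),
                         qualifying_fraction = frac, retained = keep,
                         rule = ifelse(hasLimit, "detection_limit",
                                       "completeness"),
                         row.names = NULL)
    list(assay = assay[keep, ], report = report)
}

#' Generalized log2 transform
#'
#' `glog2(x; c) = log2((x + sqrt(x^2 + c^2)) / 2)`; behaves like `log2` for
#' `x >> c` and is linear near zero, so variance is approximately stabilized
#' across the intensity range. With `c = 0` it reduces to `log2`.
#'
#' @param x non-negative numeric values.
#' @param c non-negative calibration constant.
#' @return transformed values, same shape as `x`.
#' @examples
#' glog2(8, 0)   # 3
#' glog2(3, 4)   # 2
#' @export
glog2 <- function(x, c = 0) {
    log2((x + sqrt(x^2 + c^2)) / 2)
}

#' Variance-stabilizing transform of a raw matrix
#'
#' Two deterministic steps. (1) Per-sample scaling: each sample is divided by
#' `s_j`, the median over complete features of `x_gj / ref_g`, where `ref` is
#' the geometric-mean profile over samples (the usual median-of-ratios size
#' factor). (2) A generalized log2 with a dataset-level constant `c` set to
#' the 5th percentile of the scaled non-missing values, which stabilizes
#' variance at low intensities. Missing cells stay missing; the transform is
#' strictly increasing within each sample, so ranks are preserved.
#'
#' @param assay a raw [OmicsAssay-class] (values >= 0 or `NA`).
#' @return the transformed [OmicsAssay-class] (stage `transformed`), with the
#'   calibration recorded in `metadata(x)$glog` (`c`, per-sample factors).
#' @examples
#' m <- matrix(2^abs(rnorm(20, 6)), 4, 5,
#'             dimnames = list(paste0("f", 1:4), paste0("s", 1:5)))
#' glogTransform(OmicsAssay(m))
#' @export
glogTransform <- function(assay) {
    stopifnot(is(assay, "OmicsAssay"))
    v <- SummarizedExperiment::assay(assay)
    if (any(v < 0, na.rm = TRUE))
        stop("negative values cannot be glog-transformed")
    allMiss <- rowSums(!is.na(v)) == 0L
    if (any(allMiss))
        warning(sum(allMiss), " all-missing feature(s) kept untouched")
    # median-of-ratios size factors over each sample's observed features;
    # the reference is the feature-wise geometric mean of observed,
    # positive values, so the estimate is dominated by the stable majority
    # of the panel rather than any censoring-biased complete subset
    lv <- log(v)
    lv[!is.finite(lv)] <- NA
    ref <- exp(rowMeans(lv, na.rm = TRUE))
    usable <- is.finite(ref) & ref > 0
    sizeFactors <- apply(v[usable, , drop = FALSE] / ref[usable], 2,
                         stats::median, na.rm = TRUE)
    sizeFactors[!is.finite(sizeFactors) | sizeFactors <= 0] <- 1
    scaled <- sweep(v, 2, sizeFactors, "/")
    cc <- stats::quantile(scaled, probs = 0.05, na.rm = TRUE, names = FALSE)
    out <- glog2(scaled, cc)
    SummarizedExperiment::assay(assay) <- out
    S4Vectors::metadata(assay)$glog <- list(c = cc, sizeFactors = sizeFactors)
    .advanceStage(assay, "transformed")
}

#' Deterministic left-censored imputation (minimum-quantile)
#'
#' Each missing cell of sample `j` is replaced by the `q`-quantile
#' (linear interpolation between order statistics, the default quantile
#' convention) of the observed values of that sample -- the standard
#' "MinDet"-style assumption that missingness is left-censoring at the
#' detection limit.
#'
#' @param assay a transformed [OmicsAssay-class].
#' @param q quantile used for the deterministic minimum, default 0.01.
#' @return imputed [OmicsAssay-class] (stage `imputed`), no missing values.
#' @examples
#' m <- matrix(c(1, 2, NA, 4), 2, 2,
#'             dimnames = list(c("f1", "f2"), c("s1", "s2")))
#' a <- OmicsAssay(m, stage = "raw")
#' imputeMinDet(glogTransform(a))
#' @export
imputeMinDet <- function(assay, q = 0.01) {
    stopifnot(is(assay, "OmicsAssay"))
    if (!identical(assay@stage, "transformed"))
        stop("imputeMinDet expects a transformed matrix")
    if (q < 0 || q > 1) stop("'q' must lie in [0, 1]")
    v <- SummarizedExperiment::assay(assay)
    nObs <- colSums(!is.na(v))
    if (any(nObs == 0L))
        stop("sample(s) with no observed values: ",
             paste(colnames(v)[nObs == 0L], collapse = ", "))
    for (j in which(colSums(is.na(v)) > 0L)) {
        fill <- stats::quantile(v[, j], probs = q, na.rm = TRUE,
                                names = FALSE)
        v[is.na(v[, j]), j] <- fill
    }
    SummarizedExperiment::assay(assay) <- v
    .advanceStage(assay, "imputed")
}

#' Average technical duplicate samples
#'
#' Collapses columns that share a group label (e.g. duplicate injections of
#' the same sample) to their per-feature mean, ignoring missing values.
#'
#' @param assay an [OmicsAssay-class].
#' @param groups character vector, one label per column; columns with the
#'   same label are averaged. The first column's metadata represents each
#'   group.
#' @return an [OmicsAssay-class] with one column per group, same stage.
#' @export
collapseReplicates <- function(assay, groups) {
    stopifnot(is(assay, "OmicsAssay"), length(groups) == ncol(assay))
    v <- SummarizedExperiment::assay(assay)
    keys <- unique(groups)
    out <- vapply(keys, function(k)
        rowMeans(v[, groups == k, drop = FALSE], na.rm = TRUE),
        numeric(nrow(v)))
    out[is.nan(out)] <- NA
    colnames(out) <- keys
    cd <- SummarizedExperiment::colData(assay)[match(keys, groups), ,
                                               drop = FALSE]
    rownames(cd) <- keys
    OmicsAssay(out, colData = cd, stage = assay@stage,
               metadata = S4Vectors::metadata(assay))
}
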