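## Signature enrichment scoring.
##
## Raw score of signature S in sample j: sum_i w_i x_ij / sum_i |w_i| over
## members present in the measured universe. The empirical null permutes the
## sample's values across the full measured universe (weights stay on the
## signature's slots) and the normalized enrichment score is
## NES = (raw - null_mean) / null_sd, i.e. standard deviations away from the
## permutation null.

#' Scale each feature relative to the cohort
#'
#' Per feature: subtract the mean and divide by the sample SD across
#' samples, so every measurement is expressed relative to the other samples
#' of the cohort. Constant features become all-zero with a warning.
#'
#' @param assay an imputed [OmicsAssay-class] with at least 2 samples.
#' @return the scaled [OmicsAssay-class] (stage `scaled`).
#' @examples
#' m <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
#'             dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
#' a <- OmicsAssay(m, stage = "raw")
#' a@stage <- "imputed"
#' suppressWarnings(SummarizedExperiment::assay(scalePerFeature(a)))
#' @export
scalePerFeature <- function(assay) {
    stopifnot(is(assay, "OmicsAssay"))
    v <- SummarizedExperiment::assay(assay)
    if (ncol(v) < 2L)
        stop("per-feature scaling needs at least 2 samples")
    mu <- rowMeans(v)
    sdv <- apply(v, 1, stats::sd)
    const <- sdv < .Machine$double.eps
    if (any(const)) {
        warning(sum(const), " constant feature(s) set to zero")
        sdv[const] <- 1
    }
    out <- (v - mu) / sdv
    out[const, ] <- 0
    SummarizedExperiment::assay(assay) <- out
    .advanceStage(assay, "scaled")
}

#' Weighted-mean signature score of one sample profile
#'
#' `score = sum(w_i * x_i) / sum(|w_i|)` over the intersection of signature
#' members and measured features.
#'
#' @param profile named numeric vector of (scaled) feature values.
#' @param signature an [OmicsSignature-class].
#' @param minOverlap minimum number of signature members that must be
#'   measured (default 3); smaller overlaps are noise-dominated and raise an
#'   error.
#' @return a list: `score`, `nOverlap`, `unmeasured` (signature features
#'   absent from the profile).
#' @examples
#' prof <- c(f1 = 2, f2 = -1, f3 = 0)
#' sig <- OmicsSignature("demo", c(f1 = 1, f2 = -2, f3 = 0.5))
#' wmeanScore(prof, sig)$score
#' @export
wmeanScore <- function(profile, signature, minOverlap = 3) {
    stopifnot(is(signature, "OmicsSignature"))
    w <- signature@weights
    present <- names(w) %in% names(profile)
    if (sum(present) == 0L)
        stop("signature has no overlap with the measured features")
    if (sum(present) < minOverlap)
        stop(sprintf("overlap %d below minOverlap = %d", sum(present),
                     minOverlap))
    wp <- w[present]
    if (all(wp == 0))
        stop("all overlapping weights are zero")
    x <- profile[names(wp)]
    list(score = sum(wp * x) / sum(abs(wp)),
         nOverlap = sum(present), unmeasured = names(w)[!present])
}

#' Normalized enrichment scores with a permutation null
#'
#' For every sample and signature, builds an empirical null by `nPerm`
#' random permutations of the sample's values across the full measured
#' feature universe (the signature's weights stay fixed), recomputing the
#' raw weighted-mean score each time, and reports
#' `NES = (raw - null_mean) / null_sd`. The same permutation index set is
#' shared across samples, which leaves each sample's marginal null unchanged
#' and makes the computation deterministic and fast. A zero null SD (e.g.
#' when the universe equals a uniform-weight signature) yields a missing NES
#' with a warning.
#'
#' @param assay a scaled [OmicsAssay-class] (see [scalePerFeature()]); an
#'   unscaled stage is accepted with a warning.
#' @param signatures list of [OmicsSignature-class] objects (or a single
#'   one).
#' @param nPerm number of permutations (>= 100), default 1000.
#' @param seed integer seed making the null reproducible.
#' @param minOverlap minimum measured overlap per signature.
#' @return a [ScoreTable-class].
#' @examples
#' m <- matrix(rnorm(300), 30, 10,
#'             dimnames = list(paste0("f", 1:30), paste0("s", 1:10)))
#' sig <- OmicsSignature("demo", setNames(rep(1, 5), paste0("f", 1:5)))
#' nesScores(m, sig, nPerm = 200, seed = 1)
#' @export
nesScores <- function(assay, signatures, nPerm = 1000, seed = NULL,
                      minOverlap = 3) {
    if (is(signatures, "OmicsSignature"))
        signatures <- stats::setNames(list(signatures), signatures@name)
    if (nPerm < 100) stop("nPerm must be >= 100")
    X <- if (is(assay, "OmicsAssay")) {
        if (!identical(assay@stage, "scaled"))
            warning("scoring an unscaled matrix; consider scalePerFeature()")
        SummarizedExperiment::assay(assay)
    } else assay
    if (anyNA(X)) stop("matrix contains missing values")
    nFeat <- nrow(X)
    res <- .runWithSeed(seed, {
        lapply(signatures, function(sig) {
            w <- sig@weights
            present <- names(w) %in% rownames(X)
            if (sum(present) < minOverlap)
                stop(sprintf("signature '%s': overlap %d below minOverlap",
                             sig@name, sum(present)))
            wp <- w[present]
            if (all(wp == 0))
                stop(sprintf("signature '%s': all overlapping weights zero",
                             sig@name))
            m <- length(wp)
            denom <- sum(abs(wp))
            raw <- drop(crossprod(X[names(wp), , drop = FALSE], wp)) / denom
            null <- matrix(0, nPerm, ncol(X))
            for (k in seq_len(nPerm)) {
                idx <- sample.int(nFeat, m)
                null[k, ] <- crossprod(X[idx, , drop = FALSE], wp) / denom
            }
            nullMean <- colMeans(null)
            nullSd <- apply(null, 2, stats::sd)
            zero <- nullSd < .Machine$double.eps
            if (any(zero))
                warning(sprintf(
                    "signature '%s': null SD is zero for %d sample(s); NES set missing",
                    sig@name, sum(zero)))
            nes <- ifelse(zero, NA_real_, (raw - nullMean) / nullSd)
            S4Vectors::DataFrame(sample_id = colnames(X),
                                 signature = sig@name, raw_score = raw,
                                 null_mean = nullMean, null_sd = nullSd,
                                 nes = nes)
        })
    })
    new("ScoreTable", table = do.call(rbind, unname(res)),
        nPerm = as.integer(nPerm),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Average NES per condition group
#'
#' @param scores a [ScoreTable-class].
#' @param metadata per-sample metadata with a `sample_id` column (e.g. the
#'   `colData` of the scored assay).
#' @param keys metadata columns defining the groups, default
#'   `c("matrix", "temperature", "time_h")`.
#' @return `data.frame` with the key columns, `signature`, `mean_nes` and
#'   group size `n`; empty groups are an error.
#' @export
groupAverage <- function(scores, metadata,
                         keys = c("matrix", "temperature", "time_h")) {
    stopifnot(is(scores, "ScoreTable"))
    metadata <- as.data.frame(metadata)
    if (!all(keys %in% colnames(metadata)))
        stop("metadata lacks key column(s): ",
             paste(setdiff(keys, colnames(metadata)), collapse = ", "))
    tab <- as.data.frame(scores@table)
    idx <- match(tab$sample_id, metadata$sample_id)
    if (anyNA(idx))
        stop("samples missing from metadata: ",
             paste(utils::head(tab$sample_id[is.na(idx)], 5), collapse = ", "))
    for (k in keys) tab[[k]] <- metadata[[k]][idx]
    agg <- stats::aggregate(tab["nes"], by = tab[c(keys, "signature")],
                            FUN = mean)
    names(agg)[names(agg) == "nes"] <- "mean_nes"
    cnt <- stats::aggregate(list(n = tab$nes), by = tab[c(keys, "signature")],
                            FUN = length)
    merge(agg, cnt, by = c(keys, "signature"))
}

#' NES relative to designated reference samples
#'
#' Cohort-relative scores are easiest to read against samples of known
#' quality: this reports, per signature, each sample's NES minus the mean
#' NES of the reference samples.
#'
#' @param scores a [ScoreTable-class].
#' @param referenceSamples character vector of sample ids of known quality.
#' @return `data.frame` with `sample_id`, `signature`, `nes`, `delta_nes`.
#' @export
referenceDeltaNes <- function(scores, referenceSamples) {
    stopifnot(is(scores, "ScoreTable"))
    tab <- as.data.frame(scores@table)
    if (!all(referenceSamples %in% tab$sample_id))
        stop("unknown reference sample(s): ",
             paste(setdiff(referenceSamples, tab$sample_id), collapse = ", "))
    refMean <- tapply(tab$nes[tab$sample_id %in% referenceSamples],
                      tab$signature[tab$sample_id %in% referenceSamples],
                      mean, na.rm = TRUE)
    tab$delta_nes <- tab$nes - refMean[tab$signature]
    tab[, c("sample_id", "signature", "nes", "delta_nes")]
}
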