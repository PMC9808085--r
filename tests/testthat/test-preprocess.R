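test_that("detection-limit filter matches brute-force rule application", {
    # 5 features x 6 samples with hand-set values and limits
    v <- matrix(c(
        100, 100, 100, 100, 100, 100,   # all above 10*LOD (LOD = 1)
        100, 100, 100,   5,   5,   5,   # 3/6 qualify -> 0.5 <= 0.66: drop
        5,     5,   5,  80,  80,  80,   # qualifies via LLOQ in 3/6: drop
        100, 100, 100, 100,  90,   5,   # 5/6 = 0.83 > 0.66: keep
        NA,   NA,  NA,  NA, 100, 100),  # no limits: completeness 2/6: drop
        nrow = 5, byrow = TRUE,
        dimnames = list(paste0("f", 1:5), paste0("s", 1:6)))
    limits <- data.frame(feature_id = paste0("f", 1:4),
                         lod = c(1, 1, NA, 1), lloq = c(NA, NA, 50, NA))
    res <- filterLowAbundance(OmicsAssay(v), limits, minFrac = 0.66)

    # independent oracle: enumerate the qualifying rule cell by cell
    qualifies <- function(x, lod, lloq)
        (!is.na(x)) & ((!is.na(lod) & x > 10 * lod) |
                       (!is.na(lloq) & x >= lloq))
    fr <- vapply(1:4, function(i)
        mean(qualifies(v[i, ], limits$lod[i], limits$lloq[i])), numeric(1))
    fr <- c(fr, mean(!is.na(v[5, ])))
    expect_equal(res$report$qualifying_fraction, fr)
    expect_identical(rownames(res$assay), paste0("f", c(1, 4)))
    expect_identical(res$report$rule,
                     c(rep("detection_limit", 4), "completeness"))
})

test_that("the filter is idempotent and validates minFrac", {
    sim <- smallCohort(seed = 2)
    once <- filterLowAbundance(sim$metabolome)
    twice <- filterLowAbundance(once$assay)
    expect_identical(SummarizedExperiment::assay(once$assay),
                     SummarizedExperiment::assay(twice$assay))
    expect_error(filterLowAbundance(sim$metabolome, minFrac = 0), "minFrac")
    expect_error(filterLowAbundance(sim$metabolome, minFrac = 1.2),
                 "minFrac")
})

test_that("glog2 closed forms hold", {
    expect_equal(glog2(8, 0), 3)
    expect_equal(glog2(3, 4), 2)  # log2((3 + 5) / 2)
})

test_that("glog transform preserves ranks, missingness and rejects negatives", {
    sim <- smallCohort(seed = 9)
    raw <- sim$metabolome
    tr <- glogTransform(raw)
    expect_identical(stage(tr), "transformed")
    vr <- SummarizedExperiment::assay(raw)
    vt <- SummarizedExperiment::assay(tr)
    expect_identical(is.na(vr), is.na(vt))
    for (j in c(1, 10, 25)) {
        ok <- !is.na(vr[, j])
        expect_identical(rank(vr[ok, j]), rank(vt[ok, j]))
    }
    neg <- matrix(c(-1, 2, 3, 4), 2, 2,
                  dimnames = list(c("f1", "f2"), c("s1", "s2")))
    expect_error(glogTransform(toyAssay(neg, "raw")), "negative")
    am <- matrix(c(NA, NA, 3, 4), 2, 2, byrow = TRUE,
                 dimnames = list(c("f1", "f2"), c("s1", "s2")))
    expect_warning(glogTransform(OmicsAssay(am)), "all-missing")
})

test_that("glog transform stabilizes variance against the mean", {
    # multiplicative + additive noise: SD grows with the mean before the
    # transform; afterwards the trend should shrink to <= 20% of its size
    set.seed(4)
    nGene <- 300; nSamp <- 30
    mu <- sort(2^runif(nGene, 5, 12))
    raw <- vapply(seq_len(nSamp), function(j)
        mu * 2^rnorm(nGene, 0, 0.2) + abs(rnorm(nGene, 0, 10)),
        numeric(nGene))
    dimnames(raw) <- list(sprintf("f%03d", 1:nGene), paste0("s", 1:nSamp))
    a <- OmicsAssay(raw)
    tr <- glogTransform(a)
    slopeOf <- function(m) {
        sds <- apply(m, 1, sd)
        rk <- rank(rowMeans(m))
        unname(coef(lm(sds ~ rk))[2] * nGene / mean(sds))  # relative trend
    }
    before <- slopeOf(raw)
    after <- slopeOf(SummarizedExperiment::assay(tr))
    expect_lt(abs(after), 0.2 * abs(before))
})

test_that("MinDet imputation is the per-sample low quantile", {
    # sample s1 observes exactly {10, 20, ..., 100}; its missing cell gets
    # the interpolated 1% quantile, 10 + 0.09 * (20 - 10) = 10.9 (frozen
    # from the linear-interpolation order-statistic convention)
    v <- cbind(s1 = c(NA, seq(10, 100, 10)),
               s2 = c(seq(10, 100, 10), NA))
    rownames(v) <- sprintf("f%02d", 1:11)
    imp <- imputeMinDet(toyAssay(v, "transformed"), q = 0.01)
    expect_identical(stage(imp), "imputed")
    out <- SummarizedExperiment::assay(imp)
    expect_equal(out["f01", "s1"], 10.9)
    expect_equal(out["f11", "s2"],
                 unname(quantile(seq(10, 100, 10), 0.01)))  # same oracle
    expect_false(anyNA(out))
})

test_that("imputation is identity without missing values and errors on empty samples", {
    v <- matrix(rnorm(20), 4, 5,
                dimnames = list(paste0("f", 1:4), paste0("s", 1:5)))
    a <- toyAssay(v, "transformed")
    expect_identical(SummarizedExperiment::assay(imputeMinDet(a)), v)
    v[, 3] <- NA
    expect_error(imputeMinDet(toyAssay(v, "transformed")), "s3")
    # imputed values never undercut the sample minimum
    sim <- smallCohort(seed = 6)
    imp <- imputeMinDet(glogTransform(sim$metabolome))
    vi <- SummarizedExperiment::assay(imp)
    vt <- SummarizedExperiment::assay(glogTransform(sim$metabolome))
    for (j in seq_len(ncol(vi))) {
        filled <- is.na(vt[, j])
        if (any(filled))
            expect_true(all(vi[filled, j] >= min(vt[, j], na.rm = TRUE)))
    }
    expect_false(anyNA(vi))
})

test_that("stage transitions are enforced in order", {
    v <- matrix(1:4 + 0, 2, 2,
                dimnames = list(c("f1", "f2"), c("s1", "s2")))
    raw <- OmicsAssay(v)
    expect_error(imputeMinDet(raw), "transformed")
    expect_error(scalePerFeature(raw), "stage|imputed|scaled")
    tr <- glogTransform(raw)
    expect_error(glogTransform(tr), class = "simpleError")
})

test_that("technical duplicates are averaged per feature", {
    v <- matrix(c(1, 3, 5, NA, 2, 4), 2, 3,
                dimnames = list(c("f1", "f2"), c("a1", "a2", "b1")))
    a <- OmicsAssay(v)
    out <- collapseReplicates(a, c("a", "a", "b"))
    expect_equal(SummarizedExperiment::assay(out),
                 matrix(c(3, 3, 2, 4), 2, 2,
                        dimnames = list(c("f1", "f2"), c("a", "b"))))
})
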