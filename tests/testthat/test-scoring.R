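scaledToy <- function(values) toyAssay(values, "scaled")

test_that("per-feature scaling centres and standardizes against the cohort", {
    v <- rbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5))
    colnames(v) <- paste0("s", 1:3)
    expect_warning(sc <- scalePerFeature(toyAssay(v, "imputed")),
                   "constant")
    out <- SummarizedExperiment::assay(sc)
    expect_equal(out["f1", ], c(s1 = -1, s2 = 0, s3 = 1))
    expect_equal(out["f2", ], c(s1 = 0, s2 = 0, s3 = 0))
    expect_identical(stage(sc), "scaled")
    expect_error(scalePerFeature(toyAssay(v[, 1, drop = FALSE], "imputed")),
                 "2 samples")
    # contract on a larger matrix: mean 0, SD 1 per non-constant feature
    set.seed(2)
    m <- matrix(rnorm(200), 20, 10,
                dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
    z <- SummarizedExperiment::assay(scalePerFeature(toyAssay(m, "imputed")))
    expect_equal(unname(rowMeans(z)), rep(0, 20), tolerance = 1e-10)
    expect_equal(unname(apply(z, 1, sd)), rep(1, 20), tolerance = 1e-10)
})

test_that("weighted-mean score follows its closed form", {
    sig <- OmicsSignature("w", c(f1 = 1, f2 = -2))
    prof <- c(f1 = 2, f2 = -1, f3 = 99)
    expect_equal(wmeanScore(prof, sig, minOverlap = 2)$score, 4 / 3)
    # all weights one -> plain mean of the member values
    sigu <- OmicsSignature("u", c(f1 = 1, f2 = 1, f3 = 1))
    expect_equal(wmeanScore(prof, sigu)$score, mean(prof))
    expect_error(wmeanScore(prof, sig, minOverlap = 3), "overlap")
    expect_error(wmeanScore(c(f9 = 1), sig, minOverlap = 1), "no overlap")
    sigz <- OmicsSignature("z", c(f1 = 0, f2 = 0, f4 = 1))
    expect_error(wmeanScore(prof, sigz, minOverlap = 2), "zero")
    expect_identical(wmeanScore(prof, sig, minOverlap = 2)$unmeasured,
                     character(0))
})

test_that("NES is deterministic given a seed and normalizes the raw score", {
    set.seed(10)
    m <- matrix(rnorm(40 * 8), 40, 8,
                dimnames = list(paste0("f", 1:40), paste0("s", 1:8)))
    sig <- OmicsSignature("s", setNames(c(2, 1, -1, 1, 0.5),
                                        paste0("f", 1:5)))
    a <- nesScores(scaledToy(m), sig, nPerm = 300, seed = 4)
    b <- nesScores(scaledToy(m), sig, nPerm = 300, seed = 4)
    expect_identical(scoreTable(a), scoreTable(b))
    tab <- as.data.frame(scoreTable(a))
    expect_equal(tab$nes, (tab$raw_score - tab$null_mean) / tab$null_sd)
    expect_equal(nrow(tab), 8)
})

test_that("NES is invariant to positive weight rescaling and flips with sign", {
    set.seed(11)
    m <- matrix(rnorm(40 * 6), 40, 6,
                dimnames = list(paste0("f", 1:40), paste0("s", 1:6)))
    w <- setNames(c(2, 1, -1, 1), paste0("f", 1:4))
    a <- nesScores(scaledToy(m), OmicsSignature("a", w), nPerm = 200,
                   seed = 6)
    b <- nesScores(scaledToy(m), OmicsSignature("b", 3 * w), nPerm = 200,
                   seed = 6)
    d <- nesScores(scaledToy(m), OmicsSignature("d", -w), nPerm = 200,
                   seed = 6)
    expect_equal(scoreTable(a)$raw_score, scoreTable(b)$raw_score)
    expect_equal(scoreTable(a)$nes, scoreTable(b)$nes)
    expect_equal(scoreTable(a)$raw_score, -scoreTable(d)$raw_score)
    expect_equal(scoreTable(a)$nes, -scoreTable(d)$nes)
})

test_that("a degenerate null (universe = uniform signature) yields missing NES", {
    m <- matrix(c(1, 2, 5, 7), 2, 2,
                dimnames = list(c("f1", "f2"), c("s1", "s2")))
    sig <- OmicsSignature("all", c(f1 = 1, f2 = 1))
    expect_warning(sc <- nesScores(scaledToy(m), sig, nPerm = 100,
                                   seed = 1, minOverlap = 2),
                   "null SD is zero")
    expect_true(all(is.na(scoreTable(sc)$nes)))
    expect_error(nesScores(scaledToy(m), sig, nPerm = 10), "nPerm")
})

test_that("sampled null converges to the exhaustive null on a tiny universe", {
    x <- c(3, 1, 4, 1.5, 9)
    m <- matrix(x, 5, 1, dimnames = list(paste0("f", 1:5), "s1"))
    sig <- OmicsSignature("pair", c(f1 = 1, f2 = 1))
    sc <- nesScores(scaledToy(m), sig, nPerm = 5000, seed = 3,
                    minOverlap = 2)
    # oracle: all 10 unordered 2-subsets of the universe values
    draws <- combn(x, 2, mean)
    exMean <- mean(draws)
    exSd <- sqrt(mean((draws - exMean)^2))
    tab <- as.data.frame(scoreTable(sc))
    expect_equal(tab$null_mean, exMean, tolerance = 0.05)
    expect_equal(tab$null_sd, exSd, tolerance = 0.05)
})

test_that("group averaging reduces correctly and validates keys", {
    tab <- S4Vectors::DataFrame(
        sample_id = c("a", "b", "c"), signature = "sig",
        raw_score = 0, null_mean = 0, null_sd = 1,
        nes = c(1, 3, 7))
    sc <- new("ScoreTable", table = tab, nPerm = 100L, seed = 1L)
    md <- data.frame(sample_id = c("a", "b", "c"),
                     matrix = c("plasma", "plasma", "serum"),
                     temperature = "RT", time_h = 8)
    ga <- groupAverage(sc, md)
    expect_equal(ga$mean_nes[ga$matrix == "plasma"], 2)  # (1 + 3) / 2
    expect_equal(ga$mean_nes[ga$matrix == "serum"], 7)   # single sample
    expect_equal(ga$n, c(2, 1))
    expect_error(groupAverage(sc, md, keys = "nope"), "key column")
    expect_error(groupAverage(sc, md[1:2, ]), "missing from metadata")
})

test_that("reference samples anchor the NES scale", {
    tab <- S4Vectors::DataFrame(
        sample_id = c("r1", "r2", "x"), signature = "sig",
        raw_score = 0, null_mean = 0, null_sd = 1, nes = c(1, 3, 5))
    sc <- new("ScoreTable", table = tab, nPerm = 100L, seed = 1L)
    out <- referenceDeltaNes(sc, c("r1", "r2"))
    expect_equal(out$delta_nes[out$sample_id == "x"], 3)  # 5 - mean(1, 3)
    expect_error(referenceDeltaNes(sc, "zz"), "unknown reference")
})
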