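test_that("design matrices encode the requested terms", {
    md <- data.frame(individual = rep(1:6, 8),
                     time_h = rep(rep(c(0, 2, 4, 8), each = 6), 2),
                     temperature = rep(c("4C", "RT"), each = 24))
    X1 <- buildDesign(md, designSpec("plasma", fixed = "time"))
    expect_identical(colnames(X1), c("(Intercept)", "time_h"))
    X2 <- buildDesign(md, designSpec("plasma",
        fixed = c("time", "temperature", "time:temperature")))
    expect_equal(ncol(X2), 4)
    expect_true("time_h:temperatureRT" %in% colnames(X2))
    expect_error(designSpec("serum", fixed = c("time", "temperature")),
                 "single temperature")
    md1 <- md[md$temperature == "4C", ]
    expect_error(buildDesign(md1, designSpec("plasma",
        fixed = c("time", "temperature"))), "single level")
    expect_error(designSpec("plasma", fixed = "individual",
                            random = "individual"), "both fixed and random")
})

test_that("unmoderated fit reproduces hand-computed OLS", {
    y <- matrix(c(1, 2, 2, 3), 1, 4,
                dimnames = list("f1", paste0("s", 1:4)))
    X <- cbind(`(Intercept)` = 1, x = c(0, 0, 1, 1))
    res <- as.data.frame(stabilityTable(fitLinearEbayes(y, X, d0 = 0)))
    row <- res[res$factor == "x", ]
    expect_equal(row$estimate, 1)              # slope
    expect_equal(row$statistic, sqrt(2), tolerance = 1e-12)  # t = 1.414
    expect_equal(variancePrior(fitLinearEbayes(y, X, d0 = 0))[["d0"]], 0)
})

test_that("with d0 = 0 the moderated fit equals per-feature OLS t-tests", {
    set.seed(21)
    Y <- matrix(rnorm(30 * 10), 30, 10,
                dimnames = list(paste0("f", 1:30), paste0("s", 1:10)))
    x <- rep(0:1, each = 5)
    X <- cbind(`(Intercept)` = 1, x = x)
    mine <- as.data.frame(stabilityTable(fitLinearEbayes(Y, X, d0 = 0)))
    mine <- mine[mine$factor == "x", ]
    for (g in c(1, 13, 30)) {
        ref <- summary(lm(Y[g, ] ~ x))$coefficients["x", ]
        i <- match(rownames(Y)[g], mine$feature_id)
        expect_equal(mine$statistic[i], unname(ref["t value"]),
                     tolerance = 1e-10)
        expect_equal(mine$p[i], unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
    }
})

test_that("identical residual variances collapse to ordinary t", {
    # two features that are mirror images have exactly equal s2, so the
    # prior spread estimate is non-positive, d0 -> Inf and s2tilde = s2
    y1 <- c(1, 2, 2, 3, 5, 4)
    Y <- rbind(f1 = y1, f2 = -y1 + 10)
    colnames(Y) <- paste0("s", 1:6)
    X <- cbind(`(Intercept)` = 1, x = c(0, 0, 0, 1, 1, 1))
    fit <- fitLinearEbayes(Y, X)
    expect_true(is.infinite(variancePrior(fit)[["d0"]]))
    tab <- as.data.frame(stabilityTable(fit))
    ols <- summary(lm(y1 ~ X[, 2]))$coefficients[2, "t value"]
    expect_equal(tab$statistic[tab$factor == "x" & tab$feature_id == "f1"],
                 unname(ols), tolerance = 1e-10)
})

test_that("moderated statistics agree with the limma oracle", {
    skip_if_not_installed("limma")
    set.seed(8)
    Y <- matrix(rnorm(150 * 12), 150, 12,
                dimnames = list(paste0("f", 1:150), paste0("s", 1:12)))
    Y <- Y * rep(sqrt(rchisq(150, 4) / 4), 12)  # heterogeneous variances
    X <- cbind(`(Intercept)` = 1, x = rep(0:1, each = 6))
    mine <- fitLinearEbayes(Y, X)
    ref <- limma::eBayes(limma::lmFit(Y, X))
    expect_equal(variancePrior(mine)[["d0"]], ref$df.prior,
                 tolerance = 1e-6)
    expect_equal(variancePrior(mine)[["s02"]], ref$s2.prior,
                 tolerance = 1e-6)
    tab <- as.data.frame(stabilityTable(mine))
    tx <- tab[tab$factor == "x", ]
    idx <- match(rownames(Y), tx$feature_id)
    expect_equal(tx$statistic[idx], unname(ref$t[, "x"]), tolerance = 1e-8)
    expect_equal(tx$p[idx], unname(ref$p.value[, "x"]), tolerance = 1e-8)
})

test_that("null features give approximately uniform p-values", {
    set.seed(33)
    Y <- matrix(rnorm(1000 * 16), 1000, 16,
                dimnames = list(sprintf("f%04d", 1:1000),
                                paste0("s", 1:16)))
    X <- cbind(`(Intercept)` = 1, x = rep(c(0, 2, 4, 8), 4))
    tab <- as.data.frame(stabilityTable(fitLinearEbayes(Y, X)))
    p <- tab$p[tab$factor == "x"]
    ks <- suppressWarnings(ks.test(p, "punif"))
    expect_lt(unname(ks$statistic), 0.05)
})

test_that("degenerate (constant) features are flagged with missing p", {
    Y <- rbind(f1 = rnorm(8), f2 = rep(3, 8))
    colnames(Y) <- paste0("s", 1:8)
    X <- cbind(`(Intercept)` = 1, x = rep(0:1, 4))
    tab <- as.data.frame(stabilityTable(fitLinearEbayes(Y, X)))
    f2 <- tab[tab$feature_id == "f2", ]
    expect_true(all(f2$fit_flag == "degenerate"))
    expect_true(all(is.na(f2$p)))
})

test_that("BH adjustment matches the hand-derived examples and handles NA", {
    expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
                 rep(0.04, 4))
    expect_equal(benjaminiHochberg(c(0.005, 0.5)), c(0.01, 0.5))
    expect_equal(benjaminiHochberg(0.2), 0.2)
    # NA excluded from m and reinserted in place
    expect_equal(benjaminiHochberg(c(0.005, NA, 0.5)), c(0.01, NA, 0.5))
    expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH agrees with the brute-force step-up definition", {
    set.seed(14)
    for (i in 1:200) {
        p <- runif(sample(1:40, 1))^sample(1:3, 1)
        expect_equal(benjaminiHochberg(p), bruteForceBH(p),
                     tolerance = 1e-12)
    }
})

test_that("zero individual variance forces the fixed-effects fallback", {
    sim <- simulateCohort(simulationParams(
        nMetabolites = 15, nProteins = 25, sdIndividualMetab = 0,
        lodQuantile = 0, seed = 19))
    pl <- log2Assay(sim$metabolome[, sim$metadata$matrix == "plasma"])
    res <- fitMixedStability(pl)
    tab <- as.data.frame(stabilityTable(res))
    flags <- tapply(tab$fit_flag, tab$feature_id, function(x) x[1])
    # with a true zero variance the REML estimate sits on the boundary for
    # the clear majority of features (it stays positive by sampling noise
    # for the rest, which no boundary criterion can call singular)
    expect_gt(mean(flags == "anova_fallback"), 0.6)
})

test_that("mixed-model slope estimates are unbiased on serum data", {
    sim <- simulateCohort(simulationParams(
        nMetabolites = 150, nProteins = 25, deltaRange = c(0.1, 0.4),
        lodQuantile = 0, seed = 23))
    md <- as.data.frame(sim$metadata)
    serum <- log2Assay(sim$metabolome[, md$matrix == "serum"])
    tr <- as.data.frame(sim$truth@metabolites)
    aff <- tr$feature_id[tr$affected_serum]
    res <- fitMixedStability(serum[aff, ])
    tab <- as.data.frame(stabilityTable(res))
    est <- tab$estimate[tab$factor == "time_h"]
    names(est) <- tab$feature_id[tab$factor == "time_h"]
    err <- est[aff] - tr$delta_serum[match(aff, tr$feature_id)]
    se <- sd(err) / sqrt(length(err))
    expect_lt(abs(mean(err)), 3 * se + 1e-3)
    expect_true(all(tab$fit_flag %in% c("mixed", "anova_fallback")))
})

test_that("results are invariant to sample column order", {
    sim <- smallCohort(seed = 27, nMetabolites = 30)
    imp <- imputeMinDet(glogTransform(sim$metabolome))
    spec <- designSpec("plasma", fixed = c("individual", "time"))
    sub <- imp[, SummarizedExperiment::colData(imp)$matrix == "plasma"]
    X1 <- buildDesign(SummarizedExperiment::colData(sub), spec)
    r1 <- as.data.frame(stabilityTable(fitLinearEbayes(sub, X1)))
    sub2 <- sub[, rev(seq_len(ncol(sub)))]
    X2 <- buildDesign(SummarizedExperiment::colData(sub2), spec)
    r2 <- as.data.frame(stabilityTable(fitLinearEbayes(sub2, X2)))
    expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
    expect_equal(r1$p_adj, r2$p_adj, tolerance = 1e-10)
})

test_that("significant features are counted per factor", {
    tab <- S4Vectors::DataFrame(
        feature_id = paste0("f", 1:3), factor = "time_h",
        estimate = 1, statistic = 1, df = 3,
        p = c(0.001, 0.03, 0.02),
        p_adj = c(0.01, 0.06, 0.04), fit_flag = "ols")
    res <- new("StabilityResult", results = tab,
               prior = c(d0 = 1, s02 = 1), method = "ebayes")
    expect_equal(countSignificant(res, "time_h"), 2)
    expect_error(countSignificant(res, "nope"), "unknown factor")
    tab$p_adj <- NA_real_
    tab$p <- NA_real_
    res2 <- new("StabilityResult", results = tab,
                prior = c(d0 = 1, s02 = 1), method = "ebayes")
    expect_equal(countSignificant(res2, "time_h"), 0)
})
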