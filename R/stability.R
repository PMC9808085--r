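## Feature-wise stability statistics.
##
## Two entry points mirror the two classical analyses of pre-analytical
## stability data: fitLinearEbayes() fits per-feature fixed-effects models and
## shrinks residual variances toward a global prior (moderated t/F), used for
## the individual-effect test and for sitting-time contrasts that feed
## signature derivation; fitMixedStability() fits per-feature linear mixed
## models with a random intercept per individual (Satterthwaite df), falling
## back to a fixed-effects ANOVA when the mixed fit is singular.

#' Specify a stability design
#'
#' @param matrixType `"plasma"` or `"serum"`.
#' @param fixed fixed-effect terms, a subset of `"individual"`, `"time"`,
#'   `"temperature"`, `"time:temperature"`. Serum designs may not contain
#'   temperature terms (single level by design). Defaults: all four terms for
#'   plasma (drop `individual` when it is random), `individual` + `time` for
#'   serum.
#' @param random random-intercept terms, a subset of `"individual"`.
#' @return a `DesignSpec` object.
#' @examples
#' designSpec("plasma", fixed = c("time", "temperature", "time:temperature"),
#'            random = "individual")
#' @export
designSpec <- function(matrixType = c("plasma", "serum"), fixed = NULL,
                       random = character()) {
    matrixType <- match.arg(matrixType)
    if (is.null(fixed)) {
        fixed <- if (matrixType == "plasma")
            c("individual", "time", "temperature", "time:temperature")
        else c("individual", "time")
        fixed <- setdiff(fixed, random)
    }
    new("DesignSpec", matrixType = matrixType, fixed = fixed,
        random = random)
}

setClass("DesignSpec",
    slots = c(matrixType = "character", fixed = "character",
              random = "character"))

setValidity("DesignSpec", function(object) {
    allowed <- c("individual", "time", "temperature", "time:temperature")
    msg <- NULL
    if (!all(object@fixed %in% allowed))
        msg <- c(msg, paste("fixed terms must be a subset of:",
                            paste(allowed, collapse = ", ")))
    if (!all(object@random %in% "individual"))
        msg <- c(msg, "only 'individual' may be a random term")
    if (length(intersect(object@fixed, object@random)))
        msg <- c(msg, "a term may not be both fixed and random")
    if (object@matrixType == "serum" &&
        any(grepl("temperature", object@fixed)))
        msg <- c(msg, "serum designs have a single temperature level")
    if (is.null(msg)) TRUE else msg
})

.termToVar <- c(individual = "individual", time = "time_h",
                temperature = "temperature",
                "time:temperature" = "time_h:temperature")

#' Build a fixed-effects design matrix
#'
#' Time enters as numeric hours; temperature (reference `4C`) and individual
#' (reference: lowest id) as treatment-coded factors.
#'
#' @param metadata per-sample metadata (`data.frame`/`DataFrame`) with
#'   columns `individual`, `time_h`, `temperature` as needed by the spec.
#' @param spec a `DesignSpec` (see [designSpec()]); its `fixed` terms define
#'   the columns.
#' @return the model matrix, with attributes `assign` and `term_labels`
#'   mapping columns to terms.
#' @examples
#' md <- data.frame(individual = rep(1:2, each = 4),
#'                  time_h = rep(c(0, 2, 4, 8), 2),
#'                  temperature = "4C")
#' colnames(buildDesign(md, designSpec("serum", fixed = "time")))
#' @export
buildDesign <- function(metadata, spec) {
    validObject(spec)
    metadata <- as.data.frame(metadata)
    dat <- data.frame(row.names = seq_len(nrow(metadata)))
    if ("individual" %in% spec@fixed || "individual" %in% spec@random)
        dat$individual <- factor(metadata$individual)
    if (any(grepl("time", spec@fixed)))
        dat$time_h <- as.numeric(metadata$time_h)
    if (any(grepl("temperature", spec@fixed))) {
        dat$temperature <- factor(metadata$temperature,
                                  levels = c("4C", "RT"))
        dat$temperature <- droplevels(dat$temperature)
    }
    for (v in c("individual", "temperature"))
        if (v %in% spec@fixed && nlevels(dat[[v]]) < 2L)
            stop(sprintf("factor '%s' has a single level", v))
    rhs <- paste(.termToVar[spec@fixed], collapse = " + ")
    mm <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = dat)
    attr(mm, "term_labels") <-
        attr(stats::terms(stats::as.formula(paste("~", rhs))), "term.labels")
    mm
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `adj_(i) = min_(j>=i) p_(j) * m / j`, capped at 1, with
#' `m` the number of non-missing p-values; missing entries are excluded and
#' reinserted in place.
#'
#' @param p numeric vector of raw p-values in `[0, 1]` (`NA` allowed).
#' @return adjusted p-values, same length and order.
#' @examples
#' benjaminiHochberg(c(0.005, 0.5))  # 0.01 0.50
#' @export
benjaminiHochberg <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    out[ok] <- stats::p.adjust(p[ok], method = "BH", n = sum(ok))
    out
}

## ---- empirical-Bayes variance moderation ----------------------------------

# invert the trigamma function by Newton iteration
.trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
        y <- y + dif
        if (abs(dif / y) < 1e-10) break
    }
    y
}

# moment-match a scaled-F prior to the observed log residual variances:
# returns c(d0, s02); d0 = Inf (with s02 = mean(s2)) when the spread of
# log s2 is no larger than expected from the chi-square sampling noise alone
.fitVariancePrior <- function(s2, df) {
    e <- log(s2) - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    n <- length(e)
    if (n < 2L) return(c(d0 = 0, s02 = mean(s2)))
    evar <- sum((e - emean)^2) / (n - 1L) - mean(trigamma(df / 2))
    if (evar > 0) {
        d0 <- 2 * .trigammaInverse(evar)
        s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
        d0 <- Inf
        s02 <- mean(s2)
    }
    c(d0 = d0, s02 = s02)
}

.squeezeVar <- function(s2, df, d0, s02) {
    if (is.infinite(d0)) rep(s02, length(s2))
    else if (d0 == 0) s2
    else (d0 * s02 + df * s2) / (d0 + df)
}

#' Per-feature linear models with empirical-Bayes moderated statistics
#'
#' Fits the same fixed-effects model to every feature by least squares, then
#' shrinks the per-feature residual variances `s2_g` (df `d_g`) toward a
#' global prior `(d0, s02)` estimated by moment matching on `log s2_g`:
#' `s2tilde_g = (d0 s02 + d_g s2_g) / (d0 + d_g)`. Moderated t-statistics
#' use `s2tilde_g` and `d0 + d_g` degrees of freedom; multi-column terms
#' (e.g. `individual`) get a moderated F. Named linear contrasts of the
#' coefficients are supported (e.g. the 8 h vs 0 h sitting-time contrast,
#' `8 * time_h`).
#'
#' @param assay an imputed [OmicsAssay-class] (or a complete numeric matrix,
#'   features x samples).
#' @param design design matrix from [buildDesign()] (rows = samples).
#' @param contrasts optional named list of numeric contrast vectors (length
#'   `ncol(design)`); each yields rows with `factor` set to its name.
#' @param moderate set `FALSE` (or `d0 = 0`) to disable shrinkage and obtain
#'   ordinary per-feature t-tests.
#' @param d0 optional fixed prior df overriding the moment estimate.
#' @return a [StabilityResult-class]; BH adjustment is applied per factor
#'   across features. Constant (zero-residual-variance) features are flagged
#'   `degenerate` with missing p and excluded from the FDR universe.
#' @examples
#' y <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
#' X <- cbind(`(Intercept)` = 1, time_h = rep(c(0, 2, 4, 8, 8), 2))
#' fitLinearEbayes(y, X)
#' @export
fitLinearEbayes <- function(assay, design, contrasts = NULL, moderate = TRUE,
                            d0 = NULL) {
    Y <- if (is(assay, "OmicsAssay")) SummarizedExperiment::assay(assay)
         else assay
    if (anyNA(Y))
        stop("matrix contains missing values; impute first")
    X <- design
    n <- ncol(Y)
    pcols <- ncol(X)
    if (n <= pcols)
        stop("need more samples than design columns")
    fit <- stats::lm.fit(X, t(Y))
    beta <- fit$coefficients                        # p x features
    res <- fit$residuals                            # n x features
    if (is.null(dim(beta))) {                       # single feature
        beta <- matrix(beta, ncol = 1)
        res <- matrix(res, ncol = 1)
    }
    beta <- t(beta)
    rownames(beta) <- rownames(Y)
    dfRes <- n - fit$rank
    s2 <- colSums(res^2) / dfRes
    XtXinv <- chol2inv(chol(crossprod(X)))
    vunsc <- diag(XtXinv)

    degenerate <- s2 <= .Machine$double.eps * rowSums(Y^2) / n
    useful <- !degenerate
    if (!moderate) d0 <- 0
    if (is.null(d0)) {
        prior <- if (any(useful)) .fitVariancePrior(s2[useful], dfRes)
                 else c(d0 = 0, s02 = NA_real_)
    } else {
        prior <- c(d0 = d0,
                   s02 = if (d0 > 0 && any(useful)) mean(s2[useful])
                         else NA_real_)
    }
    s2t <- .squeezeVar(s2, dfRes, prior[["d0"]], prior[["s02"]])
    dfTot <- prior[["d0"]] + dfRes

    feats <- rownames(Y)
    rows <- list()
    addRows <- function(fac, est, stat, df1, pv) {
        pv[degenerate] <- NA
        est[degenerate] <- NA
        stat[degenerate] <- NA
        rows[[length(rows) + 1L]] <<- S4Vectors::DataFrame(
            feature_id = feats, factor = fac, estimate = est,
            statistic = stat, df = df1, p = pv,
            p_adj = benjaminiHochberg(pv),
            fit_flag = ifelse(degenerate, "degenerate", "ols"))
    }

    assign <- attr(X, "assign")
    termLabels <- attr(X, "term_labels")
    for (j in seq_len(pcols)) {
        tj <- beta[, j] / sqrt(s2t * vunsc[j])
        pj <- 2 * stats::pt(-abs(tj), df = dfTot)
        addRows(colnames(X)[j], beta[, j], tj, dfTot, pj)
    }
    # moderated F for multi-column terms (categorical factors)
    if (!is.null(assign) && !is.null(termLabels)) {
        for (ti in seq_along(termLabels)) {
            cols <- which(assign == ti)
            if (length(cols) < 2L) next
            Vi <- solve(XtXinv[cols, cols, drop = FALSE])
            bsub <- beta[, cols, drop = FALSE]
            qf <- rowSums((bsub %*% Vi) * bsub)
            Fg <- qf / length(cols) / s2t
            pF <- stats::pf(Fg, length(cols), dfTot, lower.tail = FALSE)
            addRows(termLabels[ti], NA_real_, Fg, length(cols), pF)
        }
    }
    for (cn in names(contrasts)) {
        cv <- contrasts[[cn]]
        stopifnot(length(cv) == pcols)
        est <- drop(beta %*% cv)
        vc <- drop(t(cv) %*% XtXinv %*% cv)
        tc <- est / sqrt(s2t * vc)
        pc <- 2 * stats::pt(-abs(tc), df = dfTot)
        addRows(cn, est, tc, dfTot, pc)
    }
    new("StabilityResult", results = do.call(rbind, rows),
        prior = prior, method = "ebayes")
}

## ---- mixed models ----------------------------------------------------------

#' Per-feature mixed-model stability analysis
#'
#' Fits, for every feature, a linear mixed model with the spec's fixed terms
#' and a random intercept per individual (REML, Satterthwaite denominator
#' df). When the mixed fit is singular -- random-intercept variance at the
#' boundary (below `1e-8` times the residual variance) or non-convergence --
#' the feature is refit with a fixed-effects-only linear model carrying the
#' same terms and flagged `anova_fallback`. BH adjustment is applied per
#' fixed-effect factor across features; degenerate (constant) features are
#' flagged and excluded from the FDR universe.
#'
#' @param assay an imputed [OmicsAssay-class]; its `colData` must carry
#'   `individual`, `time_h` and (for plasma) `temperature`.
#' @param spec a `DesignSpec` with at least one random term; default: fixed
#'   `time + temperature + time:temperature` (plasma) or `time` (serum),
#'   random `individual`.
#' @return a [StabilityResult-class] with `fit_flag` per feature in
#'   `mixed` / `anova_fallback` / `degenerate`.
#' @examples
#' sim <- simulateCohort(simulationParams(nMetabolites = 8, nProteins = 30))
#' pl <- sim$metabolome[, sim$metadata$matrix == "plasma"]
#' imp <- imputeMinDet(glogTransform(pl))
#' fitMixedStability(imp)
#' @export
fitMixedStability <- function(assay, spec = NULL) {
    stopifnot(is(assay, "OmicsAssay"))
    cd <- as.data.frame(SummarizedExperiment::colData(assay))
    if (is.null(spec)) {
        mt <- if (length(unique(cd$matrix)) == 1L) unique(cd$matrix)
              else "plasma"
        fixed <- if (mt == "plasma" && length(unique(cd$temperature)) > 1L)
            c("time", "temperature", "time:temperature") else "time"
        spec <- designSpec(mt, fixed = fixed, random = "individual")
    }
    validObject(spec)
    if (length(spec@random) == 0L)
        stop("fitMixedStability requires a random term")
    if (min(table(cd$individual)) < 2L)
        stop("need >= 2 samples per individual")
    Y <- SummarizedExperiment::assay(assay)
    if (anyNA(Y))
        stop("matrix contains missing values; impute first")

    dat <- data.frame(individual = factor(cd$individual),
                      time_h = as.numeric(cd$time_h))
    if (any(grepl("temperature", spec@fixed)))
        dat$temperature <- factor(cd$temperature, levels = c("4C", "RT"))
    rhs <- paste(.termToVar[spec@fixed], collapse = " + ")
    formMixed <- stats::as.formula(paste("y ~", rhs, "+ (1 | individual)"))
    formFixed <- stats::as.formula(paste("y ~", rhs))

    rowsList <- vector("list", nrow(Y))
    for (g in seq_len(nrow(Y))) {
        dat$y <- Y[g, ]
        if (stats::var(dat$y) < .Machine$double.eps) {
            rowsList[[g]] <- data.frame(feature_id = rownames(Y)[g],
                                        factor = "(degenerate)",
                                        estimate = NA_real_,
                                        statistic = NA_real_, df = NA_real_,
                                        p = NA_real_,
                                        fit_flag = "degenerate")
            next
        }
        fitm <- tryCatch(
            suppressMessages(suppressWarnings(
                lmerTest::lmer(formMixed, data = dat))),
            error = function(e) NULL)
        singular <- TRUE
        if (!is.null(fitm)) {
            vc <- as.data.frame(lme4::VarCorr(fitm))
            reVar <- vc$vcov[vc$grp == "individual"][1]
            resVar <- vc$vcov[vc$grp == "Residual"][1]
            singular <- lme4::isSingular(fitm, tol = 1e-4) ||
                reVar < 1e-8 * resVar
        }
        if (!singular) {
            cf <- stats::coef(summary(fitm))
            flag <- "mixed"
        } else {
            cf <- stats::coef(summary(stats::lm(formFixed, data = dat)))
            cf <- cbind(cf[, 1:2, drop = FALSE],
                        df = stats::df.residual(stats::lm(formFixed,
                                                          data = dat)),
                        cf[, 3:4, drop = FALSE])
            flag <- "anova_fallback"
        }
        rowsList[[g]] <- data.frame(feature_id = rownames(Y)[g],
                                    factor = rownames(cf),
                                    estimate = cf[, "Estimate"],
                                    statistic = cf[, "t value"],
                                    df = cf[, "df"],
                                    p = cf[, ncol(cf)],
                                    fit_flag = flag, row.names = NULL)
    }
    res <- do.call(rbind, rowsList)
    res$p_adj <- NA_real_
    for (fac in unique(res$factor)) {
        sel <- res$factor == fac
        res$p_adj[sel] <- benjaminiHochberg(res$p[sel])
    }
    new("StabilityResult", results = S4Vectors::DataFrame(res),
        prior = c(d0 = NA_real_, s02 = NA_real_), method = "mixed")
}

#' Count significant features for a factor
#'
#' @param result a [StabilityResult-class].
#' @param factor factor/term name present in the result (e.g. `"time_h"`,
#'   `"individual"`).
#' @param alpha significance level on the BH-adjusted p-values.
#' @return integer count of features with `p_adj < alpha`.
#' @examples
#' y <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
#' X <- cbind(`(Intercept)` = 1, time_h = rep(c(0, 2, 4, 8, 8), 2))
#' countSignificant(fitLinearEbayes(y, X), "time_h")
#' @export
countSignificant <- function(result, factor, alpha = 0.05) {
    stopifnot(is(result, "StabilityResult"))
    tab <- result@results
    if (!factor %in% tab$factor)
        stop("unknown factor: ", factor)
    sum(tab$p_adj[tab$factor == factor] < alpha, na.rm = TRUE)
}
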