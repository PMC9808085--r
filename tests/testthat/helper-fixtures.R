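# shared fixture builders and independent oracles

# build an OmicsAssay at an arbitrary stage without walking the transitions
toyAssay <- function(values, stage = "imputed", colData = NULL) {
    OmicsAssay(values, colData = colData, stage = stage)
}

# small simulated cohort reused across tests
smallCohort <- function(seed = 42, nMetabolites = 80, nProteins = 40, ...) {
    simulateCohort(simulationParams(nMetabolites = nMetabolites,
                                    nProteins = nProteins, seed = seed, ...))
}

# brute-force step-up BH: literal definition, independent of p.adjust
bruteForceBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj <- rep(NA_real_, m)
    for (i in seq_len(m)) {
        r <- which(ord == i)  # rank of p[i]
        adj[i] <- min(vapply(r:m, function(j) p[ord[j]] * m / j,
                             numeric(1)), 1)
    }
    adj
}

# assay from log2 values (bypasses the raw scale), metadata attached
log2Assay <- function(rawAssay) {
    v <- log2(SummarizedExperiment::assay(rawAssay))
    toyAssay(v, stage = "imputed",
             colData = SummarizedExperiment::colData(rawAssay))
}
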