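## TSV/JSON round-trip IO, input validation and the five-stage pipeline
## (simulate -> preprocess -> stability/signatures -> score).
## All on-disk formats are plain TSV with '#' comment headers.

#' Write / read an omics matrix as TSV
#'
#' Matrices are stored features-in-rows with a `feature_id` first column and
#' a `# stage: <stage>` comment line; missing cells are `NA`.
#'
#' @param assay an [OmicsAssay-class].
#' @param path file path.
#' @return `writeOmicsMatrix`: `path`, invisibly. `readOmicsMatrix`: an
#'   [OmicsAssay-class] (stage restored from the comment line unless
#'   overridden).
#' @export
writeOmicsMatrix <- function(assay, path) {
    stopifnot(is(assay, "OmicsAssay"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# stage: %s", assay@stage), con)
    v <- SummarizedExperiment::assay(assay)
    tab <- data.frame(feature_id = rownames(v), v, check.names = FALSE)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeOmicsMatrix
#' @param metadata optional per-sample metadata (`data.frame` with
#'   `sample_id`) attached as `colData`.
#' @param stage override for the stage tag.
#' @export
readOmicsMatrix <- function(path, metadata = NULL, stage = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (is.null(stage)) {
        first <- readLines(path, n = 1L)
        stage <- if (grepl("^# stage: ", first))
            sub("^# stage: ", "", first) else "raw"
    }
    tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
    v <- as.matrix(tab[, -1, drop = FALSE])
    rownames(v) <- tab$feature_id
    cd <- NULL
    if (!is.null(metadata)) {
        metadata <- as.data.frame(metadata)
        idx <- match(colnames(v), metadata$sample_id)
        if (anyNA(idx))
            stop("metadata missing sample(s): ",
                 paste(utils::head(colnames(v)[is.na(idx)], 5),
                       collapse = ", "))
        cd <- S4Vectors::DataFrame(metadata[idx, , drop = FALSE],
                                   row.names = colnames(v))
    }
    OmicsAssay(v, colData = cd, stage = stage)
}

#' Write / read the sample metadata table
#'
#' Columns: `sample_id`, `individual`, `matrix`, `time_h`, `temperature`,
#' `centrifugation_g`.
#'
#' @param metadata `data.frame`/`DataFrame` of per-sample design factors.
#' @param path file path.
#' @return `writeSampleMetadata`: `path`, invisibly; `readSampleMetadata`:
#'   a `data.frame`.
#' @export
writeSampleMetadata <- function(metadata, path) {
    utils::write.table(as.data.frame(metadata), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSampleMetadata
#' @export
readSampleMetadata <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Validate a matrix/metadata file pair
#'
#' Machine-readable pre-flight checks: sample-id agreement between matrix
#' columns and metadata rows, duplicated feature ids, non-numeric cells,
#' unexpected sitting times (outside 0/2/4/8 h) and design violations
#' (serum held at 4C).
#'
#' @param matrixPath path to a matrix TSV (see [writeOmicsMatrix()]).
#' @param metadataPath path to a metadata TSV (see [writeSampleMetadata()]).
#' @return `data.frame` with columns `kind`, `severity` (`error`/`warning`)
#'   and `message`; zero rows when the pair is clean.
#' @export
validateInputs <- function(matrixPath, metadataPath) {
    for (p in c(matrixPath, metadataPath))
        if (!file.exists(p)) stop("no such file: ", p)
    tab <- utils::read.delim(matrixPath, comment.char = "#",
                             check.names = FALSE)
    md <- readSampleMetadata(metadataPath)
    issues <- list()
    add <- function(kind, severity, message)
        issues[[length(issues) + 1L]] <<-
            data.frame(kind = kind, severity = severity, message = message)

    if (anyDuplicated(tab$feature_id))
        add("duplicate_feature", "error",
            paste("duplicated feature ids:",
                  paste(unique(tab$feature_id[duplicated(tab$feature_id)]),
                        collapse = ", ")))
    vals <- tab[, -1, drop = FALSE]
    nonNum <- !vapply(vals, is.numeric, logical(1))
    if (any(nonNum))
        add("non_numeric", "error",
            paste("non-numeric columns:",
                  paste(colnames(vals)[nonNum], collapse = ", ")))
    mSamples <- colnames(vals)
    missMeta <- setdiff(mSamples, md$sample_id)
    if (length(missMeta))
        add("sample_mismatch", "error",
            paste("samples absent from metadata:",
                  paste(missMeta, collapse = ", ")))
    missMat <- setdiff(md$sample_id, mSamples)
    if (length(missMat))
        add("sample_mismatch", "warning",
            paste("metadata samples absent from matrix:",
                  paste(missMat, collapse = ", ")))
    if ("time_h" %in% colnames(md)) {
        odd <- setdiff(unique(md$time_h), c(0, 2, 4, 8))
        if (length(odd))
            add("unexpected_time", "warning",
                paste("sitting times outside 0/2/4/8 h:",
                      paste(odd, collapse = ", ")))
    }
    if (all(c("matrix", "temperature") %in% colnames(md)) &&
        any(md$matrix == "serum" & md$temperature != "RT"))
        add("design_violation", "warning",
            "serum samples held at a temperature other than RT")
    if (length(issues)) do.call(rbind, issues)
    else data.frame(kind = character(), severity = character(),
                    message = character())
}

.defaultPipelineConfig <- function() {
    list(simulate = list(),
         inputs = NULL,
         preprocess = list(minFrac = 0.66, q = 0.01),
         signatures = list(k = 20, hours = 8),
         score = list(nPerm = 1000,
                      groupBy = c("matrix", "temperature", "time_h")),
         seed = 1L)
}

.mergeConfig <- function(user) {
    base <- .defaultPipelineConfig()
    unknown <- setdiff(names(user), names(base))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    for (k in names(user)) {
        if (is.list(base[[k]]) && is.list(user[[k]])) {
            unknown2 <- setdiff(names(user[[k]]),
                                c(names(base[[k]]),
                                  names(formals(simulationParams))))
            if (length(unknown2))
                stop(sprintf("unknown config key(s) under '%s': %s", k,
                             paste(unknown2, collapse = ", ")))
            base[[k]][names(user[[k]])] <- user[[k]]
        } else base[[k]] <- user[[k]]
    }
    base
}

#' Run the full quality-scoring pipeline
#'
#' Executes simulate (or load) -> preprocess -> signature derivation ->
#' scoring -> group averaging for both omics layers and writes all artifacts
#' to `outDir`: raw and imputed matrices, sample metadata, ground truth
#' (simulated runs), signature TSVs, per-sample score tables, group-averaged
#' NES tables and a provenance log (`provenance.json`) with package/R
#' versions, the seed and the fully merged configuration, which suffices to
#' reproduce the run exactly.
#'
#' @param config a nested list or a YAML file path. Sections: `simulate`
#'   (arguments of [simulationParams()]), `inputs` (paths `metabolome`,
#'   `proteome`, `samples` to skip simulation), `preprocess` (`minFrac`,
#'   `q`), `signatures` (`k`, `hours`), `score` (`nPerm`, `groupBy`) and
#'   `seed`. Unknown keys are rejected.
#' @param outDir output directory (created if needed).
#' @param seed overrides `config$seed`; every stochastic stage derives its
#'   seed from it.
#' @return invisibly, a list with the in-memory artifacts (`assays`,
#'   `signatures`, `scores`, `groupScores`, `truth`, `files`).
#' @export
runPipeline <- function(config = list(), outDir, seed = NULL) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config)) stop("no such config file: ", config)
        config <- yaml::read_yaml(config)
    }
    cfg <- .mergeConfig(config)
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    keep <- function(name, path) { files[[name]] <<- path; path }

    truth <- NULL
    if (is.null(cfg$inputs)) {
        params <- do.call(simulationParams,
                          c(cfg$simulate, list(seed = cfg$seed)))
        sim <- simulateCohort(params)
        assays <- list(metabolome = sim$metabolome, proteome = sim$proteome)
        md <- as.data.frame(sim$metadata)
        truth <- sim$truth
        writeOmicsMatrix(sim$metabolome,
                         keep("metabolome_raw",
                              file.path(outDir, "metabolome_raw.tsv")))
        writeOmicsMatrix(sim$proteome,
                         keep("proteome_raw",
                              file.path(outDir, "proteome_raw.tsv")))
        writeSampleMetadata(md, keep("samples",
                                     file.path(outDir, "samples.tsv")))
        jsonlite::write_json(
            list(metabolites = as.data.frame(truth@metabolites),
                 proteins = as.data.frame(truth@proteins)),
            keep("truth", file.path(outDir, "truth.json")),
            digits = NA, na = "null")
    } else {
        for (nm in c("metabolome", "proteome", "samples"))
            if (is.null(cfg$inputs[[nm]]))
                stop("config$inputs must name '", nm, "'")
        md <- readSampleMetadata(cfg$inputs$samples)
        assays <- list(
            metabolome = readOmicsMatrix(cfg$inputs$metabolome,
                                         metadata = md),
            proteome = readOmicsMatrix(cfg$inputs$proteome, metadata = md))
    }

    conditions <- unique(md[md$time_h == max(md$time_h),
                            c("matrix", "temperature")])
    imputed <- list()
    signatures <- list()
    scores <- list()
    groupScores <- list()
    for (layer in names(assays)) {
        filt <- filterLowAbundance(assays[[layer]],
                                   minFrac = cfg$preprocess$minFrac)
        imp <- imputeMinDet(glogTransform(filt$assay), q = cfg$preprocess$q)
        imputed[[layer]] <- imp
        writeOmicsMatrix(imp, keep(paste0(layer, "_imputed"),
                                   file.path(outDir,
                                             paste0(layer,
                                                    "_imputed.tsv"))))
        sigs <- list()
        for (i in seq_len(nrow(conditions))) {
            sig <- qualitySignatureFromCohort(
                imp, conditions$matrix[i], conditions$temperature[i],
                k = cfg$signatures$k, hours = cfg$signatures$hours)
            sigs[[sig@name]] <- sig
        }
        if (layer == "proteome")
            sigs <- c(sigs, bundledContaminationSignatures())
        signatures[[layer]] <- sigs
        writeSignatures(sigs, keep(paste0(layer, "_signatures"),
                                   file.path(outDir,
                                             paste0(layer,
                                                    "_signatures.tsv"))))
        sc <- nesScores(scalePerFeature(imp), sigs,
                        nPerm = cfg$score$nPerm, seed = cfg$seed + 1L)
        scores[[layer]] <- sc
        utils::write.table(as.data.frame(sc@table),
                           keep(paste0(layer, "_scores"),
                                file.path(outDir,
                                          paste0(layer, "_scores.tsv"))),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        ga <- groupAverage(sc, md, keys = cfg$score$groupBy)
        ga <- ga[do.call(order, ga[c("signature", cfg$score$groupBy)]), ]
        groupScores[[layer]] <- ga
        utils::write.table(ga,
                           keep(paste0(layer, "_group_scores"),
                                file.path(outDir,
                                          paste0(layer,
                                                 "_group_scores.tsv"))),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    prov <- list(package = "omiqc",
                 version = as.character(utils::packageVersion("omiqc")),
                 r_version = paste(R.version$major, R.version$minor,
                                   sep = "."),
                 seed = cfg$seed, config = cfg[names(cfg) != "inputs"],
                 outputs = as.list(basename(unlist(files))))
    jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    invisible(list(assays = imputed, signatures = signatures,
                   scores = scores, groupScores = groupScores,
                   truth = truth, files = files))
}
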