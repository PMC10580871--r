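## End-to-end orchestration: simulate -> classify -> featurize -> train ->
## decide -> report, with a single root seed, append-only run directories
## and a run log.

#' Classify and featurize a simulated cohort
#'
#' Runs the built-in classifier on every sample, depletes host reads by
#' read-ID subtraction, and builds the combined feature table. The
#' run-level statistic columns are computed on each sample's
#' host-depleted (microbial) read pool.
#'
#' @param cohort output of \code{\link{simulateCohort}}.
#' @param refs the \linkS4class{TaxonRefSet} the cohort was drawn from.
#' @param config a \linkS4class{PipelineConfig}.
#' @param k classifier k-mer size.
#' @param labelled attach truth labels to the feature table.
#' @return list: \code{features} (feature table),
#'   \code{hostFractions} (named per-sample), \code{assignments}
#'   (host-depleted, with sample_id), \code{readInfo} (host-depleted).
#' @export
featurizeCohort <- function(cohort, refs, config = pipelineConfig(),
                            k = 15L, labelled = TRUE) {
    idx <- buildKmerIndex(refs, k = k)
    host <- hostTaxon(refs)
    asgList <- list()
    infoList <- list()
    hf <- numeric(0)
    for (sid in names(cohort$samples)) {
        s <- cohort$samples[[sid]]
        info <- readInfo(s$reads)
        asg <- classifyReads(s$reads, idx)
        dep <- depleteHost(list(builtin = asg), host, info$read_id)
        info <- info[info$read_id %in% dep$kept_read_ids, , drop = FALSE]
        asg <- asg[asg$read_id %in% dep$kept_read_ids, , drop = FALSE]
        info$sample_id <- rep(sid, nrow(info))
        asg$sample_id <- rep(sid, nrow(asg))
        hf[sid] <- dep$host_fraction
        asgList[[sid]] <- asg
        infoList[[sid]] <- info
    }
    allAsg <- do.call(rbind, asgList)
    allInfo <- do.call(rbind, infoList)
    rownames(allAsg) <- rownames(allInfo) <- NULL
    features <- buildFeatureTable(list(builtin = allAsg), allInfo,
                                  truths = if (labelled) cohort$truths,
                                  config = config)
    list(features = features, hostFractions = hf, assignments = allAsg,
         readInfo = allInfo)
}

#' Validate a run manifest
#'
#' @param manifest data.frame with \code{sample_id}, \code{fastq_pass}
#'   and optionally \code{fastq_fail}, \code{barcode}.
#' @return the manifest, invisibly; errors on duplicate sample ids or
#'   missing paths.
#' @export
validateManifest <- function(manifest) {
    if (anyDuplicated(manifest$sample_id))
        stop("manifest error: duplicate sample_id")
    paths <- c(manifest$fastq_pass,
               if ("fastq_fail" %in% names(manifest)) manifest$fastq_fail)
    paths <- paths[!is.na(paths) & nzchar(paths)]
    missing <- paths[!file.exists(paths)]
    if (length(missing))
        stop("manifest error: missing path(s) ",
             paste(missing, collapse = ", "))
    invisible(manifest)
}

uniqueRunDir <- function(outDir, seed) {
    base <- file.path(outDir, sprintf("run-seed%d", seed))
    d <- base
    i <- 1L
    while (dir.exists(d)) {
        i <- i + 1L
        d <- sprintf("%s-%d", base, i)
    }
    dir.create(d, recursive = TRUE)
    d
}

#' Run the pipeline end to end
#'
#' Orchestrates the stages under an append-only run directory. All
#' randomness flows from the single root \code{seed}. Modes:
#' \describe{
#'   \item{simulate}{generate references and a cohort; write FASTQ
#'     (pass/fail layout), sequencing summary, references and truth
#'     manifest.}
#'   \item{train}{simulate, classify, featurize, split, train both
#'     models, persist bundles, decide the evaluation samples and
#'     write the cohort report.}
#'   \item{predict}{load previously trained bundles (error naming the
#'     expected path when absent) and call a freshly simulated -- or
#'     manifest-supplied -- cohort.}
#' }
#' Identical (arguments, seed) give byte-identical decision and report
#' tables.
#'
#' @param outDir parent output directory; each invocation creates a
#'   fresh run subdirectory (reruns never overwrite).
#' @param mode one of \code{"simulate"}, \code{"train"},
#'   \code{"predict"}.
#' @param seed root integer seed.
#' @param config a \linkS4class{PipelineConfig}.
#' @param nPerTier cohort design (named: "10", "100", "sterile").
#' @param depth reads per sample.
#' @param nBacterial,nFungal,nKitome reference-set design.
#' @param grid hyperparameter grid for training.
#' @param bundleDir directory holding \code{status/} and
#'   \code{correctness/} bundles (predict mode).
#' @param manifest optional run manifest (predict mode): samples are
#'   read from FASTQ instead of simulated.
#' @param refs optional pre-built \linkS4class{TaxonRefSet}.
#' @return list with the run directory and the main in-memory results
#'   (invisible).
#' @export
runEndToEnd <- function(outDir, mode = c("train", "simulate", "predict"),
                        seed = 1L, config = pipelineConfig(),
                        nPerTier = c(`10` = 4, `100` = 4, sterile = 4),
                        depth = 300, nBacterial = 4L, nFungal = 2L,
                        nKitome = 3L, grid = xgbGridSmall(),
                        bundleDir = NULL, manifest = NULL, refs = NULL) {
    mode <- match.arg(mode)
    if (mode == "predict") {
        if (is.null(bundleDir))
            stop("predict mode requires bundleDir")
        for (sub in c("status", "correctness")) {
            p <- file.path(bundleDir, sub)
            if (!file.exists(file.path(p, "model.json")))
                stop("missing bundle: expected ", file.path(p, "model.json"))
        }
        if (!is.null(manifest)) validateManifest(manifest)
    }
    runDir <- uniqueRunDir(outDir, seed)
    logPath <- file.path(runDir, "run.log")
    logLine <- function(...) cat(..., "\n", sep = "", file = logPath,
                                 append = TRUE)
    cfgPath <- file.path(runDir, "config.yaml")
    writePipelineConfig(config, cfgPath)
    logLine("sterilamp ", as.character(utils::packageVersion("sterilamp")))
    logLine("mode: ", mode)
    logLine("seed: ", seed)
    logLine("config md5: ", unname(tools::md5sum(cfgPath)))

    if (is.null(refs))
        refs <- makeReferences(nBacterial, nFungal, nKitome = nKitome,
                               seed = deriveSeed(seed, "refs"))
    writeReferences(refs, file.path(runDir, "references.fasta"),
                    file.path(runDir, "taxonomy.tsv"))

    cohort <- NULL
    if (is.null(manifest)) {
        cohort <- simulateCohort(nPerTier, refs, depth = depth,
                                 seed = deriveSeed(seed, "cohortsim"))
        logLine("simulated samples: ", length(cohort$samples))
    }

    if (mode == "simulate") {
        for (sid in names(cohort$samples))
            writeRunFastq(cohort$samples[[sid]]$reads, runDir, sid)
        allInfo <- do.call(rbind, lapply(cohort$samples, function(s)
            readInfo(s$reads)))
        writeSequencingSummary(allInfo,
                               file.path(runDir, "sequencing_summary.txt"))
        writeTruthManifest(cohort$truths,
                           file.path(runDir, "truth_manifest.tsv"))
        prov <- do.call(rbind, lapply(cohort$samples,
                                      function(s) s$provenance))
        write.table(prov, file.path(runDir, "provenance.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        logLine("stage simulate: ok")
        return(invisible(list(runDir = runDir, cohort = cohort,
                              refs = refs)))
    }

    if (mode == "train") {
        writeTruthManifest(cohort$truths,
                           file.path(runDir, "truth_manifest.tsv"))
        feat <- featurizeCohort(cohort, refs, config)
        writeFeatureTable(feat$features, file.path(runDir, "features.tsv"))
        logLine("feature rows: ", nrow(feat$features))
        parts <- splitTwoLayer(feat$features, config@splitRatio,
                               seed = deriveSeed(seed, "split"))
        statusBundle <- trainClassifier(parts$train, parts$test,
                                        label = "sample_status",
                                        grid = grid, config = config,
                                        seed = deriveSeed(seed, "m1"))
        corrBundle <- trainClassifier(parts$train, parts$test,
                                      label = "correctness", grid = grid,
                                      config = config,
                                      seed = deriveSeed(seed, "m2"))
        saveModelBundle(statusBundle, file.path(runDir, "models", "status"))
        saveModelBundle(corrBundle,
                        file.path(runDir, "models", "correctness"))
        logLine("cv accuracy (status): ",
                format(bundleMetadata(statusBundle)$cv_accuracy))
        logLine("cv accuracy (correctness): ",
                format(bundleMetadata(corrBundle)$cv_accuracy))
        evalIds <- unique(parts$evaluation$sample_id)
        decisions <- decideCohort(parts$evaluation, statusBundle,
                                  corrBundle, sampleIds = sort(evalIds),
                                  matrix = config@decisionMatrix)
        write.table(decisions, file.path(runDir, "decisions.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        report <- cohortReport(decisions, cohort$truths)
        write.table(report, file.path(runDir, "report.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        logLine("stage train: ok")
        return(invisible(list(runDir = runDir, cohort = cohort,
                              refs = refs, features = feat$features,
                              parts = parts, statusBundle = statusBundle,
                              correctnessBundle = corrBundle,
                              decisions = decisions, report = report)))
    }

    # predict mode
    statusBundle <- loadModelBundle(file.path(bundleDir, "status"))
    corrBundle <- loadModelBundle(file.path(bundleDir, "correctness"))
    if (!is.null(manifest)) {
        samples <- lapply(seq_len(nrow(manifest)), function(i) {
            files <- c(manifest$fastq_pass[i],
                       if ("fastq_fail" %in% names(manifest))
                           manifest$fastq_fail[i])
            list(reads = readRunFastq(files,
                                      barcode = manifest$sample_id[i]))
        })
        names(samples) <- manifest$sample_id
        cohort <- list(samples = samples, truths = NULL)
    }
    feat <- featurizeCohort(cohort, refs, config, labelled = FALSE)
    writeFeatureTable(feat$features, file.path(runDir, "features.tsv"))
    decisions <- decideCohort(feat$features, statusBundle, corrBundle,
                              sampleIds = sort(names(cohort$samples)),
                              matrix = config@decisionMatrix)
    write.table(decisions, file.path(runDir, "decisions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    logLine("stage predict: ok")
    invisible(list(runDir = runDir, decisions = decisions,
                   features = feat$features))
}
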