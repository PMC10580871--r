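#' Create a pipeline configuration
#'
#' @param qPassThreshold phred boundary between pass and fail reads.
#' @param includeFailReads retain reads below the boundary.
#' @param blastIdentityMin species filter for BLAST-like backends:
#'   maximum percent identity must be strictly greater than this.
#' @param centrifugeMeanScoreMin species filter for the Centrifuge
#'   backend: mean classification score must be strictly greater.
#' @param splitRatio proportion retained at each layer of the two-layer
#'   split.
#' @param cvFolds number of cross-validation folds.
#' @param decisionMatrix named character vector of the four decision
#'   cells (see \code{\link{decisionMatrixDefault}}).
#' @return a validated \linkS4class{PipelineConfig}.
#' @examples
#' cfg <- pipelineConfig()
#' cfg
#' @export
pipelineConfig <- function(qPassThreshold = 7, includeFailReads = TRUE,
                           blastIdentityMin = 83,
                           centrifugeMeanScoreMin = 900,
                           splitRatio = 0.75, cvFolds = 5L,
                           decisionMatrix = decisionMatrixDefault()) {
    new("PipelineConfig", qPassThreshold = as.numeric(qPassThreshold),
        includeFailReads = isTRUE(includeFailReads),
        blastIdentityMin = as.numeric(blastIdentityMin),
        centrifugeMeanScoreMin = as.numeric(centrifugeMeanScoreMin),
        splitRatio = as.numeric(splitRatio), cvFolds = as.integer(cvFolds),
        decisionMatrix = decisionMatrix)
}

#' Read / write a pipeline configuration as YAML
#'
#' The configuration file mirrors the slots of
#' \linkS4class{PipelineConfig}, including the four decision-matrix
#' cells, so the unstated cell mapping is explicit and overridable.
#'
#' @param path file path.
#' @return \code{readPipelineConfig}: a \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    dm <- decisionMatrixDefault()
    if (!is.null(y$decision_matrix))
        dm[names(y$decision_matrix)] <- unlist(y$decision_matrix)
    pipelineConfig(
        qPassThreshold = y$q_pass_threshold %||% 7,
        includeFailReads = y$include_fail_reads %||% TRUE,
        blastIdentityMin = y$blast_identity_min %||% 83,
        centrifugeMeanScoreMin = y$centrifuge_mean_score_min %||% 900,
        splitRatio = y$split_ratio %||% 0.75,
        cvFolds = y$cv_folds %||% 5L,
        decisionMatrix = dm)
}

#' @rdname readPipelineConfig
#' @param config a \linkS4class{PipelineConfig} to serialize.
#' @export
writePipelineConfig <- function(config, path) {
    y <- list(
        q_pass_threshold = config@qPassThreshold,
        include_fail_reads = config@includeFailReads,
        blast_identity_min = config@blastIdentityMin,
        centrifuge_mean_score_min = config@centrifugeMeanScoreMin,
        split_ratio = config@splitRatio,
        cv_folds = config@cvFolds,
        decision_matrix = as.list(config@decisionMatrix))
    yaml::write_yaml(y, path)
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
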