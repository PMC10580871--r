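## Decision matrix: combine the sample-status model and the
## contaminant-correctness model into one of four sterility calls, and
## tabulate cohort-level call rates by CFU tier.

#' Default decision matrix
#'
#' The four cells mapping (sample status, any correctly-classified
#' contaminant?) to the four published call states. The mapping is
#' configurable (see \code{\link{pipelineConfig}}): the state
#' vocabulary is fixed, the cell assignment is explicit and
#' overridable.
#'
#' @return named character vector with cells
#'   \code{contaminated_correct}, \code{contaminated_none},
#'   \code{sterile_none}, \code{sterile_correct}.
#' @export
decisionMatrixDefault <- function() {
    c(contaminated_correct = "CONTAMINATED",
      contaminated_none = "POTENTIALLY_CONTAMINATED",
      sterile_none = "STERILE",
      sterile_correct = "STERILE_WITH_BACKGROUND_NOISE")
}

#' Aggregate row predictions into a sample status
#'
#' A sample is called contaminated when the maximum row probability
#' from the sample-status model is at or above 0.5; the reported
#' probability is that maximum. A sample with no surviving species
#' rows is sterile with probability 0.
#'
#' @param rowProbabilities numeric vector of per-row probabilities
#'   (may be empty).
#' @return list: \code{status} ("contaminated"/"sterile"),
#'   \code{probability}.
#' @examples
#' sampleStatus(c(0.2, 0.9))
#' sampleStatus(numeric(0))
#' @export
sampleStatus <- function(rowProbabilities) {
    if (length(rowProbabilities) == 0L)
        return(list(status = "sterile", probability = 0))
    p <- max(rowProbabilities)
    list(status = if (p >= 0.5) "contaminated" else "sterile",
         probability = p)
}

#' Apply the decision matrix to one sample
#'
#' @param status \code{"contaminated"} or \code{"sterile"} (from
#'   \code{\link{sampleStatus}}).
#' @param correctnessLabels 0/1 predictions of the correctness model
#'   for the sample's species rows (may be empty).
#' @param matrix a 4-cell decision matrix (default
#'   \code{\link{decisionMatrixDefault}}).
#' @return the call, one of the four states in \code{matrix}.
#' @examples
#' decideSample("contaminated", c(0, 1))
#' decideSample("sterile", integer(0))
#' @export
decideSample <- function(status, correctnessLabels,
                         matrix = decisionMatrixDefault()) {
    stopifnot(status %in% c("contaminated", "sterile"))
    anyCorrect <- length(correctnessLabels) > 0L &&
        any(correctnessLabels == 1L)
    cell <- paste0(status, if (anyCorrect) "_correct" else "_none")
    unname(matrix[[cell]])
}

#' Per-tier cohort call-rate report
#'
#' For each tier (sterile controls, 10 CFU/mL, 100 CFU/mL): the
#' fraction of samples called CONTAMINATED (contaminated group),
#' STERILE (sterile group), and POTENTIALLY_CONTAMINATED or
#' STERILE_WITH_BACKGROUND_NOISE (ambiguous group). The three
#' fractions sum to 1 within each tier.
#'
#' @param decisions data.frame with \code{sample_id}, \code{call}.
#' @param truths data.frame with \code{sample_id}, \code{cfu_tier}.
#' @return data.frame: \code{tier}, \code{n},
#'   \code{contaminated_rate}, \code{sterile_rate},
#'   \code{ambiguous_rate}.
#' @export
cohortReport <- function(decisions, truths) {
    m <- match(decisions$sample_id, truths$sample_id)
    if (anyNA(m)) stop("join error: decision without matching truth")
    tier <- truths$cfu_tier[m]
    tierLabel <- ifelse(tier == 0, "sterile", paste0(tier, " CFU/mL"))
    rows <- lapply(c("sterile", "10 CFU/mL", "100 CFU/mL"), function(tl) {
        sel <- tierLabel == tl
        if (!any(sel)) return(NULL)
        calls <- decisions$call[sel]
        data.frame(tier = tl, n = sum(sel),
                   contaminated_rate = mean(calls == "CONTAMINATED"),
                   sterile_rate = mean(calls == "STERILE"),
                   ambiguous_rate = mean(calls %in%
                       c("POTENTIALLY_CONTAMINATED",
                         "STERILE_WITH_BACKGROUND_NOISE")),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Decide every sample of a cohort
#'
#' Convenience wrapper: applies the sample-status model and the
#' correctness model to a labelled or unlabelled feature table and
#' produces one \code{Decision} row per sample (samples with no
#' feature rows get the no-surviving-species fallback).
#'
#' @param featureTable feature table covering the samples to call.
#' @param statusBundle,correctnessBundle the two
#'   \linkS4class{ModelBundle}s.
#' @param sampleIds samples to call (default: those in the table).
#' @param matrix decision matrix.
#' @return data.frame: \code{sample_id}, \code{call},
#'   \code{probability}, \code{supporting_species} (semicolon-joined
#'   species with a correct-contaminant prediction).
#' @export
decideCohort <- function(featureTable, statusBundle, correctnessBundle,
                         sampleIds = NULL,
                         matrix = decisionMatrixDefault()) {
    if (is.null(sampleIds)) sampleIds <- unique(featureTable$sample_id)
    statusPred <- if (nrow(featureTable)) {
        predictRows(statusBundle, featureTable)
    } else data.frame(probability = numeric(0), label = integer(0))
    corrPred <- if (nrow(featureTable)) {
        predictRows(correctnessBundle, featureTable)
    } else data.frame(probability = numeric(0), label = integer(0))
    out <- lapply(sampleIds, function(sid) {
        sel <- which(featureTable$sample_id == sid)
        st <- sampleStatus(statusPred$probability[sel])
        corr <- corrPred$label[sel]
        species <- featureTable$species[sel][corr == 1L]
        data.frame(sample_id = sid,
                   call = decideSample(st$status, corr, matrix),
                   probability = st$probability,
                   supporting_species = paste(unique(species),
                                              collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
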