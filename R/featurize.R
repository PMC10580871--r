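## Feature engineering: quality partition at the Q7 boundary, per-species
## prediction filters (strict > 83% identity, strict > 900 mean score),
## describe-style eight-number summaries, run-level statistics,
## time-to-next-read features, NaN-row removal.

#' Partition reads at the pass/fail quality boundary
#'
#' Splits reads on mean phred quality and reports the fraction of
#' additional reads gained over the high-quality baseline
#' (\code{|fail| / |pass|}) -- the benefit of retaining the fastq_fail
#' pool when hunting low-abundance contaminants.
#'
#' @param reads a \linkS4class{ReadSet} or an info data.frame with a
#'   \code{mean_q} column.
#' @param qThreshold phred boundary (default 7).
#' @return list with \code{pass_ids}, \code{fail_ids},
#'   \code{additional_fraction}.
#' @examples
#' info <- data.frame(read_id = c("a", "b", "c"),
#'                    mean_q = c(8.1, 6.9, 12))
#' partitionQuality(info)$additional_fraction
#' @export
partitionQuality <- function(reads, qThreshold = 7) {
    if (qThreshold < 0) stop("invalid-argument: qThreshold must be >= 0")
    info <- if (is(reads, "ReadSet")) readInfo(reads) else reads
    if (nrow(info) == 0L)
        return(list(pass_ids = character(0), fail_ids = character(0),
                    additional_fraction = 0))
    passSel <- info$mean_q >= qThreshold
    if (!any(passSel))
        stop("undefined-baseline: no reads at or above the quality threshold")
    list(pass_ids = info$read_id[passSel],
         fail_ids = info$read_id[!passSel],
         additional_fraction = sum(!passSel) / sum(passSel))
}

#' Species-level prediction filter
#'
#' Grouped by taxon, a species survives when (BLAST-like backends,
#' including the built-in classifier) its maximum percent identity is
#' strictly greater than \code{blastIdentityMin}, or (Centrifuge
#' backend) its mean classification score is strictly greater than
#' \code{centrifugeMeanScoreMin}. Unclassified reads never contribute
#' a surviving species.
#'
#' @param assignments assignment data.frame from a single backend and
#'   a single sample.
#' @param config a \linkS4class{PipelineConfig}.
#' @return integer vector of surviving taxon_ids.
#' @export
speciesFilter <- function(assignments, config = pipelineConfig()) {
    if (nrow(assignments) == 0L) return(integer(0))
    backend <- unique(assignments$backend)
    if (length(backend) != 1L)
        stop("invalid-input: assignments must come from a single backend")
    a <- assignments[!is.na(assignments$taxon_id), , drop = FALSE]
    if (nrow(a) == 0L) return(integer(0))
    if (backend == "centrifuge") {
        stat <- tapply(a$score, a$taxon_id, mean)
        keep <- names(stat)[stat > config@centrifugeMeanScoreMin]
    } else {
        stat <- tapply(a$identity_pct, a$taxon_id, max)
        keep <- names(stat)[stat > config@blastIdentityMin]
    }
    sort(as.integer(keep))
}

#' Run-level statistics
#'
#' Summary statistics of a read pool: totals, mean/median length and
#' quality, read-length N50 and run duration. N50 is the largest read
#' length L such that reads of length >= L contain at least half of
#' all sequenced bases; it is always a length present in the pool.
#'
#' @param info per-read info data.frame (or \linkS4class{ReadSet}).
#' @return one-row data.frame: \code{total_reads}, \code{total_bases},
#'   \code{mean_length}, \code{median_length}, \code{mean_q},
#'   \code{median_q}, \code{n50}, \code{run_duration}.
#' @examples
#' info <- data.frame(read_id = letters[1:5], length = c(1, 2, 3, 4, 10),
#'                    mean_q = 10, start_time = 1:5)
#' runStats(info)$n50
#' @export
runStats <- function(info) {
    if (is(info, "ReadSet")) info <- readInfo(info)
    if (nrow(info) == 0L) stop("empty-run: no reads")
    len <- sort(info$length, decreasing = TRUE)
    cum <- cumsum(as.numeric(len))
    total <- cum[length(cum)]
    n50 <- len[which(cum >= total / 2)[1L]]
    data.frame(total_reads = nrow(info), total_bases = total,
               mean_length = mean(info$length),
               median_length = median(info$length),
               mean_q = mean(info$mean_q, na.rm = TRUE),
               median_q = median(info$mean_q, na.rm = TRUE),
               n50 = n50,
               run_duration = max(info$start_time) - min(info$start_time))
}

#' Time-to-next-read features
#'
#' Start times are sorted; gaps are successive differences. With a
#' single read the gap features are 0 (a deliberate choice: one-read
#' species are the low-CFU signal of interest and must not be dropped
#' by the missing-value rule). Reads-per-hour is computed over the
#' enclosing run duration; a degenerate (zero) duration is treated as
#' one second.
#'
#' @param startTimes numeric start times (seconds) of one (sample,
#'   species) group.
#' @param runDuration duration of the enclosing run, seconds.
#' @return one-row data.frame: \code{gap_mean}, \code{gap_median},
#'   \code{gap_max}, \code{reads_per_hour}.
#' @examples
#' timeGaps(c(0, 30, 90), runDuration = 3600)
#' @export
timeGaps <- function(startTimes, runDuration = max(startTimes) - min(startTimes)) {
    if (length(startTimes) == 0L) stop("invalid-input: no start times")
    if (any(startTimes < 0)) stop("invalid-input: negative start time")
    st <- sort(startTimes)
    gaps <- if (length(st) > 1L) diff(st) else 0
    span <- max(runDuration, 1)
    data.frame(gap_mean = mean(gaps), gap_median = median(gaps),
               gap_max = max(gaps),
               reads_per_hour = length(st) * 3600 / span)
}

## describe-style eight-number summary; sd over a single value is 0 by
## decision (missingness must not silently drop one-read species)
describeVec <- function(x, prefix) {
    if (anyNA(x)) {
        # leave the mean missing so the NaN-row rule can catch it
        out <- data.frame(length(x), NA_real_, NA_real_, NA_real_,
                          NA_real_, NA_real_, NA_real_, NA_real_)
        names(out) <- paste0(prefix, c("count", "mean", "sd", "min", "q25",
                                       "median", "q75", "max"))
        return(out)
    }
    s <- if (length(x) > 1L) sd(x) else 0
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    out <- data.frame(length(x), mean(x), s, min(x), q[1L], q[2L], q[3L],
                      max(x))
    names(out) <- paste0(prefix, c("count", "mean", "sd", "min", "q25",
                                   "median", "q75", "max"))
    out
}

#' Feature column names of the model-ready table
#'
#' The frozen, documented column order of the per-(sample, backend,
#' species) feature table.
#'
#' @return character vector of column names.
#' @export
featureTableColumns <- function() {
    c("sample_id", "backend", "taxon_id", "species", "read_count",
      paste0("q_", c("count", "mean", "sd", "min", "q25", "median", "q75",
                     "max")),
      paste0("len_", c("count", "mean", "sd", "min", "q25", "median", "q75",
                       "max")),
      "gap_mean", "gap_median", "gap_max", "reads_per_hour",
      paste0("run_", c("total_reads", "total_bases", "mean_length",
                       "median_length", "mean_q", "median_q", "n50",
                       "duration")))
}

#' Build the model-ready feature table
#'
#' One row per (sample, backend, surviving species): read count,
#' eight-number summaries of read quality and read length, inter-read
#' gap features, and the sample's run-level statistics. Host reads are
#' assumed already depleted from \code{readInfo}; the species filter
#' is applied per (sample, backend) group. Rows with missing read
#' count or mean read quality are removed. When \code{truths} is
#' supplied, label columns are attached: \code{sample_status} (1 =
#' contaminated sample) and \code{correctness} (1 = the predicted
#' species matches the spiked species).
#'
#' @param assignmentsByBackend named list of assignment data.frames;
#'   each must carry a \code{sample_id} column (or be a single-sample
#'   table, in which case \code{sampleId} applies).
#' @param readInfo per-read metadata with a \code{sample_id} column,
#'   restricted to the host-depleted read pool.
#' @param truths optional truth data.frame (sample_id, status,
#'   spiked_species).
#' @param config a \linkS4class{PipelineConfig}.
#' @param sampleId fallback sample id for single-sample inputs.
#' @return feature table data.frame in \code{\link{featureTableColumns}}
#'   order (+ label columns when truths are given).
#' @export
buildFeatureTable <- function(assignmentsByBackend, readInfo, truths = NULL,
                              config = pipelineConfig(),
                              sampleId = "sample") {
    if (!"sample_id" %in% names(readInfo))
        readInfo$sample_id <- sampleId
    allIds <- readInfo$read_id
    if (!config@includeFailReads)
        readInfo <- readInfo[readInfo$mean_q >= config@qPassThreshold, ,
                             drop = FALSE]
    rows <- list()
    for (backend in names(assignmentsByBackend)) {
        asg <- assignmentsByBackend[[backend]]
        if (nrow(asg) == 0L) next
        if (!"sample_id" %in% names(asg))
            asg$sample_id <- sampleId
        dangling <- setdiff(asg$read_id, allIds)
        if (length(dangling))
            stop("dangling-read: assignments reference reads absent from ",
                 "metadata (e.g. ", dangling[[1L]], ")")
        asg <- asg[asg$read_id %in% readInfo$read_id, , drop = FALSE]
        for (sid in unique(asg$sample_id)) {
            sampAsg <- asg[asg$sample_id == sid, , drop = FALSE]
            sampInfo <- readInfo[readInfo$sample_id == sid, , drop = FALSE]
            if (nrow(sampInfo) == 0L)
                stop("dangling-read: sample ", sid, " has no read metadata")
            rs <- runStats(sampInfo)
            names(rs) <- paste0("run_", c("total_reads", "total_bases",
                                          "mean_length", "median_length",
                                          "mean_q", "median_q", "n50",
                                          "duration"))
            surviving <- speciesFilter(sampAsg, config)
            for (taxon in surviving) {
                ids <- sampAsg$read_id[!is.na(sampAsg$taxon_id) &
                                       sampAsg$taxon_id == taxon]
                ri <- sampInfo[match(ids, sampInfo$read_id), , drop = FALSE]
                ri <- ri[!is.na(ri$read_id), , drop = FALSE]
                if (nrow(ri) == 0L) next
                row <- cbind(
                    data.frame(sample_id = sid, backend = backend,
                               taxon_id = taxon,
                               species = as.character(taxon),
                               read_count = nrow(ri),
                               stringsAsFactors = FALSE),
                    describeVec(ri$mean_q, "q_"),
                    describeVec(ri$length, "len_"),
                    timeGaps(ri$start_time, rs$run_duration),
                    rs)
                rows[[length(rows) + 1L]] <- row
            }
        }
    }
    if (length(rows) == 0L) {
        tab <- as.data.frame(setNames(
            rep(list(numeric(0)), length(featureTableColumns())),
            featureTableColumns()))
        tab$sample_id <- character(0)
        tab$backend <- character(0)
        tab$species <- character(0)
    } else {
        tab <- do.call(rbind, rows)
    }
    # NaN-row removal: species with missing read count or mean quality
    keep <- !is.na(tab$read_count) & !is.nan(tab$read_count) &
            !is.na(tab$q_mean) & !is.nan(tab$q_mean)
    tab <- tab[keep, , drop = FALSE]
    if (!is.null(truths) && nrow(tab) > 0L) {
        m <- match(tab$sample_id, truths$sample_id)
        if (anyNA(m)) stop("join error: feature rows without truth")
        tab$sample_status <- as.integer(truths$status[m] == "contaminated")
        spiked <- truths$spiked_species[m]
        tab$correctness <- as.integer(!is.na(spiked) &
                                      tab$taxon_id == spiked)
    } else if (!is.null(truths)) {
        tab$sample_status <- integer(0)
        tab$correctness <- integer(0)
    }
    rownames(tab) <- NULL
    tab
}
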