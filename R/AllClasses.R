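#' @import methods
NULL

#' Marker reference set
#'
#' A set of marker reference sequences (bacterial 16S, fungal 18S-28S
#' operon, host amplicon, kitome background) with a taxonomy table.
#' Sequence data live in a \link[Biostrings]{DNAStringSet}; the taxonomy
#' carries one row per reference: \code{taxon_id} (unique, >= 1),
#' \code{name}, \code{kind} (one of \code{bacterial_16S},
#' \code{fungal_18S28S}, \code{host}, \code{kitome}) and a logical
#' \code{complete} flag mirroring a "complete genome" annotation.
#'
#' @slot sequences \link[Biostrings]{DNAStringSet}, one entry per taxon,
#'   named by \code{taxon_id}.
#' @slot taxonomy data.frame with columns \code{taxon_id}, \code{name},
#'   \code{kind}, \code{complete}.
#' @exportClass TaxonRefSet
setClass("TaxonRefSet",
    representation(sequences = "ANY", taxonomy = "data.frame"))

setValidity("TaxonRefSet", function(object) {
    tx <- object@taxonomy
    need <- c("taxon_id", "name", "kind", "complete")
    if (!all(need %in% names(tx)))
        return(paste("taxonomy must have columns:", paste(need, collapse = ", ")))
    if (length(object@sequences) != nrow(tx))
        return("one taxonomy row per sequence required")
    if (anyDuplicated(tx$taxon_id))
        return("taxon_id must be unique within a reference set")
    if (any(tx$taxon_id < 1L))
        return("taxon_id must be >= 1")
    badKind <- setdiff(tx$kind, c("bacterial_16S", "fungal_18S28S", "host", "kitome"))
    if (length(badKind))
        return(paste("unknown kind:", paste(badKind, collapse = ", ")))
    if (sum(tx$kind == "host") > 1L)
        return("host present at most once per reference set")
    TRUE
})

#' @describeIn TaxonRefSet constructor
#' @param sequences DNAStringSet of reference sequences.
#' @param taxonomy data.frame as described above.
#' @export
TaxonRefSet <- function(sequences, taxonomy) {
    names(sequences) <- as.character(taxonomy$taxon_id)
    new("TaxonRefSet", sequences = sequences, taxonomy = taxonomy)
}

#' @describeIn TaxonRefSet reference sequences
#' @param x a TaxonRefSet.
#' @export
refSequences <- function(x) x@sequences

#' @describeIn TaxonRefSet taxonomy table
#' @export
refTaxonomy <- function(x) x@taxonomy

#' @describeIn TaxonRefSet taxon_id of the host reference (or NA)
#' @export
hostTaxon <- function(x) {
    id <- x@taxonomy$taxon_id[x@taxonomy$kind == "host"]
    if (length(id)) id[[1L]] else NA_integer_
}

setMethod("show", "TaxonRefSet", function(object) {
    tab <- table(object@taxonomy$kind)
    cat("TaxonRefSet with", nrow(object@taxonomy), "references (",
        paste(names(tab), tab, sep = ":", collapse = ", "), ")\n")
})

setMethod("length", "TaxonRefSet", function(x) nrow(x@taxonomy))

#' Set of sequenced reads with per-read metadata
#'
#' Reads from one sample (or one run): sequences plus the per-read
#' metadata consumed downstream -- mean phred quality, length, start time
#' and the pass/fail flag at the nanopore Q >= 7 boundary. Per-base
#' qualities, when present, are stored as phred+33 strings.
#'
#' @slot sequences \link[Biostrings]{DNAStringSet} named by read_id.
#' @slot qualities \link[Biostrings]{BStringSet} of phred+33 quality
#'   strings (may be empty, meaning "constant at the read mean").
#' @slot info data.frame with columns \code{read_id}, \code{barcode},
#'   \code{length}, \code{mean_q}, \code{start_time}, \code{pass_flag}.
#' @exportClass ReadSet
setClass("ReadSet",
    representation(sequences = "ANY", qualities = "ANY", info = "data.frame"))

setValidity("ReadSet", function(object) {
    info <- object@info
    need <- c("read_id", "barcode", "length", "mean_q", "start_time", "pass_flag")
    if (!all(need %in% names(info)))
        return(paste("info must have columns:", paste(need, collapse = ", ")))
    if (length(object@sequences) != nrow(info))
        return("one info row per sequence required")
    if (anyDuplicated(info$read_id))
        return("read_id must be unique")
    w <- Biostrings::width(object@sequences)
    if (!all(info$length == w))
        return("info$length must equal sequence widths")
    nq <- length(object@qualities)
    if (nq != 0L && nq != nrow(info))
        return("qualities must be empty or parallel to sequences")
    if (nq == nrow(info) && nq > 0L &&
        !all(Biostrings::width(object@qualities) == w))
        return("quality strings must match sequence widths")
    if (any(info$mean_q < 0) || any(info$start_time < 0))
        return("mean_q and start_time must be non-negative")
    if (!all(info$pass_flag == (info$mean_q >= 7)))
        return("pass_flag must equal (mean_q >= 7)")
    TRUE
})

#' @describeIn ReadSet constructor
#' @param sequences DNAStringSet named by read id.
#' @param info per-read metadata data.frame.
#' @param qualities optional BStringSet of phred+33 strings.
#' @export
ReadSet <- function(sequences, info, qualities = Biostrings::BStringSet()) {
    names(sequences) <- info$read_id
    new("ReadSet", sequences = sequences, qualities = qualities, info = info)
}

#' @describeIn ReadSet per-read metadata
#' @param x a ReadSet.
#' @export
readInfo <- function(x) x@info

#' @describeIn ReadSet read sequences
#' @export
readSequences <- function(x) x@sequences

setMethod("show", "ReadSet", function(object) {
    info <- object@info
    cat(sprintf("ReadSet with %d reads (%.1f%% pass, mean length %.0f)\n",
                nrow(info), 100 * mean(info$pass_flag),
                mean(info$length)))
})

setMethod("length", "ReadSet", function(x) nrow(x@info))

#' Canonical k-mer index over a marker reference set
#'
#' A flat, sorted table of (canonical k-mer code, taxon_id) pairs with
#' per-taxon distinct-k-mer totals, used by the built-in classifier.
#' Each k-mer is stored once under the lexicographically smaller of
#' itself and its reverse complement.
#'
#' @slot k k-mer size (7..26).
#' @slot codes sorted numeric vector of canonical 2-bit k-mer codes.
#' @slot taxa integer vector parallel to \code{codes}.
#' @slot kmerTotals named integer vector: distinct k-mers per taxon.
#' @slot taxonomy taxonomy table of the indexed references.
#' @exportClass KmerIndex
setClass("KmerIndex",
    representation(k = "integer", codes = "numeric", taxa = "integer",
                   kmerTotals = "integer", taxonomy = "data.frame"))

setValidity("KmerIndex", function(object) {
    if (object@k < 7L || object@k > 26L)
        return("k must be in 7..26")
    if (length(object@codes) != length(object@taxa))
        return("codes and taxa must be parallel")
    if (is.unsorted(object@codes))
        return("codes must be sorted")
    TRUE
})

#' @describeIn KmerIndex k-mer size
#' @param x a KmerIndex.
#' @export
indexK <- function(x) x@k

#' @describeIn KmerIndex distinct k-mers per taxon (named by taxon_id)
#' @export
indexKmerTotals <- function(x) x@kmerTotals

setMethod("show", "KmerIndex", function(object) {
    cat(sprintf("KmerIndex (k = %d): %d k-mer entries over %d taxa\n",
                object@k, length(object@codes), nrow(object@taxonomy)))
})

#' Pipeline configuration
#'
#' The tunable constants of the pipeline: the nanopore pass/fail
#' quality boundary, whether fail reads are retained, the two species
#' prediction filters (strict \code{>} in both cases), the split ratio
#' of the two-layer partition, and the number of cross-validation
#' folds.
#'
#' @slot qPassThreshold phred boundary between pass and fail reads
#'   (default 7).
#' @slot includeFailReads keep reads below the boundary (default TRUE).
#' @slot blastIdentityMin per-species maximum percent identity must
#'   exceed this for BLAST-like backends (default 83, strict >).
#' @slot centrifugeMeanScoreMin per-species mean score must exceed this
#'   for the Centrifuge backend (default 900, strict >).
#' @slot splitRatio proportion retained at each split layer (default 0.75).
#' @slot cvFolds cross-validation folds (default 5).
#' @slot decisionMatrix named character vector of the four decision
#'   matrix cells, see \code{\link{decisionMatrixDefault}}.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
    representation(qPassThreshold = "numeric", includeFailReads = "logical",
                   blastIdentityMin = "numeric", centrifugeMeanScoreMin = "numeric",
                   splitRatio = "numeric", cvFolds = "integer",
                   decisionMatrix = "character"))

setValidity("PipelineConfig", function(object) {
    if (object@splitRatio <= 0 || object@splitRatio >= 1)
        return("splitRatio must be in (0, 1)")
    if (object@qPassThreshold < 0 || object@blastIdentityMin < 0 ||
        object@centrifugeMeanScoreMin < 0)
        return("thresholds must be non-negative")
    if (object@cvFolds < 2L)
        return("cvFolds must be >= 2")
    need <- c("contaminated_correct", "contaminated_none",
              "sterile_none", "sterile_correct")
    if (!all(need %in% names(object@decisionMatrix)))
        return(paste("decisionMatrix needs cells:", paste(need, collapse = ", ")))
    TRUE
})

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig:\n",
        sprintf("  q pass threshold: %g (include fail reads: %s)\n",
                object@qPassThreshold, object@includeFailReads),
        sprintf("  identity filter: > %g%%; centrifuge mean score filter: > %g\n",
                object@blastIdentityMin, object@centrifugeMeanScoreMin),
        sprintf("  split ratio: %g; cv folds: %d\n",
                object@splitRatio, object@cvFolds), sep = "")
})

#' Trained classifier bundle
#'
#' One trained binary model together with everything needed to apply it
#' to new data: the fitted gradient-boosted ensemble, the standard
#' scaler (per-feature mean and sd fitted on the training partition
#' only), the ordered selected-feature list, the derived-column recipe
#' (squared and log10 columns added during augmentation), and training
#' metadata (seed, chosen grid point, cross-validated accuracy, label
#' definition, cv fold assignment).
#'
#' @slot model an \code{xgb.Booster}.
#' @slot scalerCenter,scalerScale named numeric vectors over the
#'   selected features.
#' @slot features ordered character vector of selected feature columns.
#' @slot derived list with elements \code{sq} and \code{log10}: base
#'   columns for which squared / log10 columns were generated.
#' @slot label \code{"sample_status"} or \code{"correctness"}.
#' @slot metadata list: seed, grid point chosen, cv accuracy, folds.
#' @exportClass ModelBundle
setClass("ModelBundle",
    representation(model = "ANY", scalerCenter = "numeric",
                   scalerScale = "numeric", features = "character",
                   derived = "list", label = "character", metadata = "list"))

setValidity("ModelBundle", function(object) {
    if (!object@label %in% c("sample_status", "correctness"))
        return("label must be sample_status or correctness")
    if (!all(object@features %in% names(object@scalerCenter)) ||
        !all(object@features %in% names(object@scalerScale)))
        return("every selected feature must have a scaler entry")
    TRUE
})

#' @describeIn ModelBundle selected feature columns, in rank order
#' @param x a ModelBundle.
#' @export
bundleFeatures <- function(x) x@features

#' @describeIn ModelBundle training metadata list
#' @export
bundleMetadata <- function(x) x@metadata

setMethod("show", "ModelBundle", function(object) {
    cat(sprintf("ModelBundle [%s]: %d features, cv accuracy %.3f\n",
                object@label, length(object@features),
                object@metadata$cv_accuracy))
})
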