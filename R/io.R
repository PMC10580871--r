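## On-disk interfaces: MinKNOW-style fastq_pass/ fastq_fail/ directories,
## the sequencing-summary TSV dialect, truth manifests, reference FASTA +
## taxonomy tables.

phredString <- function(q, len) {
    q <- pmax(0L, pmin(93L, as.integer(round(q))))
    vapply(seq_along(q), function(i)
        strrep(rawToChar(as.raw(33L + q[i])), len[i]), character(1))
}

#' Write a sample's reads as pass/fail FASTQ
#'
#' Writes 4-line phred+33 FASTQ split into \code{fastq_pass/} and
#' \code{fastq_fail/} subdirectories, mirroring the MinKNOW run layout.
#' When the \linkS4class{ReadSet} carries no per-base qualities, each
#' read's quality string is constant at its (rounded) mean quality.
#'
#' @param reads a \linkS4class{ReadSet}.
#' @param dir run directory; subdirectories are created as needed.
#' @param sampleId file stem, typically the sample id.
#' @return invisibly, the two file paths written.
#' @export
writeRunFastq <- function(reads, dir, sampleId) {
    info <- readInfo(reads)
    seqs <- readSequences(reads)
    quals <- reads@qualities
    if (length(quals) == 0L)
        quals <- Biostrings::BStringSet(phredString(info$mean_q, info$length))
    names(quals) <- info$read_id
    paths <- character(0)
    for (part in c(TRUE, FALSE)) {
        sub <- if (part) "fastq_pass" else "fastq_fail"
        d <- file.path(dir, sub)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        idx <- which(info$pass_flag == part)
        p <- file.path(d, paste0(sampleId, ".fastq"))
        Biostrings::writeXStringSet(seqs[idx], p, format = "fastq",
                                    qualities = quals[idx])
        paths <- c(paths, p)
    }
    invisible(paths)
}

#' Read FASTQ files into a ReadSet
#'
#' Mean read quality is the arithmetic mean of the per-base phred
#' scores; start times default to zero unless supplied through a
#' sequencing summary (see \code{\link{readSequencingSummary}}).
#'
#' @param files FASTQ paths (pass and/or fail files together).
#' @param barcode barcode label attached to every read.
#' @param summary optional sequencing-summary data.frame used to fill
#'   \code{start_time} (joined on read_id).
#' @return a \linkS4class{ReadSet}.
#' @export
readRunFastq <- function(files, barcode = "unknown", summary = NULL) {
    files <- files[file.exists(files) & file.size(files) > 0]
    if (length(files) == 0L)
        stop("no non-empty FASTQ files to read")
    parts <- lapply(files, function(f)
        Biostrings::readDNAStringSet(f, format = "fastq", with.qualities = TRUE))
    seqs <- do.call(c, parts)
    quals <- do.call(c, lapply(parts, function(p)
        S4Vectors::mcols(p)$qualities))
    meanQ <- vapply(as.character(quals), function(qs)
        mean(as.integer(charToRaw(qs))) - 33, numeric(1), USE.NAMES = FALSE)
    ids <- sub("\\s.*$", "", names(seqs))
    st <- rep(0, length(ids))
    if (!is.null(summary))
        st <- summary$start_time[match(ids, summary$read_id)]
    info <- data.frame(read_id = ids, barcode = barcode,
                       length = Biostrings::width(seqs),
                       mean_q = meanQ, start_time = st,
                       pass_flag = meanQ >= 7, stringsAsFactors = FALSE)
    ReadSet(seqs, info, Biostrings::BStringSet(quals))
}

#' Write / read the sequencing-summary TSV
#'
#' Columns: \code{read_id}, \code{barcode_arrangement},
#' \code{sequence_length_template}, \code{mean_qscore_template},
#' \code{start_time} (seconds), \code{passes_filtering} (TRUE/FALSE).
#'
#' @param reads a \linkS4class{ReadSet} or a per-read info data.frame.
#' @param path TSV path.
#' @return \code{readSequencingSummary}: data.frame with internal
#'   column names (read_id, barcode, length, mean_q, start_time,
#'   pass_flag).
#' @export
writeSequencingSummary <- function(reads, path) {
    info <- if (is(reads, "ReadSet")) readInfo(reads) else reads
    out <- data.frame(read_id = info$read_id,
                      barcode_arrangement = info$barcode,
                      sequence_length_template = info$length,
                      mean_qscore_template = info$mean_q,
                      start_time = info$start_time,
                      passes_filtering = info$pass_flag)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSequencingSummary
#' @export
readSequencingSummary <- function(path) {
    d <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
    data.frame(read_id = d$read_id, barcode = d$barcode_arrangement,
               length = d$sequence_length_template,
               mean_q = d$mean_qscore_template,
               start_time = d$start_time,
               pass_flag = as.logical(d$passes_filtering),
               stringsAsFactors = FALSE)
}

#' Write / read the truth manifest TSV
#'
#' Columns: sample_id, status, spiked_species, cfu_tier.
#'
#' @param truths data.frame of sample truths.
#' @param path TSV path.
#' @export
writeTruthManifest <- function(truths, path) {
    write.table(truths[, c("sample_id", "status", "spiked_species",
                           "cfu_tier")],
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTruthManifest
#' @export
readTruthManifest <- function(path) {
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read marker references as FASTA + taxonomy TSV
#'
#' The taxonomy table doubles as the subject-to-taxon mapping used by
#' \code{\link{parseBlast6}}: columns \code{sseqid} (the FASTA name),
#' \code{taxon_id}, \code{name}, \code{kind}, \code{complete}.
#'
#' @param refs a \linkS4class{TaxonRefSet}.
#' @param fastaPath,taxonomyPath output paths.
#' @export
writeReferences <- function(refs, fastaPath, taxonomyPath) {
    tx <- refTaxonomy(refs)
    seqs <- refSequences(refs)
    names(seqs) <- tx$name
    Biostrings::writeXStringSet(seqs, fastaPath)
    out <- data.frame(sseqid = tx$name, taxon_id = tx$taxon_id,
                      name = tx$name, kind = tx$kind,
                      complete = tx$complete)
    write.table(out, taxonomyPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(c(fastaPath, taxonomyPath))
}

#' @rdname writeReferences
#' @export
readReferences <- function(fastaPath, taxonomyPath) {
    seqs <- Biostrings::readDNAStringSet(fastaPath)
    tx <- read.table(taxonomyPath, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    taxonomy <- data.frame(taxon_id = tx$taxon_id, name = tx$name,
                           kind = tx$kind, complete = as.logical(tx$complete),
                           stringsAsFactors = FALSE)
    TaxonRefSet(seqs[match(tx$sseqid, sub("\\s.*$", "", names(seqs)))],
                taxonomy)
}

#' Write a feature table (stable, documented column order)
#'
#' @param table feature table from \code{\link{buildFeatureTable}}.
#' @param path TSV path.
#' @export
writeFeatureTable <- function(table, path) {
    write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
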