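## Read -> taxon assignment: built-in canonical k-mer classifier (a
## desk-scale stand-in for the genome-scale tools whose outputs can also
## be parsed), plus host-read depletion by read-ID subtraction.

#' Build a canonical k-mer index over a reference set
#'
#' Every k-mer of each reference is stored once under the
#' lexicographically smaller of itself and its reverse complement.
#' With \code{requireComplete = TRUE}, references whose taxonomy row is
#' not flagged \code{complete} are excluded before indexing, mirroring
#' a database built only from "complete genome" records.
#'
#' @param refs a \linkS4class{TaxonRefSet}.
#' @param k k-mer size (7..26; default 15).
#' @param requireComplete drop references not flagged complete.
#' @return a \linkS4class{KmerIndex}.
#' @examples
#' refs <- makeReferences(2, 1, seed = 1)
#' idx <- buildKmerIndex(refs, k = 15)
#' idx
#' @export
buildKmerIndex <- function(refs, k = 15L, requireComplete = FALSE) {
    k <- as.integer(k)
    if (k < 7L || k > 26L) stop("invalid-argument: k must be in 7..26")
    tx <- refTaxonomy(refs)
    keep <- if (requireComplete) which(tx$complete) else seq_len(nrow(tx))
    if (length(keep) == 0L)
        stop("empty-database: no references left after completeness filter")
    seqs <- as.character(refSequences(refs))[keep]
    taxa <- as.integer(tx$taxon_id[keep])
    built <- .build_index_cpp(seqs, taxa, k)
    new("KmerIndex", k = k, codes = built$codes,
        taxa = built$taxa,
        kmerTotals = setNames(built$totals, as.character(taxa)),
        taxonomy = tx[keep, , drop = FALSE])
}

emptyAssignment <- function() {
    data.frame(read_id = character(0), taxon_id = integer(0),
               score = numeric(0), identity_pct = numeric(0),
               backend = character(0), stringsAsFactors = FALSE)
}

#' Classify reads against a k-mer index
#'
#' For each read, every k-mer position is looked up in the index; the
#' best taxon is the one hit by the most positions (ties broken by
#' smallest taxon_id). The score is that hit count; percent identity
#' is 100 x (matching positions / total k-mer positions in the read),
#' a k-mer-level identity proxy. Reads with no hit -- including reads
#' shorter than k -- are unclassified (taxon_id NA, score and identity
#' zero).
#'
#' @param reads a \linkS4class{ReadSet}, a named
#'   \link[Biostrings]{DNAStringSet}, or a named character vector.
#' @param index a \linkS4class{KmerIndex}.
#' @return assignment data.frame: \code{read_id}, \code{taxon_id} (NA
#'   when unclassified), \code{score}, \code{identity_pct},
#'   \code{backend} (\code{"builtin"}).
#' @examples
#' refs <- makeReferences(2, 1, seed = 1)
#' idx <- buildKmerIndex(refs)
#' rd <- substr(as.character(refSequences(refs))[1], 1, 300)
#' classifyReads(c(r1 = rd), idx)
#' @export
classifyReads <- function(reads, index) {
    if (length(index@codes) == 0L) stop("empty-database: index is empty")
    if (is(reads, "ReadSet")) {
        ids <- readInfo(reads)$read_id
        seqs <- as.character(readSequences(reads))
    } else {
        seqs <- as.character(reads)
        ids <- names(reads) %||% sprintf("read%06d", seq_along(seqs))
    }
    if (length(seqs) == 0L) return(emptyAssignment())
    res <- .classify_cpp(seqs, index@codes, index@taxa, index@k)
    unclass <- is.na(res$taxon_id) | res$score == 0L
    data.frame(read_id = ids,
               taxon_id = ifelse(unclass, NA_integer_, res$taxon_id),
               score = ifelse(unclass, 0, as.numeric(res$score)),
               identity_pct = ifelse(unclass | res$n_kmers == 0L, 0,
                                     100 * res$score / pmax(1L, res$n_kmers)),
               backend = "builtin", stringsAsFactors = FALSE)
}

#' Parse Centrifuge tabular output
#'
#' Expects the 8-column Centrifuge read-level report with a header row
#' (readID, seqID, taxID, score, 2ndBestScore, hitLength, queryLength,
#' numMatches). taxID 0 is the Centrifuge convention for unclassified.
#' Percent identity is approximated as 100 x hitLength / queryLength
#' (Centrifuge reports no alignment identity); the proxy is
#' informational only -- the Centrifuge species filter uses the mean
#' score, never this value.
#'
#' @param path path to the tabular file.
#' @return assignment data.frame with \code{backend == "centrifuge"}.
#' @export
parseCentrifuge <- function(path) {
    lines <- readLines(path)
    if (length(lines) == 0L)
        stop("format error: missing Centrifuge header")
    hdr <- strsplit(lines[[1L]], "\t")[[1L]]
    if (length(hdr) < 8L || hdr[[1L]] != "readID")
        stop("format error: expected Centrifuge header starting with readID")
    if (length(lines) == 1L) return(emptyAssignment())
    rows <- strsplit(lines[-1L], "\t")
    bad <- which(vapply(rows, length, integer(1)) < 8L)
    if (length(bad))
        stop(sprintf("parse error at line %d: expected >= 8 columns",
                     bad[[1L]] + 1L))
    m <- do.call(rbind, rows)
    taxid <- suppressWarnings(as.integer(m[, 3L]))
    score <- suppressWarnings(as.numeric(m[, 4L]))
    hitLen <- suppressWarnings(as.numeric(m[, 6L]))
    qLen <- suppressWarnings(as.numeric(m[, 7L]))
    bad <- which(is.na(taxid) | is.na(score) | is.na(hitLen) | is.na(qLen))
    if (length(bad))
        stop(sprintf("parse error at line %d: non-numeric field",
                     bad[[1L]] + 1L))
    unclass <- taxid == 0L
    data.frame(read_id = m[, 1L],
               taxon_id = ifelse(unclass, NA_integer_, taxid),
               score = ifelse(unclass, 0, score),
               identity_pct = ifelse(unclass, 0, 100 * hitLen / qLen),
               backend = "centrifuge", stringsAsFactors = FALSE)
}

#' Parse BLAST outfmt-6 tabular output
#'
#' Standard 12-column outfmt 6 (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore), no header. Per
#' read, the single best hit by bitscore is kept (ties broken by
#' higher pident, then first occurrence). Subject ids are mapped to
#' taxa through \code{taxmap} (columns \code{sseqid},
#' \code{taxon_id}).
#'
#' @param path path to the outfmt-6 file.
#' @param taxmap data.frame mapping sseqid to taxon_id (e.g. the
#'   taxonomy TSV written by \code{\link{writeReferences}}).
#' @return assignment data.frame with \code{backend == "hsblastn"};
#'   \code{identity_pct} is pident, \code{score} is the bitscore.
#' @export
parseBlast6 <- function(path, taxmap) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (file.size(path) == 0L) return(emptyAssignment())
    d <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("qseqid", "sseqid", "pident", "length",
                                  "mismatch", "gapopen", "qstart", "qend",
                                  "sstart", "send", "evalue", "bitscore"))
    missing <- setdiff(unique(d$sseqid), taxmap$sseqid)
    if (length(missing))
        stop("unmapped-subject: no taxon mapping for ",
             paste(missing, collapse = ", "))
    # best hit per read: bitscore desc, then pident desc, then file order
    d$.ord <- seq_len(nrow(d))
    d <- d[order(d$qseqid, -d$bitscore, -d$pident, d$.ord), ]
    d <- d[!duplicated(d$qseqid), ]
    d <- d[order(d$.ord), ]
    data.frame(read_id = d$qseqid,
               taxon_id = taxmap$taxon_id[match(d$sseqid, taxmap$sseqid)],
               score = d$bitscore,
               identity_pct = d$pident,
               backend = "hsblastn", stringsAsFactors = FALSE)
}

#' Deplete host reads by read-ID subtraction
#'
#' The removed set is the union, over all supplied backends, of read
#' IDs assigned to the host taxon -- the most aggressive removal,
#' matching the goal of subtracting the maximum number of host reads.
#'
#' @param assignmentsByBackend named list of assignment data.frames
#'   (one per backend; backends may disagree).
#' @param hostTaxon taxon_id designated as host.
#' @param allReadIds character vector of every read ID in the pool.
#' @return list with \code{kept_read_ids}, \code{removed_read_ids} and
#'   \code{host_fraction} (= removed / total).
#' @examples
#' a <- data.frame(read_id = c("r1", "r2"), taxon_id = 9L, score = 1,
#'                 identity_pct = 100, backend = "builtin")
#' depleteHost(list(builtin = a), 9L, paste0("r", 1:5))$host_fraction
#' @export
depleteHost <- function(assignmentsByBackend, hostTaxon, allReadIds) {
    allReadIds <- unique(allReadIds)
    if (length(allReadIds) == 0L)
        stop("division-undefined: empty read pool")
    removed <- unique(unlist(lapply(assignmentsByBackend, function(a) {
        a$read_id[!is.na(a$taxon_id) & a$taxon_id == hostTaxon]
    })))
    removed <- intersect(removed, allReadIds)
    list(kept_read_ids = setdiff(allReadIds, removed),
         removed_read_ids = removed,
         host_fraction = length(removed) / length(allReadIds))
}
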