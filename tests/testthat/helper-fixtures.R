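# Shared fixtures and the pure-R brute-force oracles used against the
# C++ classifier path.

revComp <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# all canonical k-mers of s, one per position (duplicates kept)
bruteKmers <- function(s, k) {
    n <- nchar(s)
    if (n < k) return(character(0))
    km <- substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
    vapply(km, function(x) min(x, revComp(x)), character(1),
           USE.NAMES = FALSE)
}

# brute-force classification: count canonical k-mer positions of the read
# hitting each reference (by direct membership in the reference's
# canonical k-mer set); ties broken by smallest taxon_id
bruteClassify <- function(read, refs, k) {
    tx <- refTaxonomy(refs)
    refSets <- lapply(as.character(refSequences(refs)),
                      function(s) unique(bruteKmers(s, k)))
    rk <- bruteKmers(read, k)
    counts <- vapply(refSets, function(set) sum(rk %in% set), numeric(1))
    if (length(rk) == 0L || max(counts) == 0)
        return(list(taxon_id = NA_integer_, score = 0, identity_pct = 0))
    best <- which(counts == max(counts))[1L]
    list(taxon_id = tx$taxon_id[best], score = max(counts),
         identity_pct = 100 * max(counts) / length(rk))
}

smallRefs <- function(seed = 101) {
    makeReferences(3, 1, len16S = 600, lenOperon = 1000, nKitome = 2,
                   lenHost = 1500, lenKitome = 500, seed = seed)
}

smallCohort <- function(refs = smallRefs(), seed = 202,
                        n = c(`10` = 4, `100` = 4, sterile = 4),
                        depth = 200) {
    simulateCohort(n, refs, depth = depth, seed = seed)
}

# linearly separable two-feature table: cluster centers 4 sd apart with
# the noise truncated at +/- 1.5 sd, so the classes are separated by a
# guaranteed margin (no draw can cross the midpoint)
separableTable <- function(n = 200, seed = 99, label = "sample_status") {
    set.seed(seed)
    rtn <- function(n, mean, sd, half) {
        qnorm(runif(n, pnorm(-half / sd), pnorm(half / sd))) * sd + mean
    }
    y <- rep(c(0L, 1L), length.out = n)
    tab <- data.frame(sample_id = sprintf("fx_%03d", seq_len(n)),
                      f1 = rtn(n, ifelse(y == 1, 14, 10), 1, 1.5),
                      f2 = rtn(n, ifelse(y == 1, 3, 7), 1, 1.5),
                      stringsAsFactors = FALSE)
    tab[[label]] <- y
    tab
}

# random assignment table for filter / depletion property tests
randomAssignments <- function(n, backend, seed) {
    set.seed(seed)
    data.frame(read_id = sprintf("r%04d", seq_len(n)),
               taxon_id = sample(c(NA, 1:6), n, replace = TRUE),
               score = runif(n, 0, 1500),
               identity_pct = runif(n, 0, 100),
               backend = backend, stringsAsFactors = FALSE)
}
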