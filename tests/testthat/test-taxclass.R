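test_that("index construction canonicalizes strands and filters incomplete refs", {
    tx <- data.frame(taxon_id = 1L, name = "t1", kind = "bacterial_16S",
                     complete = TRUE)
    refs <- TaxonRefSet(Biostrings::DNAStringSet("ACGTACGTACGT"), tx)
    idx <- buildKmerIndex(refs, k = 7)
    # brute-force: distinct canonical 7-mers of the sequence
    expect_equal(unname(indexKmerTotals(idx)["1"]),
                 length(unique(bruteKmers("ACGTACGTACGT", 7))))

    # completeness filter removes flagged references
    tx2 <- data.frame(taxon_id = 1:2, name = c("a", "b"),
                      kind = "bacterial_16S", complete = c(TRUE, FALSE))
    refs2 <- TaxonRefSet(Biostrings::DNAStringSet(
        c(paste(rep("ACGTTGCA", 4), collapse = ""),
          paste(rep("TTTTCCCC", 4), collapse = ""))), tx2)
    idx2 <- buildKmerIndex(refs2, k = 7, requireComplete = TRUE)
    expect_false("2" %in% names(indexKmerTotals(idx2)))
    tx3 <- tx2
    tx3$complete <- FALSE
    refs3 <- TaxonRefSet(refSequences(refs2), tx3)
    expect_error(buildKmerIndex(refs3, requireComplete = TRUE),
                 "empty-database")

    # determinism
    idxa <- buildKmerIndex(smallRefs(), k = 15)
    idxb <- buildKmerIndex(smallRefs(), k = 15)
    expect_identical(idxa@codes, idxb@codes)
    expect_identical(idxa@taxa, idxb@taxa)
})

test_that("built-in classification matches the brute-force k-mer oracle", {
    refs <- smallRefs()
    idx <- buildKmerIndex(refs, k = 15)
    refChr <- as.character(refSequences(refs))
    set.seed(42)
    # error-free fragments from every reference
    reads <- unlist(lapply(seq_along(refChr), function(i) {
        vapply(1:4, function(j) {
            len <- sample(100:300, 1)
            st <- sample(nchar(refChr[i]) - len, 1)
            substr(refChr[i], st, st + len - 1)
        }, character(1))
    }))
    names(reads) <- sprintf("r%02d", seq_along(reads))
    got <- classifyReads(reads, idx)
    for (i in seq_along(reads)) {
        want <- bruteClassify(reads[[i]], refs, 15)
        expect_equal(got$taxon_id[i], want$taxon_id)
        expect_equal(got$score[i], want$score)
        expect_equal(got$identity_pct[i], want$identity_pct)
    }
    # error-free reads from disjoint refs: identity is exactly 100
    expect_true(all(got$identity_pct == 100))
})

test_that("partial matches, strand symmetry and degenerate reads behave", {
    refs <- smallRefs()
    idx <- buildKmerIndex(refs, k = 15)
    refChr <- as.character(refSequences(refs))

    # read half from reference 1, half random: identity equals the
    # brute-force membership count
    set.seed(7)
    mixed <- paste0(substr(refChr[[1]], 11, 160),
                    paste(sample(c("A", "C", "G", "T"), 150, TRUE),
                          collapse = ""))
    got <- classifyReads(c(m1 = mixed), idx)
    want <- bruteClassify(mixed, refs, 15)
    expect_equal(got$identity_pct, want$identity_pct)
    expect_equal(got$taxon_id, refTaxonomy(refs)$taxon_id[1])
    expect_gt(got$identity_pct, 40)
    expect_lt(got$identity_pct, 60)

    # strand symmetry: a read and its reverse complement agree
    rc <- revComp(substr(refChr[[2]], 21, 220))
    fw <- substr(refChr[[2]], 21, 220)
    gotF <- classifyReads(c(r = fw), idx)
    gotR <- classifyReads(c(r = rc), idx)
    expect_equal(gotF$taxon_id, gotR$taxon_id)
    expect_equal(gotF$identity_pct, gotR$identity_pct)

    # a read sharing no k-mer with any reference is unclassified,
    # as is a read shorter than k
    set.seed(1)
    junk <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    while (bruteClassify(junk, refs, 15)$score > 0)
        junk <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    got <- classifyReads(c(j = junk, tiny = "ACGTACGT"), idx)
    expect_true(all(is.na(got$taxon_id)))
    expect_true(all(got$score == 0))
    expect_true(all(got$identity_pct == 0))
})

test_that("host depletion is the union across backends and partitions the pool", {
    a1 <- data.frame(read_id = c("r1", "r2"), taxon_id = 9L, score = 1,
                     identity_pct = 100, backend = "builtin")
    a2 <- data.frame(read_id = c("r2", "r3"), taxon_id = 9L, score = 1,
                     identity_pct = 100, backend = "centrifuge")
    all5 <- paste0("r", 1:5)
    dep <- depleteHost(list(b1 = a1, b2 = a2), 9L, all5)
    expect_setequal(dep$kept_read_ids, c("r4", "r5"))
    expect_equal(dep$host_fraction, 0.6)

    # no backend assigns host
    none <- depleteHost(list(b1 = transform(a1, taxon_id = 2L)), 9L, all5)
    expect_setequal(none$kept_read_ids, all5)
    expect_equal(none$host_fraction, 0)

    # all host
    allh <- depleteHost(list(b1 = data.frame(read_id = all5, taxon_id = 9L,
                                             score = 1, identity_pct = 100,
                                             backend = "builtin")),
                        9L, all5)
    expect_length(allh$kept_read_ids, 0)
    expect_equal(allh$host_fraction, 1.0)
    expect_error(depleteHost(list(b1 = a1), 9L, character(0)),
                 "division-undefined")

    # idempotence and anti-monotonicity: adding a backend never grows kept
    dep1 <- depleteHost(list(b1 = a1), 9L, all5)
    dep12 <- depleteHost(list(b1 = a1, b2 = a2), 9L, all5)
    expect_true(all(dep12$kept_read_ids %in% dep1$kept_read_ids))
    depTwice <- depleteHost(list(b1 = a1, b1again = a1), 9L, all5)
    expect_setequal(depTwice$kept_read_ids, dep1$kept_read_ids)
})

test_that("Centrifuge tabular output parses per its format definition", {
    d <- withr::local_tempdir()
    p <- file.path(d, "cent.tsv")
    writeLines(c(
        paste(c("readID", "seqID", "taxID", "score", "2ndBestScore",
                "hitLength", "queryLength", "numMatches"), collapse = "\t"),
        "r1\tsp1\t42\t1225\t0\t800\t1000\t1",
        "r2\tunclassified\t0\t0\t0\t0\t500\t1"), p)
    asg <- parseCentrifuge(p)
    expect_equal(asg$read_id, c("r1", "r2"))
    expect_equal(asg$taxon_id[1], 42L)
    expect_equal(asg$score[1], 1225)
    expect_equal(asg$identity_pct[1], 80.0)
    expect_equal(asg$backend, rep("centrifuge", 2))
    # taxID 0 is unclassified
    expect_true(is.na(asg$taxon_id[2]))
    expect_equal(asg$score[2], 0)

    # empty after header
    writeLines(paste(c("readID", "seqID", "taxID", "score", "2ndBestScore",
                       "hitLength", "queryLength", "numMatches"),
                     collapse = "\t"), p)
    expect_equal(nrow(parseCentrifuge(p)), 0L)

    # malformed rows and missing header
    writeLines(c("readID\tseqID\ttaxID\tscore\t2nd\thitLength\tqueryLength\tnumMatches",
                 "r1\tsp1\t42"), p)
    expect_error(parseCentrifuge(p), "line 2")
    writeLines("r1\tsp1\t42\t10\t0\t5\t10\t1", p)
    expect_error(parseCentrifuge(p), "format error")
})

test_that("BLAST outfmt-6 parsing keeps the best hit per read", {
    d <- withr::local_tempdir()
    p <- file.path(d, "hits.tsv")
    taxmap <- data.frame(sseqid = c("sp1", "sp2"), taxon_id = c(5L, 6L))
    row <- function(q, s, pid, bits)
        paste(q, s, pid, 100, 1, 0, 1, 100, 1, 100, "1e-20", bits,
              sep = "\t")
    writeLines(c(row("r1", "sp1", 97.3, 512),
                 row("r1", "sp2", 99.9, 300),
                 row("r2", "sp2", 88.0, 200),
                 row("r3", "sp1", 91.5, 150)), p)
    asg <- parseBlast6(p, taxmap)
    expect_equal(nrow(asg), 3L)
    r1 <- asg[asg$read_id == "r1", ]
    expect_equal(r1$identity_pct, 97.3)
    expect_equal(r1$score, 512)
    expect_equal(r1$taxon_id, 5L)
    expect_equal(asg$backend, rep("hsblastn", 3))

    writeLines(row("r1", "mystery", 90, 100), p)
    expect_error(parseBlast6(p, taxmap), "unmapped-subject.*mystery")
})
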