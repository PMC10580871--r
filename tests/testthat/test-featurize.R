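test_that("quality partition counts pass/fail and the additional-read fraction", {
    info <- data.frame(read_id = c("a", "b", "c"),
                       mean_q = c(8.1, 6.9, 12.0))
    p <- partitionQuality(info, 7)
    expect_length(p$pass_ids, 2)
    expect_length(p$fail_ids, 1)
    expect_equal(p$additional_fraction, 0.5)

    p0 <- partitionQuality(info, 0)
    expect_length(p0$fail_ids, 0)
    expect_equal(p0$additional_fraction, 0)

    expect_error(partitionQuality(info, 100), "undefined-baseline")
    empty <- partitionQuality(info[0, , drop = FALSE], 7)
    expect_equal(empty$additional_fraction, 0)
})

test_that("species filters apply strict thresholds per backend", {
    cfg <- pipelineConfig()
    mkAsg <- function(taxa, stat, backend, col) {
        d <- data.frame(read_id = sprintf("r%03d", seq_along(taxa)),
                        taxon_id = taxa, score = 0, identity_pct = 0,
                        backend = backend)
        d[[col]] <- stat
        d
    }
    # hsblastn: keep iff max identity strictly > 83
    a <- mkAsg(c(1L, 1L, 2L, 3L), c(95.2, 60, 82.9, 83.0), "hsblastn",
               "identity_pct")
    expect_equal(speciesFilter(a, cfg), 1L)
    # centrifuge: keep iff mean score strictly > 900
    b <- mkAsg(c(1L, 2L, 2L), c(1200, 900, 900), "centrifuge", "score")
    expect_equal(speciesFilter(b, cfg), 1L)
    # unclassified never survives
    u <- mkAsg(c(NA, NA), c(99, 99), "builtin", "identity_pct")
    expect_length(speciesFilter(u, cfg), 0)
    # mixed backends rejected
    mixed <- rbind(a, b)
    expect_error(speciesFilter(mixed, cfg), "invalid-input")
})

test_that("raising filter thresholds never grows the surviving set", {
    for (case in 1:50) {
        asg <- randomAssignments(60, "hsblastn", seed = 1000 + case)
        lo <- speciesFilter(asg, pipelineConfig(blastIdentityMin = 40))
        hi <- speciesFilter(asg, pipelineConfig(blastIdentityMin = 70))
        expect_true(all(hi %in% lo))
        asgC <- randomAssignments(60, "centrifuge", seed = 2000 + case)
        loC <- speciesFilter(asgC, pipelineConfig(centrifugeMeanScoreMin = 400))
        hiC <- speciesFilter(asgC, pipelineConfig(centrifugeMeanScoreMin = 900))
        expect_true(all(hiC %in% loC))
    }
})

test_that("run statistics compute N50, totals and duration", {
    info <- data.frame(read_id = letters[1:5], length = c(1, 2, 3, 4, 10),
                       mean_q = c(8, 9, 10, 11, 12), start_time = 0:4)
    rs <- runStats(info)
    expect_equal(rs$total_bases, 20)
    expect_equal(rs$n50, 10)
    expect_equal(rs$run_duration, 4)

    one <- runStats(data.frame(read_id = "a", length = 500, mean_q = 9,
                               start_time = 100))
    expect_equal(one$n50, 500)
    expect_equal(one$run_duration, 0)

    unif <- runStats(data.frame(read_id = letters[1:4], length = 5,
                                mean_q = 9, start_time = 1:4))
    expect_equal(unif$n50, 5)
    expect_error(runStats(info[0, , drop = FALSE]), "empty-run")
    # N50 is always a length present in the run (brute-force check)
    set.seed(3)
    for (i in 1:20) {
        lens <- sample(100:2000, 30, replace = TRUE)
        d <- data.frame(read_id = as.character(seq_along(lens)),
                        length = lens, mean_q = 9,
                        start_time = seq_along(lens))
        n50 <- runStats(d)$n50
        expect_true(n50 %in% lens)
        expect_gte(sum(lens[lens >= n50]), sum(lens) / 2)
    }
})

test_that("time gaps sort inputs and handle the single-read case", {
    g <- timeGaps(c(0, 30, 90), runDuration = 3600)
    expect_equal(g$gap_mean, 45)
    expect_equal(g$gap_max, 60)
    # permutation invariance
    expect_equal(timeGaps(c(90, 0, 30), runDuration = 3600), g)
    # single read: gaps are zero, rate over the enclosing duration
    s <- timeGaps(5, runDuration = 7200)
    expect_equal(s$gap_mean, 0)
    expect_equal(s$gap_max, 0)
    expect_equal(s$reads_per_hour, 0.5)
    expect_error(timeGaps(c(-1, 5)), "invalid-input")
})

test_that("the feature table summarizes per species and drops incomplete rows", {
    cfg <- pipelineConfig()
    info <- data.frame(
        read_id = sprintf("r%d", 1:6),
        barcode = "bc", sample_id = "s1",
        length = c(1000, 1200, 900, 1100, 800, 950),
        mean_q = c(10, 12, 9, 11, NA, 8),
        start_time = c(0, 30, 90, 120, 150, 180),
        pass_flag = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
    asg <- data.frame(read_id = sprintf("r%d", 1:6),
                      taxon_id = c(1L, 1L, 2L, 2L, 3L, 3L),
                      score = 50,
                      identity_pct = c(95, 90, 99, 98, 97, 96),
                      backend = "builtin", sample_id = "s1")
    truths <- data.frame(sample_id = "s1", status = "contaminated",
                         spiked_species = 1L, cfu_tier = 10L)
    tab <- buildFeatureTable(list(builtin = asg), info, truths, cfg)
    r1 <- tab[tab$taxon_id == 1L, ]
    expect_equal(r1$read_count, 2)
    expect_equal(r1$q_mean, 11)
    expect_equal(r1$q_sd, sqrt(2))
    expect_equal(r1$len_mean, 1100)
    expect_equal(r1$gap_mean, 30)
    expect_equal(r1$sample_status, 1L)
    expect_equal(r1$correctness, 1L)
    r2 <- tab[tab$taxon_id == 2L, ]
    expect_equal(r2$correctness, 0L)
    # taxon 3 has a read with missing quality -> NaN mean -> row dropped
    expect_false(3L %in% tab$taxon_id)
    # run-level columns are shared across rows of the sample
    expect_equal(unique(tab$run_total_reads), 6)
    # assignments referencing unknown reads are a hard error
    bad <- asg
    bad$read_id[1] <- "ghost"
    expect_error(buildFeatureTable(list(builtin = bad), info, truths, cfg),
                 "dangling-read")
})

test_that("sterile samples with kitome species get zero labels", {
    info <- data.frame(read_id = "r1", barcode = "bc", sample_id = "st1",
                       length = 500, mean_q = 9, start_time = 10,
                       pass_flag = TRUE)
    asg <- data.frame(read_id = "r1", taxon_id = 7L, score = 20,
                      identity_pct = 92, backend = "builtin",
                      sample_id = "st1")
    truths <- data.frame(sample_id = "st1", status = "sterile",
                         spiked_species = NA_integer_, cfu_tier = 0L)
    tab <- buildFeatureTable(list(builtin = asg), info, truths)
    expect_equal(nrow(tab), 1L)
    expect_equal(tab$sample_status, 0L)
    expect_equal(tab$correctness, 0L)
    expect_equal(tab$read_count, 1)
    # single-read gap features are zero, not missing
    expect_equal(tab$gap_mean, 0)
    expect_false(anyNA(tab))
})

test_that("including fail reads never decreases a species read count", {
    refs <- smallRefs()
    co <- smallCohort(refs, seed = 17, n = c(`10` = 2, `100` = 2, sterile = 1),
                      depth = 150)
    withFail <- featurizeCohort(co, refs, pipelineConfig())$features
    noFail <- featurizeCohort(co, refs,
                              pipelineConfig(includeFailReads = FALSE))$features
    key <- function(t) paste(t$sample_id, t$taxon_id)
    m <- match(key(noFail), key(withFail))
    expect_false(anyNA(m))
    expect_true(all(noFail$read_count <= withFail$read_count[m]))
    # row conservation: per-sample read counts never exceed classified reads
    ft <- featurizeCohort(co, refs)
    for (sid in unique(ft$features$sample_id)) {
        nAssigned <- sum(!is.na(ft$assignments$taxon_id) &
                         ft$assignments$sample_id == sid)
        expect_lte(sum(ft$features$read_count[ft$features$sample_id == sid]),
                   nAssigned)
    }
})
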