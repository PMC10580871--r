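## Synthetic marker references and amplicon runs.
##
## The generator reproduces the statistical structure the downstream
## pipeline assumes: ~98% host reads, contaminant reads at tiers mimicking
## 10 and 100 CFU/mL spikes, trace kitome background in every sample,
## per-read mean quality spanning the pass/fail boundary (Q = 7), and
## exponential inter-arrival start times.

randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## truncated normal draw on [lo, hi)
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
    plo <- pnorm(lo, mean, sd)
    phi <- pnorm(hi, mean, sd)
    qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic marker reference set
#'
#' Random DNA references with enforced canonical k-mer dissimilarity
#' (every non-host pair shares < 5% of its distinct k-mers at the given
#' k), so that the built-in classifier has a verifiable oracle. One
#' host reference is always included; kitome references model the
#' trace background species introduced by extraction and library kits.
#'
#' @param nBacterial,nFungal number of bacterial 16S / fungal 18S-28S
#'   references (>= 1).
#' @param len16S,lenOperon reference lengths in bases (>= 200).
#' @param nKitome number of kitome background references (default 0).
#' @param lenHost,lenKitome lengths of the host and kitome references.
#' @param k k-mer size used for the dissimilarity guarantee.
#' @param seed integer seed; output is a pure function of the arguments.
#' @return a \linkS4class{TaxonRefSet}.
#' @examples
#' refs <- makeReferences(3, 1, seed = 1)
#' refs
#' @export
makeReferences <- function(nBacterial, nFungal, len16S = 1450,
                           lenOperon = 4000, nKitome = 0L,
                           lenHost = 8000, lenKitome = 1200,
                           k = 15L, seed = 1L) {
    if (nBacterial < 1 || nFungal < 1 || nKitome < 0)
        stop("invalid-argument: counts must be positive")
    if (len16S < 200 || lenOperon < 200 || lenHost < 200 || lenKitome < 200)
        stop("invalid-argument: reference lengths must be >= 200")
    set.seed(seed)
    kinds <- c(rep("bacterial_16S", nBacterial),
               rep("fungal_18S28S", nFungal),
               rep("kitome", nKitome), "host")
    lens <- c(rep(len16S, nBacterial), rep(lenOperon, nFungal),
              rep(lenKitome, nKitome), lenHost)
    n <- length(kinds)
    seqs <- character(n)
    codeSets <- vector("list", n)
    for (i in seq_len(n)) {
        for (try in 1:100) {
            s <- randomDna(lens[i])
            cs <- unique(.canonical_codes(s, as.integer(k))[[1L]])
            ok <- TRUE
            for (j in seq_len(i - 1L)) {
                shared <- length(intersect(cs, codeSets[[j]])) /
                    min(length(cs), length(codeSets[[j]]))
                if (shared >= 0.05) { ok <- FALSE; break }
            }
            if (ok) break
        }
        if (!ok) stop("could not generate a sufficiently distinct reference")
        seqs[i] <- s
        codeSets[[i]] <- cs
    }
    nm <- c(sprintf("Bacterium_%02d", seq_len(nBacterial)),
            sprintf("Fungus_%02d", seq_len(nFungal)),
            if (nKitome > 0) sprintf("Kitome_%02d", seq_len(nKitome)),
            "Host")
    taxonomy <- data.frame(taxon_id = seq_len(n), name = nm, kind = kinds,
                           complete = TRUE, stringsAsFactors = FALSE)
    TaxonRefSet(Biostrings::DNAStringSet(seqs), taxonomy)
}

## Fragment-length model per reference kind: 16S-origin reads near full
## amplicon length; 18S-28S-origin reads as shorter fragments; host and
## kitome reads amplicon-sized.
fragmentLength <- function(kind, refLen, n) {
    base <- switch(kind,
        bacterial_16S = refLen * runif(n, 0.90, 1.00),
        fungal_18S28S = refLen * runif(n, 0.20, 0.60),
        host = pmin(refLen, 1450) * runif(n, 0.90, 1.00),
        kitome = pmin(refLen, 1450) * runif(n, 0.90, 1.00))
    pmax(60L, pmin(refLen, as.integer(round(base))))
}

## i.i.d. per-base errors at equal thirds substitution/insertion/deletion
mutateSeq <- function(s, errorRate) {
    L <- nchar(s)
    nerr <- rbinom(1L, L, errorRate)
    if (nerr == 0L) return(s)
    x <- charToRaw(s)
    type <- sample.int(3L, nerr, replace = TRUE)
    bases <- charToRaw("ACGT")
    ns <- sum(type == 1L)
    if (ns > 0L) {
        pos <- sample.int(length(x), min(ns, length(x)))
        x[pos] <- bases[sample.int(4L, length(pos), replace = TRUE)]
    }
    nd <- sum(type == 2L)
    if (nd > 0L && length(x) - nd >= 60L)
        x <- x[-sample.int(length(x), nd)]
    ni <- sum(type == 3L)
    if (ni > 0L) {
        pos <- sample.int(length(x) + 1L, ni, replace = TRUE)
        ins <- bases[sample.int(4L, ni, replace = TRUE)]
        # inserted bases sort in just before their target position
        at <- c(seq_along(x), pos - 0.5)
        x <- c(x, ins)[order(at)]
    }
    rawToChar(x)
}

#' Simulate one amplicon run sample
#'
#' Draws \code{depth} reads whose origins follow a multinomial over
#' host, spiked contaminant, kitome background and an unclassifiable
#' remainder; each read is an error-perturbed fragment of its source
#' reference. Per-read mean quality is drawn from a two-component
#' distribution straddling the pass/fail boundary; start times have
#' exponential inter-arrival gaps.
#'
#' @param truth list or one-row data.frame with \code{sample_id},
#'   \code{status} ("contaminated" or "sterile"), \code{spiked_species}
#'   (taxon_id or NA), \code{cfu_tier} (10, 100 or 0) and
#'   \code{host_fraction}.
#' @param refs a \linkS4class{TaxonRefSet}.
#' @param depth number of reads to draw (>= 1).
#' @param contamFraction expected fraction of reads from the spiked
#'   species (0 for sterile samples).
#' @param kitomeFraction expected fraction of reads from kitome
#'   references, split evenly among them.
#' @param errorRate per-base error probability, applied as equal thirds
#'   substitution / insertion / deletion.
#' @param qualityModel list with \code{passMeanQ}, \code{failMeanQ},
#'   \code{failProb}: a read is drawn from the fail component (mean
#'   quality truncated below Q7) with probability \code{failProb},
#'   otherwise from the pass component (truncated at or above Q7).
#' @param gapRate rate (1/seconds) of the exponential inter-read gaps.
#' @param seed integer seed.
#' @return list with elements \code{reads} (a \linkS4class{ReadSet}),
#'   \code{truth}, and \code{provenance} (data.frame read_id, origin,
#'   taxon_id; taxon_id 0 marks unclassifiable filler reads).
#' @examples
#' refs <- makeReferences(2, 1, nKitome = 1, seed = 1)
#' tr <- list(sample_id = "s1", status = "contaminated",
#'            spiked_species = 1L, cfu_tier = 10, host_fraction = 0.9)
#' sim <- simulateSample(tr, refs, depth = 50, contamFraction = 0.05,
#'                       seed = 2)
#' table(sim$provenance$origin)
#' @export
simulateSample <- function(truth, refs, depth = 1000,
                           contamFraction = 0,
                           kitomeFraction = 0.006,
                           errorRate = 0.005,
                           qualityModel = list(passMeanQ = 11,
                                               failMeanQ = 5,
                                               failProb = 0.0645),
                           gapRate = 0.5, seed = 1L) {
    truth <- as.list(truth)
    if (depth < 1) stop("invalid-argument: depth must be >= 1")
    tx <- refTaxonomy(refs)
    spiked <- truth$spiked_species
    contaminated <- identical(truth$status, "contaminated")
    if (contaminated) {
        if (is.null(spiked) || is.na(spiked) || !spiked %in% tx$taxon_id)
            stop("unknown-taxon: spiked_species not in reference set")
    } else contamFraction <- 0
    hf <- truth$host_fraction
    if (hf + contamFraction + kitomeFraction > 1 + 1e-9)
        stop("invalid-argument: host + contaminant + kitome fractions exceed 1")
    set.seed(seed)

    kitomeTaxa <- tx$taxon_id[tx$kind == "kitome"]
    hostId <- hostTaxon(refs)
    origins <- c(if (!is.na(hostId)) hostId,
                 if (contaminated) spiked,
                 kitomeTaxa, 0L)
    probs <- c(if (!is.na(hostId)) hf,
               if (contaminated) contamFraction,
               rep(kitomeFraction / max(1L, length(kitomeTaxa)),
                   length(kitomeTaxa)),
               max(0, 1 - hf - contamFraction - kitomeFraction))
    originTaxon <- sample(origins, depth, replace = TRUE, prob = probs)

    seqsChr <- character(depth)
    refChr <- as.character(refSequences(refs))
    names(refChr) <- as.character(tx$taxon_id)
    for (t in unique(originTaxon)) {
        idx <- which(originTaxon == t)
        if (t == 0L) {
            lens <- as.integer(round(runif(length(idx), 300, 800)))
            seqsChr[idx] <- vapply(lens, randomDna, character(1))
        } else {
            kind <- tx$kind[tx$taxon_id == t]
            ref <- refChr[[as.character(t)]]
            refLen <- nchar(ref)
            lens <- fragmentLength(kind, refLen, length(idx))
            starts <- as.integer(floor(runif(length(idx), 1, refLen - lens + 2)))
            seqsChr[idx] <- substring(ref, starts, starts + lens - 1L)
        }
    }
    if (errorRate > 0)
        seqsChr <- vapply(seqsChr, mutateSeq, character(1),
                          errorRate = errorRate, USE.NAMES = FALSE)

    isFail <- runif(depth) < qualityModel$failProb
    meanQ <- numeric(depth)
    meanQ[!isFail] <- rtruncnorm1(sum(!isFail), qualityModel$passMeanQ, 1.5, 7, 30)
    meanQ[isFail] <- rtruncnorm1(sum(isFail), qualityModel$failMeanQ, 1.5, 0, 7)
    startTime <- cumsum(rexp(depth, gapRate))
    readId <- sprintf("%s-%05d", truth$sample_id, seq_len(depth))
    info <- data.frame(read_id = readId,
                       barcode = truth$sample_id,
                       length = nchar(seqsChr),
                       mean_q = meanQ,
                       start_time = startTime,
                       pass_flag = meanQ >= 7,
                       stringsAsFactors = FALSE)
    origin <- ifelse(originTaxon == 0L, "junk",
              ifelse(!is.na(hostId) & originTaxon == hostId, "host",
              ifelse(originTaxon %in% kitomeTaxa, "kitome", "contaminant")))
    prov <- data.frame(read_id = readId, origin = origin,
                       taxon_id = originTaxon, stringsAsFactors = FALSE)
    list(reads = ReadSet(Biostrings::DNAStringSet(seqsChr), info),
         truth = truth, provenance = prov)
}

#' Simulate a cohort of sterile and contaminated samples
#'
#' Generates samples across the study's three tiers: sterile negative
#' controls and contaminated samples at read fractions mimicking 10 and
#' 100 CFU/mL spikes. The two contaminated tiers differ only in their
#' contaminant read fraction (the 10-tier strictly lower). Per-sample
#' seeds are derived deterministically from the global seed. Each
#' sample's host fraction is capped at one minus the contaminant and
#' kitome fractions, so the origin proportions always form a valid
#' multinomial.
#'
#' @param nPerTier named vector/list: samples per tier, names
#'   \code{"10"}, \code{"100"}, \code{"sterile"}.
#' @param refs a \linkS4class{TaxonRefSet}.
#' @param contamFractions named numeric: contaminant read fraction per
#'   contaminated tier (default 1% at 10 CFU/mL, 5% at 100 CFU/mL).
#' @param hostFraction nominal host read fraction (default 0.98).
#' @param depth,kitomeFraction,errorRate,qualityModel,gapRate passed to
#'   \code{\link{simulateSample}}.
#' @param seed global integer seed.
#' @return list with \code{samples} (named list of per-sample results),
#'   \code{truths} (data.frame sample_id, status, spiked_species,
#'   cfu_tier, host_fraction) and \code{manifest}.
#' @examples
#' refs <- makeReferences(2, 1, nKitome = 2, seed = 1)
#' co <- simulateCohort(c(`10` = 1, `100` = 1, sterile = 1), refs,
#'                      depth = 60, seed = 3)
#' co$truths
#' @export
simulateCohort <- function(nPerTier, refs,
                           contamFractions = c(`10` = 0.01, `100` = 0.05),
                           hostFraction = 0.98, depth = 1000,
                           kitomeFraction = 0.006, errorRate = 0.005,
                           qualityModel = list(passMeanQ = 11,
                                               failMeanQ = 5,
                                               failProb = 0.0645),
                           gapRate = 0.5, seed = 1L) {
    nPerTier <- unlist(nPerTier)
    if (sum(nPerTier) < 1) stop("invalid-argument: empty cohort")
    if (contamFractions[["10"]] >= contamFractions[["100"]])
        stop("invalid-argument: 10-tier fraction must be below 100-tier")
    tierN <- function(nm) if (nm %in% names(nPerTier)) nPerTier[[nm]] else 0L
    tiers <- c(rep("10", tierN("10")), rep("100", tierN("100")),
               rep("sterile", tierN("sterile")))
    n <- length(tiers)
    set.seed(deriveSeed(seed, "cohort"))
    sampleSeeds <- sample.int(2147483646L, n)
    tx <- refTaxonomy(refs)
    contamTaxa <- tx$taxon_id[tx$kind %in% c("bacterial_16S", "fungal_18S28S")]
    spikes <- rep_len(sample(contamTaxa), n)

    samples <- vector("list", n)
    truths <- vector("list", n)
    counters <- c(`10` = 0L, `100` = 0L, sterile = 0L)
    for (i in seq_len(n)) {
        tier <- tiers[i]
        counters[[tier]] <- counters[[tier]] + 1L
        sterile <- tier == "sterile"
        label <- if (sterile) "sterile" else sprintf("cfu%03d", as.integer(tier))
        sid <- sprintf("%s_%03d", label, counters[[tier]])
        cf <- if (sterile) 0 else contamFractions[[tier]]
        hf <- min(hostFraction, 1 - cf - kitomeFraction)
        truth <- list(sample_id = sid,
                      status = if (sterile) "sterile" else "contaminated",
                      spiked_species = if (sterile) NA_integer_ else spikes[i],
                      cfu_tier = if (sterile) 0L else as.integer(tier),
                      host_fraction = hf)
        samples[[i]] <- simulateSample(truth, refs, depth = depth,
                                       contamFraction = cf,
                                       kitomeFraction = kitomeFraction,
                                       errorRate = errorRate,
                                       qualityModel = qualityModel,
                                       gapRate = gapRate,
                                       seed = sampleSeeds[i])
        truths[[i]] <- truth
    }
    truths <- do.call(rbind, lapply(truths, function(t)
        data.frame(sample_id = t$sample_id, status = t$status,
                   spiked_species = t$spiked_species,
                   cfu_tier = t$cfu_tier,
                   host_fraction = t$host_fraction,
                   stringsAsFactors = FALSE)))
    names(samples) <- truths$sample_id
    manifest <- data.frame(sample_id = truths$sample_id,
                           barcode = truths$sample_id,
                           stringsAsFactors = FALSE)
    list(samples = samples, truths = truths, manifest = manifest)
}
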