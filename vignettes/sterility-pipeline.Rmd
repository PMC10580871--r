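---
title: "Sterility calling from amplicon reads: models, parameters and design decisions"
author: "sterilamp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sterility calling from amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sterilamp)
```

# The problem

A cell-therapy lot must be released as sterile before it expires.
Amplicon sequencing of the bacterial 16S rRNA gene and the fungal
18S–28S rRNA operon on a nanopore instrument can reveal microbial DNA
within a day, but a caller must contend with three structural
features of the data:

* **host dominance** — the cultured human cells contribute the vast
  majority of reads (~98% in spiked T-cell experiments), so
  contaminant evidence rides on a few dozen reads at best;
* **kitome background** — extraction and library kits carry trace
  microbial DNA, so even sterile controls show a few reads of
  background species; a naive "any microbial read means contaminated"
  rule has no specificity;
* **low-quality reads matter** — at 10 CFU/mL every read counts, so
  the pipeline deliberately retains reads below the nanopore pass
  threshold (mean Q < 7, the fastq_fail pool) instead of discarding
  them.

`sterilamp` addresses this with two binary classifiers over
per-species feature rows, combined by a decision matrix into a
four-state call. This vignette records the package's own account of
each stage: the model, its tunable parameters, and the design
decisions taken where the design was genuinely open.

# The synthetic cohort generator

Every stage is testable without external downloads because the
package ships a cohort generator whose defaults are the study
conditions the pipeline targets.

**References** (`makeReferences`). References are uniform random DNA,
not real rRNA genes. The pipeline's logic is sequence-content
agnostic — it consumes classifier outputs, qualities and timings —
and random references admit an exact oracle: the generator enforces
that every non-host pair shares < 5% of its canonical k-mers
(rejection sampling, default k = 15), so a read's true origin is
unambiguous and a brute-force scan can verify every classification.
Defaults: 16S references 1450 bp (full-length amplicon), 18S–28S
operon references 4000 bp, host 8000 bp, kitome 1200 bp.

**Read sampling** (`simulateSample`). Each of `depth` reads draws an
origin from a multinomial over host (`host_fraction`), the spiked
contaminant (`contamFraction`), kitome references (`kitomeFraction`,
split evenly), and an unclassifiable remainder (random DNA emulating
reads that match nothing). Fragment lengths: 16S-origin reads are
drawn near full amplicon length (90–100% of the reference),
18S–28S-origin reads as shorter fragments (20–60%), reflecting the
smaller fragment sizes seen for the long fungal operon; host and
kitome reads are amplicon-sized.

**Errors.** Per-base errors are i.i.d. at rate `errorRate`, split in
equal thirds among substitution, insertion and deletion — the
simplest model that stresses the identity filter. The default is
0.005/base, emulating high-accuracy basecalls. This value interacts
with the identity filter (below): the built-in classifier's identity
proxy is a k-mer match fraction that decays like $(1-e)^k$, so at
$e = 0.005, k = 15$ a typical read shows ~93% identity, comfortably
above the 83% filter; at $e = 0.02$ it would drop to ~74% and the
filter would remove genuine species. Real BLAST percent identity
degrades far more slowly with error rate than a k-mer proxy, which is
why the filter value and the error default must be read together.

**Quality.** Per-read mean quality is a two-component mixture:
with probability `failProb` the read draws from a fail component
(normal, mean 5, truncated to [0, 7)); otherwise from a pass
component (mean 11, truncated to [7, 30)). Truncation makes the
pass/fail flag exactly equivalent to the mixture component, so the
fail-read fraction converges to `failProb`. The default
`failProb = 0.0645` makes the fail pool add ~6.9% extra reads over
the pass baseline, matching the additional-read yield the pipeline is
designed to exploit. Per-base qualities are constant at the read mean
— only the mean is consumed downstream.

**Timing.** Start times accumulate exponential inter-arrival gaps
(default rate 0.5/s), giving time-to-next-read features a known
distribution.

**Kitome.** Kitome reads appear in *all* samples — sterile and
contaminated — at `kitomeFraction = 0.006` of depth, i.e. an
expectation of ~2 reads per kitome species per 1000-read sample,
spanning presence/absence across samples. The trace level is a free
parameter: no published value exists, and this choice puts kitome
read counts (0–5) in the same range as a 10 CFU/mL contaminant's
(~10), which is what makes the correctness model's job non-trivial
and realistic.

**Cohorts** (`simulateCohort`). Tiers differ only in contaminant read
fraction: 1% at 10 CFU/mL, 5% at 100 CFU/mL, 0 for sterile controls.
The nominal host fraction is 0.98; because host + contaminant +
kitome proportions must form a valid multinomial, each sample's host
fraction is capped at one minus the other fractions (so a 100 CFU/mL
sample runs at host ≈ 0.944). Per-sample seeds derive
deterministically from the cohort seed; every generator is a pure
function of (arguments, seed).

**What the simulator does not emulate:** real nanopore error profiles
(homopolymer compression, quality-correlated errors), barcode
sequences and demultiplexing cross-talk, chimeras, PCR-cycle
amplification bias, and real rRNA sequence homology (where related
species share k-mers and classification is genuinely ambiguous).
Passing tests therefore demonstrate that the *decision machinery* is
correct and recoverable under the stated statistical structure — not
that any particular wet-lab protocol achieves these error rates or
abundances.

# Classification and host depletion

The built-in classifier is deliberately a k-mer set-membership
method, not seed-and-extend alignment: on k-mer-disjoint references
it is exactly checkable against brute-force string search, which is
the role it plays in the test suite. Real genome-scale classifier
outputs enter through `parseCentrifuge` (8-column read-level report;
taxID 0 = unclassified; identity approximated as hitLength/queryLength
since Centrifuge reports no alignment identity — informational only,
never filtered on) and `parseBlast6` (standard outfmt-6; best hit per
read by bitscore, ties by pident then file order).

Scoring: for each read, every k-mer position is looked up under
canonical-strand encoding; the best taxon is the one hit by the most
positions, ties broken by smallest taxon id (a documented, arbitrary
but deterministic rule); identity is the hit fraction × 100. Reads
shorter than k are unclassified, not errors. k defaults to 15 — small
enough that a 1450 bp amplicon read yields ~1400 overlapping k-mers,
large enough that random 15-mer collisions between synthetic
references are negligible.

Host depletion removes the *union* over backends of read IDs assigned
to the host taxon. The union is the most aggressive choice and
matches the intent of removing as many host reads as possible;
requiring agreement between backends would leak host reads into the
microbial pool. The combination rule is a configuration point: any
named list of backend assignments can be supplied.

# Featurization

A species survives into the feature table only if it passes its
backend's prediction filter: for BLAST-like backends (including the
built-in classifier) the species' **maximum percent identity must
strictly exceed 83**; for Centrifuge its **mean score must strictly
exceed 900**. Both boundaries are strict — a species at exactly 83.0
or 900.0 is removed. Raising either threshold can only shrink the
surviving set (anti-monotonicity, property-tested).

Each surviving (sample, backend, species) becomes one row:

* read count, plus describe-style eight-number summaries (count,
  mean, sd, min, 25%, median, 75%, max) of read mean quality and read
  length — sd uses the n−1 denominator and quartiles use linear
  interpolation (R type 7), matching the conventional describe
  summary;
* inter-read gap features (mean/median/max of successive sorted start
  times) and reads-per-hour over the run duration;
* the sample's run-level statistics (totals, mean/median length and
  quality, N50, duration), computed on the **host-depleted microbial
  read pool** — the feature table is built after depletion, and the
  microbial pool's size and composition is the informative signal
  (total microbial reads is the single strongest contamination
  feature);
* optional labels: `sample_status` (1 = contaminated sample) and
  `correctness` (1 = the row's species is the spiked species).

Degenerate-case decisions, all chosen so that genuine one-read
species — the signal of interest at low CFU — survive: a single-read
species gets gap features of 0 (not missing); its sd is 0 (not
missing); reads-per-hour over a zero-duration run treats the duration
as one second. Rows with missing read count or mean quality are
removed (the NaN-row rule); the "additional fraction" of the quality
partition is |fail| / |pass|, defined relative to the pass baseline,
and is an error when no read passes.

# The two models

Both models are gradient-boosted tree ensembles (xgboost) over the
same feature rows; the sample-status model is trained at row level
and aggregated to sample level in the decision stage — this keeps one
shared feature table feeding both models.

**Split** (`splitTwoLayer`): two successive 75:25 splits give
train / test / evaluation. Splits are *grouped by sample* (all rows
of a sample travel together — splitting a sample's rows across
partitions would leak run-level features) and *stratified by sample
status* with floor rounding per stratum. The evaluation partition is
never touched until final scoring; a structural test verifies that
permuting evaluation labels cannot change the trained model.

**Augmentation** (`augmentFeatures`): gaussian-noise-jittered row
copies (per-feature sd × `noiseSd`, default 0.1), squared-feature
columns, and log10 columns for strictly positive features
(non-positive features are skipped rather than producing NaNs). The
derived-column recipe is stored in the bundle so prediction-time
inputs get identical columns. Order of operations: augment → select →
scale; augmenting first lets selection see the derived columns.

**Feature selection** (`selectFeatures`): a two-stage decorrelating
rule — drop the member of any |Pearson r| > 0.9 pair with the lower
label mutual information (quartile-binned), then rank survivors by
single-tree (rpart) importance with MI and input order as
tie-breaks, keeping the top 15. This is a declared stand-in with the
contract "a decorrelated, informative subset"; the exact ranking
heuristic is not the scientific point.

**Scaling** (`fitScaler`/`applyScaler`): standard z-scores with
parameters fitted on the (augmented) training partition only and
reused verbatim on test, evaluation and new data. A feature constant
in training scales to 0 everywhere.

**Grid search**: 5-fold cross-validated accuracy over learning rate
{0.05, 0.1, 0.3}, depth {3, 5, 7}, rounds {100, 300}, L1 weight
{0, 1}, L2 weight {1, 10}, gamma {0, 1} (the compact
`xgbGridSmall()` covers {0.1, 0.3} × {3, 5} × 60 rounds × L1 {0, 1}
for quick runs). CV folds are grouped by sample, like the outer
split. Splits are found with the exact greedy algorithm
(`tree_method = "exact"`): at feature-table scale it is cheap, puts
thresholds at value midpoints, and is bit-reproducible. A probability
of exactly 0.5 is called positive — fail-safe toward flagging
contamination.

Bundles persist as a directory of text files (JSON model, TSV scaler
at full decimal precision, feature list, JSON metadata including the
seed, chosen grid point, cv accuracy and fold assignment) and reload
bit-for-bit.

# The decision matrix

The sample-status model aggregates by the max rule: a sample is
contaminated if any of its rows has probability ≥ 0.5; a sample with
no surviving species is sterile with probability 0. The four-state
call combines this with whether any species row is predicted a
*correctly classified* contaminant:

| sample status | ≥ 1 correct species | call |
|---|---|---|
| contaminated | yes | `CONTAMINATED` |
| contaminated | no  | `POTENTIALLY_CONTAMINATED` |
| sterile      | no  | `STERILE` |
| sterile      | yes | `STERILE_WITH_BACKGROUND_NOISE` |

The state vocabulary is fixed; the cell mapping is an explicit,
overridable 4-cell table in the configuration (the mapping above is
the package default). It is monotone-safe: adding a
correctly-classified species can never move a call from
`CONTAMINATED` toward `STERILE`. `cohortReport` tabulates per-tier
rates of the contaminated / sterile / ambiguous groups.

# Reproducibility and problem sizes

All randomness flows from one root seed through a documented
derivation (`seed × 1009 + hash(stage) × 131 mod 2³¹−1`), and the
full pipeline is byte-reproducible: two runs with the same seed write
identical decision and report tables.

The package's verification experiments use these problem sizes,
chosen to exercise every code path at laptop scale: classifier-oracle
checks on 100 error-free reads over 5 mutually disjoint references;
filter and depletion property tests over 200 randomized tables;
split-protocol checks on 160 synthetic samples (80 contaminated + 80
sterile, giving exact 90/30/40 partitions under floor rounding); and
an end-to-end parameter-recovery cohort of 40 samples per tier at
1000 reads/sample, on which the evaluation-partition sample-status
accuracy and correctness accuracy are required to reach 0.90 and
0.85. `scripts/acceptance.R` re-runs that cohort from scratch and
writes the measured quantities as JSON.

# Known limitations

* The built-in classifier is a testing oracle and a desk-scale
  stand-in; real studies should feed Centrifuge / BLAST outputs
  through the parsers. Its k-mer identity proxy is *not* comparable
  to BLAST pident at realistic nanopore error rates.
* Random references cannot probe taxonomic ambiguity between related
  organisms; misclassification in the simulator comes only from the
  error process and the filters.
* Single-sample calls only: replicate-level aggregation (e.g.
  five-fold replication schemes) is out of scope.
* The sample-status model leans on microbial-pool size features;
  in regimes where kitome load rivals the contaminant signal
  (very low depth), its sample-level accuracy degrades gracefully
  toward the ambiguous calls, as the worked example in the README
  shows.
* No probability calibration: the 0.5 threshold is a decision rule,
  and the reported probabilities are raw model outputs.
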