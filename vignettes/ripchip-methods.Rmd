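---
title: "Methods: Ago2 RIP-Chip targetome calling with ripchip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Ago2 RIP-Chip targetome calling with ripchip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripchip)
```

## The experimental design this package models

Argonaute-2 RIP-Chip identifies miRNA targets biochemically: RISC-bound
transcripts are immunoprecipitated with an anti-Ago2 antibody, and both the
immunoprecipitated fraction (IP) and the total RNA fraction (T) of the same
cells are profiled on two-color microarrays, each fraction labeled with both
Cy3 and Cy5 as dye replicates. A transcript bound by miRNA-loaded RISC is
enriched in the IP fraction, so the IP/T signal ratio of its probes measures
miRNA targeting directly, without relying on sequence prediction.

miRNA-*specific* targets are isolated by contrasting two constructs of the
same cell line: one in which the miRNA of interest has been perturbed
(retroviral overexpression, or a sponge transcript that sequesters it) and
an empty-vector control. `ripchip` implements the complete analysis chain
for this design — preprocessing, enrichment statistics, seed-site sequence
validation, binding-site motif-set enrichment, and the growth-assay
statistics used for functional follow-up — plus a synthetic-data generator
that plants known targets so every stage can be validated end to end
without any array download.

## Preprocessing (array_core)

**Quantile normalization** is applied jointly across all channels (both
fractions, both constructs, both dyes), mirroring a single analysis session
of the original feature-extraction software. Every column's sorted values
are replaced by the cross-column mean of order statistics; ties receive the
mean of the tied ranks' normalized values. The operation is idempotent and
rank-preserving per column.

**Detection calls.** Feature-extraction exports carry per-spot "detected"
flags; the flag algorithm itself is proprietary. When flags are present
they are used as-is and never overwritten. When absent, a probe is called
detected in a channel iff its signal strictly exceeds the channel's 10th
percentile (`detection_quantile`, configurable). A strict inequality means
a constant channel detects nothing, which is the conservative reading.

**Probe filtering** applies the two published quality rules, in fixed
order. (1) Probes *not detected in more than half* of the sample channels
are removed; we read the quote literally, so a probe detected in exactly
half the channels is retained (`detected_fraction < 0.5` removes).
"Samples" is interpreted as individual dye channels (a flag in
`filter_probes()` arguments would accept pre-averaged inputs instead; the
channel reading is the default because flags are per channel). (2) Probes
whose Cy3 and Cy5 signals differ by more than 2-fold
(`max(a,b)/min(a,b) > 2`, symmetric and scale-free) in *any* (cell line,
construct, fraction) dye pair are removed. A floor of 1.0 fluorescence
unit inside the ratio prevents division by zero at background-level spots.

**Dye averaging** takes the arithmetic mean of the Cy3 and Cy5 channels on
the linear scale, because the downstream IP/T ratio is formed on the linear
scale; a geometric mean is available via `method = "geometric"` for users
who prefer log-symmetric averaging.

Whether normalization preceded filtering in the original software is not
documented; `ripchip` normalizes first so that detection thresholds and dye
ratios are judged on comparable scales.

## Targetome and specific-target calling (targetome)

For each (cell line, construct), the IP fold enrichment of a probe is
`IP / max(T, 1)` on averaged signals; the floor again guards against
dropout-level totals. The **targetome** is every probe with IP/T ≥ 2
(inclusive). A probe is a **miRNA-specific target** when

* IP/T ≥ 2 in the test construct (miRNA-overexpressing cells), and
* the ratio is at least 2-fold lower in the reference construct
  (`ratio_test / ratio_ref ≥ 2`).

Both thresholds are configurable; raising either can only shrink the call
set (tested as a monotonicity property). Sponge designs reuse the same rule
with roles swapped: specific means enriched in the control (miRNA-high)
sample and ≥2-fold lower under the sponge. Whether the original analysis
required expression of a probe in the reference construct is unstated; the
default here requires presence in both constructs (the fold-lower
comparison needs a reference value), with `require_ref_expressed = FALSE`
to call on the test criterion alone.

Probe calls are collapsed to genes through the annotation; each gene keeps
its highest-enrichment probe (`gene_ratio` = max probe ratio), the same
collapse used for ranking in gene-set enrichment. Probes with no annotated
gene are counted and reported, never silently dropped. Cross-sample
enrichment **categories** use half-open bins to make the published
descriptions mutually exclusive: Enriched `[2, ∞)`, MildlyEnriched
`[1.5, 2)`, NotEnriched `(0, 1.5)`, NotExpressed (no retained probe).

## Seed-site scanning (seed_scan)

Canonical seed-match sites are derived from the mature miRNA on the target
(mRNA sense) strand in DNA letters: the 6mer is the reverse complement of
miRNA positions 2–7, the 7mer-m8 of positions 2–8; the 7mer-A1 and 8mer add
an A opposite position 1. For hsa-miR-155-5p these are GCATTA and
AGCATTAA.

```{r sites}
derive_sites(mature_mirna("hsa-miR-155-5p", "UUAAUGCUAAUCGUGAUAGGGGU"))
```

Scanning slides each site over the given strand only (no reverse-complement
scan — miRNA sites live on the transcript), case-insensitive, U read as T,
ambiguity codes never matching, all overlapping occurrences counted, with
1-based position reporting. Counting is *inclusive* by default: an 8mer
occurrence also counts as the 6mer/7mer it contains, consistent with
published site-content fractions in which the 6mer carrier set contains the
8mer carriers. `inclusive = FALSE` restricts each type to occurrences not
contained in a longer site. CDS sequences are scanned by the identical
machinery; the host feature is metadata.

Overlap with an external prediction list (e.g. a TargetScan gene list) is
tested with a Pearson chi-square on the 2×2 table (1 df, no continuity
correction by default since the source analysis names only "Chi-square
test"; Yates available by flag).

## Motif-set enrichment (motif_enrichment)

Genes are ranked by descending log2 gene ratio with deterministic
lexicographic tie-breaks, and the weighted Kolmogorov–Smirnov running-sum
enrichment score is computed with weight exponent `p = 1` (the standard
weighted statistic; `p = 0` gives the classic KS form). With one dye-pair
per fraction there are no replicates to permute phenotypes over, so the
null is a **gene-label permutation**: null scores are computed on random
gene subsets per set-size stratum. NES divides the observed ES by the mean
|null ES| of matching sign, and p-values are sign-stratified tail fractions
with add-one smoothing — the convention under which null sets yield
uniform p-values (verified by a KS calibration test). For tiny universes an
exact mode enumerates every subset. Benjamini–Hochberg adjusted p-values
are provided as a convenience; they are not part of the source procedure.

Motif sets (miRNA binding-site signatures) are identified by an explicit
flag or a name pattern; synthetic runs build one motif set from the planted
targets plus size-matched random sets, so the motif-set rank and the
top-20 motif fraction can be checked against ground truth.

## Growth-assay statistics (growth_stats)

GFP competition series are baseline-normalized: the GFP+ percentage at the
first measured day (day 3 or 4 post-transduction) is set to 1 and the
analysis response is `relative value − 1`, which is identically 0 at
baseline. The model is intercept-free with only construct×day interaction
fixed effects — day categorical by default (one term per construct per
post-baseline day), or linear in `day − baseline` for a two-slope
parameterization — and a random intercept per biological replicate. The
repeated-measures phrasing of the source protocol is ambiguous between a
random-effect and a compound-symmetry covariance; the random intercept is
the simplest structure consistent with it, and an OLS fallback (the
zero-variance limit of GLS) is used with a warning when the variance
estimate is singular. The construct contrast is tested with a Satterthwaite
F (joint across days, or 1 df on the slope difference).

Baseline-day rows are retained in the data structures but excluded from
the model likelihood by default (`include_baseline = FALSE`): their
response is 0 *by construction*, so treating them as stochastic
observations would bias both variance components toward zero and make the
test anticonservative. With this choice the type-I error at α = 0.05 sits
inside [0.03, 0.07] over 500 null simulations (recomputed by the test
suite and the acceptance script).

Group comparisons of miRNA levels use the Mann–Whitney U test: exact
enumeration when the pooled sample is ≤ 16 and tie-free, otherwise the
normal approximation with tie and continuity corrections. Two-sided by
default.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions the rest of the package is validated under:

* Signals are lognormal: `2^(baseline + effects + noise)` with per-probe
  baselines from Normal(10, 1.5) on the log2 scale, reproducing array
  dynamic range without modeling scanner physics.
* Two constructs × two fractions × two dyes (8 channels, one cell line);
  planted targets receive an IP enrichment multiplier only in the
  miRNA-high construct. The paper-like preset plants 54 targets among
  8000 genes (2 probes per gene, matching a 44k array's redundancy) with
  folds drawn uniformly from [2.0, 12.6] — the published count and
  enrichment range of the overexpression screen.
* Per-cell log2 noise sd 0.25 and per-channel dye offsets (sd 0.1),
  detection dropout 2%: the deposited arrays report no per-probe variance
  or detection rates, so these are plausibility choices, made once. At
  these levels ~2–3% of probes fail the dye-consistency filter, a
  realistic QC loss.
* Dropout sets the detection *flag* rather than zeroing the signal,
  keeping QC filtering separable from intensity modeling.
* UTRs are uniform ACGT; background sequence is rejection-sampled so the
  8mer seed site occurs only where planted, which keeps the planted-site
  gene set an exact ground truth (chance 6mer occurrences are left in —
  they are realistic, and the 6mer content of a random 800-nt UTR is
  substantial). Planting rates default to the published carrier fractions
  (48% of targets, ~2% of background).
* Sponge experiments use the same machinery with the enrichment applied in
  the control construct and shrunk toward 1 in the sponge construct; the
  weak-sponge preset shrinks only 20%, reproducing the near-null specific
  calls seen when sequestration is incomplete.
* Growth series: measurements every ~3 days from day 4 to day 22, 3
  replicates per construct, baseline 30% GFP+, replicate and residual sd
  0.05 on the relative scale. The default advantage of 1/18 per day puts
  the test construct at relative value ≈ 2 on day 22, the magnitude of the
  published overexpression effect.

Everything is reproducible from one integer seed; the pipeline fans a
global seed out to per-stage child seeds (`child_seed()`) so stages can be
re-run in isolation.

### What passing tests do and do not show

The generator emulates enrichment magnitudes, lognormal noise, dye
effects, dropout and probe redundancy. It does **not** model
cross-hybridization, spatial artifacts, probe-sequence affinity, GC
content, or correlated biological replicates, so perfect recovery on
synthetic data bounds algorithmic correctness, not the biological error
rate of a real screen.

## Numerical choices and degenerate inputs

* Thresholds on ratios are inclusive (`≥ 2`), matching the published
  wording; category bins are half-open for exclusivity.
* Denominator floors: 1.0 fluorescence unit on T signals and inside dye
  ratios.
* Ties: quantile normalization averages tied ranks; gene ranking breaks
  metric ties by gene id; the max-probe collapse breaks ratio ties by
  probe id. All deterministic.
* Degenerate statistics are answered, not errored, where a value is
  defined: identical groups give U = n·m/2, p = 1; a 2×2 table with a zero
  margin is rejected as degenerate.
* Problem sizes in the validation suite were chosen to exercise each
  property at the smallest scale at which it is informative: 200-probe
  oracle instances, the full 8000-gene paper-like preset for end-to-end
  recovery, 500/200-run simulation batches for test calibration, power
  and bias.

## Known limitations

* Joint quantile normalization compresses IP enrichment for probes whose
  IP signal exceeds the background's top order statistics (their
  normalized value becomes a cross-column mean dominated by unenriched
  channels). With realistic planted fractions (≤ ~1% of probes) the effect
  is negligible, but in small simulations with a large enriched fraction a
  top-ranked target can fall below the 2-fold threshold even at zero
  noise. This is a property of the published procedure itself, not of this
  implementation.
* No statistical error model on IP/T ratios (no variance shrinkage or
  moderated tests): the source procedure is deterministic thresholding and
  is implemented as such.
* No background subtraction, within-array loess, or spatial correction;
  inputs are plain-text exports, not binary scanner files.
* The GSEA variant is preranked with gene-label permutation; with
  replicated designs a phenotype-permutation null would be preferable.
* TargetScan predictions are consumed as a provided gene list; the
  prediction algorithm itself is out of scope.

## Reproducing a full run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  sim = ripchip_sim_config(n_genes = 8000, probes_per_gene = 2,
                           n_planted_targets = 54,
                           ip_enrichment_fold_targets = c(2.0, 12.6),
                           noise_sd_log2 = 0.25, rng_seed = 1),
  n_perm = 500, rng_seed = 1)
report <- run_pipeline(cfg, out_dir = "ripchip_run")
report$truth      # recall / precision against the planted targets
report$gsea       # motif-set rank among the synthetic collection
```

The same quantities, plus the growth-model calibration, are recomputed
from scratch by `scripts/acceptance.R` (see the README).
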