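---
title: "foxomir: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foxomir: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foxomir)
```

# The scientific problem

Cigarette smoking lowers PD-1 expression on CD8+ T cells and enriches a
CD27+CD107a− "naive-memory" population; one candidate mechanism is an
altered microRNA (miR) environment acting on the FOXO signalling pathway
that maintains CD8+ memory programming (FOXO1, BCL6, IL7R, TCF7, and the
exhaustion receptor PDCD1). foxomir packages the complete computational
chain that such a study needs, with a seeded synthetic-cohort generator so
every stage can be exercised and tested without downloading anything:

1. miR microarray detection calling, background subtraction, sample QC,
   expression filtering, log2 transform, cyclic loess normalization;
2. two-group differential expression with empirical-Bayes variance
   moderation;
3. ΔΔCT qPCR quantification and relative quantity (RQ) to the cohort
   median;
4. a median-threshold naive-memory phenotype point score;
5. the per-sample mRNA/miR ratio statistic, its high/intermediate/low
   classification, and the paired nicotine-response shift test;
6. exact small-sample statistics (odds ratio, Fisher, Mann-Whitney U,
   Wilcoxon signed rank), Ward/Spearman clustering, and a file-based
   pipeline with a run manifest.

# Models and procedures

## Detection and background subtraction

A spot is a true signal when its raw intensity exceeds the sample's
background `noise_mean + 2 * noise_sd` (the platform's QC rule; `k_sd` is
configurable). Detected spots are background-corrected by subtracting
`noise_mean`, floored at zero; undetected spots become missing. Because
detection requires intensity strictly above the noise mean, corrected
values are strictly positive, which makes the operation idempotent on its
own output under zero-noise statistics — a property the tests assert.
Background subtraction is the simplest reading consistent with per-sample
noise statistics; the source protocol names the step without a formula.

Sample QC removes arrays whose detected count falls below `min_detected`
(default 10% of probed features — the original cohort lost two arrays this
way but printed no number, so the default is an explicit, configurable
choice). The expression filter keeps features whose mean corrected
intensity over non-missing samples strictly exceeds 80 arbitrary units
(`top_n` mode keeps the n largest means instead; the threshold mode is the
default because both descriptions appear in the source and the threshold
is the one with a stated constant). The mean is computed after background
subtraction, matching the stage order of the protocol text.

## Cyclic loess normalization

On the log2 scale (offset 1 AU admits zeros), every unordered array pair
(i, j) contributes an MA regression: M = x_i − x_j against
A = (x_i + x_j)/2, fitted with a locally weighted scatterplot smoother
(span 0.7, the conventional MA-plot default; the source names only "cyclic
loess"). Half of the fitted trend is subtracted from i and added to j, so
each pair's adjustments cancel exactly and the grand total is preserved;
the sweep over all pairs runs 3 times. Features missing in one sample of a
pair are excluded from the fit but receive the adjustment predicted at
their available abundance; fully missing values stay missing. Convergence
of the between-array median M is monotone only up to a small ripple
between consecutive sweeps (the adjustments are sequential, not joint),
which the tests assert with an explicit tolerance rather than pretending
strict monotonicity.

## Moderated differential expression

Per feature, ordinary least squares on the non-missing samples gives the
log2 fold change (test − reference; in the smoking contrast, smokers are
the test group), the residual variance s², and its degrees of freedom.
The variances are then shrunk toward a pooled prior: assuming
s² | σ² ~ σ²·χ²_d/d and 1/σ² ~ scaled χ², the prior degrees of freedom d0
and prior variance s0² are estimated by method of moments on log s²
(solving a trigamma equation by Newton iteration), the posterior variance
is (d0·s0² + d·s²)/(d0 + d), and the moderated t = logFC / (s̃ ·
stderr-factor) is referred to a t distribution on d + d0 degrees of
freedom (capped at the pooled total; normal when d0 is infinite). The
implementation is the package's own; the test suite checks it against the
reference implementation of this procedure to 1e-6 on a 200-feature
dataset, and checks both limits exactly: d0 = 0 is the ordinary t, d0 = ∞
the pooled z-like statistic.

Selection follows the published rule — raw p < 0.05 and logFC strictly
greater than 0.5 (or strictly below −0.5). Benjamini-Hochberg adjusted
p-values are always reported but not used for selection by default,
matching the source's use of unadjusted p and keeping multiplicity
visible. Exact-zero variances get a 1e-8 floor before moderation so no
statistic is infinite. RA/HC status is not a covariate in the default
smoking contrast (the source pools both diagnoses); a covariate hook and a
diagnosis contrast exist.

## ΔΔCT and relative quantity

For target a and its side's reference (GAPDH for mRNA, RNU6b for miR):
ΔCT = CT_a − CT_ref; ΔΔCT subtracts the mean calibrator ΔCT; fold change
is 2^(−ΔΔCT). The geometric mean of per-calibrator fold changes equals
2^(−mean ΔCT), so the two calibrator summaries offered by the interface
coincide; both are kept for the configuration surface. RQ divides each
analyte by its median over a stated sample scope — the unstimulated
control cultures in the nicotine experiment — so the median RQ over the
scope is exactly 1. RQ is computed on the fold-change / 2^(−ΔCT) scale,
which is what a "relative quantity" heatmap displays.

## Phenotype score

One point per marker strictly above the cohort median of that marker;
ties at the median score zero. This strictness is a deliberate, documented
reading of "above the median" — it changes calls for samples sitting
exactly at an even cohort's mid-value, and it makes the score invariant
under any strictly monotone per-marker transform (only ranks matter, so
mixing a protein frequency with mRNA levels is well-defined). Variant A
(CD27+ frequency, IL7R, FOXO1, TCF7; ≥ 2 points) and variant B (IL7R,
FOXO1, BCL6, TCF7; ≥ 3 points) are both built in. The median includes the
scored sample itself; a leave-one-out mode exists but is off, matching
"median of all samples". Missing markers score zero and flag the sample
as incomplete rather than excluding it, since the source's figures
classify samples with missing entries.

## mRNA/miR ratio and the nicotine shift

Per sample: the median RQ over the mRNA panel divided by the median RQ
over the miR panel. Groups use strict cutoffs 1.5 and exactly 2/3 (the
rational value of 1/1.5, not a rounded decimal, so boundary classification
is bit-stable); boundary values are intermediate. Group membership is
frozen at the control condition and never re-derived after nicotine. The
paired shift test applies the exact two-sided Wilcoxon signed-rank test to
nicotine-minus-control ratio differences within each control group; when
all n pairs move the same way the exact p is 2/2^n — 0.0078125 at n = 8
and 0.03125 at n = 6, which reproduce the printed 0.0078 and 0.031 and
identify those group sizes as 8 and 6.

## Exact tests

The odds ratio is the exact cross-product a·d / (b·c) (Haldane-Anscombe
+0.5 optional). Fisher's two-sided p sums hypergeometric point
probabilities ≤ the observed one, with relative tolerance 1e-7 so
equal-probability tables are not lost to floating point. Mann-Whitney and
Wilcoxon exact p-values evaluate the full null distributions (count
recursion over all C(nx+ny, nx) labelings; generating-function expansion
over all 2^n sign assignments) and double the smaller tail, capped at 1 —
the convention that reproduces the printed values above. Zeros are
dropped before signed ranking; any ties route to the normal approximation
with tie and continuity corrections, because the classical exact
distributions assume none. Every exact path is property-tested against
literal brute-force enumeration.

## Clustering

Sample distances are 1 − Spearman ρ on pairwise-complete observations
(each pair ranked over its own complete cases; constant vectors are
errors, not NaNs). Ward's minimum-variance linkage is applied through the
Lance-Williams update directly on these correlation distances. Two
caveats are deliberate: (i) Ward formally assumes squared Euclidean
distances — applying it to correlation distances mirrors the described
method and common heatmap practice, and heights remain monotone; (ii)
when clustering *samples*, per-feature baselines shared by all samples
dominate within-sample ranks and can mask real group structure. Measured
on the default synthetic cohort, clustering the 8 planted miRs unscaled
yields a pure smoker/non-smoker split in only ~62% of seeds, versus ~93%
after per-feature mean-centering. The package therefore exposes
`center_features` on the distance function (default off, so the
definitional examples d = 0 / d = 2 hold exactly) and the pipeline's
sample-clustering stage enables it. This deviates from the original plan
of clustering strictly unscaled values; the measurement above is why.

# The synthetic cohorts: what they emulate, and what they do not

All generators are pure functions of (config, seed).

**Microarray** (`simulate_microarray`): 2,656 probed miRs, 125 expressed,
7 smokers vs 6 non-smokers — the analyzed cohort's shape. Background spots
are lognormal around each sample's noise mean (sdlog 0.35); per-sample
noise means U(8, 12) AU and SDs U(1, 2) AU; expressed features are
lognormal with baselines U(120, 4000) AU (planted features U(400, 2000) so
a negative effect cannot push them under the 80-AU filter) plus normal
log2 residuals with SD 0.3, chosen as typical MA-plot scatter for
single-channel intensity data (the source prints no value). Planted
effects are the eight reported miRs: six up at +0.6..+1.0, two down at
−0.6 and −1.0, spanning the reported |logFC| > 0.5 regime. Bad arrays
(for QC tests) collapse the entire array into a tight background
(sdlog 0.05) so almost nothing exceeds the detection threshold. Not
emulated: probe-level spatial artifacts, spike-in controls, dye effects,
donor pooling correlation — so a green recovery test establishes that the
statistical chain works at the stated effect and noise scale, not that it
survives those artifacts.

**qPCR** (`simulate_qpcr_cohort`): 25 donors planted as 8 high / 11
intermediate / 6 low ratio samples. The generator inverts the
quantification model — measured CT = reference CT + baseline ΔCT − planted
log2 quantity + noise — so the ΔCT/RQ stage is genuinely exercised rather
than bypassed. The planted shift is twofold per side (mRNA up and miR
down in the high group, mirrored in the low group), giving expected
ratios of 4, 1 and 1/4 against cutoffs 1.5 and 2/3. CT noise is 0.09 CT
per measured value, the scale expected after averaging ~3 technical
replicates of ~0.15 CT each; at this noise the probability of any of the
25 samples crossing a cutoff boundary is of order 1e-5 per cohort, so the
(8, 11, 6) recovery is a property of the stated world, not of a lucky
seed. Nicotine subtracts 2·strength·log2(2) from the dominant side and
adds it to the other; at strength 1 every high pair decreases and every
low pair increases, reproducing the 2/2^n shift p-values.

**Phenotype markers** (`simulate_phenotype_markers`): planted naive-memory
samples sit `separation` = 1.5 log-units above effector samples per
marker with residual SD 0.5, enough for ≥ 90% label recovery by the
median-threshold score; smoker enrichment defaults to the published 2×2
expectation (9/13 vs 5/16), with a deterministic mode that forces those
counts exactly so the OR 4.95 is reproduced as arithmetic, not sampling.

# Numerical choices and degenerate inputs

* Missing tokens on input: empty cell, `NA`, and (opt-in) `X`, because the
  source's own figures mark missing data with "X"; internally a single NA
  sentinel. Orientation is explicit at read time; internal canonical form
  is features × samples.
* Full-precision (`%.17g`) table output, so write→read round-trips within
  1e-12 for every value kind.
* `value_kind` tags (raw_intensity / log2 / normalized_log2 / ct / rq) are
  checked by every stage, enforcing the pipeline order by construction.
* Ward ties break deterministically on the smallest index pair; the
  cyclic-loess smoother interpolates its fitted curve (rule-2
  extrapolation at the range ends) to adjust half-missing features.
* Fisher point-probability comparison tolerance 1e-7 (relative);
  signed-rank zeros dropped; tied ranks route to the corrected normal
  approximation; exact enumeration caps at combined n = 25 by default.
* All randomness flows from a single integer seed per generator call; the
  pipeline writes the seed and md5 digests of every output into its run
  manifest.

# Known limitations

* The accession-based integration checks (the deposited series' 125 kept
  miRs and 6-up/2-down contrast) require a download and are not part of
  the offline test suite; the synthetic cohort mirrors their structure
  instead, and the normalize/DE stages accept any user-supplied intensity
  and noise tables of that shape.
* Donor pooling (1–3 donors per array) is carried in the metadata
  (`pooled_n`) but does not weight the tests, as no weighting rule is
  stated; the hook exists for users who want one.
* The empirical-Bayes prior is estimated on whatever feature set is passed
  in — by design the post-filter set (the "top 125" analysis set), not the
  full array.
* No amplification-efficiency correction in ΔΔCT; no duplicate-correlation
  or array weights in the linear models; no bootstrap stability for the
  clustering.

# Parameter reference

| Parameter | Default | Units | Why |
|---|---|---|---|
| `k_sd` | 2 | noise SDs | platform detection rule |
| `min_detected` | 10% of features | spots | QC rule; source prints none |
| `mean_threshold` | 80 | AU | stated filter constant |
| `offset` | 1 | AU | admit zero intensities |
| `span` / `iterations` | 0.7 / 3 | — | conventional MA smoothing |
| `lfc_cut` / `p_cut` | 0.5 / 0.05 | log2 / p | published selection rule |
| `hi_cut` / `lo_cut` | 1.5 / 2⁄3 | ratio | published cutoffs, exact rational |
| `min_points` | 2 (A), 3 (B) | points | published score variants |
| `exact_max_n` | 25 | samples | exact-test feasibility bound |
| `residual_sd_log2` | 0.3 | log2 | typical array scatter |
| `ct_noise_sd` | 0.09 | CT | ~3 technical replicates at 0.15 CT |

Every number above is either a stated constant of the method being
reimplemented or a package default documented here; none is tuned against
test outcomes.
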