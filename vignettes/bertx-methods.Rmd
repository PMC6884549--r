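---
title: "Models and methods behind bertx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bertx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bertx)
library(dplyr)
```

bertx quantifies five assays used to study AAG-initiated base excision
repair (BER) in transcribed chromatin. This vignette explains the model
behind each estimator, the tunable parameters and their defaults, what the
simulators do and do not emulate, and the numerical choices made where the
underlying assay conventions leave room.

## The damage-qPCR model

The lesion-mapping assay digests sheared genomic DNA (~200 bp fragments)
with AAG plus APE1, converting every AAG substrate into a strand break that
blocks PCR across the amplicon; an APE1-only digestion is the baseline arm.
We model lesions per amplicon as Poisson with mean $\lambda$ and assume a
single lesion fully blocks amplification — the standard long-amplicon
damage-qPCR assumption, and the simplest model consistent with a
$\Delta$Ct readout. The amplifiable fraction is then the Poisson zero
class,

$$p_\text{intact} = e^{-\lambda},$$

so with per-cycle amplification factor $E$ the observed shift is
$\Delta\text{Ct} = \lambda / \ln E$ and inversion gives
$\hat\lambda = \Delta\text{Ct}\cdot\ln E$. The package carries both forms:
`intact_fraction()` is the closed form, and `mc_intact_fraction()` is a
brute-force Monte-Carlo that actually places Poisson lesion counts on
simulated fragments and counts survivors. The two agree to within 0.01 in
intact-fraction units at $10^5$ fragments across $\lambda \in [0, 3]$ —
note that an *absolute* tolerance is the meaningful one here, because the
binomial sampling error of the Monte-Carlo itself exceeds 1% *relative*
error once $e^{-\lambda}$ is small.

Parameters and defaults:

* `efficiency` ($E$): 2.0, perfect doubling, the universal qPCR convention;
  override per assay if primer efficiencies are known.
* `ct_noise_sd`: 0.15 cycles of additive Gaussian technical noise, a
  typical replicate spread for SYBR assays.
* `n_replicates`: 3 technical replicates, the common bench default.
* Negative $\Delta$Ct is reported as-is but clamped to 0 before computing
  $\hat\lambda$ (negative lesion frequencies are unphysical); clamped rows
  are flagged.
* Replicates are averaged on the Ct scale *before* differencing, matching
  standard qPCR practice.

Per-gene profiles use three amplicons — promoter, middle, 3′ end — and are
reported relative to the promoter. "Relative amount" is implemented as the
$\hat\lambda$ ratio by default because $\lambda$ is the physically
interpretable lesion density; a `ddct` mode reporting the cycle difference
$\Delta\text{Ct}_\text{region} - \Delta\text{Ct}_\text{promoter}$ is
provided since the ratio-vs-difference convention varies between labs. When
the promoter $\hat\lambda$ is exactly 0 a pseudocount (default 0.01,
roughly one noiseless lesion quantum) is applied with a warning rather than
failing — the affected ratios are flagged as unreliable.

### Ratio recovery is assessed aggregate-first

At a promoter rate of $\lambda = 0.1$ with 0.15-cycle noise and three
replicates, the per-experiment denominator
$\hat\lambda_\text{promoter}$ has a coefficient of variation near 1 and
frequently lands at or below zero. A per-experiment end/promoter ratio is
therefore heavy-tailed — its sample mean drifts far above the true gradient
no matter how many experiments are averaged. The package's recovery checks
consequently estimate gradients as the *ratio of means*: average the
(unclamped) $\Delta$Ct estimates across experiments first, then form the
ratio, with a delta-method standard error. This estimator is unbiased and
recovers a planted 5-fold gradient to within sampling error at 200
experiments. `lesion_profile()` still reports the per-experiment ratio,
which is the right summary when $\lambda$ values are comfortably away from
zero; the aggregate-first route matters only in the noisy-low-signal
regime.

## ChIP-qPCR percent input and relative occupancy

The input well measures an aliquot containing a fraction $f$ of the
chromatin, so its Ct is first corrected by $\log_E(1/f)$ cycles to
represent 100% of input; the immunoprecipitate is then expressed as

$$\%\text{input} = 100 \cdot E^{(\text{Ct}_\text{input} - \log_E(1/f)) -
\text{Ct}_\text{IP}},$$

which satisfies the usual sanity identities (IP equal to its own 1% aliquot
gives 1%; one extra IP cycle halves the percentage at $E=2$; a common Ct
shift cancels). Relative occupancy divides each region's percent input by
the promoter's, so promoter rows are exactly 1. The input fraction is a
required argument rather than a default — it is a property of the bench
protocol that analysis must not guess. The simulator
(`simulate_chip_qpcr()`) is the exact inverse of this arithmetic, so
noiseless simulation recovers a planted profile to machine precision.

## FM-HCR repair capacity

The host-cell reactivation readout scores expression of a reporter plasmid
carrying a site-specific lesion. The quantity chain is
$F = N \cdot \text{MFI} / S$, $F^O = F / F^E$ and
$\%\text{R.E.} = 100 \cdot F^O_\text{dam} / F^O_\text{un}$. The
definitions of $N$ and $S$ are taken as: $S$ = all live singlet events,
$N$ = the reporter-positive subset, MFI = the arithmetic mean intensity
(linear scale) of those $N$ — this reading makes $F$ a per-cell-normalized
total signal, and makes %R.E. behave as a repair fraction: if a fraction
$r$ of transfected cells repair the lesion, the expected %R.E. is
$100\,r$.

Gating uses fixed thresholds: scatter bounds, an FSC-H/FSC-A singlet band
(default 0.8–1.2), a viability-dye ceiling, and per-channel positivity
thresholds. Thresholds are constants rather than data-driven because the
simulated populations are well separated; with real cytometry data they
should be set from an untransfected background percentile. Gating is
idempotent and relaxing any bound can only increase the retained count.
Spillover/compensation is not modeled — channels are treated as already
compensated.

Replicate handling: %R.E. is computed per replicate (damaged/undamaged
ratio within a replicate) and then averaged as mean ± SEM per condition.
Ratio-per-replicate-then-average keeps each ratio paired to its own
transfection batch, which is the variance the replicate structure exists to
capture; averaging before the ratio would discard that pairing.

## DEG overlap and direction quadrants

DEGs are called at $|\log_2\text{FC}| \ge \log_2(\text{min fold})$ and
FDR $\le$ threshold, both inclusive (a "$\ge 1.5$-fold" criterion includes
the boundary; likewise "FDR $\le 0.1$"). The defaults mirror the study
this package models: 1.5-fold for the AAG knockout table, 2-fold for the
ELP1 knockout table, FDR 0.1 for both. FDR values are consumed when
present; otherwise Benjamini–Hochberg adjustment is applied to the p-value
column (`bh_adjust()` delegates to `stats::p.adjust`; the test suite
verifies it against an independently written step-up implementation).
DE model fitting itself (negative-binomial shrinkage etc.) is deliberately
out of scope — the package consumes DE tables.

Genes present in only one table are treated as non-DE in the other: they
cannot enter the overlap, whose genes are partitioned into four direction
quadrants (up/down in each knockout). The default
`de_sim_config()` plants the published overlap structure — 1,045 DEGs in
knockout A, 489 in knockout B (343 down), 113 co-regulated — with a
quadrant split of 77/15/13/8 (up-A/down-B first). Only the 113 total, the
overall direction biases and the up-A/down-B *plurality* are published
facts; the exact 77/15/13/8 split is this package's choice, constructed to
respect all of them. Planted effects default to $|\log_2\text{FC}| = 2$
with 0.1 log2-units of noise, so planted genes always clear the thresholds
and null genes essentially never do; under the global null the empirical
false-discovery behaviour stays within the BH guarantee.

## Comet FLARE

Percent tail DNA is $100 \cdot \text{tail}/(\text{head}+\text{tail})$ —
the standard definition; Olive-moment variants are intentionally not
implemented. Group summaries report mean ± SEM both across cells and
across replicate means (the latter is the honest unit when cells within a
slide are correlated). "AAG-specific" damage is defined as the difference
in mean percent tail between the +AAG-enzyme and buffer arms within a
condition: the enzyme converts AAG substrates into strand breaks, so the
difference isolates the glycosylase-revealed lesions from pre-existing
breaks. Significance testing uses the package-wide convention: one-way
ANOVA with Dunnett contrasts against a stated control (`group_anova()`),
falling back to Holm-corrected pairwise t-tests with a message when
multcomp is unavailable.

The comet simulator draws per-cell tail fractions from a Beta distribution
around the planted group mean (dispersion 30 by default, giving the
dispersed-but-unimodal spread typical of comet data) and splits a
log-normal total intensity between head and tail, so planted means are
recovered exactly in expectation. Defaults plant 6% tail in both buffer
arms, 12% under DMSO+AAG and 22% under DRB+AAG — i.e. transcription
inhibition increases AAG-revealed damage without changing baseline breaks —
with 50 cells per replicate and 4 replicates, matching common comet
scoring practice.

## What the simulators do and do not emulate

Each generator reproduces the statistical structure the estimator relies
on: Poisson lesion counts and exponential intact fractions; log-normal
fluorescence mixtures with threshold-separable populations; planted DEG
sets with clean effect sizes; Beta-distributed tail fractions. They do not
emulate primer-specific amplification curves, cytometer spillover,
autofluorescence drift, DE model miscalibration, or comet image
segmentation artifacts. Passing recovery tests therefore demonstrates that
the *arithmetic and estimators* are correct and unbiased under the assumed
noise models — not that those noise models capture every failure mode of
real bench data.

## Determinism and problem sizes

Every generator is a pure function of its arguments including the seed
(RNG state is scoped with `withr` and never leaks). `run_pipeline()`
records a config hash, seed and package version so outputs are traceable,
and identical configs reproduce identical files. The validation suite uses
deliberately modest problem sizes — $10^5$ fragments for the digestion
oracle, $10^4$ events per flow sample with 50-replicate means, 200
simulated experiments for gradient recovery, 200 null simulations for the
FDR check — chosen so each estimator's sampling error is several times
smaller than the effect it must resolve.

```{r example}
# one end-to-end run at the defaults
res <- run_pipeline(list(seed = 1, assays = c("de", "comet")))
glance(res$de$result)
glance(res$comet$result)
```
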