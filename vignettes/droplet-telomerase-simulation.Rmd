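---
title: "Methods: droplet single-cell culture simulation and telomerase splice-variant quantitation"
author: "emulsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet single-cell culture simulation and telomerase splice-variant quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emulsim)
```

# The experiment being emulated

Single lymphoblast cells (e.g. Jurkat, K562) are encapsulated in nanoliter
culture droplets, grown for up to three days, and assayed colony-by-colony
with a multiplex RT-PCR for six RNA targets: hTR, GAPDH, and the four
alpha/beta hTERT splice variants (`a+b+`, `a-b+`, `a+b-`, `a-b-`).
Amplicons are sized and quantified by capillary electrophoresis; the peak
area per target, normalized to the number of cells in the colony, serves as
relative transcript abundance. Three analyses sit on top of the readout:
limiting-dilution digital quantitation of per-cell copy numbers, Hartigan's
dip test for bimodality of abundance across colonies, and a fold-change +
Mann-Whitney rule for calling drug-induced expression changes.

The package implements that entire chain twice over: once as a synthetic
generator with retained ground truth, and once as the analysis toolkit that
consumes either simulated or real peak tables.

# Generator model

## Encapsulation

Cells load independently as `founding_cells ~ Poisson(mean_cells_per_droplet)`
with a default mean of 0.1, so ~90% of droplets are empty and under 5% of
occupied droplets carry more than one cell. Empty droplets are retained
(they matter for loading QC). A single cell in a droplet of volume $V$ nl
experiences an effective bulk density of $10^6/V$ cells/ml
(`effective_concentration()`); the default 5.9 nl droplet corresponds to
about 170,000 cells/ml, in the normal passaging range for these lines.

## Growth

Each cell carries an absolute division clock; generation times are
$\mathcal N(T, (cv\,T)^2)$ truncated at $0.05\,T$, with $T$ =
`doubling_time_h` (default 20 h) and `division_cv` = 0.1. The small CV gives
the synchronized 1/2/4/8-cell colony-size ladder seen in control cultures.
The 20 h default is a typical lymphoblast doubling time; it also means
day-1 snapshots are taken comfortably *after* the first division rather
than exactly on top of it, which keeps colony sizes (and therefore per-cell
normalization) clean at each sampling day.

Nutrients are modeled as a hard carrying capacity
`capacity_cells_per_nl * droplet_volume` (default 2.5 cells/nl, i.e. ~15
cells in 5.9 nl and ~8 in 3.4 nl). A colony that reaches capacity stops
dividing; from the following day it is flagged non-viable and its count
declines by 30%/day, reproducing the volume-dependent plateau-then-decline
of small droplets. Non-viable colonies transcribe nothing, so they drop out
downstream at the GAPDH gate — the model's stand-in for "no live cells, no
successful reaction".

## Transcription

Per live cell and sampling day, at most one hTERT splice variant is drawn
into a high-burst state (one categorical draw weighted by
`variant_burst_rates`, defaults `a+b+` 0.05, `a-b+` 0.04, `a+b-` 0.15,
`a-b-` 0.08; total 0.32). Burst sizes are
$1+\mathrm{NB}(\mu = 49, \text{size} = 40)$ molecules — mean 50, tightly
enough dispersed that bursting and silent cells separate into two abundance
populations. Non-bursting variants emit 0–1 baseline molecules
(`baseline_expr_prob` 0.05). This *exclusive-burst* construction is the
simplest mechanism consistent with single cells expressing predominantly a
single variant at a time, with fewer than 25% of cells high for any given
variant; the expected total hTERT per cell works out to ~16 molecules, in
the tens-of-copies range the dilution assay measures.

hTR and GAPDH are Poisson around per-cell means of 1000 and 500. hTR gets
an extra between-cell lognormal factor (CV 0.5), so single cells are
visibly heterogeneous while colony averages converge with size (law of
large numbers); both are generated independently of hTERT, which the
analysis verifies as $R^2 < 0.05$ between hTR and total hTERT.

## Curcumin perturbation

With `curcumin$enabled`, division noise triples
(`division_cv_multiplier` 3: intermediate colony sizes, desynchronized
division) and growth rate is scaled by `growth_rate_multiplier` (default 1:
a sub-lethal dose with no significant growth effect). From day 2, each
alpha-minus variant is expressed near-constitutively — per cell, each
alpha-minus variant bursts with probability `alpha_minus_burst_prob`
(default 0.95) on top of the exclusive draw — and all alpha-minus burst
output is multiplied by `alpha_minus_fold` (default 300).

Two modeling points deserve emphasis. First, multiplying burst *output*
alone would make treated day-2 colonies look *more* bimodal (zeros versus
huge values); it is the near-constitutive burst *frequency* that removes
the low-hTERT population and collapses bimodality, which is exactly the
observed signature of treatment. The default 0.95 (rather than, say, 0.9)
also avoids a discreteness artifact: with a visible fraction of
variant-by-cell slots silent, colony totals cluster at ratios k/2m and a
spurious internal gap can re-trigger the dip test. Second, the exclusivity
invariant ("one variant per cell") is a property of the *default* config
only; the perturbed cell state intentionally violates it. The fold of 300
is chosen so the *measured* fold change — after detection losses and
readout noise — robustly exceeds 100 on both alpha-minus variants.

GAPDH is modeled as stable housekeeping expression across days. A
deliberately emulated day-to-day GAPDH drift was considered and rejected:
at the default cohort size (~200 gated colonies/day) any shift large
enough to be interesting is detected by the rank test with essentially
full power, and the pipeline's correct behavior — GAPDH never starred — is
better exercised by the fold-change bound (FC ≈ 1 lies inside (0.5, 2))
than by an unstable p-value near threshold.

## Readout

A molecule is reverse-transcribed and detected with probability
`detection_prob` (default 0.5); detected counts are Binomial, so a target
at Poisson mean $\lambda d$ per reaction is read positive with probability
$1 - e^{-\lambda d\, p}$ (the thinning identity the digital assay relies
on). Detected molecules produce one CE peak per target with

$$\text{area} = \Big(\sum_{i=1}^{k} Y_i\Big)\times \text{area\_per\_molecule}\times E,$$

where the $Y_i$ are mean-1 lognormal per-molecule amplification yields
(`molecule_noise_cv`, default 0.8; approximated by a matched normal for
$k > 30$) and $E$ is a mean-1 lognormal per-peak factor (`area_noise_cv`,
default 0.3). The per-molecule term is what makes the generator's
single-molecule regime realistic: a lone baseline molecule yields a peak
area anywhere within a factor of a few, while a 25-molecule burst has
relative spread $\approx 0.8/\sqrt{25}$. Without it, baseline-only output
forms an area comb at multiples of `area_per_molecule` that the dip test
correctly—but unhelpfully—flags as multimodal; with it, the no-burst null
is smoothly unimodal while burst-driven bimodality remains obvious.
Only positive targets (≥ 1 detected molecule) emit peak rows, as in a real
peak-caller export; fragment sizes get a small (SD 0.15 bp) jitter within
the ±1 bp assignment window.

# Quantitation machinery

## Limiting-dilution Poisson estimation

`fit_lambda()` minimizes $\sum_d (k_d/N_d - (1 - e^{-\lambda d}))^2$ over
$\lambda \ge 0$. The objective can be locally flat at saturation, so the
minimizer is bracketed on a 300-point log grid over $[10^{-4}, 10^4]$ and
refined with `stats::optimize` (tolerance $10^{-10}$); a dedicated test
keeps it within $10^{-3}$ relative of a 10,000-point grid oracle. All-zero
series return 0; all-positive series set a `lower_bound` flag because λ is
then only bounded from below. Weighted least squares ($1/SE^2$) is
available but off by default — the plain frequency-scale fit is the literal
reading of the procedure being reproduced. Error bars use the
positive-count rule $\sqrt{k}/N$ with a $1/N$ floor at $k=0$. The
goodness-of-fit p-value is a parametric bootstrap on the residual sum of
squares under the fitted zero-class model (single-row series: $p = 1$ by
convention, there are no residual degrees of freedom). The default ladder
is nine 2-fold dilutions from 1 to 1/256 at $N = 18$ reactions, matching
the assay's validation design; across the working range
(0.16–12.5 copies/cell) the replicate-averaged estimator is unbiased to
within a few percent.

## Hartigan's dip

`dip_statistic()` computes
$D = \min_{U \text{ unimodal}} \sup_x |F_n(x) - U(x)|$ exactly, in C, by
the iterative algorithm: within the current candidate modal interval, fit
the greatest convex minorant and least concave majorant of $F_n$, find the
largest discrepancy between the two fits, tighten the modal interval, and
accumulate the deviations of $F_n$ from the fits outside it; distances are
kept in count units and halved/scaled at the end, so $D \in [1/(2n), 1/4]$
for samples with at least two distinct values. Ties need no special
casing (slope tests use cross products); a fully degenerate sample returns
0, since a point mass is unimodal. The implementation was verified to
$10^{-9}$ against an independent linear-programming oracle that minimizes
the sup-distance over all unimodal CDFs directly (convex/concave chain
constraints per candidate mode, including an atom at the mode); 70 frozen
oracle values ship with the test suite, covering $n \le 8$ with ties and
zero inflation.

`dip_test()` bootstraps the null from Uniform(0,1) samples of the same
size — the least-favorable unimodal null — with
$p = (1 + \#\{D_b \ge D\})/(B+1)$, $B = 2000$ by default and seeded;
`B < 100` warns. A `null_dips` argument lets calibration studies reuse one
null table. The test is applied to per-cell-normalized abundance on the
linear scale (histograms in this field are linear); day-pooled statements
pool the named days' samples.

## Gating, fold change, significance

Only samples with a detected GAPDH peak enter statistics (live-cell gate);
areas are divided by cell count. Fold change between days is the ratio of
arithmetic means of normalized abundance, undefined when the earlier mean
is zero (reported with `defined = FALSE`, never starred). Significance
requires both Mann-Whitney two-sided $P \le 0.01$ and FC outside
$(0.5, 2)$ — statistical and biological relevance. The Mann-Whitney p-value
is exact (via the null distribution of the rank sum) when the pooled
sample is ≤ 20 and tie-free, and the tie-corrected normal approximation
with continuity correction otherwise; growth-rate comparisons use the
Welch t-test ("Student's t-test" with the safer variance assumption).
Both rank and t machinery are delegated to base R's `wilcox.test`/`t.test`
rather than re-implemented.

# What the generator does and does not emulate

Emulated: Poisson loading statistics; volume-limited colony growth with
synchronized division and nutrient decline; exclusive splice-variant
bursting with realistic per-cell copy numbers; stable high-copy hTR/GAPDH
with hTR converging to the population mean as colonies grow;
hTR–hTERT independence; detection losses, per-molecule amplification noise
and peak-area noise; curcumin's alpha-minus upregulation, loss of
bimodality and division desynchronization.

Not emulated: droplet formation physics (volumes are inputs, not computed
from flow rates); sequence-level PCR (primers, thermal profiles,
amplification-efficiency curves); cross-run CE normalization against the
sizing standard; mRNA degradation dynamics (bimodality is generated purely
through burst frequency — degradation-driven bimodality would be
observationally similar but is a different mechanism); destructive
colony sampling (every colony is read out every day; a real experiment
consumes each sampled colony); apoptosis at high drug dose; and subculture
recovery after treatment ends.

Passing tests therefore show that the *analysis machinery* is correct and
that the *study conditions as modeled* reproduce the qualitative and
quantitative signatures of interest — not that real colonies follow a hard
carrying capacity or negative-binomial bursts.

# Numerical choices and problem sizes

* Stage seeds derive from the single config seed (distinct multipliers per
  stage, offset by day), so equal seeds give byte-identical peak tables and
  report bundles, and single stages can be re-run in isolation. Pipeline
  logs carry no wall-clock timestamps for the same reason.
* Tie-breaks: duplicate in-window CE peaks per (sample, target) keep the
  maximum area, ties resolved toward the smaller fragment size.
* Degenerate inputs: empty droplets pass through growth untouched;
  all-GAPDH-negative matrices yield empty-but-valid results end to end;
  a zero-variance target makes the correlation an `NA` sentinel.
* Test-suite problem sizes were chosen to keep the full suite around a
  minute while leaving comfortable statistical margins: dilution-recovery
  checks average 200 ladders per abundance; dip null calibration uses 500
  replicates at $n = 100$ with $B = 500$; generator-level dip claims use
  15 seeded experiments of 1600 droplets per arm; the curcumin acceptance
  run uses 2000 droplets (~200 gated colonies per day, above the ≥150
  the fold-change recovery is specified at).

# Known limitations

* The dip's bootstrap null is Uniform(0,1); interpolated look-up tables
  (as in classic implementations) are deliberately not provided, so very
  large samples pay the bootstrap cost (mitigated by `null_dips` reuse and
  the C statistic, ~microseconds per evaluation).
* The least-squares λ estimator is the procedure's literal reading, not
  the binomial MLE; at the saturated top of a ladder it inherits the
  usual slight upward noise-bias (a couple of percent at λ = 12.5 with
  N = 18), which replicate averaging does not remove entirely.
* `mann_whitney_u()` switches to the normal approximation in the presence
  of any tie, as the classic calculators do; for small tied samples an
  exact conditional test would be marginally more accurate.
* The generator's day is a discrete snapshot: burst states are redrawn
  each day rather than persisting through a lineage, so day-to-day
  autocorrelation of a colony's dominant variant is absent.
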