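---
title: "Methods: fecal protease activity profiling from kinetic fluorescence assays"
author: "protrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fecal protease activity profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protrace)
```

## The assay and its model

Fecal protease activity profiling incubates diluted stool extracts with a
panel of short peptide substrates carrying a C-terminal AMC fluorophore.
Cleavage of the terminal peptide bond releases AMC, and fluorescence read on
a microplate reader grows in proportion to the accumulated product. Each
extract is assayed against every substrate under several buffer pH
conditions (default 5.5, 6.5, 7.5, 8.0) in replicate wells, with reads every
5 minutes over 75 minutes. The measurand is an *activity rate* in RFU/min:
the slope of the early, linear part of each progress curve, where product
accumulation is proportional to active enzyme and substrate depletion is
negligible.

`protrace` models one well's observed fluorescence as

$$\mathrm{RFU}(t) \;=\; g_p\,\bigl(B_i + v\,\tau\,(1 - e^{-t/\tau})\bigr) + \varepsilon_t,
\qquad \varepsilon_t \sim \mathcal N(0, \sigma^2),$$

where $g_p$ is a multiplicative plate gain, $B_i$ a constant per-sample
intrinsic baseline, $v$ the enzymatic rate (RFU/min), and $\tau$ a
substrate-depletion timescale; $\tau \to \infty$ gives the ideal linear
trace $g_p(B_i + v\,t)$. The single-exponential product-formation term is
the simplest curve with an exactly linear early phase followed by
saturation; it is a phenomenological depletion model, not a Michaelis-Menten
fit, and the package deliberately performs no conversion of RFU/min into
molar enzyme units (no AMC standard curve is part of the workflow).

The fitting procedure in `fit_activity()` inverts this model stage by stage:

1. **Plate normalization.** Each plate's reads are divided by its
   normalization factor, the mean fluorescence of its empty (buffer-only)
   wells divided by the same quantity on a designated reference plate. This
   removes $g_p$ up to the reference plate's own gain, which becomes the
   common scale of the study.
2. **Intrinsic subtraction.** The extract-only (intrinsic) trace of each
   sample, normalized the same way, is subtracted read-by-read from the
   sample's digestion curves, removing $B_i$ and the plate background.
   Corrected traces may dip below zero under noise; they are retained
   unclipped because slope estimation is offset-invariant.
3. **Linear-phase detection.** A deterministic window search (below) finds
   the early linear region of the corrected curve.
4. **OLS slope.** Ordinary least squares over the window estimates $v$; the
   intercept is discarded. Replicate wells are aggregated as arithmetic
   mean and sample SD (n-1 denominator; a single replicate reports a
   missing SD rather than 0).

Steps 1 and 2 commute within a plate, and normalizing raw traces is
equivalent, for OLS slopes, to normalizing fitted slopes; the package fixes
the order above so every intermediate trace lives on the reference scale.

## Linear-phase detection

An R-squared threshold cannot decide linearity here because genuinely flat
traces -- healthy-control samples with negligible activity are common -- have
undefined or unstable R-squared. The detector instead works on absolute
deviations:

* Candidate windows are contiguous runs of reads inside `[0, t_max_window]`
  (default 20 min, configurable; the assay's linear phase is typically
  within the first 5-20 min), with at least `min_points` reads (default 4)
  and at least `t_min_window` minutes of span (default 5).
* Candidates are ordered by decreasing length, ties broken by earliest
  start, and the first window accepted wins. A window is accepted when the
  maximum absolute deviation of its reads from their own least-squares line
  is at most `linearity_tol` (default 0.02) times the window's RFU span
  plus three times a noise scale, estimated as the SD of first differences
  over the trace tail (the last `max(4, floor(n/3))` reads, where the curve
  is flattest).
* If the slope over the whole candidate region is below
  `activity_floor_rfu_per_min` (default 0.5 RFU/min), the trace is flagged
  `low_activity` and given the default window -- its rate is then a
  near-zero number whose window choice is immaterial.
* If no candidate passes (heavily curved, noisy traces), the earliest
  shortest window is used as the best available early-phase estimate.

The test suite holds this detector equal to an independently coded
exhaustive search applying the same acceptance rule over all windows, on a
thousand randomized linear and saturating traces ($\tau \in
\{5, 10, 30, \infty\}$ min).

## Intrinsic-fluorescence QC

Some extracts carry strong substrate-independent fluorescence from soluble
fluorophores (incompletely absorbed mesalazine being the canonical source).
The boundary between "correctable" and "excessive" background is a policy
choice, so `qc_policy()` makes it explicit and records it in every report:

* `absolute(threshold_rfu)` excludes samples whose mean intrinsic baseline
  exceeds a fixed RFU level;
* `adaptive(k)` (default, `k = 10`) excludes samples above
  `mean + k * SD` of the pooled empty-well reads, i.e. samples whose
  baseline is far outside anything attributable to plate background.

Excluded samples are dropped from all downstream statistics but kept,
flagged, in the QC report and audit tables. Exclusion under the absolute
policy is monotone in the threshold, and on well-separated synthetic
contamination (50-fold inflated baselines) the adaptive rule recovers the
true contaminated subpopulation exactly.

## Cohort signatures

The per-sample rates assemble into a samples x (substrate, pH) matrix;
cohort mean profiles average the non-missing, non-excluded samples per cell
(heatmap display clipping, default 0-600 RFU/min, never alters stored
values). Normalized contributions divide clamped-at-zero mean rates by
their total, per cohort and pH by default (`per_ph`); clamping applies only
inside the fraction computation because a share of total activity cannot be
negative, while raw means stay unclamped in the profile. "Normalized across
pH" is ambiguous between per-pH and pooled-pH totals, so both scopes are
implemented; `per_ph` is the default used in reports, and the pooled
variant is available as `across_ph`. Class-level fractions sum member
substrates before dividing, which makes the class table exactly consistent
with the substrate table. Fractions are computed from cohort means (matching
the mean-based heatmap representation) rather than per-sample-then-averaged;
the alternative weighs samples differently and is not currently exposed.

## Group statistics

* **t tests.** Unpaired comparisons use Student's pooled-variance form
  (`df = n_a + n_b - 2`), matching the equal-SD assumption under which the
  assay's comparisons are framed; Welch is available behind
  `var_equal = FALSE`. Matched phases (acute vs remission) use the paired
  test. All p values are two-sided. Zero-variance degeneracies follow a
  documented convention: equal means give `t = 0, p = 1`; unequal means
  give an infinite statistic and `p = 0`. No multiple-testing correction is
  applied by default across the substrate x pH grid; a Benjamini-Hochberg
  column is available behind `adjust_p = TRUE` and recorded in the
  manifest.
* **ROC/AUC.** The AUC is the Mann-Whitney probability that a positive
  sample outscores a negative one, ties counting one half, computed exactly
  via midranks. The curve thresholds at every distinct score, so its
  trapezoidal area equals the rank AUC exactly, ties appearing as diagonal
  segments.
* **Inhibition.** Percent inhibition is `100 * (1 - inhibited/control)` per
  sample, reported as-is when negative (activation) and undefined (missing)
  for non-positive control rates, with a paired t test across samples.

## The synthetic-data generator

No patient measurements ship with the package, so `simulate_study()`
generates datasets with the statistical structure the analysis assumes,
plus the generating truth for recovery tests. It emulates: linear-then-
saturating AMC-release traces; cohort-structured mean rates with
multiplicative lognormal inter-individual variability (unit-mean
multipliers, so cohort means stay calibrated); a constant per-sample
intrinsic baseline with a Bernoulli high-background subpopulation;
lognormal per-plate gains; additive homoscedastic Gaussian read noise; and
triplicate wells alongside intrinsic, substrate-only and empty controls.
Default cohort sizes are HC 12, CD 12, UC 11, IBS 4; 20% of samples are
high-background.

Parameters the workflow does not pin down were chosen once as plausible
assay magnitudes and are not tuned: plate background 100 RFU; intrinsic
baselines lognormal with mean 25 and SD 8 RFU (a modest fraction of plate
background); the high-background multiplier 50 (an order of magnitude above
any ordinary baseline, making "excessive" unambiguous); read noise SD 5
RFU; plate-gain sdlog 0.05; depletion timescale 60 min (visibly saturating
within the 75-min cycle while leaving the first ~20 min linear); rate CV
0.6 (substantial inter-individual spread on a lognormal scale). The default
effect matrix is an **illustrative fixture**, qualitatively shaped --
healthy controls near zero, CD/UC broadly elevated with stronger
cathepsin-like activity in UC, IBS dominated by furin-like substrates --
and explicitly not measured data.

Randomness derives from one master seed through five documented stage
substreams (high-background flags, baselines, rate multipliers, plate
gains, read noise): the master seed yields five stage seeds via
`sample.int`, and each stage reseeds independently, so any stage can be
regenerated without replaying the others and identical configurations
reproduce identical datasets bit for bit.

What the generator does **not** emulate bounds what passing tests show
about real data: there are no pH-activity continuous curves (each condition
has its own mean rate), no enzyme-level mixture structure behind a
substrate's rate, no heteroscedastic or drifting noise, no plate-position
effects, and no microbiome composition. Recovery results therefore validate
the pipeline's arithmetic and its robustness to the nuisances modelled --
gains, backgrounds, saturation, replicate noise -- not the biological
fidelity of any particular signature.

## Simulated layout

One simulated plate holds one sample at one pH: 14 substrates x 3
replicate digestion wells, one intrinsic well, one substrate-only well per
substrate, and two empty wells (59 of 96 wells). This keeps a single gain
per (sample, pH) and guarantees every digestion well an intrinsic control
on its own plate. The reference plate defaults to the first plate in input
order and is configurable.

## Numerical choices and degenerate inputs

* OLS is computed in closed form with explicit centering; slopes are exact
  for affine traces and offset-invariant to machine precision.
* Negative fitted slopes are retained in activity records; clamping happens
  only where non-negativity is mathematically required (contribution
  fractions).
* Missing reads (empty CSV cells) flag a trace `incomplete` -- never
  silently interpolated; the QC stage excludes samples whose intrinsic
  trace is incomplete.
* Zero-variance t-test inputs and zero-denominator contribution blocks
  follow the documented conventions above rather than erroring.
* Well ordering on disk is canonical (plate id, natural well order, time),
  making write-read-write a fixpoint and parsing independent of row order.

## Problem sizes in the validation suite

The shipped tests exercise the pipeline at deliberately moderate scale: 500
traces for slope-recovery calibration, 1,000 randomized traces for the
window-search equivalence, 200 samples for QC recovery, 50 samples per
cohort for class-fraction recovery, 10,000 replicates for t-test null
calibration, 500 per group for the binormal AUC construct, and a
15-sample, 2-pH demo study for end-to-end determinism. These sizes give the
recovery checks comfortable statistical resolution at their stated
tolerances while keeping a full run in the order of a minute.

## Known limitations

* The pipeline estimates relative activities on the reference plate's
  scale; absolute enzymatic units are out of scope by design.
* Contribution fractions inherit the cohort-mean convention; cohorts with
  heavy-tailed rate distributions are summarized by means, not medians.
* The linear-phase detector assumes the earliest reads are the most
  trustworthy; assays with lag phases would need a different window policy
  (`t_min_window`/`t_max_window` are configurable but the search always
  anchors within the early region).
* Vendor plate-reader exports must be pre-converted to the long tidy CSV;
  no proprietary formats are parsed.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 2026)
sim <- simulate_study(cfg)
fit <- fit_activity(sim$plates, sim$sheet, cfg$panel)
summary(fit)

profile <- cohort_mean_profile(coef(fit))
normalized_contributions(profile, cfg$panel, level = "class")

# end to end, with a report bundle on disk:
bundle <- run_pipeline(read_run_config(
  system.file("extdata", "demo_config.yaml", package = "protrace")))
render_report(bundle)
```
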