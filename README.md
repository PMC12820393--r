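# protrace

Fecal protease activity profiling from kinetic fluorescence assays.

Dysregulated protease activity in stool is a candidate non-invasive marker
for distinguishing inflammatory bowel disease (Crohn's disease, ulcerative
colitis) from irritable bowel syndrome and healthy controls. The assay
behind this package incubates diluted stool extracts with a panel of 14
AMC-labelled peptide substrates — probing elastase-, furin-, SKI-1/S1P-,
trypsin- and cathepsin-like activities — under four buffer pH conditions,
and reads fluorescence on a microplate every 5 minutes for 75 minutes.
`protrace` is for analysts of such plate-reader kinetics: it turns raw
progress curves into per-sample activity rates, cohort-level enzymatic
signatures, and group statistics, and ships a synthetic-data generator with
ground truth so every stage is testable without patient data.

## The model

One well's fluorescence is modelled as

    RFU(t) = g_p * ( B_i + v * tau * (1 - exp(-t / tau)) ) + eps,   eps ~ N(0, sigma^2)

with plate gain `g_p`, per-sample intrinsic baseline `B_i` (RFU), enzymatic
rate `v` (RFU/min) and substrate-depletion timescale `tau` (min); `tau -> Inf`
is the ideal linear trace. The estimator `fit_activity()` inverts this stage
by stage:

1. divide each plate's reads by its **normalization factor**
   `mean(empty wells of plate) / mean(empty wells of reference plate)`;
2. subtract each sample's **intrinsic** (extract-only) trace from its
   digestion curves;
3. detect the **linear phase** of the corrected curve (deterministic window
   search with an absolute-deviation acceptance rule);
4. estimate `v` as the **OLS slope** over that window, in RFU/min, and
   aggregate replicates (mean ± SD over triplicates).

Samples with excessive intrinsic fluorescence (e.g. mesalazine carry-over)
are excluded by an explicit QC policy; downstream, rates assemble into a
samples × (substrate, pH) matrix, cohort mean profiles, normalized
substrate/class contribution fractions, pooled or paired t tests,
Mann–Whitney ROC/AUC, and percent-of-control inhibition summaries. The
methods vignette (`vignettes/protease-profiling-methods.Rmd`) documents
every rule and default.

## Worked example

```r
library(protrace)

cfg <- read_run_config(system.file("extdata", "demo_config.yaml", package = "protrace"))
bundle <- run_pipeline(cfg)   # simulates a 15-sample study, fits, tests, writes the bundle
render_report(bundle)
```

```
Protease activity profiling report
==================================
Samples: 15 across 4 cohorts (CD=4, HC=4, IBS=3, UC=4)
1 samples excluded by QC (threshold 146.2 RFU, policy adaptive)
Normalization: reference value 97.58 RFU; factors in [0.923, 1.144]
Most active substrate per cohort (mean RFU/min):
  CD   R-AMC               218.2
  HC   ERSLK-AMC             5.1
  IBS  PHLVRQKR-AMC        214.7
  UC   ERSLK-AMC           225.6
Cysteine-class share of total activity:
  HC   pH 5.5   48.4%
  HC   pH 7.5   25.5%
  CD   pH 5.5   46.2%
  CD   pH 7.5   22.3%
  UC   pH 5.5   59.0%
  UC   pH 7.5   36.9%
  IBS  pH 5.5   14.1%
  IBS  pH 7.5   11.6%
Smallest-p cohort comparisons:
  HC_vs_UC     DGPYSLVA-AMC     pH 5.5  p = 1.43e-06
  CD_vs_HC     PANQRRHL-AMC     pH 7.5  p = 3.62e-05
  CD_vs_HC     RRHL-AMC         pH 5.5  p = 3.65e-05
  HC_vs_IBS    VFRSLK-AMC       pH 5.5  p = 4.23e-05
  IBS_vs_UC    DGPYSLVA-AMC     pH 5.5  p = 4.78e-05
ROC discrimination:
  UC_vs_CD_RSVL-AMC_pH5.5        AUC = 1.000
```

Reading the report: one of the 15 simulated extracts exceeded the adaptive
intrinsic-fluorescence threshold (mean empty-well RFU + 10 SD) and was
excluded; plate gains within ±15% of the reference plate were absorbed by
normalization; healthy controls show near-zero activity while the disease
cohorts are strongly elevated; cysteine-class (cathepsin-like) substrates
carry a larger share of total activity in UC; and the requested
single-substrate ROC (UC vs CD on the RSVL substrate at pH 5.5) separates
the two small demo cohorts completely. The demo's generating rates are an
illustrative fixture, not measured data, so these numbers characterize the
pipeline, not patients.

The bundle directory holds `qc_report.csv`, `activity_table.csv`,
`cohort_profile.csv`, `contributions.csv`, `stats_report.csv`,
`roc_curves.csv`, `summary.json` and a `manifest.json` recording every
threshold, policy and seed; identical configurations produce byte-identical
bundles.

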