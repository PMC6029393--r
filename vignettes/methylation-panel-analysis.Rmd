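---
title: "Evaluating urine methylation marker panels: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating urine methylation marker panels: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methpanel)
```

`methpanel` evaluates multi-marker MS-qPCR methylation panels as diagnostic
tests. This vignette is the package's account of the underlying models, the
parameters that matter, the synthetic cohort the tests run on, and the
design choices made where the design was genuinely open.

## From Cq to methylation level

MS-qPCR reports, per well, either a quantification cycle $C_q$ (the cycle
at which fluorescence crosses threshold; lower = more methylated template)
or no amplification. `cq_to_level()` inverts this into a level
$L = c - C_q$ for $C_q$ strictly below the cutoff $c$ (default 32 cycles,
the upper limit for a positive reaction under the panel's 32-cycle
protocol), and $L = 0$ otherwise. Levels are semi-quantitative: each
doubling of methylated input shifts $C_q$ by roughly 1–1.5 cycles, so $L$
is a log-scale burden proxy, not a copy number.

Two conventions deserve note:

- **A Cq exactly at the cutoff is negative.** $L(c) = 0$, and positivity
  everywhere downstream is $L > 0$. The alternative — calling $C_q = c$
  positive — would create a "positive" reaction carrying zero signal,
  contradicting every score built on $L$.
- **Levels above 15 are kept, with a warning.** 0–15 is the observed
  working range in urine DNA, not a hard bound; clamping would silently
  discard dynamic range on unusually strong samples.

Duplicate wells aggregate by **maximum level** (minimum Cq). The
aggregation rule for replicates is not dictated by the chemistry; maximum
is chosen for consistency with the dual-assay merge rule below, and
`aggregate_replicates()` accepts `mean` and `mean_of_positives` for
sensitivity analyses. Assays absent for a sample are imputed as level 0
(absence of amplification is the 0 state) with a per-sample QC warning;
`missing_action = "exclude"` drops such samples instead. Sample-level
exclusions for insufficient DNA happen upstream of this package.

## Marker scores

Five islands of the default panel carry two assays (forward and
reverse-complement designs interrogating different portions of the
island). `merge_dual_assays()` takes the **highest level detected**:
island fragments are not equally represented in urine DNA, so the stronger
assay better reflects the island's methylation status, and a marker is
positive iff either assay is (the union rule — merged sensitivity can only
rise, merged specificity only fall, relative to each constituent assay;
this dominance is asserted property-style in the tests).

Each sample then yields:

- `n_positive`: the count of merged markers with $L > 0$ ("n-of-19");
- `avg_methylation`: the sum of the 19 **merged** marker levels divided
  by 19.

The average deliberately uses the 19 post-merge values rather than the 24
raw assay values: dividing a 24-assay sum by 19 would double-weight the
five dual-assay islands. The classifier `classify_sample()` is
"test-positive iff `n_positive >= t`", inclusive at the threshold, with
$t = 6$ as the default operating point (chosen, in the study design this
package follows, for a target specificity of 70%).

## Diagnostic metrics and intervals

`diagnostic_metrics()` derives sensitivity, specificity, PPV and NPV from
exact 2×2 counts against the biopsy reference. Zero-denominator metrics
are reported as `NA` with a reason code, never as 0. Four interval methods
are available:

| method | default | notes |
|---|---|---|
| `wilson` | yes | score interval; reproduces the published per-assay intervals at 2 dp |
| `normal` | | Wald, clamped to [0, 1] |
| `clopper-pearson` | | exact beta; lower limit exactly 0 at 0/n |
| `bootstrap` | | seeded percentile, 2000 resamples |

Wilson is the default because it reproduces the checked per-assay interval
examples exactly at report rounding. The per-threshold table in the source
study prints intervals that match neither Wilson, Wald, nor
Clopper–Pearson on hand-checked rows (e.g. 34/38 → (0.79, 0.97)), possibly
a bootstrap; the method is therefore configurable and interval values are
not treated as exact reproduction targets. Report tables round to two
decimals **half-up** (`round_half_up()`), matching the published tables;
base R's half-to-even would differ on exact ties. Machine-readable outputs
keep full precision.

## ROC and subset enumeration

`empirical_auc()` is the tie-corrected Mann–Whitney statistic computed via
midranks; `roc_curve()` builds the empirical step curve whose trapezoidal
area equals it to 1e-12 (ties appear as diagonal segments — the half-credit
convention). The tests verify both against exhaustive pair counting on
every small cohort and against an independent ROC implementation.

`enumerate_subset_aucs()` scores every $\binom{19}{k}$ marker subset by
its subset count and computes all AUCs exhaustively — $\binom{19}{6} =
27{,}132$ subsets is desk-scale (a few seconds) — in lexicographic marker
order, so output is deterministic with no sampling. On any informative
cohort the mean subset AUC rises and its spread falls with $k$, the
panel-size argument the enumeration exists to quantify.

PSA enters as a comparison score (raw value, higher = more suspicious);
patients missing PSA are dropped from the PSA curve only, with a logged
count.

## Paired and group comparisons

- **Per-marker DRE−FV differences**: paired t-test with t-based 95% CI.
  The published table reports a mean difference with symmetric CI and
  p-value, which identifies the paired-t family; zero-variance difference
  vectors are flagged degenerate rather than erroring.
- **Classifier comparison**: differences in sensitivity (among cases) and
  specificity (among controls), each with an exact two-sided binomial test
  on discordant pairs — exact McNemar, doubling the smaller tail of
  $\mathrm{Bin}(b+c, \tfrac12)$ capped at 1, so balanced discordants give
  exactly p = 1 — and a paired Wald interval on the difference (the
  interval method is not pinned by the source and is the conventional
  default).
- **Group comparisons**: Wilcoxon rank-sum via `stats::wilcox.test`,
  wrapped to use the exact distribution when the combined n ≤ 20 with no
  ties and the tie-corrected normal approximation (continuity-corrected)
  otherwise; the exact branch is validated against full enumeration.
- **Risk-grade correlation**: Pearson r with the Fisher-z interval
  $\tanh(\mathrm{atanh}\,r \pm z_{\alpha/2}/\sqrt{n-3})$. The closed form
  reproduces the published correlation intervals at the printed precision
  when evaluated among cases only, which is how the package applies it:
  the ordinal risk group (0 = negative biopsy; 1 = CAPRA 1–2; 2 = CAPRA
  ≥ 3) is correlated with average methylation among cases, with raw CAPRA
  scores accepted when available.
- **Quantiles** everywhere are type 7 (linear interpolation), R's
  default, so summaries are bit-reproducible.

## The synthetic cohort

`generate_cohort()` exists so every stage is testable with no patient
data. It emulates:

- **Cohort structure**: 42 cases / 52 controls; sample availability drawn
  as 60/94 paired, 27/94 DRE-only, 7/94 FV-only — the study design sizes.
- **Per-assay positivity**: calibrated to the published post-DRE
  proportions per biopsy stratum (`default_params_from_table2()`).
  Positivity is generated at **marker** level and split to assays through
  conditionally independent detection, mirroring the observation that two
  assays per island raise sensitivity. The decomposition
  $p_m = u_1 u_2 / (u_1 + u_2 - c)$ (assay rates $u_i$, merged rate $c$)
  is capped at 1; one island (RASSF5) has nearly disjoint assay positives
  and is infeasible under conditional independence, so the cap preserves
  its assay-level rates exactly while its merged rate deviates by ~0.01.
- **Levels**: positive reactions draw from a normal(6, 3) truncated to
  (0, 15], rounded to 0.1 (the Cq resolution), then back-transformed to
  $C_q = 32 - L$ so the generator exercises the real ingest path,
  duplicate wells included (the duplicate re-amplifies with probability
  0.9).
- **Paired structure**: a marker's state is shared between a patient's two
  samples with probability 0.8, else redrawn. The true within-patient
  agreement is unidentifiable from published summaries; 0.8 is a modeling
  choice, not an estimate. First-void detection is attenuated for the
  three assays reported as better recovered after DRE (AOX1rc ×0.6,
  GFRA2 ×0.9, NEUROG3 ×0.6, ratios read off the two strata's published
  proportions).
- **Clinical covariates**: PSA log-normal with medians 6.4 (cases) / 5.2
  (controls) and log-sd matched to the published means; age normal per
  stratum; elevated-risk membership with probability 20/35.
- **Risk-group effect**: a log-odds gap of 0.8 in case marker positivity
  between elevated- and low-risk cases, applied as a **centered contrast**
  (low-risk shifted down by the elevated fraction, elevated up by the
  low-risk fraction) so the marginal case rates stay at calibration —
  an uncentered shift would break parameter recovery by construction.

All randomness flows from a single mandatory seed; generation is
deterministic and fixtures are byte-identical across runs.

**What passing tests do and do not show.** The generator draws markers
independently within a patient (given stratum and risk group). Real
methylation markers are positively correlated — patients tend to be
globally heavily or lightly methylated — which spreads the control count
distribution. Independence concentrates it instead: at the same per-assay
calibration, the synthetic 6-of-19 operating point sits near sensitivity
0.95–1.00 and specificity 0.80–0.90, cleaner than real urine data, and the
count-score AUC near 0.98 rather than ~0.9. The end-to-end acceptance
bands are therefore set from the generator's own calibration (sensitivity
≥ 0.85; specificity in [0.60, 1]; case count medians 9–13 DRE / 8–13 FV,
control medians 1–6; score AUCs ≥ 0.85; specificity crossing 0.70 between
thresholds 4 and 9), chosen before the tests were run. Passing them shows
the pipeline's machinery is correct and its emergent behavior
qualitatively right; it does not validate the panel on real patients, and
quantitative reproduction of the real study requires its marker-level
supplement, which has no public accession.

## Problem sizes in the test suite

The suite runs the full pipeline at the study design size (94 patients),
the AUC oracle on all cohorts of ≤ 12 patients, sweep monotonicity on
1000 random cohorts, exhaustive subset enumeration at $k \le 6$, and
parameter recovery at 2000 patients per arm with full sample availability
(the size at which the ±0.03 recovery band is stated). The whole suite
completes in well under two minutes on one core.

## Known limitations

- The bisulfite-condition group attached to each assay in the default
  config is nominal metadata (the per-assay assignment is documented in
  assay-level material not modeled here); it feeds QC only and never
  enters scores.
- Recovery-control assays (NSD1, HOXD9 promoter) are tracked as per-sample
  QC counts; no automatic sample exclusion is applied on control failure.
- No absolute copy-number quantitation and no cross-batch normalization:
  levels are comparable within the assay conditions that produced them.
- No multiple-testing adjustment across markers (none is applied in the
  analysis this package implements); per-marker p-values are descriptive.
- Machine-learning panel selection (boosting, elastic net,
  cross-validated best-subset search) is out of scope; the subset-AUC
  enumeration covers the count-score combinatorics only.
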