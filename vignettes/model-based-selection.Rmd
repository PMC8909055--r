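---
title: "Model-based selection of proton therapy candidates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based selection of proton therapy candidates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonMBS)
```

## The problem

Intensity-modulated proton therapy (IMPT) can spare normal tissue that a
state-of-the-art photon plan (VMAT) must traverse, but proton slots are
scarce and expensive. For head-and-neck sites such as nasopharyngeal
carcinoma, the accepted way to triage patients is *model-based selection*
(MBS): optimize a rival proton plan for each photon-treated patient, convert
both dose distributions into predicted complication risks with published
normal tissue complication probability (NTCP) models, and refer the patient
to protons only when the predicted risk reduction is clinically meaningful.

`protonMBS` implements that pipeline end to end: dose-volume histogram (DVH)
quantifiers, a configurable 16-model NTCP registry, per-endpoint risk
differences, a weighted comprehensive toxicity score, the MBS eligibility
rule, paired cohort statistics, and a seeded generator of synthetic paired
cohorts so that every stage is testable without patient data.

## Dose quantifiers

A `structure_dvh` stores one structure's dose distribution on a common dose
grid, in differential form (volume fraction per dose bin) or cumulative form
(fraction receiving at least each dose); the two are interconvertible
exactly on the same grid, and the cumulative form is canonical internally.
From it the package computes:

* **Dx%** — the minimum dose received by the hottest x% of the volume,
  by linear interpolation between cumulative grid points. The field uses
  both interpolating and nearest-bin conventions; we adopt interpolation
  with the rule that flat segments of the cumulative curve resolve to the
  *highest* qualifying dose, which makes step DVHs (point masses) agree
  with the direct voxel-sorting answer. For the step DVH with half the
  volume at 40 Gy and half at 60 Gy, D50% is 60 Gy.
* **Davg** — the fraction-weighted mean dose.
* **CI** — conformity index: the fraction of the PTV receiving at least
  95% of its prescription dose. The volume count uses the "equal or
  higher" convention exactly (mass at the threshold is included), so a
  half/half DVH at 0.96 and 0.90 of prescription yields CI = 0.5.
* **HI** — homogeneity index, (D2% − D98%)/D50%; zero for uniform dose and
  invariant under dose rescaling.
* **Integral dose** — mean dose to the scanned body volume times that
  volume, in Gy(RBE)·cm³.

Structures only partially covered by the dose grid are handled by computing
on the covered fraction with a warning; nothing is imputed.

## NTCP layer

Each registry entry names an organ, a dose summary and a dose-response
form. The dose summary is the mean dose, a near-maximum dose Dx%, or the
generalized equivalent uniform dose

$$\mathrm{gEUD}(a) = \Big(\sum_i v_i\, d_i^{\,a}\Big)^{1/a},$$

the power mean over the differential DVH. `a = 1` recovers the mean dose,
large `a` the maximum (serial organs). For `a < 0`, zero-dose bins would
drive the power mean to zero; such bins are excluded with a warning and the
summary refers to the irradiated fraction (an all-zero distribution is
flagged undefined). Large `|a|` is stabilized by factoring out the extreme
dose.

Three functional forms cover the published model families:

* **Lyman–Kutcher–Burman probit**: $\Phi\!\big((S - TD_{50})/(m\,TD_{50})\big)$,
* **multivariable logistic**: $1/(1+e^{-(\beta_0 + \sum_i \beta_i x_i)})$,
  where one coefficient multiplies the dose summary and the others patient
  covariates (e.g. age),
* **log-logistic**: $1/\big(1+(D_{50}/S)^{4\gamma_{50}}\big)$.

All three are intrinsically bounded in [0, 1]; no clipping is ever applied.
A model whose organ or covariate is missing returns NA ("not evaluable")
with a warning — never silently zero — and is excluded pairwise from
downstream scores.

The shipped registry (`default_registry()`) carries the published
*structure* of the 16-model set — organs, endpoints, CTS weights (0.2
dysphagia, 0.2 xerostomia, 0.15 trismus, 0.1 brain necrosis, 0.1
temporal-lobe infarction, 0.07 each optic endpoint, 0.05 mucositis, 0.02
hypothyroidism, 0.01 tinnitus, 0.005 for six low-impact endpoints; summing
to unity), the 7-member MBS subset and both threshold sets — but the
dose-response parameters themselves are **synthetic representative values**
(the source publications' parameters are not redistributed here). The file
name and header say so explicitly; for clinical use each `parameters:`
block must be transcribed from the cited reference. Whether covariate-bearing
models are evaluated with patient-specific covariates or population defaults
was left open in the source analysis; the registry supports both and uses
patient values whenever present.

No fractionation (EQD2) conversion is applied: the analysis consumes
RBE-weighted physical dose as planned, and the registry makes that explicit
rather than offering a silent conversion.

## Scores and the eligibility rule

For each patient and model, $\Delta NTCP_{x-p} = 100\,(NTCP_{photon} -
NTCP_{proton})$ percentage points; positive values favour protons. Two
decision layers consume these:

* the **comprehensive toxicity score** $CTS = \sum_{i=1}^{16} w_i\,
  \Delta NTCP_i$, a clinically weighted summary of the whole toxicity
  profile. Because weights sum to unity the CTS is itself in percentage
  points, and the 11 models with weight ≤ 0.07 together carry exactly one
  quarter of the total weight, limiting the influence of many small gains;
* the **MBS rule**: a patient is eligible when any of the 7 key endpoints
  improves by *strictly more than* its threshold (standard set: 10 brain
  necrosis, 5 optic toxicity, 5 visual loss, 10 mucositis, 5 dysphagia, 15
  xerostomia, 10 trismus; relaxed "young" set 5/3/3/10/3/15/7.5), or when
  the summed gain over those 7 endpoints is *at least* 35 points (an ideal
  concomitant 5-point gain on each). The strict/non-strict asymmetry
  follows the rule's published wording and matters on boundary cases, so it
  is enforced and documented rather than harmonized.

Negative differences (proton worse) enter the composite sum as-is by
default; an optional clamp-at-zero mode exists and its use is recorded in
every verdict and report. The threshold mode is chosen per run and applied
to the whole cohort — the in-silico design assumes age does not change plan
optimization — with an optional per-patient age switch (< 40 years) for
sensitivity analyses. The "young" composite threshold stays at 35, since
only per-model young thresholds are published.

The published cohort counts are arithmetically inconsistent in one place
(five single-criterion patients quoted alongside 18 single / 10 composite /
20 total); `eligible_fraction()` therefore reports all four
inclusion–exclusion counts (single-only, composite-only, both, union)
explicitly rather than reproducing any single quoted figure.

## Cohort statistics

Per-endpoint photon-proton NTCP differences are tested with a two-sided
Wilcoxon signed-rank test at α = 0.05, implemented in the package rather
than delegated so that the small-sample branch is auditable: zeros are
dropped, tied absolute differences mid-ranked, and for n ≤ 12 the null
distribution of W⁺ is enumerated exactly over all 2ⁿ sign assignments of
the observed ranks. For larger n a continuity-corrected normal
approximation is used, with the variance computed from the observed
mid-ranks (which reproduces the classical tie correction exactly) and
refined by the fourth-cumulant Edgeworth term: the plain normal
approximation deviates from the exact enumeration by up to ~0.017 around
the branch crossover, while the refined version stays within ~0.002. No
multiple-testing correction is applied across the 16 endpoints — each is
reported at its nominal level, and every report carries a footnote saying
so.

The CTS comparison between eligible and non-eligible patients involves two
*independent* groups, although the published description names a
signed-rank (paired) test; the package defaults to the Wilcoxon rank-sum
test (delegated to `stats::wilcox.test`), exposes a signed-rank variant for
auditability (it requires equal group sizes), and records which was used.
Stratified passing-rate tables (all patients; T1–T2 vs T3–T4; N0, N1,
N2–N3) are computed from integer counts and rounded half away from zero to
one decimal.

## The synthetic cohort generator

No DVH data are deposited with the source analysis, so the generator is a
first-class module that emulates the *metric-level* conditions the analysis
assumes, not any anatomy. Defaults are the study conditions: 50 patients;
T-stage mix 40/14/30/16%, N-stage 16/28/30/26%, treatment 8/54/38%;
prescriptions in 33 fractions with a 69.96 Gy(RBE) high-dose level and
56.1/59.4 Gy(RBE) lower levels in a 24/20/56% scheme mix; 0.1 Gy dose grid.

Each structure's cumulative DVH comes from a two-parameter family — a
logistic sigmoid in dose, truncated to [0, d_max] and renormalized — chosen
because the source reports only metric-level behaviour, and this family is
smooth, strictly monotone and analytically invertible for calibration. The
location parameter is roughly the mean dose; per-structure `d_max` encodes
the clinical near-maximum constraint (e.g. 48 Gy spinal cord, 50 Gy optic
pathways, 74 Gy for structures overlapping the target). Photon dose
locations of OARs adjacent to the target (brain, optic pathways, cochlea,
superior pharyngeal constrictor) shift upward with T stage (0/2/5/8 Gy),
reproducing the mechanism by which advanced tumors irradiate neighbouring
organs harder. Proton plans multiply the location parameter by a
per-structure sparing factor with patient-level noise, keeping the spread
parameter fixed — so the gain concentrates in the low-to-middle dose range
while the high-dose tail shrinks less, and the proton cumulative curve is
dominated by the photon curve pointwise (proton mean dose can never exceed
photon mean dose by construction). Both plans' PTVs meet V(0.95·Rx) ≥ 0.95
by construction, verified as feasible before any sampling; target metrics
are therefore equivalent between modalities up to small jitter.

Per-structure sparing defaults (0.45–0.85) and DVH locations were chosen
once to give complication probabilities and photon-proton gains of
realistic magnitude for this anatomy — mean gains of roughly 12 points for
xerostomia, 2–3 for brain necrosis, 3 for mucositis, 5 for trismus, 7–9 for
tinnitus and hypothyroidism, and mean-dose reductions above 30% for distant
OARs such as cord and esophagus — and are fixed; they are calibration
targets in the family's parameter space, not reconstructions of any real
cohort. What passing tests show is therefore that the *pipeline arithmetic
and statistics* behave correctly under realistic dose structure; they say
nothing about inter-structure dose correlations (beyond the shared T-stage
shift), about real DVH shapes, or about the clinical validity of the
synthetic dose-response parameters.

One global seed drives everything through deterministic per-patient
substreams, so a cohort can be extended without reshuffling earlier
patients and identical seeds reproduce identical cohorts bit for bit.

`plant_effect()` inverts the generator: given a target fraction of patients
whose gain on some MBS endpoint should exceed its threshold, it bisects on
the sparing factor — under common random numbers on an internal reference
cohort (default 400 patients) — until the expected pass fraction matches.
This enables parameter-recovery testing: a configuration planted for a 24%
xerostomia pass rate yields observed 50-patient pass fractions inside the
exact binomial 95% interval around 0.24 in well over 90% of seeded
replicates.

## Numerical choices and degenerate inputs

* Dose grids must be strictly increasing; cumulative curves non-increasing
  within 1e-9; differential fractions are non-negative and sum to ≤ 1
  (tolerance 1e-9). Conversion round trips are exact to 1e-12.
* All-zero paired differences give a degenerate signed-rank test with p = 1
  by convention, flagged and logged.
* An empty eligibility group makes the CTS comparison "not testable", an
  explicit marker rather than an NA of unstated origin; single-patient
  groups report means but no test.
* Registry validation (weights summing to unity, thresholds present for
  every MBS member) happens at load time, never at scoring time.
* Percentage cells in reports use round-half-away-from-zero, so 0.05 → 0.1
  rather than banker's rounding.

## Problem sizes

The shipped test-suite and acceptance script run entirely on synthetic
cohorts: 50 patients for the cohort-level studies, 400-patient reference
cohorts for effect calibration, 200 replicates for recovery coverage, and
10,000 covariate-only draws for composition checks. These sizes were chosen
to keep Monte Carlo error well below the decision margins they support
(e.g. SE ≈ 2 points on a planted 24% pass fraction).

## Limitations

The package consumes DVHs; it does not optimize plans, parse DICOM-RT,
resample 3-D dose grids, or model variable proton RBE (doses are assumed
RBE-weighted upstream with the constant 1.1 factor). The shipped registry's
dose-response parameters are synthetic stand-ins; conclusions about real
patients require transcribing the published parameters and, ideally,
models validated for the treatment technique at hand. Confidence intervals
on NTCP differences and additional endpoints (hypoglossal palsy, carotid
stenosis) are out of scope.
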