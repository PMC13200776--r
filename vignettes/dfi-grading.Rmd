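---
title: "Grading facial palsy with the Digital Facial Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading facial palsy with the Digital Facial Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfigrade)
```

## The measurement model

Unilateral facial palsy weakens one hemiface. The Digital Facial Index
(DFI) turns 3D facial-landmark recordings of standardized movement tasks
into a single 0–100% score of facial function by exploiting the healthy
hemiface as the patient's own reference:

1. **Amplitude extraction.** For a movement task probing region
   $g \in \{\text{forehead}, \text{eye}, \text{mouth}\}$, each landmark's
   maximum Euclidean displacement (mm) from its rest-face position is
   computed across the capture window (default 5 s), and the per-side
   amplitude $A_{g,s}$ is the mean of these maxima over the region-side
   landmark set.
2. **Contralateral normalization.** The regional symmetry ratio is
   $r_g = \min(A_{g,\text{affected}} / A_{g,\text{contra}},\, 1)$.
3. **Weighted composite.**
   $\mathrm{DFI} = 100\,(0.1\,r_\text{forehead} + 0.4\,r_\text{eye} +
   0.5\,r_\text{mouth})$, so 0% is complete paresis and 100% intact
   function.

The movement battery comprises nine training movements (eyebrow
elevation, eye closure, cheek inflation, lip pursing, lateral mouth
movements right/left, wide mouth opening, mouth-corner elevation, showing
the teeth); diagnostic use needs only the three-grimace subset with one
task per region. Regions probed by several tasks (the mouth, by up to
six) use the *mean* of per-task ratios — the mean rather than the minimum
matches the graded character of the composite, where a single poorly
executed task should not dominate.

### Choices the score definition leaves open

The composite weighting and the 0–100% semantics are fixed; several
operational details are not, and this package resolves them as follows.

* **Amplitude aggregation** — per-landmark *maximum* displacement,
  *averaged* over the region's landmarks. The maximum makes the amplitude
  robust to frame rate (no resampling is ever done); averaging over
  landmarks suppresses single-landmark tracking glitches.
* **Head-motion removal** — facial and head motion are confounded in raw
  coordinates, so before measuring displacement every frame is rigidly
  aligned to the neutral frame by least-squares superposition (Kabsch) of
  the *midline* landmarks, which do not move laterally during the
  grimaces. With at least three non-collinear midline landmarks the
  alignment removes arbitrary per-frame rigid motion exactly; with fewer,
  only the translation is removed. Amplitudes are consequently invariant
  under rigid transforms of the whole scene (tested to 1e-9 mm).
* **Supranormal ratios** — an affected side moving *more* than the
  contralateral side is clipped to $r_g = 1$: the scale is defined only up
  to "normal" and renormalizing would let one region mask a deficit in
  another.
* **Dead zone** — when both sides of a region move less than 0.5 mm there
  is no evaluable motion and the ratio is set to 1 (absence of motion on
  both sides is not asymmetry); when only the affected side is below the
  threshold the ratio is 0. The threshold is a tunable argument
  (`dead_zone`, mm); 0.5 mm sits comfortably above sensor noise and below
  any voluntary movement.
* **Affected-side inference** — the clinic knows the affected side, a
  standalone tool must infer it: the side whose regional amplitudes,
  weighted by the composite weights, average smaller is reported. An
  exact tie is an explicit error asking for an override rather than a
  silent coin flip.
* **Rounding** — reports print one decimal; all internal computation is
  full precision.

## Scale conversion

Clinician scales are standardized onto a common percent-intact-function
axis by linear maps anchored at the scale endpoints: the Stennert Index
(0–10, inverse) as $(10 - \mathrm{SI}) \times 10$, the House-Brackmann
grade (I–VI, inverse) as $(6 - \mathrm{HBS}) \times 20$, and the
Sunnybrook composite (0–100, direct) and DFI as the identity. These
linear forms reproduce the anchor equivalence DFI 60% = SI 4 = HBS III =
SFGS 60 exactly; alignments *between* anchors are an interpolation of
this package, not a published calibration. Converting onto a discrete
scale rounds to the nearest grade with ties going to the worse-function
grade — when a percent sits exactly between two grades, conservative
clinical reporting prefers the more severe one.

```{r conversion}
convert_score("DFI", "SI", value = 60)
convert_score("DFI", "HBS", value = 60)
```

## Questionnaire scoring

* **FDI** — two five-item subscales (physical 1–5, social/well-being
  6–10) on a 1–5 response format. The published instrument description
  omits the transformation; the linear map
  $\mathrm{percent} = (\text{item sum} - 5) \times 5$ is used, which is
  the unique affine map sending the all-worst vector to 0 and all-best to
  100 and which reproduces the published end-of-study physical composite
  (85.0) from its printed item means exactly. One missing item is imputed
  by the respondent's subscale mean; more are refused — with 5 items any
  heavier imputation is guesswork.
* **SUS** — ten 1–5 Likert items; positive items (1,3,5,7,9) contribute
  `response − 1`, negative items (2,4,6,8,10) are reversed and contribute
  `5 − response`; the score is 2.5 × the sum of the ten 0–4
  contributions. `sus_from_adjusted()` accepts already-reversed 0–4
  values (e.g. published item means). Bands: ≥85 excellent, 70–84 good,
  50–69 acceptable, <50 poor.
* **Likert summaries** — per-item mean and sample SD (n−1); the overall
  score is the mean of item means. A single respondent yields SD 0 with
  an explicit flag rather than `NA` arithmetic downstream.

## Agreement statistics

The validation battery follows standard definitions: Spearman correlation
as the Pearson correlation of mid-ranks; Bland–Altman bias, SD of the
differences, and limits of agreement at exactly ±1.96 SD (the
conventional multiplier, not a t-quantile); the two-way mixed-model ICC
in all four type × unit forms from the balanced ANOVA mean squares; and
Cronbach $\alpha$, which is algebraically the consistency/average ICC
(property-tested to 1e-9). Differences in Bland–Altman are
`method_a − method_b`; passing the DFI as method A makes a positive bias
read "DFI more optimistic". Classification uses the Cicchetti ICC bins
(<0.4 unacceptable, 0.4–0.6 fair, 0.6–0.75 good, ≥0.75 excellent) and
the $\alpha$ bins (<0.7, 0.7–0.8, 0.8–0.9, ≥0.9), half-open with the
boundary in the upper bin.

Paired pre/post comparisons are gated by a Shapiro–Wilk test on the
differences at $\alpha = .05$: normal-looking differences use a paired
t test, others the Wilcoxon matched-pairs signed-rank test (both
delegated to `stats`). ICC significance is reported as the
$MS_R/MS_E$ F-test p-value plus a flag instead of suppressing
non-significant values, so the user sees every estimate with its
evidence. A table with zero between-subject variance has no meaningful
reliability; it is reported as ICC 0 with a `degenerate` flag.

## What the simulator emulates — and what it does not

`simulate_recording()` builds a mirror-symmetric canonical face (22
landmarks: three per region and side, four non-collinear midline points)
and drives the probed region's landmarks along a smooth half-sine
activation, chosen so that the max-displacement amplitude equals the
planted peak exactly in the noise-free case. The healthy side reaches a
peak of 8 mm — a realistic grimace excursion at millimetre scale — and
the affected side `8 × severity[region]`, so the planted severities *are*
the expected symmetry ratios. Isotropic Gaussian landmark noise (default
0, typical sensor level ~0.1 mm) is added per frame. Defaults: 31 frames
over 5 s (an odd count places a frame exactly at the activation peak).

`simulate_cohort()` draws per-patient baseline function from a normal
distribution (mean 40%, SD 15%, clamped to [0, 95]) — the published
cohort gives no distributional facts about baseline severity, so these
defaults are documented as plausible for acute palsy rather than
calibrated — and recovers it exponentially toward 100% at a log-normal
per-patient rate (mean 0.1/day), consistent with most scores converging
to near-normal by week four. Raters observe `truth + bias + noise` and
record it on each scale through the conversion scheme (SI and HBS
discretize; SFGS stays continuous); the DFI measurement is
`truth + dfi_bias + noise`. This truth-plus-noise structure is the
simplest model under which the planted ICC, Bland–Altman bias, and
Spearman targets have closed forms. `simulate_rater_table()` exposes the
pure two-way model (subject + rater + error) for variance-component
recovery tests.

The simulator does **not** emulate: landmark estimation error structure
of a real depth camera (correlated, expression-dependent), synkinesis or
other co-movement, task-to-task execution variability within a region,
head motion (tests add it synthetically via rigid transforms), or
missing/partial captures. Passing the planted-recovery tests therefore
shows the *pipeline arithmetic* is right, not that the score is valid on
real faces — that is what the clinical agreement statistics are for.

## Numerical and testing choices

* Zero-motion tolerance 1e-9 mm; ratio, weight, and identity assertions
  at 1e-9; noise-free planted-composite recovery at 1e-6.
* ICC implementation uses closed-form balanced sums of squares; the test
  oracle re-derives mean squares independently through `stats::aov` on
  long-format data, on exhaustive small tables (n ≤ 6, k ≤ 4) and random
  tables.
* Problem sizes in the test suite — 100-replicate noisy DFI recovery,
  50-patient slope recovery at 0.1 mm noise, 500-replicate ICC
  variance-component recovery at n = 30, single-table ICC recovery and
  planted +15-point Bland–Altman bias at n = 200 — are chosen so the
  Monte-Carlo error is several times smaller than the asserted tolerance
  while the whole suite stays interactive (~15 s).
* Fixed seeds throughout; the simulator restores the caller's RNG state,
  so library use never perturbs a user's random stream.

## Known limitations

Which landmarks a production depth-camera pipeline feeds into each region
— and whether it aggregates geometry or expression coefficients — is not
public; the landmark-geometry route here is a reconstruction, and the
region assignment table is user-overridable. The conversion chart between
non-anchor scale values is a linear interpolation. SFGS item-level
subscores (voluntary movement, resting symmetry, synkinesis) are out of
scope, as are synkinesis detection, longitudinal smoothing of repeated
DFI measurements, and any camera capture or face detection.
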