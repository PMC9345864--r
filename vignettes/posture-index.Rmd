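---
title: "Quantifying postural abnormalities from depth-camera landmarks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying postural abnormalities from depth-camera landmarks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PostureIPA)
```

## The measurement model

A subject stands 2 m in front of a depth camera, first facing it, then
turned 90°; in each orientation 5 s of relaxed stance and 5 s of actively
corrected stance are recorded at 30 fps. Each frame yields 3D positions of
six anatomical landmarks — midpoint of head (MH), midpoint of neck (MN),
C7 and L5 spinous processes, the vertebral fulcrum FC (the most convex
point of the spine), and the lateral malleolus (LM) — either directly, or
derived from a 25-joint Kinect-v2 skeleton.

The method assumes the camera is level, so the vertical image axis is the
gravity line: frontal-view frames are projected onto the coronal plane by
dropping depth, lateral-view frames onto the sagittal plane by dropping the
lateral coordinate, and in both projections the second coordinate is
vertical. No tilt or gravity calibration is applied, because the
acquisition protocol does not define one; a tilted camera biases all angle
features equally and is the user's responsibility to avoid.

Three geometric primitives generate all six features: the acute angle
between a segment and the vertical (`atan(|du|/|dv|)`, range 0–90°); the
deviation-from-collinearity angle between two segments (180° minus the
angle between their direction vectors, so an erect trunk scores 0); and the
perpendicular distance from a point to an infinite line. F7 = 100·D1/D2
normalises the spine's convexity by trunk length, removing anthropometric
scale: all six features are invariant under uniform scaling and rigid
in-plane translation of the skeleton, which the test suite verifies by
construction.

Angles are reported unsigned. The published healthy-control means are small
and positive, which is consistent only with deviation-from-neutral
magnitudes; left/right or forward/backward signedness is deliberately not
encoded.

## Aggregation and windows

Each feature is the **median** of its per-frame values over one protocol
window. The median (rather than the mean) makes the estimate robust to
transient tracking glitches: corrupting any minority of frames leaves the
feature unchanged, which is tested explicitly. Frames with degenerate
geometry (coincident landmarks) are excluded with a warning; a window is an
error only when empty or entirely degenerate.

By default features come from the **relaxed** windows — the habitual
posture is what the index is meant to grade — and the corrected stance is
retained for optional reporting via `windowPolicy = "corrected"`. Window
boundaries are read from file metadata when present and otherwise inferred
from the protocol (first 5 s relaxed, next 5 s corrected, per view).

## Deriving landmarks from a Kinect-v2 skeleton

The mapping MH=Head, MN=Neck, C7=SpineShoulder, L5=SpineBase is fixed (and
overridable through the run configuration), since the features are defined
on anatomy, not on sensor joints. LM is the midpoint of the two ankle
joints; if only one ankle is tracked it is used alone. The midpoint choice
is the package's own: the protocol does not say which malleolus was used,
and in the lateral projection the two nearly coincide.

FC is defined only anatomically ("most convex point of the spine"), so the
package operationalises it as the point of maximal perpendicular distance
to the C7–L5 line along a quadratic Bezier curve with control points
SpineShoulder, SpineMid, SpineBase, evaluated in the sagittal projection.
The curve is sampled at 51 equally spaced parameter values; on smooth
spines the 51-point maximum agrees with a 10,001-point brute-force search
to well under 1 mm, i.e. far below sensor noise, which the tests verify.
Ties — including the fully collinear spine, where every sample is at
distance zero — break toward the most cranial sample, with a 1e-12 m
floating-point tolerance so that exact arithmetic ties do not resolve by
rounding accident.

## The index and its cut-offs

The index is the linear combination with weights 0.132, 0.126, 0.165,
0.113, 0.067, 0.400 on F1, F2, F3, F4, F5, F7. The weights are the
published feature importances of the upstream decision-tree model and are
constants here; they sum to 1.003 and are **not renormalised**, because the
published worked examples (group mean features → group mean index)
reproduce only under the printed values. Linearity means a cohort's mean
index equals the index of its mean feature vector — the identity the
package's acceptance checks exploit.

Classification uses the published cut-offs 12.96 (PD vs healthy controls)
and 20.14 (PD with vs without postural abnormalities), with boundary scores
classifying positive; the inequality direction is not stated in the source
material, and `>=` keeps reported sensitivities intact when a score lands
exactly on a cut-off.

## The statistical layer

* **Normality gate.** Group comparisons of numeric variables run a
  Lilliefors-corrected Kolmogorov–Smirnov test per group at α = 0.05; both
  groups normal → Student's t test, otherwise Mann–Whitney U. Groups with
  fewer than 8 observations never pass the gate: the Lilliefors
  approximation has essentially no power there, and tiny samples belong
  with the rank test (whose exact p-value is used for untied samples up to
  n = 12 per group, a normal approximation with continuity correction
  otherwise).
* **Categorical variables** use the chi-square test without continuity
  correction, which reproduces the published gender comparison.
* **Spearman correlation** uses average ranks for ties and pairwise-complete
  deletion, with interpretation bands on |rs| at 0.10/0.40/0.70/0.90.
* **Simple regression** reports the standardised slope (the z-scored
  regression coefficient) and the one-predictor adjusted
  R² = 1 − (1 − R²)(n − 1)/(n − 2), which can be negative for null fits.
* **ROC.** The AUC is the rank (Mann–Whitney) statistic with ties counted
  one half. Candidate cut-offs are the midpoints between adjacent distinct
  scores plus sentinels beyond both extremes; the returned cut-off
  maximises Youden's J, with ties broken toward higher specificity — the
  screening-friendly choice. The 95% CI is DeLong's (computed through
  pROC), a normal approximation whose bounds can exceed [0, 1] just as
  published intervals do. Accuracy bands: <0.7 low, 0.7–0.9 moderate,
  >0.9 high.
* **No multiple-testing correction** is applied anywhere, matching the raw
  p-value reporting convention of the validation workflow.

Covariate-adjusted AUCs are out of scope: no standard adjustment method is
implied by the source material, so none is guessed.

## The synthetic-data generator

`makePosture()` inverts the feature definitions: in the sagittal plane L5
sits at the origin with LM one leg length straight down, the L5→C7
direction at F4 from vertical, FC on the ray at F5 with its distance solved
so that 100·D1/D2 equals F7 (D1 grows linearly along the ray while D2 is
fixed), and the head segment at F3; the frontal plane analogously realises
F1 and F2 over a vertical leg. Noise-free extraction therefore recovers the
targets to machine precision, which is the package's strongest
end-to-end correctness check. Unsatisfiable targets are rejected: F7 > 0
requires F4 ≠ F5, F7 = 0 forces F5 = F4, and the fulcrum may not sit more
than 1.6 trunk lengths from L5 (a generous anatomical bound). Isotropic
Gaussian jitter (default SD 5 mm, typical of depth-camera landmark
tracking) is added per landmark per frame; corrected-stance windows hold
the targets scaled by 0.5, a plausible partial self-correction.

`simulateCohort()` draws each subject's six features **independently** from
zero-truncated normal distributions. Only marginal group moments are
published, so independence is the minimal assumption. The truncated
distributions are *mean-matched*: the location parameter is solved (by
`uniroot` on the closed-form truncated-normal mean) so the truncated mean
equals the published group mean exactly, while the scale is the published
SD. Plain truncation of a normal with the published parameters would bias
means upward by up to 0.4° for near-zero features, and matching both
truncated moments exactly is infeasible where the published mean/SD ratio
is below the truncated-normal minimum (e.g. controls' F2, 0.3 ± 0.6); exact
means were chosen because the index's published group means are the
quantities the emulation must reproduce, at the cost of a somewhat
shrunken realised SD for features concentrated near zero.

**What passing synthetic tests do and do not show.** Real features are
correlated (severe posture deforms several angles at once) and non-normal;
the independence assumption narrows the simulated within-group index SD
relative to the published one (e.g. ≈1.4 vs 1.6 for controls, ≈5 vs 7.3 for
the abnormal-posture group). Consequently the simulated PD-vs-control AUC
(≈0.999) exceeds the binormal-theory reference computed from the published
pooled index moments (≈0.977), and the simulator makes no attempt to match
published AUCs, sensitivities or correlation coefficients —
`runValidationStudy()` reports both numbers side by side and says so in its
notes. What the synthetic study does establish is structural: the step-like
ordering of all six feature means across control / without / with
postural-abnormality groups, the significance of the index contrast between
the PD subgroups, and the internal consistency of the ROC machinery against
brute-force oracles.

## Numerical choices

* CSV/JSONL writers print doubles with 17 significant digits, so write/read
  round trips are bit-exact.
* The feature extractor and geometry primitives are vectorised over frames;
  angle computations use `atan2` and clipped `acos`, so boundary
  configurations (horizontal or vertical segments) are exact rather than
  special-cased.
* Cohort sampling uses inverse-CDF draws, making every simulated dataset a
  deterministic function of the seed.
* Test problem sizes: property suites use 1,000 random frames for the
  extraction oracle, 100 random target sets for the round trip, 200-point
  ROC inputs, and cohorts of 10,000 per group for the law-of-large-numbers
  checks and 300–500 per group for the study-level checks — sizes at which
  Monte-Carlo error is far below the asserted tolerances while the full
  suite stays fast.

## Known limitations

* No camera-tilt or gravity calibration; a tilted camera biases all angles.
* One subject per recording; multi-person scenes and tracking are the
  capture system's job.
* The feature weights and cut-offs are fixed published constants; the
  package does not refit them.
* The simulator emulates marginal feature distributions only; correlated or
  skewed real-world feature structure, medication state, and within-session
  posture drift are not modelled.
* Published patient-level results (correlation tables, regression
  coefficients, empirical AUCs) cannot be reproduced without the original
  cohort; the package covers them with property-based and band-labelling
  checks instead.
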