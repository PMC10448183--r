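---
title: "Facial kinematics from landmark trajectories: models, features and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Facial kinematics from landmark trajectories: models, features and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Blunted facial expressivity is a core negative feature of at-risk mental
states (ARMS) for psychosis. Given only per-frame facial-landmark
trajectories extracted from brief interview videos — the 51 points numbered
17–67 in the standard 68-point annotation scheme, jawline excluded —
`facekin` asks whether a participant can be classified as ARMS or control
from the *movement statistics* of the face alone, and whether the features
driving that classification track clinician-rated negative symptoms
(SIPS items, notably N2 Avolition and N3 Expression of Emotion).

The package deliberately avoids pre-set expression codings such as facial
action units: every landmark's raw kinematics enters the feature set, and
the model decides what matters.

## Per-frame geometry

Each frame's 51 points are condensed to interpretable scalar signals:

* **Eye aspect ratio (EAR)** on each eye's six landmarks
  $p_1,\dots,p_6$:
  $\mathrm{EAR} = \dfrac{\lVert p_2-p_6\rVert + \lVert p_3-p_5\rVert}{2\lVert p_1-p_4\rVert}$.
  The per-frame EAR is the mean of the left (42–47) and right (36–41) eye;
  per-eye values exist internally. EAR collapses toward 0 during blinks and
  is invariant under similarity transforms, so camera distance and head
  roll do not contaminate it.
* **Mouth aspect ratio (MAR)** on the inner-lip points 60–67, by direct
  analogy: three vertical inner-lip distances over twice the corner
  distance. The cited aspect-ratio construction does not fix the landmark
  set; we chose the inner lips because they close completely, making the
  closed-mouth value near 0 and speech openings large.
* **Head-pose Euler angles.** A synthetic neutral 3-D face template
  (shipped as `face_template_3d_synthetic.csv`, units ≈ mm) is fitted to
  six stable 2-D correspondences (33, 27, 36, 45, 48, 54 — all inside the
  51 used points) under a pinhole camera with focal length = image width
  and principal point at the image centre. The rotation is parametrised as
  $R = R_z(\mathrm{roll})\,R_y(\mathrm{yaw})\,R_x(\mathrm{pitch})$ and the
  fit is a damped Gauss–Newton (Levenberg–Marquardt) minimisation of
  reprojection error, warm-started from the previous frame. Published
  landmark-based pose estimators rarely state their formulas; this
  solver is our reconstruction and is validated by forward-simulation
  tests (known poses recovered within 0.5°, identity pose within 1e-3°).
* **Nose-anchored point angles**: for each other landmark $j$, the
  per-frame angle $\operatorname{atan2}(y_j-y_{33},\,x_j-x_{33})$, in
  image convention (y down). Series crossing the ±180° branch cut are
  unwrapped before summarisation so the cut itself contributes no
  artificial dispersion.

## The 649-feature inventory

Recordings differ in length, so time series are summarised per participant
with robust statistics (IQR with type-7 interpolated quantiles; unscaled
MAD, since the MAD is used as a summary, not a σ estimator; Tukey-fence
outlier fraction; lag-1 partial autocorrelation; Spearman rank
correlation). The published total is 649 features, but the exact inventory
lives in unavailable supplementary material; the default manifest is a
documented reconstruction constrained to that total:

| group | features | count |
|---|---|---|
| coordinates | 51 pts × 2 axes × {IQR, MAD, outliers, PACF₁} | 408 |
| nose-anchored angles | 50 series × {IQR, MAD, outliers} | 150 |
| symmetric-pair Spearman | 21 mirror pairs × 2 axes | 42 |
| Euler angles | 3 × {IQR, MAD, outliers} | 9 |
| EAR | {IQR, MAD, outliers, PACF₁, % below Q1} | 5 |
| MAR | same five | 5 |
| movement speed | inter-frame displacement MAD, 30 expressive pts | 30 |

The manifest is plain data (`default_feature_manifest()`,
`read_feature_manifest()`), so an alternative inventory drops in without
code change. Open choices resolved here: the outlier rule is the Tukey
1.5·IQR fence (no rule is published); PACF uses lag 1 (no lag is named);
the EAR "below first quartile" reference uses the pooled *training-cohort*
EAR Q1 rather than each video's own quartile — a per-video Q1 pins the
feature near 25% by construction and destroys its between-subject
information (a per-video mode remains available by passing
`ear_q1_reference = NULL`).

## Selection and the classifier

Feature selection is gradient-boosting importance (xgboost, no row or
column subsampling, one thread — deterministic; `"gain"` by default,
`"split"` available), staged as: rank the 649 base features, keep the top
*m* = 40; append all *m(m−1)/2* pairwise products named `"a * b"`;
re-rank and keep the top *k* = 30. The staging and the sizes are our
reconstruction — the source describes products of features surviving
selection but not the exact procedure; *m* = 40 keeps the product stage
(~860 columns) well-conditioned against ~90 training rows.

The classifier is discrete AdaBoost over random-forest weak learners
$G_m$: the committee is $G(x) = \operatorname{sign}\sum_m \alpha_m G_m(x)$
with $\alpha_m = \eta \cdot \tfrac12\log\frac{1-\mathrm{err}_m}{\mathrm{err}_m}$
and case weights multiplied by $e^{\mp\alpha_m}$ for correct/incorrect
classifications. The published operating point — 900 estimators, learning
rate η = 2, forests of 5 depth-1 trees with log₂(p) candidate features —
is the default. η = 2 is unusually large for AdaBoost; it is retained as
published and configurable. Scores in [0, 1] are the normalised
α-weighted vote; the decision threshold is 0.5 (the published work does
not state its threshold).

## Evaluation

Monte Carlo cross-validation: 100 random 70/30 splits by default,
stratified per class with a floor — on 58 ARMS / 70 controls every split
trains on 40 + 49 = 89 and tests on 39, preserving prevalence
(stratification is our choice; the split proportion is published, the
stratification is not). Inside each split, *everything* data-dependent is
recomputed from the training rows only: the pooled-EAR Q1 reference, the
per-feature imputation medians, the two-stage selection and the fit.
Mutation tests assert that perturbing held-out rows changes none of these.
Metrics are sensitivity, specificity, F1, balanced accuracy
(≡ (sens + spec)/2, asserted per split to machine precision) and rank
AUC; the averaged ROC is vertical averaging on a fixed 101-point FPR grid
with the origin pinned at (0, 0). Permutation feature importance is the
mean held-out F1 drop over within-column permutations, summed per feature
across splits.

Convergent validity dichotomizes each SIPS negative item at scores 0–1
(absent) versus ≥ 2 (present) and applies a two-sided Wilcoxon rank-sum
test per feature, with the tie-corrected normal approximation at cohort
sizes and the exact null distribution when both groups have ≤ 12
observations (the regime the enumeration oracle tests exercise). P-values
are reported per feature without multiplicity correction, matching
per-feature reporting in this literature; a Benjamini–Hochberg column is
available via `adjust = "BH"`.

## The synthetic cohort generator

No videos or landmark files are deposited with the source study, so the
generator *defines* the study conditions under which the pipeline is
validated: 58 ARMS / 70 control participants, 3000 frames at 10 fps
(≈ 5-minute recordings). Each trajectory is the 3-D template animated by

* AR(1) Euler-angle head motion (φ = 0.95; stationary SDs 3°/4°/2°
  pitch/yaw/roll), keeping PACF features non-degenerate;
* transient smile (4/min) and brow-raise (6/min) events with raised-cosine
  time courses, plus a continuous speech-like mouth-opening process that
  also moves the mouth corners;
* blinks at 15/min closing the eyelid landmarks;
* i.i.d. Gaussian landmark jitter (SD 0.5 px), emulating localisation
  noise,

projected through the same pinhole camera the pose solver assumes. The
ARMS effect is amplitude attenuation of all expression events (default
0.6) plus reduced head-motion variability (default 0.7), mirroring the
blunted-expressivity interpretation and loading on exactly the feature
families the published model selected (dispersion, outlier, symmetric-pair
correlation). Participants draw individual expressivity and motion scales
log-normally (SDs 0.25 / 0.15) around their group values, and synthetic
N2/N3 scores increase stochastically as realized expressivity falls, so
feature–symptom coupling is real by construction. Event rates and
amplitudes were fixed once at physiologically plausible magnitudes.

What the generator does *not* emulate: landmark-tracking failures and
occlusions, camera motion, speech-content structure, demographic
covariate effects, and any facial morphology differences — so green tests
certify the pipeline's statistical machinery under its assumed data model,
not clinical performance on real video.

## Calibration bands and problem sizes

The published headline metrics (F1 83%, specificity 89%, sensitivity 81%,
balanced accuracy 85%, ROC-AUC 93% over 100 splits of 128 real
participants) are not reproducible without the cohort; the only analytic
check they admit is (81 + 89)/2 = 85. The stochastic acceptance checks are
therefore *calibration bands of our synthetic construction*: with both
effect parameters neutral the full pipeline must evaluate at chance (mean
AUC in [0.40, 0.60]); at the default effect (0.6 attenuation / 0.7 motion
ratio) mean AUC must exceed 0.75; and across the three-point grid
(1.0/1.0, 0.6/0.7, 0.4/0.5) mean AUC must be non-decreasing within
Monte-Carlo error (±0.03). These runs use 128 participants, 50 splits and
a 100-forest ensemble — problem sizes chosen so the whole calibration
completes in minutes on a single core while leaving the Monte-Carlo error
of a 50-split mean AUC (≈ 0.01) far smaller than the band widths. At these
settings the default-effect cohort evaluates around AUC ≈ 0.94 and
balanced accuracy ≈ 0.85.

## Numerical choices and degenerate inputs

* Quantiles are type-7 everywhere (R's default), MAD unscaled.
* Undefined statistics (zero-variance PACF/Spearman, degenerate EAR
  frames, failed pose fits) become `NA` and are imputed at table level
  with training-split medians — the smallest intervention compatible with
  split-wise evaluation; the per-feature missingness is visible in the
  feature table.
* Gaps in frame indices up to 5 frames are filled by linear
  interpolation; longer gaps are recorded breaks, never fabricated, and
  inter-frame speed is not computed across them.
* Boosting stops early on a perfect round or a round no better than
  chance; a chance-level first round keeps one learner with negligible
  weight so prediction stays defined.
* Selection ties (including never-used features at importance 0) break by
  column order, making ranking deterministic.
* All randomness fans out from one master seed via a fixed integer
  recurrence, so any split or permutation can be reproduced in isolation.

## Known limitations

The 649-feature inventory, the selection staging, the pose solver and the
EAR-quartile reference are documented reconstructions of under-specified
published choices; alternatives can be swapped in (manifest as data,
`importance_type`, per-video EAR mode, selection sizes). PACF treats a
segmented recording as concatenated, slightly biasing autocorrelation at
break points. The rank-sum normal approximation is used above n = 12 per
group even though moderate samples would admit exact computation with
ties. The generator's realism ceiling is discussed above.
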