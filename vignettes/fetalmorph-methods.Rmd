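---
title: "Methods: SES scoring, hull-based cortical folding metrics, and the association model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SES scoring, hull-based cortical folding metrics, and the association model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fetalmorph` implements a quantitative-MRI analysis pipeline for studying
how parental socioeconomic status (SES) relates to fetal brain development:
SES scoring, label-based volumetry, convex-hull-referenced cortical folding
metrics, and a mixed-effects statistical battery, together with a seeded
synthetic-data generator that provides ground truth for every stage.  This
vignette explains the models and the choices behind them.

## The socioeconomic score

Parental education and occupation are each coded on an ordinal 1-5 scale
(lowest to highest).  The two-factor index of social position combines them
as

$$\mathrm{score} = 7 \times \mathrm{occupation} + 4 \times \mathrm{education},$$

giving integers from 11 (unemployed, minimal schooling) to 55 (higher
executive, post-college education).  A family is assigned to the *high* SES
group when either parent's score is **strictly** above the configurable
threshold (default 51, the cohort median in the motivating study);
"higher than" is read as a strict inequality throughout the package, so a
score equal to the threshold maps to *low*.  When one parent's score is
missing, the present parent decides; a family with no score at all is an
error rather than a silent default.  Homemakers and the unemployed are
occupation level 1 — there is no separate "not in labor force" code.

Maternal distress is flagged per MRI visit: high distress means at least one
completed questionnaire total **strictly** exceeds its threshold (SSAI 40,
STAI 40, PSS 15, EPDS 10).  Visits with no completed questionnaire are
flagged missing, never low, and distress-adjusted models use complete cases
with the dropped count reported on the fit.

## Volumetry

A `label_volume` is a 3-D integer grid plus a 4x4 voxel-to-world affine in
mm.  The volume of a label set is the voxel count times
$|\det A_{3\times3}|/1000$ cm^3 — always world geometry, never an isotropic
assumption.  Tissue volumes (cortical gray matter, white matter, deep gray
matter, cerebellum, brainstem, ventricles) come from the segmentation image;
lobe volumes come from the parcellation image, by default restricted to the
white-matter mask of the segmentation (so "frontal lobe volume" is frontal
WM), with a full-lobe mode available.  The exact parcellation-code
composition of each lobe is a configuration input, not a constant, because
label conventions differ across segmentation tools.

Whole-brain volume is the sum of the five tissue classes *excluding* the
ventricles — ventricular CSF is not brain tissue — and the composition is
configurable and checked (the sum identity is exact by construction).

## Cortical folding metrics

Both metrics are computed on the gray-white junction (the inner surface of
the cortical gray matter), which is segmented more reliably than the pial
surface, and both are referenced to the convex hull of the hemisphere's
surface vertices.  One hull per hemisphere is used for both metrics, which
avoids cross-midline artifacts and keeps the two metrics consistent.

**Sulcal depth** at a vertex is the Euclidean distance to the nearest point
of the hull surface, minimised with the exact point-to-triangle distance
over all hull facets (compiled kernel).  Gyral crowns touch the hull
(depth ~0); fundi are deepest.

**Local gyrification index (LGI)** at a vertex is the ratio of the surface
area to the hull area inside a Euclidean ball of radius $r$ centred at the
vertex.  The "circular region on the surface" is implemented as the
ball-surface intersection rather than a geodesic disc: it is the standard
tractable choice for hull-referenced LGI, and the hull side of the ratio has
no meaningful geodesic analogue on a different surface.  The default radius
is 10 mm, appropriate to fetal-brain scale (hemisphere radius ~30 mm) and
larger than typical mesh edge lengths; it is exposed as `lgi_radius`
everywhere.

Numerical choices:

* **Triangle inclusion.**  A triangle's area is attributed to the ball when
  its centroid lies inside (`inclusion = "centroid"`).  Because hull facets
  bridge entire sulci and can be much larger than the ball, all facets are
  first 4-split until every edge is at most $r/4$; this makes the centroid
  rule a good quadrature of the true intersection.  An adaptive
  exact-clipping mode (`inclusion = "clip"`, recursive subdivision of
  boundary-crossing triangles) exists for validation; the two agree within
  5% on folded test surfaces.
* **Undefined vertices.**  If the ball captures zero hull area (a fundus
  deeper than $r$), LGI is undefined at that vertex: it is flagged `NA`,
  excluded from aggregates, and warned about — never imputed.
* **Hull robustness.**  The incremental hull resolves degenerate inputs
  (cospherical rings, coplanar facets) with a deterministic
  symbolic-perturbation jitter of relative size 1e-10 used only for facet
  selection; reported facets use the original coordinates, and containment
  holds to well under 1e-6 mm at brain scale.  Truly coplanar point sets are
  rejected.
* **Aggregation.**  Regional summaries are area-weighted by default
  (barycentric vertex areas, so the regional mean is a surface integral over
  the region); an unweighted per-vertex mode is available.  Area weighting
  was chosen because it is invariant to remeshing density, which per-vertex
  means are not.

Invariance properties verified by the test suite: rigid motions change
neither metric beyond 1e-6; uniform scaling by $s$ (with $r$ scaled
likewise) leaves LGI unchanged and multiplies depth by $s$; convex surfaces
sit at the LGI = 1, depth = 0 limit; both metrics increase with fold
amplitude.

## The association model

Each SES measure (education, occupation, score — continuous, or the low/high
group coded 0/1) is related to each morphometric outcome with a linear
mixed-effects model

$$y_{ij} = \beta_0 + \beta_{\mathrm{SES}}\,x_i + \beta_{GA}\,GA_{ij}
  + \beta_{sex}\,s_i + b_i + \varepsilon_{ij}, \qquad
  b_i \sim N(0, \tau^2),\; \varepsilon_{ij} \sim N(0, \sigma^2),$$

with a random intercept $b_i$ per fetus absorbing intra-subject correlation
across repeated scans.  Sex is coded female 0 / male 1.  Estimation is REML
(`lme4`); the contract is a nonnegative random-intercept variance, however
the optimizer parameterises it.  Inference on $\beta_{\mathrm{SES}}$ is
two-sided Wald ($z = \hat\beta/\mathrm{SE}$, 95% CI $\hat\beta \pm 1.96\,
\mathrm{SE}$); with ~144 subjects the difference from Satterthwaite degrees
of freedom is negligible, and the simpler rule is documented rather than
hidden.  Rank-deficient designs error naming the collinear columns;
non-convergence and singular variance fits are flagged on the result.

The nonparametric battery mirrors standard practice: Wilcoxon-Mann-Whitney
on midranks (exact permutation enumeration up to pooled n = 20 — valid with
ties — otherwise the tie-corrected normal approximation with continuity
correction; both groups' rank sums are reported since conventions differ on
which one is "the" statistic), Pearson chi-square without continuity
correction, Spearman correlation with the t approximation, and a
Kolmogorov-Smirnov normality test.  Because the normal's mean and SD are
estimated from the sample, the KS p-value uses the Lilliefors correction by
default; the plain KS p (valid only for fully specified nulls) is available
explicitly.  Benjamini-Hochberg q-values are computed within declared
families — the 5 tissue types form one family and the 4 lobes another, per
predictor and feature — matching how such results are reported.  The
significance convention is two-sided 0.05 everywhere.  Inter-rater
agreement uses the two-way random-effects absolute-agreement single-measure
ICC from ANOVA mean squares.

Growth rates for twice-scanned fetuses are per-subject slopes
$(y_2 - y_1)/(GA_2 - GA_1)$, compared between SES groups by rank-sum.

## The synthetic-data generator

No fetal MRI cohort of this kind is publicly deposited, so the generator is
a first-class module: it emulates the study conditions and plants known
effects so every downstream stage can be validated.

* **Cohort structure.**  144 subjects, 40 of them with a longitudinal pair
  (184 scans); GA 24-39.4 weeks, singles uniform over the window,
  longitudinal first scans in the early third trimester with a 4-8.5 week
  gap; P(male) = 75/144.
* **SES distributions.**  Education and occupation level probabilities are
  the published cohort tables (education skewed to college/graduate levels,
  occupation bimodal); the two parents' latent traits are linked by a
  Gaussian copula with correlation 0.5.  The true inter-parent correlation
  is not published; 0.5 is a free modelling parameter, not a claim, and is
  configurable.
* **Outcomes.**  Each outcome follows the linear mixed model above with the
  SES slope planted on the *maternal* score.  Default slopes carry the
  published directions and magnitudes (CGM negative; WM, cerebellum,
  brainstem, lobe volumes positive; LGI and sulcal depth negative), and the
  per-outcome noise SDs are back-derived from the published 95% CIs
  (SD ~ SE x SD(score) x sqrt(n)), so simulated precision matches what such
  a study actually resolves.  The random-intercept SD defaults to 0.7x the
  per-scan noise SD.  Distress questionnaires are completed by 58.3% of
  subjects.
* **Surfaces.**  A folded hemisphere is an icosphere (10·4^s + 2 vertices)
  displaced radially by a seeded band-limited spherical-harmonic field
  (degrees 2 to `max_degree`, Gaussian coefficients) normalised to unit RMS
  and scaled by `amplitude` in mm.  This gives one amplitude knob that is
  provably zero-fold at 0 (exact sphere, the convex limit) and monotonically
  deepens folds.  Vertex labels are the four spatial quadrants, documented
  stand-ins for lobes — real parcellations are not emulated.
* **Volumes.**  Label grids are built either with exact per-label voxel
  counts (compact blobs grown in world distance from a seeded voxel) or as
  rasterised ellipsoids; regions never overlap.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: MRI intensities, motion artifacts, segmentation
errors, realistic sulcal geometry (spherical-harmonic folds are smoother and
more isotropic than real sulci), spatial covariance between neighbouring
regions, and SES-correlated missingness.  Recovery of planted effects
validates the estimator chain, not the biology.

## Validation design

Two choices in the study-scale checks deserve explanation:

* **Parameter recovery** uses a planted SES slope of half a per-scan noise
  SD on a single outcome, 50 seeded cohorts at n = 144.  At the
  paper-matched default effect sizes the single-fit relative SE is 25-45%
  (the published t statistics are themselves only ~2-4), so a 50-replicate
  mean would measure Monte-Carlo error rather than estimator bias; a
  well-powered planted effect makes the 5% mean-bias bound a test of the
  estimator.
* **The sign-direction check** (CGM negative; WM, cerebellum, brainstem
  positive) is asserted on the *mean* estimate over 10 seeded
  default-parameter cohorts, because at realistic noise a single cohort
  reproduces the full joint sign pattern only ~3 times in 4 — the brainstem
  effect is as marginal in simulation as it is in print.

Problem sizes throughout the suite (icosphere level 3-4 surfaces, 20^3
label grids, 50-200 Monte-Carlo replicates) were chosen as the smallest
scales at which the tested properties are stable.

## Known limitations

* The Euclidean-ball LGI differs from geodesic-disc formulations; values are
  comparable within a study but not across definitions.
* The hull is built per hemisphere from vertices alone; a hemisphere whose
  medial wall is open (non-closed mesh) still gets a valid hull, but depth
  near the opening reflects the hull cap, as with any hull-referenced
  method.
* Wald inference can be mildly anticonservative for very few subjects;
  with n in the dozens and upward this is immaterial, but the fit result
  carries everything needed to recompute p-values differently.
* Count-mode synthetic label regions are compact but not anatomically
  shaped; they validate bookkeeping (counts, affines, additivity), not
  segmentation realism.
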