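---
title: "1D airway-network modelling of asthma with fixed airway obstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{1D airway-network modelling of asthma with fixed airway obstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaycfd)
```

## The problem

Asthma with fixed airway obstruction (FAO; post-bronchodilator FEV1/FVC
below 0.7) carries worse lung function and faster decline than reversible
obstruction, but spirometry alone says little about *where* and *how* the
obstruction acts. Quantitative CT at two breath-holds — total lung
capacity (TLC) and functional residual capacity (FRC) — supplies airway
geometry, lobar air volumes, and registered voxel-density pairs. This
package turns those inputs into computational phenotypes: normalized
structural metrics, parametric-response-map (PRM) functional percentages,
and regional pressures from a dynamic one-dimensional airway-network
simulation, followed by a pooled two-group statistical comparison.

Because patient CT data cannot be redistributed, the package ships a
synthetic cohort generator whose group-level distributions are
parameterized by the published summaries for the two asthma groups
(24 subjects without FAO, "group A"; 12 with, "group B"). Every stage of
the pipeline runs, and is tested, against that generator.

## Healthy-reference geometry

The anchor of all structural normalization is a regression of tracheal
diameter on demographics fitted to 222 healthy Korean adults:

$$D_{trachea,pred}\,[\mathrm{mm}] = 12.79 - 0.13\ln(age)
  - 5.82\ln(height)\,sex + 3.01\ln(age)\ln(height),$$

with height in meters, age in years and sex coded 0 (male) / 1 (female).
Note the model has no standalone height term for males — height enters
only through the sex interaction and the age-height interaction; the
equation is implemented exactly as published. A companion table of
generational diameter ratios $D_{aver}$ (per lobe, generations 2–10,
shipped as `inst/extdata/daver_table.csv`) converts the tracheal
prediction into a healthy caliber for any (lobe, generation):

$$D_{ave,pred} = D_{trachea,pred}\times D_{aver},\qquad
  D_{ave}^{*} = D_{ave}/D_{ave,pred}.$$

$D_{ave}^{*}$ is the constriction/dilation index: near 1 in health, below
1 under constriction. Generations deeper than the deepest tabulated entry
reuse the deepest ratio (the ratios visibly flatten with depth; no
extrapolation rule is published), and generations shallower than a lobe's
first entry are an error rather than a guess.

```{r}
demo <- demographics(sex = 0, height = 1.70, age = 60)
predict_trachea_diameter(demo)
predict_generation_diameter(demo, "LUL", 2)
```

## Completing the tree beyond CT resolution

CT resolves airways down to roughly 2 mm. Beyond that, conducting
branches are grown by recursive volume filling: each growing branch owns
part of a lobar point cloud; the cloud is split by the plane through its
centroid that contains the branch direction (oriented along the dominant
point spread); a child is extended from the parent's tip a fraction
(default 0.4) of the way to each half's centroid. Growth into a half
stops when the half holds no more points than `point_threshold` (default
1 — a branch grown toward a single seed point is terminal) or the
candidate length falls below `length_limit` (default 1.2 mm). The
construction is fully deterministic given the cloud; all stochasticity
enters later through diameters.

Horsfield orders are then assigned bottom-up (terminals are order 1; a
parent is one more than its highest-ordered child) and each grown branch
receives a healthy caliber from the classical power law
$D(\nu) = D_a\,r^{\nu-\nu_a}$ anchored at its lobe's attachment branch
*predicted* (not measured) diameter, so that disease enters only through
the next step: every grown branch is multiplied by an independent draw
from the lobe's Normal(mean, SD) of $D_{ave}^{*}$ computed over the CT-
resolved branches of that lobe. Draws at or below 0.05 are redrawn (a
non-positive caliber multiplier is unphysical; the positivity guard is
the package's choice), and a child is finally capped at its parent's
caliber.

The per-order ratio defaults to $r = 1.4$, the literature value for human
conducting airways; with the default 24 seed points per segmental
attachment the grown subtrees run 5–7 orders deep, which places terminal
calibers around 0.5–0.7 mm — the anatomical scale of terminal
bronchioles and consistent with the published terminal means
(0.543/0.590 mm). These defaults are set once from anatomy, not fitted.

## The breathing cycle and the pressure decomposition

Boundary conditions follow the study setup: a sinusoidal tidal volume
$V(t) = \tfrac{V_T}{2}(1-\cos 2\pi t/T)$ with $V_T = 1$ L and $T = 4$ s,
and a fixed global respiratory compliance $C = 0.2$ L/cmH2O for all
subjects (so group contrasts reflect anatomy, not tissue properties).
Geometry at time $t$ interpolates node coordinates, diameters and lengths
between the FRC and TLC trees through the inflation fraction
$\lambda = V(t)/(V_{TLC}-V_{FRC})$. Only two imaged states exist, so the
geometry is necessarily linear in $\lambda$; the Akima spline smoothing
named in the source model is applied to the $\lambda(t)$ knot series
(an Akima interpolant needs at least three knots, which two static images
cannot anchor per branch). Both methods reproduce the endpoint trees
exactly and close the cycle at $t = T$.

At each step the inlet flow $Q(t) = dV/dt$ is apportioned to terminal
branches, each branch's viscous drop is
$\Delta P = \gamma(\mathrm{Re})\,128\mu L Q/(\pi D^4)$ — Poiseuille, with
an optional (default) Pedley entrance-effect factor
$\gamma = \max\!\big(1, \tfrac{c}{4\sqrt2}\sqrt{\mathrm{Re}\,D/L}\big)$,
$c = 1.85$ — and node pressures are running sums along each path from the
tracheal inlet (the zero reference). Wall compliance and parenchymal
inertance terms of the source dynamic model are deliberately omitted:
the solve is quasi-static and resistive on moving geometry, which is
sufficient for pressures reported at two cycle instants.

The decomposition is:

* $P_{alv}$ — mean pressure at the distal nodes of terminal branches
  (the trachea-to-terminal pressure drop; negative during inspiration);
* $P_{tp} = V_{lung}/C$ with $V_{lung} = V_{FRC,air} + V(t)$ — the
  elastic recoil load;
* $P_{pl} = P_{alv} - P_{tp}$, so the identity
  $P_{tp} = P_{alv}-P_{pl}$ holds to machine precision by construction.

Peak inspiration (PI) and peak expiration (PE) default to the peak-flow
instants $t = T/4$ and $3T/4$: the alveolar drop is a flow-driven
quantity, largest in magnitude and opposite in sign at peak flow, which
matches the reported sign pattern ($P_{alv} < 0$ at PI, $> 0$ at PE);
the end-inspiration alternative is exposed as
`phase_indices(definition = "end_volume")`. Workload per cycle is
$\left|\oint P_{pl}\,dV\right|$, and the $P_{pl}$–volume loop is returned
as the hysteresis curve.

### Flow apportionment at desk scale

Lobar flow shares follow each lobe's TLC−FRC air-volume change — the
regional ventilation that image registration provides in the clinical
pipeline. Within a lobe, the package's simulations split the lobar share
in proportion to each terminal branch's viscous conductance $D^4/L$
rather than uniformly. The reason is scale: a few hundred generated
terminals stand in for tens of thousands of real acinar pathways, so a
*prescribed* uniform split forces 100-fold-concentrated flows through
stochastically constricted 0.3 mm terminals and lets a handful of
branches dominate the alveolar mean — a numerical artifact a real
resistive network resolves by redistributing flow. The conductance split
keeps every lobar share exactly as prescribed while representing that
redistribution; the uniform split remains available
(`terminal_weights(within_lobe = "uniform")`).

This scale compression also means absolute $|P_{alv}|$ from the default
synthetic trees (a few hundred Pa) runs higher than the published
cohort means (tens of Pa, computed on trees grown to acinar scale).
Signs, identities, scalings and group directions are the quantities the
model preserves — and the ones the test suite asserts.

## QCT metrics

PRM classification of registered density pairs uses the standard
thresholds: a voxel is emphysematous when inspiratory density
< −950 HU, else air-trapped (functional small airway disease, fSAD) when
expiratory density < −856 HU, else normal. The study describes its
thresholds only as "adjusted", so the standard values are the documented,
configurable default and are recorded in output metadata. Percentages are
reported per lobe and for the pooled total (voxel-weighted, not a mean of
lobes). Structural metrics are the hydraulic diameter $D_h = 4A/P$ and
wall thickness over 11 regions (six central branches and five subgrouped
segmental regions averaged unweighted over their constituent segments),
normalized by the predicted tracheal diameter and a predicted tracheal
wall thickness. The wall-thickness reference equation is not published;
it is a pluggable constant/callable defaulting to 1.5 mm, which rescales
$WT^{*}$ uniformly without touching group contrasts.

## Statistics

Each variable is compared between groups by a Shapiro–Wilk-gated choice:
Welch's unequal-variance t-test when both samples look normal
(p ≥ 0.05 in each), otherwise the Mann–Whitney U test with the
tie-corrected normal approximation (the unequal group sizes, 24 vs 12,
make pooled-variance t fragile). All comparisons from a pipeline run —
demographics, lung function, PRM, structure, constriction, pressures —
form a single Benjamini–Hochberg family, mirroring the pooled testing of
the study; the family contents are explicit in the report so sub-family
behaviour is reproducible. Spearman correlations (mid-ranks,
t-approximation p-values) link lung-function variables to computational
outputs. Calibration of the gated test at the study's group sizes is
asserted by simulation in the test suite (type-I error within
[0.04, 0.06] at nominal 0.05).

## The synthetic cohort

`generate_cohort()` draws, per subject:

* demographics — sex to match the group's published split (4/20 male/
  female in A, 8/4 in B), age and BMI from the published means/SDs;
  heights are not published and default to Normal(1.70, 0.06) m for men
  and Normal(1.57, 0.055) m for women;
* lung function — pre/post FEV1, FVC and FEV1/FVC from the published
  distributions, with post-bronchodilator FEV1/FVC truncated at the 0.7
  boundary that *defines* the groups;
* a canonical resolved tree (trachea, main bronchi, bronchus
  intermedius, lobar bronchi, 19 labelled segments) whose lobe-labelled
  calibers are $D_{ave,pred}\times D_{ave}^{*}$ with per-branch FRC draws
  from the published per-lobe means/SDs, and whose central calibers
  follow the published normalized hydraulic diameter profiles;
* the TLC caliber of every branch as its FRC caliber plus a positive
  inflation increment (mean 0.10 in group A, 0.05 in group B, truncated
  ≥ 0.01). The published table gives only FRC columns; encoding TLC as
  "FRC minus a decrement" would make airways *narrower* at full
  inflation, violating the branchwise TLC ≥ FRC constraint, so the
  package instead gives the stiffer, remodelled FAO group a smaller
  dilation on inflation — which reproduces the reported direction (TLC
  constriction deeper in group B relative to A) while staying physical;
* lung air volumes — FRC air Normal(1.28, 0.36) L in group A and
  Normal(1.82, 0.59) L in group B. These are back-computed from the
  published transpulmonary pressures through $P_{tp} = V/C$ (871 and
  1138 Pa at peak inspiration imply ≈1.78 and ≈2.32 L with the 0.5 L
  tidal contribution) and encode the air-trapping contrast that drives
  the pleural-pressure separation; inspiratory capacity adds
  Normal(2.6, 0.4) L truncated ≥ 1.2 so every subject can take the 1 L
  tidal breath;
* PRM density pairs from a three-component HU mixture — emphysematous
  insp/exp Normal(−980, 15); fSAD insp Normal(−880, 25), exp
  Normal(−880, 20); normal insp Normal(−850, 40), exp Normal(−750, 60) —
  whose weights are solved from the per-component classification
  probabilities so the *expected classified* percentages equal the
  group's published lobe targets under the default thresholds.

What the generator does **not** emulate: scanner noise and reconstruction
kernels, registration error fields, true anatomical variation in branch
angles and lobe shapes (lobar point clouds are uniform ellipsoids with
fixed centers), within-subject spatial correlation of disease, or any
correlation between a subject's PRM burden and their airway caliber
beyond what the group labels induce. Passing tests therefore demonstrate
that the *methods* recover the statistical structure they assume, not
that they would behave identically on clinical images.

The QC rule from the study is applied before analysis: subjects whose
expiratory/inspiratory volume ratio exceeds 90% are excluded for
inadequate expiration (strictly greater — a ratio of exactly 0.9 stays).

## Numerical choices and degenerate inputs

* Quadrature is trapezoidal; at 1000 steps the inspired-volume identity
  holds to 8e-7 L.
* The quasi-static solve is exact per time step (path sums), so junction
  conservation holds to rounding; the suite asserts 1e-9 relative.
* Degenerate point sets (empty, coincident) are errors, not silent
  no-ops; a point cloud already within `length_limit` of its attachment
  legitimately grows nothing.
* A single-branch lobe reports SD = 0 and its multiplier distribution
  collapses to the mean; a constant sample routes the normality gate to
  the Mann–Whitney branch (Shapiro–Wilk is undefined on constants).
* Ties in ranks use mid-ranks; the Mann–Whitney p uses the tie-corrected
  normal approximation with continuity correction.
* Seeds: the cohort master seed determines every draw; subject-level
  seeds are exposed for isolation. All simulation stages are
  deterministic given the completed trees.

## Problem sizes

Default runs use 36 subjects (24 + 12), 24 seed points per segmental
attachment (≈ 400–450 terminals per subject), 2000 density voxels per
lobe, and 40 time steps per breathing cycle; a full pipeline run takes
well under a minute on one CPU. Recovery tests use 1e5 voxels (PRM
percentages to ±1 point) and 2000 null replicates (test calibration).
These sizes were chosen so the Monte-Carlo tolerances quoted in the test
suite are comfortably resolved.

## Known limitations

* Absolute alveolar-pressure magnitudes are scale-compressed (see
  above); comparisons between groups and against thresholds are
  meaningful, absolute Pa values are not clinically calibrated.
* The pleural decomposition is global: one compliance, one lung volume.
  Regional heterogeneity of compliance is out of scope by design.
* The energy-balance resistance closure is Poiseuille/Pedley; turbulence
  and unsteady (inertance) effects are not modelled.
* The constriction statistics feeding the stochastic completion come
  from few resolved branches per lobe (2–6), so per-subject SD estimates
  are noisy — as they necessarily are in the clinical pipeline too.
```{r}
set.seed(1)
subject <- generate_subject("B", id = "demo")
subject <- complete_subject(subject)
sim <- simulate_subject(subject)
sim
```
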