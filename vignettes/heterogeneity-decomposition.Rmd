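---
title: "Decomposing symptom heterogeneity with three-mode PCA: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing symptom heterogeneity with three-mode PCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetcube)
```

## The problem and the model

Repeated symptom-questionnaire data form a three-mode array: `n` persons ×
`m` symptoms × `T` time points. Heterogeneity lives in all three modes and in
their interactions — which symptom domains stay elevated for which kinds of
patients in which phase of treatment. Single-slice latent variable models
(latent class analysis cross-sectionally, growth mixtures longitudinally)
each address one mode and are not mutually compatible.

`hetcube` fits the Tucker3 decomposition

$$X_{ijk} = \sum_{p=1}^{P}\sum_{q=1}^{Q}\sum_{r=1}^{R}
  a_{ip}\, b_{jq}\, c_{kr}\, g_{pqr} + e_{ijk},$$

with column-orthonormal loading matrices $A\ (n \times P)$,
$B\ (m \times Q)$, $C\ (T \times R)$ and a free core array
$G\ (P \times Q \times R)$. Orthonormal loadings with a free core are the
standard identification; the solution is still rotation-indeterminate within
each mode's column space, which matters for how recovery can be measured
(see *Identifiability* below). No rotation (varimax or otherwise) is applied
to fitted solutions.

Model assumptions worth keeping in mind: entries are treated as continuous
in least squares even though the scores are ordinal (standard practice in
multiway analysis of questionnaire data); residuals are implicitly
homoscedastic across cells; and the data must be complete — the
decomposition has no missing-data mechanism, so incomplete persons are
rejected at cube assembly, never imputed.

## Preprocessing

Two steps, both invertible affine maps whose parameters are stored:

* **Fiber centering** — each (item, time) fiber is centered across persons.
  This removes, per symptom and week, the mean level shared by all patients,
  so the fitted components describe heterogeneity *around* the common
  course (for a treatment cohort: the general downward trend). Grand-mean or
  per-person centering would not remove that shared trajectory, which is why
  they are not offered.
* **Slab normalization** — each item's $n \times T$ slab is divided by its
  root mean square, so every item contributes equal total variance
  ($\sum_{i,t} x_{ijt}^2 = nT$ per item, total sum of squares $nmT$).
  Without it, coarsely scored high-variance items dominate the fit. The
  option `normalize = "none"` exists for sensitivity analysis.

A zero-variance item slab cannot be normalized and raises an error naming
the item. Tolerances (fiber means below 1e-12, slab mean squares within
1e-9, round-trip within 1e-9) are asserted in the test suite.

## Fitting: alternating least squares

Fitting is higher-order orthogonal iteration: each sweep replaces one mode's
loadings with the leading left singular vectors of the data projected on the
other modes' current loadings. Each update maximizes the explained sum of
squares given the other two matrices, so the fit trace is non-decreasing —
a property the test suite checks on every run. Defaults: relative fit-change
tolerance 1e-8, at most 500 sweeps, 5 starts (HOSVD plus 4 seeded random
orthonormal starts). The core is the projection
$G = X \times_1 A' \times_2 B' \times_3 C'$, and
$\mathrm{fit} = 100\,(1 - \mathrm{SSE}/\mathrm{SST})$ on the preprocessed
cube.

Reproducibility conventions: every column's largest-magnitude entry is made
positive (sign flips absorbed into the core); components within each mode
are ordered by descending explained sum of squares (core-slice sum of
squares), ties by original index; all randomness derives from one master
seed via counter-keyed sub-streams, so identical calls are bit-identical
across runs.

Degenerate requests are handled explicitly: component numbers above a mode's
size are errors; when a requested mode rank exceeds what an unfolding can
support (e.g. $P > QR$, where the extra columns cannot carry signal), the
basis is completed with deterministic orthonormal columns whose core slices
are zero.

## Choosing the component numbers

`grid_search()` fits every combination up to the given bounds. Each cell's
start set includes the zero-padded best solutions of all coordinate-wise
smaller neighbours, which guarantees fit is monotone along every grid
coordinate. Grid cells use a lighter setting (tolerance 1e-6, 200 sweeps,
no extra random starts) since the grid is only ranked; the selected model is
refit at full precision. On an 82 × 12 × 9 cube a (4,4,4) grid takes a few
seconds.

`select_model()` makes the informal "fit percentage versus number of
parameters" trade-off reproducible: it returns the smallest model (by total
component count, then lexicographically) whose fit cannot be improved by at
least `min_gain_percent` (default 1.0) fit-percentage points *per added
component* by any expansion of at most one component per mode. Expansions
must be judged jointly rather than one mode at a time: a Tucker3 mode's
effective rank is capped by the product of the other two modes' counts, so
$(2,1,1)$ always fits exactly like $(1,1,1)$, and a rule probing single-mode
steps only could never leave the smallest model. The free-parameter count
reported alongside is $nP + mQ + TR + PQR - P^2 - Q^2 - R^2$, the raw
parameter count minus the rotational indeterminacy absorbed by
orthonormality.

The threshold of 1 percentage point per component is a visible-elbow
convention, not an optimality claim; the full grid is always emitted so any
other rule can be applied. One consequence worth knowing: on pure noise at
small $n$ (a few dozen persons), the leading singular directions of a random
matrix capture more than one fit point each, so the rule can report
structure; at the study scale (82 × 12 × 9) noise gains stay below the
threshold.

## Interpretation tables

`assign_components()` applies the boldfacing rule used in component-score
tables: each entity (item, week, or person) is assigned to the component
with the largest absolute score. Ties go to the lower component index;
near-ties (absolute gap < 0.05) and negative dominant scores are flagged
rather than hidden. `core_table()` lists all $P \cdot Q \cdot R$ core
entries in long format, person-component major — with $(3,2,2)$, twelve
rows. Narrative component labels (such as "persisting phase") are
user-supplied strings only; the package never infers meaning.

### Identifiability and recovery measurement

`match_components()` greedily pairs estimated and reference columns by
maximal absolute Tucker congruence
$\phi(x,y) = \sum x y / \sqrt{\sum x^2 \sum y^2}$, reporting the signed
$\phi$ per pair. Because the model is invariant to rotating $A$ and
counter-rotating $G$, column-wise congruence against an arbitrary planted
basis is ill-defined; the planted-cube generator therefore reports its
ground truth in the canonical (HOSVD, sign-fixed) parameterization of the
planted signal. Recovery claims then mean: the canonical basis of each
planted subspace is recovered.

## Latent variable baselines

* **Latent class analysis** (`fit_lca`): a K-class multinomial mixture with
  local independence, fitted by EM; the M-step's weighted category
  frequencies make the observed log-likelihood non-decreasing. Free
  parameters: $(K-1) + 2Km$ for 3 categories.
* **Growth mixtures** (`fit_growth_mixture`): K-class mixtures of
  $T$-variate normals with quadratic mean curves
  $\beta_0 + \beta_1 t + \beta_2 t^2$ on weeks $t = 1..T$ (raw, uncentered
  time — this affects only the $\beta$ parameterization). `"lcgm"` fixes all
  growth-parameter variances at zero (covariance $\sigma^2 I$); `"gmm_ri"`
  adds a random intercept (compound symmetry $\tau^2 J + \sigma^2 I$);
  slopes and quadratic terms never get random effects. Fitting is
  expectation/conditional-maximization: class curves by generalized least
  squares given the variances (with a common design this reduces to GLS on
  the responsibility-weighted mean trajectory), then exact variance updates
  via the compound-symmetry eigendecomposition ($\sigma^2 + T\tau^2$ on the
  constant direction, $\sigma^2$ elsewhere), with the $\tau^2 \ge 0$
  boundary handled by pooling. Each conditional step increases the EM
  objective, so the log-likelihood trace is monotone, and fixing
  $\tau^2 = 0$ reproduces the LCGM exactly — the nesting the comparison
  relies on.

Design choices where the convention was open: the residual variance
$\sigma^2$ (and $\tau^2$) is shared across classes — with classes of a
dozen persons, class-specific variances are fragile, and shared variances
match common software defaults for these models. Classes are ordered by
descending weight before any comparison (label switching), and a warning is
raised when a class holds fewer than 10 persons. Exact multinomial/normal
densities are used throughout, so log-likelihoods, AIC
($-2\ell + 2k$) and BIC ($-2\ell + k\ln n$, $n$ = persons) are absolute.

## Synthetic data: what it emulates, and what not

The original patient-level data are not publicly deposited, so all numeric
work runs on seeded generators.

**Planted Tucker3 cubes** (`generate_planted_cube`) draw random orthonormal
loadings and a core, add white noise, and return the canonical ground truth
(see above). Two design points:

* The core is *balanced*: a few sweeps replace each mode-unfolding's
  singular values by a mildly decaying profile (ratio 0.85, total sum of
  squares fixed at $PQR \cdot \mathrm{core\_scale}^2$). With an iid-normal
  core, the smallest mode singular value — the smallest singular value of a
  near-square Gaussian matrix — is frequently near zero, i.e. the generator
  would advertise a third person component that carries under one fit point
  and is rightly not selected. Balancing makes every planted component
  material, so "the planted triple" describes the data it labels.
* Noise can be specified directly (`noise_sd`) or via a target construction
  fit (`target_fit`), with
  $\mathrm{fit} \approx 100\,s/(s + \sigma^2 nmT)$ for signal sum of squares
  $s$; `target_fit = 80` reproduces the fit regime of interest for this
  design (a strong but noisy structure).

**QIDS-like cohorts** (`generate_qids_like`) build a continuous latent
severity per person-item-week: a shared downward trend
($1.45 - 0.22(t-1)$ in latent units) plus an archetype × domain × phase
interaction, thresholded at fixed global cutpoints (0.45, 1.45) into 0–2
scores (per-item cutpoints would be realistic but opaque; the raw 0–3 mode
exists to exercise the recoding rules, with the mutually exclusive
appetite/weight alternatives held at zero). The planted structure is
(3,2,2): three person archetypes (quick recovery; persistent
somatic/affective; increasing), two symptom domains of six items each, and
an early (weeks 1–5) versus late (weeks 6–9) phase split. The slow/worsening
severity class for the growth models *is* archetype 3 (12% of persons,
against 88% quick) — tying the trajectory split to the archetype keeps the
person mode three-dimensional instead of silently planting a fourth
direction.

Defaults (archetype weights 0.50/0.38/0.12, effect scale 1.9, loading
jitter 0.30, latent noise SD 0.95) were calibrated once so that the default
dataset selects (3,2,2) under the default elbow rule — the calibration is a
property of the fixture design. Two forces trade off: ordinal thresholding
is a saturating nonlinearity, and with too little latent noise it manufactures
spurious higher-order person components (weak selection of (4,2,2)), while
latent noise dithers the thresholds and linearizes the mapping at the cost
of explained variance. The defaults land at roughly 43–46% fit for the
selected model. What the generator does **not** emulate: per-item threshold
differences, floor/ceiling asymmetries of real QIDS items, serial
correlation of measurement errors, dropout, and any claim about the actual
cohort's parameter values. Passing recovery tests on these cubes shows the
estimator and selection machinery work under the planted regime — not that
real depression data have this structure.

**LVM generators** (`generate_lca_data`, `generate_growth_data`) sample
exactly from the fitted model classes. For the LCA recovery study the
"separated profiles" condition is instantiated as category probabilities
(0.90, 0.07, 0.03) versus (0.03, 0.07, 0.90) with equal weights: at
$n = 1000$ the binomial standard error of a within-class frequency near
$p = 0.2$ is about 0.018, so the maximum over 72 estimated cells would
exceed a 0.05 error bound by sampling error alone under milder separation —
the bound presupposes profiles about this separated.

## Problem sizes and runtime

The test suite and acceptance script run at the study's own scale
(82 × 12 × 9 cubes; grids to (4,4,4); 20 replicates for recovery and
selection studies; LCA at $n = 1000$; growth mixtures at $n = 200$–500),
chosen so the full suite completes in a couple of minutes on one core while
keeping the Monte-Carlo properties sharp.

## Known limitations

* No missing-data support by design; persons with incomplete measurements
  must be excluded upstream.
* No CANDECOMP/PARAFAC, Tucker2, constrained cores, bootstrap confidence
  intervals, or rotation of solutions.
* The growth mixtures implement exactly the two covariance structures
  compared here; no random slopes/quadratics, no class-specific residual
  variances, no robust (sandwich) standard errors.
* Exploratory factor analysis with oblique rotation is outside the package;
  the assignment rule it shares with the component tables is implemented,
  the estimator is not.
* ALS converges to local optima; multiple starts mitigate but do not
  guarantee global optimality.
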