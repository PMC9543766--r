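---
title: "Mixed-kernel SVR for UPDRS telemonitoring: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-kernel SVR for UPDRS telemonitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixsvr)
```

## The regression model

`mixsvr` fits ε-insensitive support vector regression: a function
$f(x) = \sum_i \theta_i K(x_i, x) + b$ that is as flat as possible in the
kernel-induced feature space while keeping training residuals inside a
tube of half-width ε (in UPDRS points). Residuals inside the tube incur no
loss; excesses are penalized linearly, with the box constraint
$|\theta_i| \le C$ bounding each observation's influence. Only the linear
ε-insensitive loss is implemented — quadratic and Huber variants exist in
the literature but are not part of this package's scope.

The problem is solved in its dual form by sequential minimal optimization
(`svr_fit()`, C++ core in `src/smo.cpp`): each iteration selects the
maximal-KKT-violating pair of dual variables and solves that
two-variable subproblem in closed form. The working-set rule is
deterministic, so fits are bit-for-bit reproducible; the `seed` slot of
`svr_control()` is accepted for interface stability but currently has no
effect. Tests verify the solver against an independent interior-point
quadratic-programming solution (`kernlab::ipop`) and against a hand-solved
two-point fixture whose optimum, $f(x) = 0.8x + 0.1$ with dual objective
$0.32$, is known exactly.

**Bias handling.** The prediction formula of the dual is often written
without the offset $b$; the primal formulation contains it, and standard
ε-SVR requires it, so predictions here always include $b$. It is recovered
from the tube-boundary conditions of free support vectors
($0 < |\theta_i| < C$ places the point exactly on the tube edge), averaged
over all free points; when no free point exists (e.g. constant targets,
where the optimal coefficient vector is zero), every observation
constrains $b$ to an interval and the midpoint of the intersection is
used, which returns the target value itself in the constant case.

**Degenerate settings.** ε = 0 is allowed — the tube collapses and nearly
all points become support vectors, which is expected and occasionally
selected by the grid search on smooth synthetic data. Duplicate training
points merely make the Gram matrix rank-deficient (still positive
semi-definite). Non-convergence within the iteration cap
(`max_iter`, default $10^5 n$) raises a typed condition carrying the
best-so-far diagnostics rather than returning silently.

## Kernels and admissibility

Four kernel families are provided: radial basis
$K_{RB}(x,z) = \exp(-\gamma\|x-z\|^2)$ (local), polynomial
$K_P(x,z) = (1 + \sigma\langle x,z\rangle)^p$ (global), their convex sum
$\beta K_{RB} + (1-\beta) K_P$, and their product $K_{RB} \cdot K_P$. A
plain inner-product kernel exists for hand-solvable fixtures. Mercer
admissibility is checked empirically: the symmetric Gram matrix on the
training points is diagonalized and the fit refuses kernels whose minimum
eigenvalue falls below $-10^{-8} n$ (the tolerance scales with $n$ to
absorb floating-point eigenvalue noise on large matrices).

The radial kernel is evaluated with a **negated exponent** and γ > 0. The
positive-exponent variant $\exp(+\gamma\|x-z\|^2)$ is unbounded and
demonstrably indefinite — on the three points {0, 1, 2} with γ = 1 its
Gram matrix has a large negative eigenvalue — so it cannot serve as a
similarity measure; it remains available via `kernel_rbf(negate = FALSE)`
solely so that the admissibility check can demonstrate the failure.

**Kernel parameter defaults.** Both γ and σ default to $1/d$, where $d$ is
the feature dimension. For γ this is the common radial-basis heuristic.
For σ the same scaling keeps $\sigma\langle x,z\rangle$ of order one on
standardized features — with σ = 1 the degree-$p$ kernel grows like
$d^p$, producing badly scaled Gram matrices as dimension increases — and
matches the convention of the libsvm family of implementations, where the
polynomial kernel's inner-product scale defaults to $1/d$. The polynomial
degree defaults to 2, the degree used by the grouped analysis; the
sum-mixture weight defaults to β = 0.8 (local-dominant), the value
selected in the original telemonitoring analysis.

## The tuning, splitting, and grouping protocol

`split_patient_proportional()` assigns recordings to tune/train/test
(8/72/20 by default) within each patient by largest-remainder rounding of
that patient's recording count, so every patient contributes proportional
replication to each subsample; which recordings go where is random and
seed-reproducible. Patients with fewer recordings than labels are
allocated by the priority train > test > tune. Because the rounding rule
of the original 476/4223/1176 split is unstated, per-label totals can
differ from those counts by a few recordings. The tuning subset can
alternatively be drawn uniformly across recordings
(`tune_mode = "uniform"`), since a uniform draw is equally consistent
with its description; the patient-proportional mode is the default for
consistency with the train/test statement.

`grid_search()` fits one model per grid point (ε ∈ {0, 0.1, …, 1},
C ∈ {2², …, 2⁹}; 88 points by default) **on the tuning subset** and scores
it **on the training subset**; the winner — minimum validation RMSE, ties
broken toward smaller C then smaller ε, preferring flatter and sparser
models — is refit on the training subset, and the test subset is touched
only by the final evaluation. The selection metric is a package decision
(telemonitoring analyses report MAE/R²/RMSE without singling one out),
as is the absence of cross-validation inside the search: a single held-out
subset is used, consistent with standard practice for SMO-based fits at
this scale. Grid points whose fit fails to converge are flagged and
excluded rather than aborting the search.

`assign_groups()` stratifies patients into the four gender × age groups
with the cut at 65 years; an age of exactly 65 joins the older group (the
source describes "under" and "over" 65 and never places the boundary).
`tune_per_group()` then runs an independent grid search and fit per group
on voice-only features (the grouping already encodes the demographics),
with polynomial degree 2 — mirroring the stratified analysis — and
reports per-group metrics, their unweighted across-group averages, and
gain percentages relative to a reference model via `gain_table()`.

## Metrics

`mae()`, `rmse()`, and two R² variants are computed side by side.
`r2_ratio()` is the explained-variation ratio
$\sum(\hat y_i - \bar y)^2 / \sum(y_i - \bar y)^2$ — the form printed in
the telemonitoring analysis. It is nonnegative and **can exceed 1** when
predictions are more dispersed than the observations
(`r2_ratio(c(0,1), c(-1,2))` is 9), so the conventional
`r2_standard()` = $1 - RSS/TSS$ is always reported alongside. Gains are
percentage decreases for the error metrics and percentage increases for
R². Metric rows always satisfy MAE ≤ RMSE (power-mean inequality), which
the test suite asserts on arbitrary data.

## The synthetic cohort generator

`synth_generate()` emulates the telemonitoring data's documented
structure: 42 patients (two-thirds male), ages from a normal distribution
centred at 65 (sd 9) truncated to 36–85, roughly weekly recording
sessions with repetitions across 180 days, UPDRS anchors at days 0/90/180
linearly interpolated to the recording times, and voice features built
from a Gaussian factor model that induces pairwise correlation 0.9 inside
the jitter (5 features) and shimmer (6 features) blocks and −0.6 between
HNR and NHR. Feature marginals match cohort-scale means and standard
deviations; 70% of each feature's variance is a stable patient level, the
rest recording-to-recording fluctuation.

The noiseless ground truth is
baseline + 0.3·(age − 65) + 3·[male] + 4·tanh(1.2 z_PPE) −
3·tanh(1.2 z_HNR) + 4·z_PPE·z_DFA, clipped to the observed score range
[7, 55], plus a patient-level intercept (sd 5 points) that no feature
explains, anchor-to-anchor increments of mean 1.5 and sd 2 points (so
progression is non-decreasing in expectation), and 1 point of measurement
noise per recording. These values are the package's own design: they
reproduce the documented artifacts (block collinearity, interpolated
labels, age/sex trends, score range, an overall mean near 29 points) at
cohort-realistic magnitudes. What the generator does **not** emulate:
the true marginal shapes of the voice measures beyond two moments, any
acoustic origin of the features, medication or measurement-session
effects, and informative dropout. Consequently, passing tests demonstrate
correctness of the machinery and recoverability of planted structure —
not clinical validity on real recordings.

## Test problem sizes and what the comparisons show

The multi-seed model comparisons in the tests and the acceptance script
use 20 patients × 30 recordings (≈600 rows) over ten seeds, and the
full-width checks use the 42-patient default cohort — sizes chosen so the
whole protocol (88-point grids included) runs in seconds while leaving
the planted nonlinear structure recoverable. On these cohorts the
product-mixture SVR consistently beats an affine least-squares baseline,
confirming that the kernel machinery captures the planted nonlinearity.
The product-mixture and radial-only SVRs, by contrast, land within a few
hundredths of a UPDRS point of each other: with standardized features, a
tuned single-bandwidth radial kernel is itself a universal approximator,
and the patient-proportional split keeps every test recording close (in
feature space) to training recordings of the same patient, so the global
polynomial factor has little extra to contribute. The large
radial-vs-product separations reported on the real cohort are consistent
with fits on unstandardized features, where a default-bandwidth radial
kernel degenerates toward a diagonal Gram matrix; that regime is
numerically hostile (enormous polynomial Gram entries, slow dual
convergence) and is deliberately not the package default, which
standardizes features fitted on training rows only.

## Known limitations

* Dual SMO cost grows between $O(n^2)$ and $O(n^3)$; the full Gram matrix
  is materialized (at $n \le 10^4$), so cohorts beyond tens of thousands
  of recordings need subsampling.
* No shrinking heuristics, ν-SVR, low-rank approximations, or
  classification mode.
* The β search and kernel-parameter grids are exhaustive, not adaptive.
* Motor UPDRS is generated only as an affine companion column for schema
  fidelity; no modeling claims attach to it.
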