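---
title: "Statistical methods behind the aqbd workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind the aqbd workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqbd)
```

This vignette documents the models, assumptions and numerical choices
behind the package, in the order a method-development campaign uses
them. The running example is the embedded study: a cyclodextrin-modified
MEKC separation of trimecaine and its four impurities, developed through
a three-level screening phase (seven method parameters) and a
response-surface phase (five parameters), with five critical method
attributes (CMAs): the resolutions R2, R3, R5, the impurity-2 plate
count N_I2 and the analysis time t.

## Factor coding and designs

Continuous factors are coded as `(physical - center)/step`; a factor's
declared `rounding` records the instrument's setting resolution, and
decoded levels are rounded to it. The embedded CCD stores the *exact*
coded axial levels (±1.6644...) while its physical table shows the
rounded settings (e.g. 25.0 mM cyclodextrin for a nominal 24.97): the
orthogonality mathematics uses the exact codes, the bench protocol the
rounded values.

The orthogonal CCD axial distance comes from requiring the centred
quadratic columns of the moment matrix to be mutually orthogonal, which
for F factorial runs in N total runs gives α = sqrt((sqrt(NF) − F)/2);
α is always recomputed from the run counts, never stored as a constant.
The half-fraction factorial block aliases the last factor with the
product of the others (resolution V for five factors); half fractions
with fewer than five factors are refused when a quadratic model is
intended, since second-order terms would be aliased.

The 16-run 3^7//16 screening array is shipped as a fixture rather than
generated: it is a vendor-constructed symmetric orthogonal array whose
construction algorithm is not public, and the analysis only needs the
array itself. Any user-supplied three-level orthogonal array can be
wrapped with `design_matrix()`. Plackett–Burman matrices are built from
the standard cyclic first rows for 8–24 runs; the default size for k
factors is the smallest with at least k + 5 columns, so that four or
more unassigned columns remain as pure-error carriers. Run order is
fixed and deterministic throughout: the package analyses printed or
simulated tables, and randomisation of bench execution is out of scope.

## Screening: the Free-Wilson model

Each three-level factor contributes additive level effects under a
sum-to-zero constraint, encoded as two indicator contrasts per factor
(level 3 contributing (−1, −1)); the third level coefficient is implied.
The fit is ordinary least squares; the whole-model ANOVA compares the
regression mean square to an error term.

Two error conventions are exposed, because screening software differs:
the residual mean square of the fit (default) and a pure-error estimate
pooled from duplicated runs. For the embedded 16-run array both carry a
single degree of freedom and coincide exactly, so the choice is
immaterial there; with one error df the ANOVA is conservative, and one
of the five embedded screening models (R5) sits just above the 5%
threshold (p ≈ 0.06) even though its effects are large. Level-change
contrasts (2→1, 3→2, 3→1) are t-tested with variance
c'(X'X)⁻¹c·s²; "best level" statements are assertions about the ordering
of level effects, not their magnitudes, and are tested as such.

## Response-surface models and Q²-driven refinement

The full quadratic model (21 terms for five factors) is fitted by least
squares on coded levels. The plate count N_I2 is fitted as log10(N_I2):
it is strictly positive, its errors are closer to multiplicative, and
the round specification N_I2 ≥ 10,000 maps to 4.0 on the fitting scale.
Runs with a missing response are excluded from that response's fit only
— in the embedded study the three co-migration runs (signed R3 exactly
zero) leave 26 usable runs for the plate-count model while all other
models keep 29.

Prediction quality is Q² = 1 − PRESS/SS_tot with PRESS computed through
the exact leave-one-out identity e_(i) = e_i/(1 − h_ii); the identity is
cross-checked in the tests against explicit refits at 1e-10. The raw Q²
is reported (it can be negative for overfitted models); a floored
variant is available because some RSM software clips it at zero.

Refinement removes one term at a time: among terms non-significant at
the current model's residual df (α = 0.05), the removal with the largest
Q² gain is applied until no removal increases Q². Ties within 1e-12 go
to the larger p-value, then to the later term in canonical order
(intercept, linear, quadratic, interactions). Heredity is not enforced —
a quadratic term may survive its linear parent's removal — matching the
default of the RSM software this workflow mirrors. On the embedded study
the refined models span R² 0.826–0.996 and Q² 0.507–0.982, inside the
quality window the study reports; the analysis-time model lands exactly
on the reported upper values (R² 0.9959, Q² 0.9823), which supports this
reading of the refinement rule. Note that backward elimination was
chosen over exhaustive subset search deliberately: with 21 candidate
terms the greedy Q² path is reproducible, cheap, and matches practice.

Predictions back-transform log10 means pointwise (no smearing
correction). This is deliberate: wherever the distribution matters —
specification checking — the Monte Carlo engine back-transforms *per
draw*, so the smearing question never arises; the point back-transform
is used only for display surfaces such as contour and sweet-spot plots.
The prediction standard deviation combines coefficient covariance and
residual variance on the fitting scale, sqrt(x'Vx + s²). An
extrapolation guard warns beyond |coded| = α + 0.1.

## Monte Carlo design-space mapping

The uncertainty model samples, per draw, a coefficient vector from the
multivariate normal defined by the least-squares estimate and its
covariance, plus additive residual noise N(0, s²) on the fitting scale;
draws are back-transformed and checked against all specifications
jointly. Responses are fitted independently, so their draws are
independent. At a fixed point x the coefficient part collapses exactly:
x'β with β ~ MVN(b, V) is the scalar normal N(x'b, x'Vx), so the
implementation draws from N(x'b, x'Vx) + N(0, s²) directly — two normal
streams instead of a p-dimensional one. This is an identity, not an
approximation; the tests compare it against literal coefficient-vector
sampling (MASS::mvrnorm) within binomial error. Both uncertainty
sources are sampled by default because a design-space claim should
reflect predictive, not merely estimative, uncertainty; sampling only
the coefficient part would overstate the operable region.

Risk of failure is 100 minus the joint pass percentage; DPMO is
10⁶ × (1 − p). A node belongs to the MODR when DPMO ≤ 100,000, i.e.
risk ≤ 10%. Probability maps assign node i the seed `base seed + i`, so
a map is bit-reproducible and each node equals a direct
`joint_pass_probability()` call at that seed. The default 20,000 draws
put the binomial standard error near 0.2 percentage points around 10%
risk; maps intended for orientation can run lighter (the shipped tests
use 13×13 to 21×21 node panels at 2,000–3,000 draws, which is ample to
rank panels), while single-point statements such as the working-point
check use the full 20,000.

The mean-prediction sweet-spot trellis and the uncertainty-aware
probability maps disagree on purpose: on the embedded study the widest
all-criteria sweet spot sits in the high-voltage/high-buffer panel, but
once model error is propagated the widest in-MODR area moves to the
medium-voltage/medium-buffer panel. Reproducing that reversal is one of
the package's qualitative regression tests.

The MODR *box* is an axis-aligned convenience summary: each factor's
interval is grown by bisection (other factors at the working point)
until the pass probability drops below target, then the full box is
shrunk proportionally toward the working point until all 2^k vertices
pass. Requiring joint corners to pass is much stricter than the
axis-wise intervals (the reported per-factor intervals of a study are
axis-wise statements), so the object carries both: `intervals`
(vertex-validated) and `axis_intervals`. The map, not the box, is the
primary artifact; the true region is generally non-convex. Interval
endpoints inherit Monte Carlo noise of the order of the bisection
tolerance plus the binomial error at the target.

Fixed settings (here SDS 65.0 mM and 22 °C, fixed after screening) are
carried as constants and never simulated. Within the embedded study's
reported operable region there is one internal inconsistency in the
source material for the cyclodextrin interval (17–23 mM in one place,
21–26 mM in another, the latter excluding the 20 mM working point); the
package compares against 17–23 mM, the variant consistent with the
working point.

## Robustness and system suitability

Plackett–Burman robustness data are fitted with main effects only; the
effect is mean(high) − mean(low) = 2 × the regression coefficient, and
significance is tested against the dummy-column error (one df per
unassigned column). System-suitability ranges run from the minimum to
the maximum attribute value observed during robustness testing; when a
model prediction exceeds the observed maximum the upper limit is
widened to cover it and the range is flagged with the reason. The
embedded study's robustness raw data are not part of the shipped
tables, so this module is exercised against synthetic robustness
studies generated around the working point, with perturbation
half-widths defaulting to screening-step-scaled steps and the voltage
range kept at ±1.5 kV (a 3 kV window being the narrowest practical
voltage perturbation).

## The synthetic-study generator

`truth_model()`/`simulate_study()` generate responses as quadratic truth
plus Gaussian noise on the fitting scale; log10-tagged responses are
generated on the log scale and exponentiated, so they stay positive
with multiplicative noise. A co-migration rule blanks the efficiency
response wherever |R3| falls below 0.05 — the embedded table reports R3
as exactly 0.00 at its three not-determined runs, so 0.05 is the
smallest resolution the data treat as a readable pair of peaks.
`trimecaine_truth_models()` calibrates the generator to the refined
models of the embedded study, giving a realistic truth whose end-to-end
re-analysis keeps the working point operable in most replicates.

What the generator emulates: quadratic mean surfaces, heteroscedastic
(log-scale) efficiency noise, sign-changing resolution, co-migration
missingness, duplicated centre runs. What it does not: electropherogram
shapes, drift or carry-over between runs, correlated errors across
responses measured on the same electropherogram, and non-Gaussian
outliers. Passing the recovery and closure tests therefore demonstrates
that the *analysis chain* is correct under its own assumptions, not that
real separations obey them.

## Problem sizes and numerical choices

The shipped tests run the parameter-recovery study at 200 replicates of
the 29-run design with noise at 5% of the response range, the pipeline
closure test at 50 replicates, and the working-point probability at
20,000 draws — sizes chosen so the whole suite documents the behaviour
in well under a minute on a laptop. Matrix algebra is QR-based;
rank-deficient fits raise immediately rather than pseudo-inverting.
Degenerate inputs are handled explicitly: constant screening responses
report a not-computable ANOVA, zero-variance contrasts report p = 1,
and a working point whose pass probability is below target refuses box
extraction rather than returning an empty region.
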