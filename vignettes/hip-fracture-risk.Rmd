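---
title: "In-silico hip-fracture risk: model, surrogate and trial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico hip-fracture risk: model, surrogate and trial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipfxsim)
```

## The estimand

For one subject, the quantity of interest is the probability of hip fracture
given a fall, `P_Fx`. A fall is described by two random variables: the fall
angle `theta` (degrees; -90 anterior, 0 lateral/sideways, +90 posterior) and
the impact velocity `v` (m/s). The subject's biomechanics enter through the
*critical-velocity curve* `v*(theta)`: the minimum impact speed at which the
simulated fall produces a fracture length of at least 10 mm on the femoral
surface. Then

```
P_Fx = 100 * q_hip * E_theta[ P(v > v*(theta)) ]        (percent)
```

where `q_hip = 0.4` is the probability that a fall impacts the hip at all.
Repeating the computation with a hip protector in the simulation gives
`P_Fx_HP`, and the per-subject relative risk is `RR = P_Fx_HP / P_Fx`,
undefined (and excluded from cohort summaries) when the baseline is zero.

## The fall-configuration model

`fall_config()` encodes the exposure distribution:

* fall angle: piecewise-uniform over three segments, anterior
  `[-90, -30)` with mass 12%, sideways `[-30, 30)` with 39.36%, posterior
  `[30, 90]` with 48.64%. Only the segment masses are empirically grounded;
  the within-segment distribution is taken uniform as the maximum-entropy
  choice given those masses.
* impact speed: normal with mean 2.14 m/s and SD 0.63 m/s, truncated at 0
  and renormalised. The truncated mass (about 3.4e-4) is negligible but a
  speed must be non-negative; the renormalisation keeps the survival function
  an exact probability, and it is why a critical velocity *at* the truncation
  point yields fracture probability exactly 1 (and hence `P_Fx` exactly 40%
  for an always-fracturing subject).
* hip-impact factor 0.4, applied as a final scaling.

`compute_pfx()` evaluates the angle integral per segment by the trapezoid
rule on a 1-degree grid whose nodes include the segment boundaries, so the
density discontinuities at -30 and 30 degrees never straddle a trapezoid.
The speed dimension is available in closed form (truncated-normal survival),
so no sampling is needed; `compute_pfx_mc()` retains a Monte-Carlo mode as an
independent cross-check, and the test suite verifies agreement within three
Monte-Carlo standard errors at 10^6 draws. `P_Fx` can never exceed
`100 * q_hip = 40%`.

## The surrogate and its active-learning loop

Each fall simulation of the reference model is expensive, so the
critical-velocity curve is reconstructed from a small budget of simulations
(20 per subject by default) with a Gaussian-process surrogate of fracture
length over (angle, velocity):

* kernel `C * RBF * DotProduct + WhiteKernel` — constant variance scale,
  smooth nonlinearity, a linear-trend component, and a white term absorbing
  simulation noise and regularising duplicated points;
* inputs scaled inside the GP only: angle divided by 90, velocity centred at
  the domain midpoint and divided by the half-range, both to `[-1, 1]`.
  Fracture lengths stay in mm. This makes a single RBF length-scale
  identifiable across the two axes;
* hyperparameters by marginal-likelihood maximisation (L-BFGS-B on log
  parameters, 5 random restarts within bounds: constant variance
  `[1e-4, 1e4]` mm^2, length-scale `[1e-2, 1e2]` scaled units, dot-product
  offset `[1e-2, 1e2]`, white noise `[1e-8, 1]` mm^2). The kernel structure
  is shared by all subjects; the hyperparameters are subject-specific.

The loop starts from a fixed, deterministic 6-point design — lateral falls at
the two velocity extremes, two off-lateral midpoints, and the two extreme
angles at the lowest velocity — chosen because the initial placement is
otherwise unconstrained ("at least 3" simulations) and a fixed design keeps
runs reproducible and angle-spanning. The two low-velocity corner anchors
matter: the acquisition rule concentrates every later simulation near the
10 mm contour, and without any observation in the low-velocity corners the
composite kernel can extrapolate spuriously above the threshold there,
corrupting the extracted curve with false lower-bound sentinels at extreme
angles (observed on roughly 1 in 7 synthetic subjects with a 4-point
design). Each subsequent
simulation is placed by minimising the acquisition objective

```
f = -exp(-1e3 * (10 - FxL_GPR)^2) * sigma
```

which targets the point of maximal predictive uncertainty among
configurations predicted to lie on the 10 mm contour. The `1e3` rate assumes
fracture lengths in mm (the same units as the 10 mm threshold that appears
beside it). Numerically, `f` underflows to exactly zero more than ~0.1 mm
away from the contour, so gradient steps started far from it stall on a flat
plateau. `propose_next()` therefore optimises the equivalent monotone
transform `-1e3 * (10 - FxL_GPR)^2 + log(sigma)` — the argmax is unchanged,
but the surface has informative gradients everywhere — screening a dense
interior grid (37 x 17 by default) and refining from the best 12 screening
points with bounded L-BFGS-B; ties are broken by first-found in row-major
grid order, the best raw grid point is the fallback if every local search
fails, and a degenerate surrogate with zero predictive uncertainty everywhere
yields the first grid point. Proposed points always lie strictly inside the
domain. `acquisition_objective()` still returns `f` in its raw form.

Curve extraction marches a 200-point velocity grid per angle and bisects the
first upward crossing of the posterior mean through 10 mm to 1e-4 m/s — the
*smallest* root, since the definition is the minimum fracturing speed. Two
sentinels cover the degenerate cases: `+Inf` when the mean stays below 10 mm
over the whole velocity domain, and the lower velocity bound when the mean is
already above it there. The velocity domain `[0.5, 4.5]` m/s covers the
impact-speed distribution to beyond mean + 3.7 SD; curves that exit the
domain at large |angle| are compared and integrated through these sentinels,
and `curve_rmse()` clamps both curves to the domain before comparing so
out-of-domain disagreement is penalised without infinite arithmetic.

Protected and unprotected surrogates are fitted independently, with the same
seed, so that a protector with zero effect reproduces the unprotected curve
exactly (and the null trial has RR identically 1).

## The synthetic cohort and oracle

No subject-level simulation data can be redistributed, so the package ships
a parametric stand-in for the reference fall-simulation model; it is labelled
synthetic throughout and exists so that every downstream stage is testable
against closed forms.

* `generate_cohort()` draws covariates per sex-by-ethnicity stratum from
  independent truncated normals matching published stratum means/SDs of an
  elderly Singaporean population (age, weight, height, TSTT, FRAX-HFP, aBMD,
  T-score); BMI is recomputed from weight and height. Truncation bounds are
  physiological (age 55-100, weight 30-150 kg, height 130-200 cm, TSTT
  0.5-8 cm, T-score -5..2, FRAX-HFP 0-30%, aBMD 0.2-1.5 g/cm^2). Covariates
  are sampled independently because only marginal statistics are published;
  a correlation-matrix hook (`corr`) is provided for sensitivity analyses
  and defaults to identity.
* `oracle_fracture_length()` is a ramp,
  `FxL = slope * max(0, v - v_c(theta))`, with limit state
  `v_c(theta) = v_c0 * (1 + curvature * (theta/90)^2)` and, with a protector,
  `v_c + shift * cos^2(pi * theta/180)`. The ramp-with-quadratic-angle form
  is the simplest surface with an exact closed-form critical-velocity curve
  (`v_c(theta) + 10/slope`), which is what makes surrogate validation
  rigorous; the `cos^2` attenuation encodes a benefit that is maximal for
  lateral and substantial for posterior-lateral falls and vanishes at pure
  anterior/posterior impacts. Observation noise defaults to 0 because the
  reference simulator is deterministic per configuration; non-zero noise is
  an opt-in stress test for the white kernel.
* `assign_response_params()` links covariates to the oracle:
  `v_c0 = 2.2 + 0.25*t_score + 0.15*tstt - 0.02*(age - 70)` m/s (clamped at
  0.3), plus a subject-level Gaussian residual (SD 0.15 m/s) and a
  truncated-normal protector shift (mean 0.35, SD 0.15 m/s). The directions
  encode the established biomechanics — weaker bone, thinner trochanteric
  soft tissue and older age all lower the tolerable impact speed — and the
  magnitudes were chosen once so that a default cohort lands in a realistic
  regime (cohort-mean `P_Fx` in the low single-digit percent range, mean RR
  around 0.4, Chinese > Malay > Indian and male > female orderings). The
  scales are deliberately *not* calibrated to reproduce any published
  cohort means: no per-subject response surfaces exist to calibrate against,
  so only orderings and mechanisms are emulated, and passing tests certify
  the machinery, not population-level agreement with real data.

What the generator does **not** emulate: covariate correlations (unless
supplied), fall-frequency differences between sexes, measurement error in
DXA-derived inputs, and any non-ramp nonlinearity of real force-strain
response. Conclusions from synthetic trials are therefore about the method's
internal consistency, not about clinical effect sizes.

## Cohort statistics

`cohort_report()` (and the standalone functions) implement the trial-level
statistics:

* risk classification: FRAX-HFP high iff strictly above 2%; `P_Fx` high iff
  strictly above the cohort's top-tertile threshold (linear-interpolation
  quantile at 2/3; ties are low risk). The tertile rule is used because no
  established `P_Fx` threshold exists.
* agreement: Cohen's kappa from the 2x2 paired-classification counts;
  McNemar's test using the exact binomial on the discordant pair when
  `down + up < 25` and the continuity-corrected chi-square otherwise (the
  variant is unspecified in standard practice; this split is the
  conventional small-sample rule). Zero discordance returns p = 1, flagged.
* reclassification: `down_pct = 100 * down / (reference high)`;
  `net_down_pct = 100 * (down - up) / N`. With the overall-cohort counts
  227/284/162/27 these give 41.65% and 19.29% (the latter is sometimes
  quoted rounded as 19.30, which is a rounding slip of (162-27)/700).
* odds ratios: `ad/bc` with the Haldane-Anscombe +0.5 applied to all cells
  only when a cell is zero; Wald 95% CI on the (possibly corrected) cells;
  two-sided Fisher exact p on the uncorrected table. The test suite checks
  the p-value against full hypergeometric enumeration for every 2x2 table
  with `N <= 40`.
* compliance adjustment: `RR_adj = c * RR + (1 - c)`, the mixture of
  protected and unprotected person-time at compliance `c`; reported to two
  decimals rounded half away from zero (`format_rr()`).
* sample size: the two-sample normal approximation
  `n = 2 * (z_{1-a/2} + z_{power})^2 / d^2` per group, rounded to the
  nearest integer with a floor of 2 (d = 0.81, alpha = 0.05, power 0.90
  gives 32). An exact-t iteration was considered and rejected as default
  because the normal approximation is the standard planning formula and
  reproduces the published worked example.

## Problem sizes and reproducibility

Every stochastic step takes an explicit seed, and identical configuration
plus seed gives byte-identical results (cohorts, surrogate traces, reports).
The shipped tests exercise: the full 20-simulation budget on 20
generator-drawn subjects for surrogate-curve recovery (RMSE against the
analytic curve below 0.15 m/s for at least 18 of 20); 10^6-draw Monte-Carlo
cross-checks of the quadrature; trial orchestration on small cohorts
(budgets of 6-8 simulations, 2-4 subjects) whose statistics path is
identical to a full-size run. A full 210-subject, 20-budget trial runs in
well under an hour on a single core via `run_trial(trial_config(seed = 1))`.

## Known limitations

* The oracle is a caricature: real fracture-length surfaces need not be
  ramps, and the surrogate's excellent recovery on the ramp is an easier
  problem than the reference simulator poses.
* `P_Fx` conditions on a fall occurring; fall frequency (which differs by
  sex and health status) is out of scope, so `P_Fx` is not a fracture
  incidence.
* The tertile-based high-risk threshold is cohort-relative; thresholds
  derived from one cohort do not transfer.
* Age adjustment of odds ratios (a routine covariate regression) is not
  implemented; reported ORs are crude.
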