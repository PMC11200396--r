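---
title: "Methods: isobolographic analysis of two-drug cytoprotection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isobolographic analysis of two-drug cytoprotection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isobolr)
```

## The problem

When two candidate neuroprotective drugs each attenuate cell death in an
in-vitro ischemia model (oxygen-glucose deprivation followed by
reoxygenation, OGD/R), the natural question is whether their combination
is merely additive or genuinely synergistic. `isobolr` implements the
classical fixed-ratio isobolographic workflow for answering this from
plate-based viability assays:

1. raw optical-density (or fluorescence) wells are converted to derived
   endpoints — viability %, lethality %, cytoprotection %, LDH
   cytotoxicity %, percent-of-control;
2. each monotherapy's cytoprotection is fitted as a sigmoidal
   concentration-response curve and summarised by its EC50;
3. fixed-ratio ("ray") mixtures are designed from the monotherapy EC50s;
4. the mixture's experimentally fitted EC50 (EC50E) is compared with the
   Loewe-additive prediction (EC50T), and the interaction index
   I = EC50E / EC50T classifies the interaction.

## Endpoint model

Viability is the treated signal relative to the control-group mean,
`100 * S_trt / S_ctrl`; lethality is its complement. Cytoprotection is the
viability gain over the untreated injured (OGD/R) baseline,
`viability_trt - viability_OGDR`. LDH cytotoxicity interpolates the
treatment OD between blank and maximum-release wells and is therefore
invariant to a common OD offset. Replicates are aggregated by arithmetic
mean with SEM = sd/sqrt(n), the dispersion convention used throughout;
an endpoint cell with a single replicate reports an undefined (NA) SEM
rather than zero. Viability above 100% is reported as-is — clipping only
happens when values are mapped to effect fractions for fitting, so no raw
information is lost upstream. Calibration curves (e.g. glutathione or
p-nitroanilide standards) are straight-line OLS fits over the assayed
range; inverse prediction flags, but does not clip, negative
extrapolations below the blank.

## Concentration-response model

`fit_concentration_response()` models the effect fraction
(cytoprotection rescaled to `[0, 1]` between the OGD/R baseline and the
control ceiling, or lethality over `[0, 100]`%) as

    E(c) = linkinv( intercept + slope * log10 c ),

with a probit (default) or logit link. Points are treated as binomial
proportions with effective size equal to the replicate count and the model
is fitted by weighted maximum likelihood (`stats::glm`, IRLS, convergence
tolerance 1e-10, at most 200 iterations); the parameter covariance is the
inverse information scaled by the estimated quasi-binomial dispersion, so
the nominal binomial variance does not have to be believed literally.
Effect fractions are clipped to `[1e-6, 1 - 1e-6]` to keep the link
finite. The log10 metameter makes the estimator exactly equivariant under
concentration unit changes, and zero-concentration control wells are used
only for normalisation, never entered into the log-scale fit.

Effective concentrations follow in closed form,
`ECp = 10^((q_p - intercept)/slope)` with `q_p` the link quantile; their
SEM comes from the delta method on the log10 scale and is propagated to
micromolar, and 95% limits are `+/- 1.96 * se` on the log10 scale, then
exponentiated. The choice of 1.96 (rather than a t quantile on the few
residual degrees of freedom of an 8-point design) keeps the interval
definition simple but places its realised coverage near the lower end of
the nominal range; the test suite checks that coverage stays within
0.90-0.98 at the default design. The default link is probit; both links
agree closely at the median, which is the quantity the downstream synergy
analysis uses, and the choice is exposed to the user.

## Fixed-ratio design and the synergy core

A ray with EC50-fraction `f_a` combines `c_a = f_a * EC50_A` with
`c_b = (1 - f_a) * EC50_B`; its total is the Loewe-additive EC50 of that
ratio, `EC50T = f_a * EC50_A + (1 - f_a) * EC50_B`. Ratio strings like
"1:4" are labels only — the controlling parameter is `f_a` (0.5, 0.25,
0.75 for the canonical 1:1, 1:4 and 4:1 rays). Dilution series around a
chosen mixture are geometric (default factor 2, three steps each side,
center excluded — the bracketing design that surrounds the most effective
screening concentration).

EC50T's SEM uses independent linear error propagation,
`sqrt(f_a^2 sem_A^2 + (1-f_a)^2 sem_B^2)`; when an externally supplied SEM
is preferred (e.g. reproducing a published table whose uncertainty was
derived differently) it can be passed directly. The additivity index of a
point is `i = c_a/EC50_A + c_b/EC50_B` (1 on the additivity line); the
interaction index is `I = EC50E/EC50T`. The classification requires both
the index direction and statistical significance: EC50T and EC50E are
compared by Welch's t on (value, SEM, n) summaries with
Welch-Satterthwaite degrees of freedom, and only a significant I < 1 is
called synergistic (I > 1 antagonistic); otherwise the verdict is
additive, i.e. indistinguishable from the Loewe line. This keys the
decision on the I-threshold rule alone, with the t-test as the gate.

## What the synthetic generator emulates

`simulate_ogdr_experiment()` reproduces the statistical structure the
analysis assumes: control and OGD/R baseline wells, two monotherapy arms
on 8-point concentration grids (defaults 6.04-30.6 uM and 0.047-0.24 uM),
and fixed-ratio mixture rays, all with 9 replicates per group. True
monotherapy curves are Hill sigmoids (default EC50s 10.06 and 0.07 uM,
Hill slope 2 — a modelling choice, since curve steepness is not
identifiable from published summaries; note a Hill curve is exactly a
logit model in log concentration). The OGD/R baseline restores 47.19% of
control viability, and a saturating treatment restores the full
control-baseline gap by default.

Combination effects follow a Loewe model with a single interaction
parameter psi: the effect `e` solves
`c_a/ECe_a + c_b/ECe_b = psi`, with `ECe_x` the inverse Hill curve
(bisection to 1e-12). psi = 1 is exact additivity; with equal Hill slopes
the ray's true 50% total is `psi * EC50T`, so the true interaction index
equals psi in closed form — the anchor the recovery tests use. Well noise
is Gaussian on the signal scale with sd 5% of the control signal
(matching SEMs of roughly 1.5-6% of group means at n = 9), and one root
seed spawns deterministic per-arm child seeds so arms can be regenerated
independently. The simulated ray series uses four dilution steps per side
(center/16 to center*16) so that even a strongly synergistic mixture
(EC50E near a tenth of the additive total, as in the motivating study) is
bracketed by assayed concentrations rather than extrapolated;
`dilution_series()` itself defaults to three steps for user designs.

Features of real plates the generator does not emulate: spatial/edge
effects, non-Gaussian or heteroscedastic optical noise, drifting controls
between plates, and any mechanistic ROS/GSH/caspase kinetics. Passing
recovery tests therefore demonstrates correctness of the estimators under
the assumed sampling model, not robustness to those artifacts.

## Numerical and design choices

- Probit vs logit: both implemented, probit default, user-chosen; no
  automatic model selection.
- Initialisation is whatever IRLS uses from the family defaults; the
  likelihood is concave in the linear predictor's parameters, and the test
  suite confirms the optimiser attains the global optimum found by an
  independent 200 x 200 grid search over (slope, log10 EC50).
- Degenerate inputs fail loudly: fewer than 4 distinct positive
  concentrations, zero/negative control signals, an LDH window with
  maximum <= blank, flat standard curves, zero SEMs in the t-test.
- A design with all observations on one side of 50% effect fits but warns
  that ECp extrapolates; a negative fitted slope warns about effect coding.
- Best-ray selection in `run_analysis()` is by maximal mean cytoprotection
  at each ray's design concentration, mirroring the screening step of the
  fixed-ratio protocol.
- Companion group statistics (one-way ANOVA with Dunnett-type contrasts
  against the OGD/R group) are computed via standard library routines and
  reported for context; they never gate the synergy call.

## Validation problem sizes

The package's checks use: 20 random curves for optimiser-vs-grid
likelihood equivalence (tolerance 1e-6); 500 simulated monotherapy
experiments at the default design (8 concentrations, 9 replicates,
Gaussian effect-fraction noise of 5% of the dynamic range per well) for
EC50 recovery (median relative error < 5%) and 95%-CI coverage
(within 0.90-0.98); and 200 simulated full-pipeline experiments per
psi in {0.1, 0.5, 1.0} for interaction-index recovery (mean within
+/- 0.03 of psi).

## Known limitations

- On the full plate path, all endpoint cells share one estimated control
  mean (and the effect fractions share one estimated OGD/R baseline).
  This common normalisation error is not represented in the per-fit
  covariance, so confidence intervals from plate-normalised data are
  somewhat anticonservative; the CI calibration statement above applies to
  noise on the effect-fraction scale. A hierarchical model propagating
  normalisation uncertainty is out of scope.
- Fitting a probit link to Hill-generated (logistic) curves leaves a small
  link-mismatch bias (well under 1% at the median); matched-link fits
  recover the truth to numerical precision.
- At strong synergy the mixture's informative concentrations sit at the
  bottom of the bracketing series, and the estimated interaction index
  carries a small finite-sample downward bias (within the +/- 0.03 band
  above).
- Only two-drug, fixed-ratio, 50%-level isoboles are supported; Bliss
  independence, Chou-Talalay surfaces and >2-drug mixtures are non-goals.
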