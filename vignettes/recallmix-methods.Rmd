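---
title: "Mixture modelling of continuous-report memory: models, thresholds and dissociation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture modelling of continuous-report memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recallmix)
```

## The analysis problem

In a continuous-report memory experiment, a participant reconstructs a
feature of a studied object — its color, orientation, or location — on a
circular 0–360° space, and the datum is the signed angular error between
response and target, wrapped into (−180, 180]. recallmix implements the
standard decomposition of such error distributions into latent sources, the
model-based definition of a "successful" retrieval, and the subject-level
statistics that ask whether retrieval success, retrieval precision, and
subjective vividness are separable facets of memory.

## The mixture models

Three nested models are fitted to a set of errors $x_i$ (degrees):

* **M1_VM** — all responses are noisy reports of the target:
  $f(x) = \phi(x;\mu,\kappa)$, where $\phi$ is the von Mises density on the
  degree scale, $\phi(x;\mu,\kappa)=e^{\kappa\cos((x-\mu)\pi/180)}/(360\,I_0(\kappa))$.
* **M2_VM_UNIF** — responses are target reports with probability
  $p_T$ or uniform guesses: $f(x) = p_T\,\phi(x;\mu,\kappa) + (1-p_T)/360$.
* **M3_VM_UNIF_NT** — additionally, with probability $p_N$ the response is
  centred on one of the $m$ non-target objects' feature values
  (a swap/binding error), with the same $\kappa$ and $\mu$ as the target
  component and the swap mass split equally across the $m$ non-targets.

$p_T$ is the operational measure of **retrieval success**, $\kappa$
(the von Mises concentration, unitless; higher = narrower) of **retrieval
precision**. The response-bias mean $\mu$ is fittable but fixed at 0 by
default: the analyses this package reproduces never report a bias
parameter, and all published quantities are recovered under $\mu = 0$. With
$\mu$ fixed, the free-parameter counts for AIC/BIC are $k = 1, 2, 3$ for
M1–M3; `mu_mode = "free"` adds one to each.

### Fitting

`fit_model()` maximizes the likelihood by EM. The E-step computes posterior
responsibilities of each component per trial; the M-step updates weights as
responsibility means and $\kappa$ via $A_1^{-1}$ of the
responsibility-weighted resultant length (the non-target deviations
$x_i - \delta_{ij}$ pool into the same resultant, since the components
share $\kappa$). With $\mu$ pinned at 0, only the cosine moment enters, and
a negative moment collapses to $\kappa = 0$. $A_1(\kappa)=I_1/I_0$ is
inverted by the standard three-regime closed-form approximation refined by
Newton steps, accurate to better than $10^{-3}$ across
$\kappa \in [0.1, 100]$ (tested). $\kappa$ is capped at 500 so degenerate
(near-identical) samples cannot diverge.

Mixture likelihoods are multimodal, so fitting uses multiple starts
(default 10): $\kappa$ log-uniform in $[0.5, 50]$, weights
Dirichlet-random; the lowest negative log-likelihood wins, ties broken by
start index. Convergence is declared when the NLL changes by less than
$10^{-6}$, with a 500-iteration cap; a fit that exhausts the cap is
returned with `converged = FALSE` and a warning, never an error. EM
guarantees the NLL is non-increasing across iterations, and the winning
start's trace is kept on the fit object so this invariant is directly
testable.

`compare_models()` fits all three models (M3 only when non-target offsets
exist) and tabulates AIC $= 2k - 2\ln L$ and BIC $= k\ln n - 2\ln L$. Each
larger model also receives the smaller model's optimum as a deterministic
extra start — once with exactly zero mass on the new component, which EM
then keeps at zero — so the fitted log-likelihoods respect the nesting
order $\ln L_{M1} \le \ln L_{M2} \le \ln L_{M3}$ by construction rather
than by luck of the random starts.

## The success threshold and trial-level precision

Under the fitted M2, the posterior probability that an error $x$ came from
the target component is
$p_T\phi(x;\kappa) / [p_T\phi(x;\kappa) + (1-p_T)/360]$. `derive_cutoff()`
solves for the $|x|$ at which this falls to $\alpha$ (default 0.05):
$\cos(x\pi/180) = \ln\!\big(\tfrac{\alpha}{1-\alpha}\cdot\tfrac{1-p_T}{p_T}\cdot I_0(\kappa)\big)/\kappa$,
clamped to 0 or 180 when the posterior never crosses $\alpha$. At the
published pooled parameters ($p_T = 0.62$, $\kappa = 10.05$) the solution
is 63.04°, displayed as the integer 63. Classification uses the exact root
by default; `use_rounded = TRUE` pins it to the printed integer (the
difference is negligible at this $\kappa$ — both supported because the
original rounding convention is not stated).

A trial is **successful** iff $|x| \le$ cutoff. The boundary counts as a
success: the defining phrase is "within 63 degrees", and the inclusive
reading is adopted and documented here. Successful trials get a precision
value $180 - |x|$ (degrees), so precision ranges over
$[180 - \text{cutoff}, 180]$ — $[117, 180]$ under the 63° cutoff.
Unsuccessful trials carry no precision (their error is attributed to
guessing). Trials flagged `omitted` (no response) are excluded from
classification; how the original analysis treated them is unstated, so
exclusion is the default and the flag is a generator option.

The cutoff is derived from a single fit pooled across all subjects' errors,
matching the analysis it reproduces; per-subject thresholds can be obtained
by calling `derive_cutoff()` on per-subject fits.

## Dissociation statistics

`subject_summaries()` fits M2 per subject, giving the triplet (retrieval
success $p_T$, precision $\kappa$, mean vividness). The report computes the
three pairwise Pearson correlations (two-tailed p from the t transform with
$n-2$ df) and, per outcome, the two-predictor regression on standardized
variables, using the closed forms in the sample correlations:

$$R^2 = \frac{r_{y1}^2 + r_{y2}^2 - 2 r_{y1} r_{y2} r_{12}}{1 - r_{12}^2},\quad
\beta_j = \frac{r_{yj} - r_{yk} r_{12}}{1 - r_{12}^2},\quad
F = \frac{R^2/2}{(1-R^2)/(n-3)}$$

with $t_j = \beta_j \sqrt{(n-3)(1-r_{12}^2)/(1-R^2)}$ on $n-3$ df. These
identities are verified in the tests against `lm()` on z-scored data to
machine precision, and the degrees of freedom are always computed from the
data (df = (2, 17) at $n = 20$). Unexplained variance is reported as
$1 - R^2$. No multiple-comparison correction is applied, matching the
behavioral analysis reproduced. The Fisher-z standard error of $r$ is
exposed alongside each correlation.

Two known arithmetic wrinkles, handled openly rather than silently: from
the printed 3-dp correlations (0.543, 0.527, 0.519) the success-regression
F evaluates to 5.146, while the published value 5.14 reflects unrounded
data; the tests therefore check F within the input-rounding band (±0.015)
while $R^2$ and $\beta$ agree at 3 dp. And the published F = 3.67 for the
precision regression is inconsistent with its own printed correlations and
p-value (the closed form gives ≈ 4.67, matching p = 0.024); it is treated
as a typo and not asserted anywhere.

## What the synthetic generator emulates

`simulate_experiment()` reproduces the design the analysis assumes:

* 48 displays of 3 objects, feature values uniform on 0–360° with a
  minimum same-feature circular separation of 62.04° within a display
  (rejection sampling, checked exhaustively in tests); 8 blocks × 6
  displays; 2 of 3 objects tested per display on all 3 features
  (6 judgments per display); one subject loses block 1, emulating a lost
  first scan run. The default cohort therefore yields exactly
  20·8·6·2·3 − 36 = 5724 feature trials and 20·48 − 6 = 954 vividness
  ratings.
* Feature-question orders counterbalanced: each of the 6 permutations of
  (color, orientation, location) equally often per subject, with no
  feature at the same question position more than 4 slots in a row
  (rejection shuffling with a retry cap).
* Subject heterogeneity from a Gaussian copula: latent trivariate normal
  traits with pairwise correlation 0.5 (the published across-subject
  correlations are ≈ 0.52–0.54) mapped through moment-matched marginals —
  logit-normal for $p_T$ (mean 0.62, SD 0.16), log-normal for $\kappa$
  (mean 10.05, SD 3.41), clamped normal for mean vividness (mean 48.23,
  SD 15.83). The logit-normal match has no closed form and is solved
  numerically once per call.
* Responses drawn from the chosen generative model; under M3 the swap
  probability defaults to 0.1 — the source analyses favored the no-swap
  model, so no published value exists, and 0.1 is a typical long-term
  memory swap rate chosen once for stress-testing the M3 path.
* Vividness ratings: subject mean + normal noise, clamped to [0, 100] and
  quantized to the task's 100-point grid. The within-subject rating SD is
  not published; the default of 20 points keeps single ratings spread over
  the scale the way the task's response histograms look. Trial-level
  coupling between a display's rating and that display's accuracy is not
  modelled (the published correlations are subject-level, n = 20); a
  trial-level coupling is deliberately out of the generator's scope, so
  passing tests say nothing about trial-wise vividness–accuracy coupling
  in real data.

The generator emulates the *statistical* structure only: no images, no
carried-over dial values between successive judgments of one object, no
BOLD signal. Real error distributions can also deviate from the generative
family (e.g. heavy-tailed precision heterogeneity across trials), so
recovery results here bound estimator behavior under the model, not under
model misspecification.

## The event-table export

`build_event_table()` converts classified trials into a BIDS-events-like
table with the six event types of the scanning analysis: one 12 s encoding
event per display (parametric modulator = number of its subsequently
successfully retrieved features, 0–6), one 8 s vividness event per display
(modulator = rating), one 6 s event per successful feature judgment under
its feature's regressor (modulator = precision, in [180 − cutoff, 180]),
and a pooled no-modulator regressor for unsuccessful judgments. Modulators
are mean-centered within event type so the base regressors keep their
interpretation. Onsets are laid out sequentially with jittered
inter-trial intervals (shifted-exponential approximation of the task's
400–2800 ms, mean ≈ 961 ms fixation; the 2 s background-only period before
the vividness slider is folded into the single 8 s vividness event). No
HRF convolution or design-matrix construction is performed — the export
stops at bookkeeping.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: `a1_inv` returns the κ ceiling
(500) with a warning at resultant length ≥ 1; `derive_cutoff` clamps to 0
or 180 outside the solvable range and refuses $p_T \in \{0, 1\}$;
collinear predictors and constant vectors raise named errors; a subject
with no classifiable trials is dropped with a warning. Ties across EM
starts go to the lowest start index, making fits bit-reproducible for a
given seed.

The test suite sizes simulations to keep the full run near a minute while
leaving comfortable statistical margins: parameter recovery uses 200
simulated subjects at 286 trials each (the per-subject trial count of the
full design) and a 100,000-trial pooled recovery; the grid oracle uses a
100 × 101 (κ × $p_T$) lattice on ≤ 200-trial fixtures; copula calibration
is checked at 2,000 subjects. `scripts/acceptance.R` re-derives the
headline quantities from scratch at the same sizes.

## Limitations

* No variable-precision or hierarchical models; each subject is fitted
  independently and the three error models are the whole model space.
* No circular–circular correlation or circular regression; the
  dissociation statistics treat $p_T$, $\kappa$ and vividness as ordinary
  real-valued subject measures, as the reproduced analysis does.
* The pooled real-data fit statistics of the original study (AIC/BIC
  differences, 76.04% mean success, mean vividness 48.23 as an outcome)
  require its source data files and are out of scope here; the package
  reproduces the closed-form and model-derived quantities and validates
  the estimators on synthetic cohorts instead.
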