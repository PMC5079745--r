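# recallmix

Mixture modelling of continuous-report episodic memory.

In continuous-report memory tasks, participants reconstruct object features
(color, orientation, location) on circular 0–360° spaces, and the datum is
the signed angular error between response and target. `recallmix` is for
researchers analysing such tasks: it decomposes error distributions into
latent retrieval sources, defines retrieval success model-wise, and tests
whether success, precision and subjective vividness are dissociable
subject-level measures.

## The models

Three nested mixtures are fitted to wrapped errors $x \in (-180, 180]$ by
EM with multiple random starts, and compared by AIC/BIC:

* **M1_VM** — von Mises only: $f(x) = \phi(x;\mu,\kappa)$
* **M2_VM_UNIF** — von Mises + uniform guessing:
  $f(x) = p_T\,\phi(x;\mu,\kappa) + (1-p_T)/360$
* **M3_VM_UNIF_NT** — additionally, swap errors centred on the non-target
  objects' feature values (shared $\kappa$, mass split across non-targets)

Here $\phi(x;\mu,\kappa) = e^{\kappa \cos((x-\mu)\pi/180)} / (360\, I_0(\kappa))$
is the von Mises density per degree; $p_T$ is *retrieval success* and
$\kappa$ is *retrieval precision*. From the pooled M2 fit, a success cutoff
is derived as the error magnitude where the posterior probability of the
target component falls to 5%:

$$\cos(x\,\pi/180) = \frac{1}{\kappa}\,
\ln\!\Big(\frac{\alpha}{1-\alpha}\cdot\frac{1-p_T}{p_T}\cdot I_0(\kappa)\Big)$$

Trials within the cutoff are successful and get a trial-level precision of
$180 - |x|$ degrees. Subject-level triplets (success, precision, mean
vividness) then enter pairwise correlations and standardized two-predictor
regressions, computed by closed form in the sample correlations.

A synthetic-experiment generator reproduces the task design (48 three-object
displays with ≥ 62.04° same-feature separation, 8 blocks × 6 displays, 2 of
3 objects tested on 3 features, counterbalanced question orders, 0–100
vividness ratings, one subject missing a block) with subject heterogeneity
from a Gaussian copula, so the whole pipeline runs and is tested without any
external data.

## Worked example

```r
library(recallmix)

sim <- simulate_experiment(seed = 42)      # full default cohort
nrow(sim$trials)                           # 5724 feature trials
nrow(sim$ratings)                          # 954 vividness ratings

fit <- fit_model(error_set_from_trials(sim$trials), "M2_VM_UNIF",
                 n_starts = 10, seed = 43)
fit
#> M2_VM_UNIF fit (n = 5724, fixed mu)
#>   p_target = 0.6017  p_uniform = 0.3983  p_nontarget = 0.0000
#>   kappa = 10.384  mu = 0.00 deg
#>   logLik = -30532.532  AIC = 61069.06  BIC = 61082.37  converged: TRUE

spec <- derive_cutoff(fit$p_target, fit$kappa)
spec
#> success cutoff: +/- 61.528 deg (displayed as 62) at posterior level 0.050
#>   from pooled fit: p_target = 0.602, kappa = 10.384

cl <- classify_trials(sim$trials, spec)
rates <- subject_success_rate(cl)
c(mean = attr(rates, "mean"), sd = attr(rates, "sd"))
#>      mean        sd
#> 0.7389663 0.1151532
```

The pooled fit recovers the generative population (target proportion 0.62,
concentration 10.05) within sampling error of one 5724-trial cohort; the
cutoff lands near the 63° obtained at the population parameters
(`derive_cutoff(0.62, 10.05)` → 63.04°, displayed 63), and the mean success
rate sits near the analytic mass $p_T + (1-p_T)\cdot 2\cdot 63/360 \approx 0.75$ —
higher than $p_T$ because guesses can land inside the cutoff. Per-subject
fits and the dissociation report:

```r
summ <- subject_summaries(sim$trials, sim$ratings, seed = 44)
rep <- build_dissociation_report(summ)
rep
#> Dissociation report (n = 20 subjects)
#> Pairwise correlations:
#>   success_precision    r =  0.621  p = 0.0034
#>   success_vividness    r =  0.529  p = 0.0164
#>   precision_vividness  r =  0.694  p = 0.0007
#> Regressions (outcome ~ other two, standardized):
#>   success    R2 = 0.405  F(2,17) = 5.78  p = 0.0122  unexplained = 59.5%
#>     vividness    beta = 0.189  t(17) = 0.73  p = 0.4761
#>     precision    beta = 0.490  t(17) = 1.89  p = 0.0765
#>   ...
```

With 20 subjects the sample correlations scatter widely around the
generative 0.5 (95% envelope roughly ±0.35); the report's point is the
*unexplained* variance — even correlated measures leave most variance of
each unaccounted for by the other two. `run_pipeline(pipeline_config(...))`
chains all stages and writes CSV/JSON/TSV outputs, including the
fMRI-style event table with mean-centered parametric modulators; a thin
command-line wrapper with verbs `simulate | fit | threshold | stats |
events | all` lives at `inst/cli/recallmix.R`.

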