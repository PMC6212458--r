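# vpalloc

**Variable-precision models of how visual working memory resource is
allocated across items of unequal behavioral relevance.**

When four items are remembered but only one — with known probability 0.6,
0.3, 0.1 or 0.0 — will be probed after a delay, how much memory resource
does each item get? `vpalloc` implements a complete modeling pipeline for
this priority memory-guided saccade paradigm, for researchers in
computational cognitive modeling and visual psychophysics:

* **Generative model** — memory precision *J* (inverse variance per axis of
  the 2-D saccade-endpoint distribution) is gamma-distributed with mean
  *J̄* and scale *τ*; the Euclidean error is Rayleigh given *J*, and its
  observed density marginalizes over *J* by quadrature:
  *p(ε | J̄, τ) = ∫ Jε e^(−Jε²/2) Gamma(J; J̄/τ, τ) dJ*.
* **Allocation strategies** over the share *pᵢ* of total resource
  *J̄*<sub>total</sub>: Proportional (*p = t*, the probe probabilities),
  Flexible (free proportions), Minimizing Error (argmin of
  *Σ tᵢ E[ε^β]*, the error-to-a-power loss), Maximizing Points (argmax of
  expected wager points).
* **Post-decision wager** (Experiment 2) — a circle of radius *r* centered
  on the saccade endpoint scores *120·e^(−0.4r)* points on a hit; expected
  utility multiplies points by the Rayleigh hit probability
  *1 − e^(−Jr²/2)*, and the chosen radius follows a softmax on expected
  utility with temperature *λ*.
* **Fitting & comparison** — per-participant multistart maximum likelihood
  (errors alone, or errors and radii jointly through their shared latent
  precision), AICc/BIC with bootstrapped median confidence intervals,
  parameter- and model-recovery diagnostics.
* **Model-free statistics** — per-priority summaries, within-priority
  standardized Spearman correlations between error and wager size, and
  stratified permutation nulls that control for stimulus location and
  delay.
* **Synthetic data** — a task-design-faithful generator (targets at
  10 ± 1 dva on a 10° angular grid avoiding cardinal axes, delays
  1000–4000 ms, probe probabilities 0.6/0.3/0.1), so the entire pipeline is
  testable without any data download.

## Worked example

Simulate four synthetic participants from the Flexible model at allocation
(0.49, 0.28, 0.23), check the behavioral signature, and refit one
participant:

```r
library(vpalloc)

spec <- model_spec(1, "flexible")
theta_true <- c(Jbar_total = 4, tau = 1, p_high = 0.49, p_med = 0.28)
trials <- generate_experiment(spec, theta_true,
                              design_config(n_trials = 600,
                                            n_participants = 4),
                              seed = 1)
priority_summary(trials)
#> Per-priority summary (mean +/- SEM across participants):
#>  priority n_participants mean_error  sem_error
#>       0.6              4   1.119354 0.03785220
#>       0.3              4   1.918605 0.19824124
#>       0.1              4   2.275381 0.02532809
#> monotonically decreasing with priority: error = TRUE
```

Estimation error grows as probe probability falls — the signature of
priority-dependent resource allocation. Refitting recovers the generating
allocation:

```r
fit <- fit_model(spec, trials[trials$participant == "S01", ],
                 n_starts = 10, seed = 2)
fit
#> VP fit: experiment 1, flexible strategy (S01)
#>   theta_hat: Jbar_total = 4.309, tau = 1.102, p_high = 0.5086, p_med = 0.2633
#>   loglik = -710.968 over 600 trials (10 starts); AICc = 1430.00, BIC = 1447.52
```

The error-minimizing allocation for the same resource budget is flatter
than the probe probabilities — less to the high-priority item, more to the
low-priority one:

```r
minimize_error_allocation(Jbar_total = 4, tau = 1, beta = 2)
#> [1] 0.3681841 0.3335676 0.2982482
```

`run_pipeline()` chains these stages (simulate or load → fit a model list →
compare → behavioral statistics → figures) from one configuration list or
YAML file and writes CSV/JSON tables, PDF figures and a manifest to an
output directory; see `?run_pipeline`. The methods vignette
(`vignettes/resource-allocation-methods.Rmd`) documents the model,
numerical choices, and what the synthetic-data tests do and do not
establish.

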