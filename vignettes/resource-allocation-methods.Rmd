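---
title: "Modeling priority-dependent allocation of visual working memory resource"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling priority-dependent allocation of visual working memory resource}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpalloc)
```

## The scientific problem

Visual working memory (VWM) is resource-limited: remembering one item more
accurately means remembering others less so. When items differ in behavioral
relevance — here, in the probability (0.6 / 0.3 / 0.1 / 0.0) that they will
be probed after a delay — observers must decide how to split the resource.
`vpalloc` implements a complete modeling pipeline for a memory-guided
saccade paradigm that asks *what strategy* governs that split: four
candidate allocation rules embedded in a common variable-precision (VP)
generative model, fit by maximum likelihood to saccade estimation errors
(Experiment 1) and jointly to errors plus post-decision wagers
(Experiment 2), with information-criterion model comparison, parameter and
model recovery, and model-free behavioral statistics.

## The generative model

On each trial the memory precision $J$ of the probed item is a random
variable,

$$J \sim \mathrm{Gamma}\!\left(k = \bar J / \tau,\ \text{scale} = \tau\right),$$

so that $\mathbb E[J] = \bar J$ and $\tau$ controls trial-to-trial
variability at fixed mean. **Precision is the inverse variance per axis** of
the two-dimensional Gaussian from which the saccade endpoint is drawn
around the target (per-axis sd $J^{-1/2}$; conventions differ across the
literature, so this is worth stating precisely). The Euclidean error
$\varepsilon$ is then Rayleigh given $J$,

$$f(\varepsilon \mid J) = J \varepsilon\, e^{-J\varepsilon^2/2},$$

and the observed error density marginalizes over $J$ by numerical
quadrature (`marginal_error_pdf()`). The marginal has a closed Burr-type
form, $p(\varepsilon) = \varepsilon k \,/\, \big(\tau^k(\varepsilon^2/2 +
1/\tau)^{k+1}\big)$, which the test suite uses as an independent oracle
while the pipeline itself integrates numerically — the quadrature path is
the one that generalizes to the joint error–wager likelihood, where no
closed form exists.

A condition with allocation share $p_i$ of the total resource
$\bar J_\mathrm{total}$ has mean precision $\bar J_i = p_i \bar
J_\mathrm{total}$, with a common $\tau$.

### Allocation strategies

* **Proportional** — $p_i = t_i$, the probe probabilities.
* **Flexible** — $p_\mathrm{high}, p_\mathrm{med}$ free parameters.
* **Minimizing Error (ME)** — $p$ minimizes
  $\sum_i t_i\, \mathbb E[\varepsilon^\beta \mid p_i \bar J_\mathrm{total},
  \tau]$, using the closed-form power moment
  $\mathbb E[\varepsilon^\beta] = 2^{\beta/2}\Gamma(1+\beta/2)
  \tau^{-\beta/2}\Gamma(k-\beta/2)/\Gamma(k)$ (finite only for
  $k > \beta/2$; the fitter treats a divergent loss as $-\infty$
  log-likelihood rather than silently returning infinity). The exponent
  $\beta$ acts as sensitivity to error. In the $\tau \to 0$, $\beta = 2$
  limit the optimum is the square-root rule $p_i \propto \sqrt{t_i}$ —
  flatter than proportional, i.e. underallocating to high-priority and
  overallocating to low-priority items, exactly the qualitative pattern the
  Flexible fits show. As $\beta \to 0$ the ME optimum approaches the
  proportional rule, so ME nests Proportional in the limit.
* **Maximizing Points (MP, Experiment 2 only)** — $p$ maximizes expected
  wager points $\sum_i t_i\, \mathbb E_J[\max_r EU(r; J)]$. Because the
  payoff saturates, the MP observer concentrates resource on
  high-probability items and nearly ignores the low-priority one (e.g. at
  $\bar J_\mathrm{total} = 4, \tau = 1$: $p \approx (0.61, 0.33, 0.06)$),
  qualitatively opposite to ME's flattening — which is what makes the two
  strategies empirically separable.

### The post-decision wager

After the saccade, the observer sets the radius $r$ of a circle centered on
the endpoint; a hit (target inside) earns $120\,e^{-0.4 r}$ points. With
known trial precision $J$ the hit probability is the Rayleigh CDF
$1 - e^{-J r^2/2}$, and the expected utility is the product of points and
hit probability. Decision noise is a softmax on expected utility with
temperature $\lambda$ (in points): $P(r) \propto e^{EU(r;J)/\lambda}$ over
a discrete radius grid. Two modeling choices deserve note:

* Radii live on a **finite grid** (0.1–10 dva, 0.05-dva steps,
  configurable). The display bounds the response, the softmax normalization
  becomes exact, and observed continuous radii are snapped to the nearest
  node (with a warning), whose 0.05-dva spacing keeps discretization error
  below fit noise.
* The observer is assumed to have **perfect metacognitive access** to the
  trial's $J$ when wagering; metacognitive noise is out of scope. The
  softmax temperature is applied to expected utility (the natural reading
  of the utility-then-hit-probability-then-EU construction), parameterized
  as $e^{EU/\lambda}$ — equivalent to $e^{\beta' EU}$ up to
  reparameterization.

Sharing $J$ between the error and the wager is what generates the
within-priority error–radius correlation; with $\tau = 0$ the correlation
vanishes, a property the tests verify in both directions.

## Likelihood and fitting

Experiment 1 trials contribute $\log p(\varepsilon_n \mid p_{c(n)}\bar
J_\mathrm{total}, \tau)$; Experiment 2 trials contribute the shared-$J$
integral $\log \int f(\varepsilon_n \mid J) P(r_n \mid J, \lambda)\,
\mathrm{Gamma}(J)\, dJ$. Both are evaluated in log space against a common
quadrature grid.

**Quadrature.** Nodes are log-spaced over the gamma distribution of $J$
(the integrand is smooth in $\log J$), with composite Simpson weights, 500
nodes by default and 300 during fitting. The grid spans at least the
central $1 - 10^{-12}$ gamma mass, with the lowest node clamped at
$10^{-14}$ of the highest: the clamp bounds the log-range (keeping node
spacing fine even for gamma shapes below 1, whose lower quantiles collapse
toward zero), and every integrand used here vanishes linearly in $J$ at the
origin, so the clipped sliver is immaterial. These settings hold the
marginal density to within $10^{-6}$ relative error of the closed form
across the distribution's bulk; far-tail evaluations (densities many orders
below the peak) are governed by the truncation and are not relied on.

**Optimization.** Multistart Nelder-Mead on a transform of the parameter
space: positive-scale parameters (resource, $\tau$, $\beta$, $\lambda$)
move on a log-scale logit between generous, task-scale bounds
($\bar J_\mathrm{total} \in [0.5, 500]$, $\tau \in [0.1, 200]$ dva$^{-2}$,
$\beta \in (0, 5]$, $\lambda \in [0.01, 100]$ points), and the allocation
pair uses a stick-breaking map so every iterate is a valid simplex point.
Starts are Latin-hypercube draws from a seeded, fixed-size pool, so
enlarging `n_starts` extends rather than replaces the start set — the
returned maximum can only improve, a property the tests assert. The
default is 10 starts — enough for these smooth 2-5 parameter problems,
with ~50 a sensible choice for fits of record — and the multistart trace
is kept in the `FitResult` so convergence can be audited.

The ME and MP strategies solve an *inner* allocation problem at every
likelihood evaluation. Both objectives are smooth and low-dimensional, so
the inner search uses few restarts, and results are memoized per
$(\bar J_\mathrm{total}, \tau[, \beta])$; the MP planner additionally
warm-starts from the previous solve, since its optimum moves continuously
with the parameters. The MP planner's inner maximization over $r$ is
noiseless (the decision-noise parameter shapes responses, not the planning
objective) and uses a fine grid with local refinement.

**Model comparison.** AICc $= -2LL + 2k + 2k(k+1)/(n-k-1)$ and BIC
$= -2LL + k\ln n$, with $n$ the number of analyzed trials for that
participant (the natural choice, stated explicitly since definitions of
$n$ vary). Group-level differences are summarized by the median across
participants with a percentile-bootstrap 95% CI of the median (participants
resampled with replacement). Signs are always reported with the pair order
explicit (`a_minus_b`; criteria are lower-better, so positive differences
favor model b).

## The synthetic-data generator

`generate_experiment()` emulates the task design: per trial, four targets
(one per visual quadrant) at $10 \pm 1$ dva eccentricity on a 10°
polar-angle grid excluding the cardinal axes; a probed condition drawn with
probabilities (0.6, 0.3, 0.1); a delay uniform on 1000–4000 ms in 500-ms
steps; then the VP generative process, and for Experiment 2 a softmax wager
and payoff scoring. Default 600 trials per synthetic participant — session
structure is not part of the public record, and 600 trials gives per-cell
counts (≈ 60 low-priority trials) comparable to a realistic multi-session
experiment while keeping recovery informative.

Choices worth recording:

* **Jitter is radial only** ($\pm 1$ dva on the eccentricity, angle kept on
  the grid). A 2-D positional jitter of 1 dva at 10 dva eccentricity could
  rotate a target to within ~4.3° of a cardinal axis; radial jitter
  preserves both the $[9, 11]$ dva eccentricity bound and the 10° angular
  margin that the location-stratified permutation test relies on.
* **Delay does not affect precision by default** — the generator emulates
  the finding that error–wager coupling exists beyond any delay effect. An
  optional `delay_decay` hook multiplies mean precision by
  $e^{-\text{decay}\cdot\text{delay}/1000}$, existing solely to exercise
  the permutation machinery on data with a genuine delay confound.
* **Screening is summarized, not simulated**: an optional uniform dropout
  flag stands in for the 1–7% of trials the original screening removed; the
  package models post-screening data.
* **Representative generating parameters** for the recovery analyses (the
  study reports allocation proportions but not precision parameters):
  $\bar J_\mathrm{total} = 4$ dva$^{-2}$, $\tau = 1$ dva$^{-2}$, chosen
  once so that per-priority mean errors span ≈ 1.2–2.6 dva — typical for
  memory-guided saccades to 10-dva targets — and $\lambda = 5$ points,
  which yields clearly dispersed but informative wagers.

What the generator does **not** emulate: swap/binding errors, guessing,
response truncation at screen edges, oblique-vs-cardinal anisotropies in
memory quality, saccade dynamics, or metacognitive noise. Passing recovery
tests therefore certify the *pipeline* (data → fits → comparison) under the
model's own assumptions, not the adequacy of the VP model for any
particular empirical dataset.

## Behavioral statistics

`priority_summary()` gives per-priority means ± across-participant SEM (and
the per-participant × priority table for external repeated-measures
ANOVAs, which are deliberately out of scope). Error–radius correlations
within each priority are Spearman correlations, pooled after
per-participant standardization (mean 0, sd 1 — removing between-subject
offsets) and also reported per participant.

The confound controls are **stratified permutation tests**: within each
participant × priority cell, wager radii are shuffled only among trials
sharing a covariate stratum — the exact delay value (7 levels), or a 10°
polar-angle bin matching the design's angular grid (the bin width is a
parameter). This preserves any covariate-driven association while
destroying trial-level coupling; the observed correlation is compared to
the null median per cell and, across participants, with a Wilcoxon
signed-rank test. Singleton strata cannot be permuted and are flagged with
a warning; with sparse low-priority cells they leave the location null
slightly above zero, which is why conclusions rest on the
observed-versus-null comparison rather than on the null being exactly
centered. The exact stratification is this implementation's definition of
the confound control; it is the natural one given the discrete design.

## Problem sizes and numerical checks

The suite's heavier checks run at deliberately chosen scales: parameter
recovery with 20 synthetic participants × 600 trials (Experiment 1) and one
participant × 600 trials (Experiment 2, joint fit) at 10 starts; model
recovery over the full 4-model Experiment-2 space with two 600-trial
datasets per generating model at reduced starts (winner *fractions* are the
meaningful quantity — where one model nearly nests another, the AICc race
on a single dataset is close to a coin weighted only ~5:1); planner optima
verified against exhaustive 0.005-step simplex grids on 20 random parameter
draws; quadrature verified against the closed form at $10^{-6}$ relative
tolerance. Two generating-parameter choices in the recovery design matter.
The Flexible generating allocation is taken off the monotone-strategy
manifold (0.55, 0.22, 0.23) — ME allocations always have a middle share
near 1/3 and nest Proportional as $\beta \to 0$, so a Flexible truth too
close to that manifold is won by the smaller model on the parameter
penalty, the documented nesting exception. And the MP observer is simulated
at a larger budget ($\bar J_\mathrm{total} = 10$): at low budgets its
optimal low-priority share implies a gamma shape well below 1, whose
singular lower tail generates astronomically large "errors" that a real
display would never record; at 10 the MP optimum (low share ≈ 0.12) keeps
every condition's shape at or above 1 and the simulated behavior physical.

Degenerate inputs are handled explicitly: divergent ME losses error (or
flag $-\infty$ likelihood inside fits), empty quadrature grids and
out-of-bounds parameters error, off-grid radii snap with a warning,
all-zero signed-rank differences return the degenerate $p = 1$ rather than
erroring, and flat simplex optima break ties toward the lexicographically
smallest point (reachable only in symmetric cases).

## Known limitations

* The VP-plus-strategy family is assumed; alternative architectures
  (interference, slots-plus-averaging) are not implemented.
* Fits are per participant; there is no hierarchical/random-effects
  pooling and no Bayesian posterior over parameters.
* The wager model's perfect-metacognition assumption means recovered
  $\lambda$ absorbs both decision noise and any metacognitive noise.
* The optimizer is a general-purpose bounded multistart Nelder-Mead; it is
  reproducible and adequate for these smooth 2–5 parameter problems but
  makes no global-optimality guarantee beyond its multistart evidence.
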