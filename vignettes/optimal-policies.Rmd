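---
title: "Optimal stopping for multi-alternative value-based decisions"
author: "valuedp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal stopping for multi-alternative value-based decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decision problem

A decision maker samples noisy evidence simultaneously about the values of
two or three options and must decide when to stop sampling and which option
to take; the reward is the (subjective) value of the chosen option, and
time is costly. `valuedp` solves this optimal-stopping problem by backward
induction and simulates agents that apply the resulting policies, with one
scientific question in view: when are reaction times *magnitude-sensitive*,
i.e. when do they depend on the overall value of the option set even though
the options are exactly equal?

The package models the belief about each option's value rate as a conjugate
Gaussian: a prior $N(\bar{x}_p, \sigma_p^2)$ updated by momentary evidence
$x_\tau \sim N(\bar{x}\,dt, \sigma_a^2\,dt)$. The posterior mean after
observing for time $t$ with evidence sum $\sum_\tau x_\tau$ is

$$\hat{x}(t) = \frac{\bar{x}_p\,\sigma_a^2 + \sigma_p^2 \sum_\tau x_\tau}
                    {\sigma_a^2 + \sigma_p^2\,t},$$

with posterior variance $v(t) = (1/\sigma_p^2 + t/\sigma_a^2)^{-1}$. This
is the unique form that returns the prior mean with no data and the
evidence sample mean in the flat-prior limit; both limits are asserted in
the test suite, together with agreement to a discretized numerical Bayes
rule. Posterior means are a martingale: over a look-ahead $\delta t$ the
next mean is distributed $N(\hat{x}(t), s^2(t,\delta t))$ with
$s^2 = v(t) - v(t+\delta t)$ — the expectation in the Bellman recursion
reduces to a Gaussian smoothing with exactly this width.

## The two cost regimes

Writing $r_i$ for the expected reward of choosing option $i$, the value
function on the grid of posterior-mean estimates satisfies, under **linear
(Bayes-Risk) time costs**,

$$V(t,\hat{x}) = \max\Big\{\max_i r_i(\hat{x}) - \rho\,t_w,\;
  \langle V(t+\delta t,\hat{x}(t+\delta t))\rangle - (c+\rho)\,\delta t\Big\},$$

where $c$ is the linear cost per unit time, $t_w$ the inter-trial wait and
$\rho$ the reward rate earned per unit time across a sequence of trials.
$\rho$ is calibrated to its self-consistent fixed point: the value of the
problem at its own starting state (all estimates at the prior mean, $t=0$)
must be zero, otherwise the assumed earning rate is inconsistent with the
policy it induces. `calibrate_reward_rate()` solves this by bisection on
$(10^{-6}, \max U/t_w)$ to a value residual below $10^{-3}$, which directly
bounds the policy error near the prior.

Under **geometric discounting**, future reward is scaled by a per-unit-time
survival probability $\gamma \in (0,1)$:

$$V(t,\hat{x}) = \max\Big\{\max_i r_i(\hat{x}),\;
  \langle V(t+\delta t,\hat{x}(t+\delta t))\rangle\, \gamma^{\delta t}\Big\}.$$

The contrast between the regimes is the package's central prediction:
discounting makes the continuation value scale with the *magnitude* of
what is at stake, so low-value equal option sets are worth waiting on
(the discount costs little) while high-value sets demand immediate choice
— reaction times decrease with magnitude. Linear costs subtract the same
amount regardless of stakes, so with linear utility the policy depends
only on value *differences* and equal-alternative reaction times are
magnitude-insensitive.

## Subjective utility and the two reward modes

Utilities are linear ($U(x)=x$) or logistic,
$U(x) = m\,(2/(1+e^{-sx}) - 1)$, spanning near-linear ($U \approx (ms/2)x$
for small $s$) to near-stepwise ($U \to m\,\mathrm{sign}(x)$ for large $s$)
shapes.

The reward of stopping, $r_i$, can be evaluated two ways, and the package
exposes both:

* `utility_mode = "point"` (default): $r_i = U(\hat{x}_i)$, the utility of
  the posterior-mean estimate. This matches the convention of drawing
  decision boundaries directly in estimate space.
* `utility_mode = "expected"`: $r_i = E[U(X_i)\mid \text{data}]$ under the
  full Gaussian posterior, computed by Gauss–Hermite quadrature.

The modes genuinely differ for strongly saturated utilities. With $m=4$,
$s=3.5$ the point-mode reward at the default prior mean is
$U(1.5) = 3.958$, within 1% of the ceiling $m$; under geometric
discounting with $\gamma \le 0.2$ the continuation is bounded by
$\gamma^{\delta t} m < U(1.5)$, so stopping immediately at the prior is
provably optimal and every simulated reaction time is zero — the utility
has flattened away the question. In expected mode the same parameters
leave the stop reward well below ceiling while the posterior is broad
(the negative tail of $U$ drags the expectation down), waiting buys
variance reduction, and the magnitude-sensitivity contrast between the two
cost regimes is expressed. The full-scale checks in the test suite
therefore run saturated utilities in expected mode; moderate slopes
($s \lesssim 1$ at the default prior) show the same contrast in point
mode.

## Numerical choices

* **Grid.** Estimates live on a regular per-axis grid, default
  $[-5,5]$ with 41 points (121 for figure-quality boundary plots). The
  expectation over next estimates is a separable per-axis Gaussian
  smoothing; kernel rows are renormalized so no probability mass leaks at
  the edges. The defaults suit boundary sections near the prior; **for
  magnitude sweeps the support must cover the swept values plus the
  decision-boundary width**. Truncation at the edge otherwise induces a
  small spurious magnitude sensitivity precisely in the case that is
  exactly insensitive in continuous space (linear utility, linear costs):
  on $[-5,5]$ a sweep to $v=4$ shows a reaction-time dip of order
  $10^{-3}$ time units at the top value, which vanishes when the support
  is widened to $[-7,7]$ at the same spacing. The package's full-scale
  sweep tests use $[-7,7]$ with 41 points.
* **Horizon.** Default 3 time units with $\delta t = 0.05$ and a forced
  argmax choice at the horizon. Because the transition std collapses as
  the posterior sharpens, policies are insensitive to the horizon beyond
  roughly 2 units at the default belief parameters.
* **Tie-breaking.** Stored action arrays break argmax ties to the lowest
  option index (deterministic); the simulator breaks ties uniformly at
  random. Permutation equivariance of policies is asserted away from tie
  sets.
* **Stop rule in simulation.** The simulator runs at
  $dt = 5\times10^{-3}$, much finer than any feasible DP grid, and decides
  stop-vs-continue by multilinear interpolation of the signed
  stop-minus-continuation gap at the nearest policy time slice; this
  avoids the aliasing of nearest-node action lookup. Estimates outside the
  grid are clamped to the edge.
* **Censoring.** Trials reaching the horizon are resolved by forced argmax
  choice, flagged, included in mean RT (conservative), and reported as a
  censoring fraction.
* **Degenerate inputs.** $s=0$ logistic slopes are rejected rather than
  coerced to linear; a utility with no positive range calibrates to
  $\rho^\ast = 0$; zero observation noise is allowed in the evidence
  sampler as an exact limiting mode.

## What the generators emulate

`generate_trial_schedule()` reproduces the combinatorics of a three-patch
brightness psychophysics session: all $4^3 = 64$ ordered triples over
levels $\{0.3, 0.4, 0.5, 0.6\}$, ten repeats of each equal triple plus one
of each unequal triple (100 trials), uniform inter-trial intervals from
$\{0.5, 1, 1.5\}$ s, uniformly shuffled. `frame_noise()` adds per-frame
Gaussian luminance noise with SD $= 0.25\times$ mean brightness, keeping
the signal-to-noise ratio constant across magnitudes; values are not
clipped to $[0,1]$ by default since clipping would break exactly that
property. `slime_design()` builds the balanced four-concentration
$\times$ 50-replicate foraging design. `generate_synthetic_rt_dataset()`
produces reaction times with a linear magnitude effect (default slope
$-1.95$ per brightness unit, a realistic human-scale setting), subject
random intercepts, and a mean-zero lognormal residual to mimic RT
skewness.

What they do *not* emulate: sequential and learning effects across trials,
pseudo-randomisation constraints beyond uniform shuffling, display timing,
motivation or attention lapses, and any mechanistic model of slime-mould
chemotaxis. A green end-to-end test establishes that the pipeline recovers
the structure it planted — not that these simplifications hold in real
data.

## Limitations

* At most three options: the grid representation scales as
  `grid_n^n_options`.
* No fitting to behavioural data; time units are arbitrary and not
  calibrated to seconds.
* The policy container stores full value/action/gap arrays as JSON text:
  portable and dependency-free, but large for figure-quality grids.
* Magnitude-sensitivity summaries use the OLS slope of mean RT on value; a
  mixed-effects treatment of per-trial data is out of scope.

## A minimal session

```{r example}
library(valuedp)

cfg <- bellman_config(cost_regime = "geometric", gamma = 0.1,
                      utility = utility_logistic(m = 4, s = 0.5))
policy <- solve_policy(cfg)

# triangular boundary section at t = 0 on the plane x1 + x2 + x3 = 0
slice <- project_boundary_slice(policy, t = 0, v = 0)
plot(slice)

set.seed(1)
curve <- magnitude_sweep(cfg, values = seq(-4, 4, by = 2),
                         n_per_value = 2000, policy = policy)
plot(curve)
magnitude_slope(curve)
```
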