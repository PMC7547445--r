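---
title: "Utility-based design of phase II/III programs with discounted phase II estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Utility-based design of phase II/III programs with discounted phase II estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phase23opt)
```

## The planning problem

A sponsor runs one exploratory phase II trial and, if its result is
promising, one confirmatory phase III trial, both two-armed with a
time-to-event endpoint.  The true treatment effect is
$\theta = -\log(HR)$, with positive values favouring treatment.  With
$d_2$ events in phase II, the estimate is asymptotically
$\hat\theta_2 \mid \theta \sim N(\theta,\, 4/d_2)$.  The program goes to
phase III when the estimate used for decision making clears a threshold
$\kappa = -\log(HR_{go})$, and the phase III event number is planned from
the estimate used for planning:
$$D_3 = \frac{4\,(z_{1-\alpha} + z_{1-\beta})^2}{(\hat\theta_2^{s_2})^2},$$
the log-rank event formula for one-sided level $\alpha$ and power
$1-\beta$.  The phase III statistic is
$T_3 \mid \theta \sim N(\theta\sqrt{D_3}/2,\, 1)$ and success means
$T_3 > z_{1-\alpha}$.

Because only promising phase II results trigger phase III, the planning
estimate conditional on going is biased upward: selection keeps the random
highs.  Underpowered phase III trials are the consequence.  The package
therefore supports discounting the estimate before it is used:

* **multiplicative** (retention factor): $\hat\theta_2^\lambda = \lambda\,
  \hat\theta_2$, $\lambda \in [0.2, 1]$;
* **additive** (confidence-bound planning): $\hat\theta_2^{\alpha_{CI}} =
  \hat\theta_2 - z_{1-\alpha_{CI}}\sqrt{4/d_2}$, $\alpha_{CI} \in
  [0.025, 0.5]$.

$\lambda = 1$ and $\alpha_{CI} = 0.5$ leave the estimate untouched.  Five
program set-ups are distinguished by which estimate decides and which
plans: `u,u`, `u,lambda`, `lambda,lambda`, `u,alphaCI` and
`alphaCI,alphaCI` (decision selection first, planning selection second;
when the decision is adjusted it always reuses the planning parameter).
Set-ups that adjust only the decision rule are deliberately not offered:
optimizing the threshold makes them redundant.

Uncertainty about $\theta$ is expressed by a Gaussian-mixture prior.  The
bundled oncology parameterization mixes a strong effect
($HR = 0.69$, certainty equivalent to 210 events, i.e. variance $4/210$)
with a moderate one ($HR = 0.88$, variance $4/420$); the weight $w$ on the
strong component spans pessimistic ($0.3$) to optimistic ($0.9$) views.
Any number of components is accepted.

## Expected program characteristics

All design comparisons rest on prior-averaged ("assurance"-style)
quantities: the probability to go, the expected phase III events
$d_3 = E[D_3 \cdot 1\{\text{go}\}]$, the conditional planning estimate
$e_2 = E[\hat\theta_2^{s_2} \mid \text{go}]$ (reported on the HR scale as
$\varepsilon_2 = e^{-e_2}$), the probability of a successful program
(go *and* significant phase III), and the decomposition of success into
three effect-size categories.  The categories follow the health-technology
convention of grading the phase III result by where the upper bound of the
95% CI for the HR falls relative to 1, 0.95 and 0.85; on the
test-statistic scale the cut points are $z_{1-\alpha}$,
$z_{1-\alpha} - \log(0.95)\sqrt{D_3}/2$ and
$z_{1-\alpha} - \log(0.85)\sqrt{D_3}/2$, which move with $D_3$ and are
therefore kept inside the integral.

Monetary structure (all in units of $10^5$): fixed costs $c_{02}, c_{03}$,
per-patient costs $c_2, c_3$, and event rates $\xi_2, \xi_3 \in (0,1]$
converting events to patients ($\text{patients} = \text{events}/\xi$).
Expected cost, gain and utility are
$$E[c] = c_{02} + \tfrac{d_2}{\xi_2} c_2 + c_{03}\, p_{go} +
  \tfrac{c_3}{\xi_3}\, d_3, \qquad
  E[g] = \textstyle\sum_j b_j P_j, \qquad E[u] = E[g] - E[c],$$
with $b_1 \le b_2 \le b_3$ the category benefits and $P_j$ the category
probabilities.  `optimize_program()` maximizes $E[u]$ over a grid of
$(d_2, HR_{go}, \text{parameter})$; `optimize_with_budget()` restricts to
$E[c] \le K$.

### Defaults and why

| parameter | default | rationale |
|---|---|---|
| $\alpha$, $1-\beta$ | 0.025, 0.90 | conventional confirmatory standards |
| $c_{02}, c_{03}$ | 100, 150 | fixed set-up costs, oncology-scale ($10^5$ units) |
| $c_2, c_3$ | 0.75, 1 | reported oncology per-patient costs; phase III collects more data |
| $\xi_2, \xi_3$ | 0.7 | compromise between data maturity and follow-up length |
| benefit presets `bs1`–`bs7` | (1000,2000,3000) … (1000,4000,6000) | low to medium-large overall benefit, 5-year income, 0.2 margin |
| $d_2$ grid | 50–350 by 2 | wide enough that optima are interior |
| $HR_{go}$ grid | 0.70–0.90 by 0.01 | from strict to liberal decision rules |
| $\lambda$ grid | 0.2–1 by 0.025 | full retention range incl. no discounting |
| $\alpha_{CI}$ grid | 0.025–0.5 by 0.025 | one-sided CI levels incl. no discounting |

The $\alpha_{CI}$ grid uses a uniform 0.025 step so that every CI level on
the quarter-percent lattice (0.45, 0.40, …) is a candidate; optima in this
family routinely land on such values.

A lower bound on $\kappa$ doubles as a minimal clinically relevant effect:
raise `min(hr_go)`'s counterpart (i.e. cap `max(hr_go)`, e.g. at 0.8) to
refuse phase III unless phase II shows at least that effect.

## Numerical strategy

The defining quantities are two- and three-layer integrals over
$(\theta, \hat\theta_2, T_3)$.  The package reduces them analytically as
far as Gaussian structure allows:

1. **$T_3$ layer.** For given $\theta$ and $D_3$, tail probabilities of
   $T_3$ are normal CDF differences — closed form.
2. **$\theta$ layer.** Per mixture component, $\hat\theta_2$'s marginal is
   $N(m_k, v_k + 4/d_2)$ and $\theta \mid \hat\theta_2$ is again normal
   (conjugacy), so $E_\theta[\Phi(a\theta + b) \mid \hat\theta_2]$ is a
   single $\Phi$ evaluation.  The go probability becomes fully closed
   form.  With a distinct, independent phase III prior the same identity
   is applied to its components instead.
3. **$\hat\theta_2$ layer.** The one remaining integral, over the go
   region $[\kappa_{\text{eff}}, \infty)$, has no closed form because
   $D_3 \propto 1/(\hat\theta_2^{s_2})^2$.  It is computed by
   Gauss–Legendre quadrature (64 nodes by default) on
   $[\kappa_{\text{eff}},\ \max_k(m_k + 8\sqrt{v_k + 4/d_2})]$.  The
   integrands are smooth and compactly concentrated; doubling the nodes
   changes the default-scenario characteristics by less than $10^{-4}$
   relative, and results are identical to a dense nested 2-D quadrature
   of the raw integrals to $10^{-6}$.

The decision rule is always rewritten as a threshold
$\kappa_{\text{eff}}$ on the raw estimate ($\kappa$, $\kappa/\lambda$, or
$\kappa + z_{1-\alpha_{CI}}\sqrt{4/d_2}$), so one integration template
serves all five set-ups.  $D_3$ is kept continuous everywhere — expected
values integrate it as a smooth function, and rounding is applied only for
display.

**Feasibility.** Additive planning with an unadjusted decision rule can
make the planning estimate nonpositive inside the go region (when
$\kappa \le z_{1-\alpha_{CI}}\sqrt{4/d_2}$), where $1/(\cdot)^2$ is not
integrable.  Such designs are excluded from optimization and counted in
the result's infeasibility log; single-design evaluators raise an error
naming the design.  The conditional planning estimate $e_2$ alone is
$D_3$-free and is computed for any design with positive go probability.

**Ties.** Utility ties on the grid (exact float equality) are broken
toward the smallest $d_2$, then the largest $HR_{go}$, then the parameter
closest to no adjustment — the cheapest, least restrictive, least
discounted design.  Optimization is deterministic and bit-identical on
re-run.

**Caching across benefit scenarios.** Characteristics do not depend on the
benefit vector, so when several benefit presets are compared the evaluated
grid is reused and only the category-probability dot product changes.
This is how the bundled tests sweep all seven benefit presets at one
weight in a few seconds.

**$d_3$ convention.** Report tables in this field sometimes label the
phase III events "when going to phase III" while defining the
unconditional $E[D_3 \cdot 1\{\text{go}\}]$.  The package computes the
unconditional value as `d3` and also exposes `d3_given_go = d3 / p_go`, so
either reading can be checked; the bundled defaults match the published
unconditional values.

**Distinct phase II/III priors.** When different populations motivate
different priors, the two true effects are modelled as independent draws
(`prior3` argument).  Independence is a modelling choice — the main-text
formulation gives only conditional distributions — and a positive
dependence between the two effects would raise success probabilities
relative to this default.

## The Monte Carlo program simulator

`simulate_program_batch()` draws whole programs from the same generative
model the integrals describe: effect(s) from the prior(s), estimate,
go decision, planned $D_3$, phase III statistic, category, cost, gain.
One random stream with a fixed draw order (effects, estimate, phase III
innovation) keeps batches seed-stable.  Sample means carry standard
errors, so every quadrature output can be checked to within sampling
error; the test suite does this at $n = 200{,}000$ for ten designs
spanning all five set-ups, at three standard errors.

The simulator emulates the *asymptotic planning model*, not patient-level
data: normality of $\hat\theta_2$ and $T_3$ is exact in the simulation,
whereas in a real trial it holds only approximately for small event
counts; proportional hazards, independence of the two trials, a common
endpoint in both phases, and the absence of interim looks are all assumed
rather than tested.  Agreement between simulator and quadrature therefore
validates the computation, not those modelling assumptions.

## Worked example

```{r example, eval = FALSE}
prior <- default_prior(w = 0.3)
scenario <- scenario_spec(prior, benefits = benefit_scenario(1))

# a single candidate design
program_characteristics(design_point(d2 = 82, hr_go = 0.80), prior)
#> p_go = 0.4571, d3 = 145.6, eps2 = 0.6463, PsP = 0.2428

# full grid searches (a few seconds each)
optimize_program(optimization_grid("u,u"), scenario)
#> u* = 77.2 at d2 = 86, HR_go = 0.80
optimize_program(optimization_grid("lambda,lambda"), scenario)
#> u* = 100.1 at d2 = 84, HR_go = 0.81, lambda = 0.75
```

Discounted planning buys a higher maximal expected utility than the naive
set-up here, with a lower go probability but a larger phase III
investment conditional on going — money is spent more selectively.  The
test suite reproduces this ordering (multiplicative $\ge$ additive $\ge$
unadjusted) across all seven benefit presets at $w = 0.3$.

## Problem sizes and limitations

The default grids contain 3,171 (`u,u`), 104,643 (multiplicative) and
63,420 (additive) designs; the package evaluates them in vectorized
chunks of 8,000 in seconds on one core, which is the scale the bundled
tests and the reproduction script use.  Known limitations: one phase II
and one phase III trial only (no multi-arm, multi-trial or seamless
designs), no interim or futility analyses, no surrogate endpoints, no
time-discounting of cash flows, and Gaussian mixtures as the only prior
family (the closed-form reductions rely on it).
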