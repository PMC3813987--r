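---
title: "Dose finding with a normalized total toxicity profile: models, designs, and simulation machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose finding with a normalized total toxicity profile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nttp)
```

## The problem

Phase I oncology trials search a fixed ladder of doses $d_1 < \dots < d_K$
for the dose to recommend (RD) for further study, using toxicity as the
primary endpoint. Conventional designs reduce each patient's toxicity
experience to a single binary dose-limiting toxicity (DLT) indicator, which
discards the severity of sub-threshold events, the relative severity of
different DLTs, and the multiplicity of concurrent events. For molecularly
targeted agents — which tend to produce several moderate toxicities rather
than classical DLTs — that reduction wastes most of the signal.

This package implements a quasi-continuous alternative. Each patient's
grades $g_1, \dots, g_L$ over $L$ prespecified toxicity types are mapped
through a clinician-elicited weight matrix $W = \{w_{l,j}\}$ (type $l$,
grade $j \in \{0,\dots,4\}$) into the **total toxicity profile**

$$TTP = \sqrt{\textstyle\sum_{l} w_{l, g_l}^2},$$

the Euclidean norm of the observed weights. The norm, rather than an
arithmetic sum, keeps many mild events from outweighing one severe event
while still crediting every event; it also satisfies the triangle
inequality, so two toxicities concentrated in one patient score less than
the same two events split across two patients. Dividing by a normalization
constant $\nu = TTP_{max} + \epsilon$ gives the **nTTP** $\in [0, 1)$,
which can be treated as a fractional Bernoulli event. Grade 5 (death) is
deliberately outside the score's grade space: such an event must go to the
safety committee, not to an allocation rule, and the package raises a hard
error if one is scored.

The slack $\epsilon > 0$ exists so that a severe toxicity that was not
weighted a priori can be integrated mid-trial without renormalizing past
observations; the package stores $\nu$ itself (for the bundled example
matrix, $\nu = 2.5$).

### The target

The design needs a target score $\theta^*$ playing the role that the
target DLT rate plays in a classical CRM. `elicit_target()` implements the
elicitation arithmetic: clinicians classify hypothetical cohorts into
escalate / repeat / de-escalate decisions; once the classification is
consistent (every escalate cohort's mean TTP below every repeat cohort's,
and those below every de-escalate cohort's), $\theta$ is the mean of the
repeat cohorts' mean TTPs and $\theta^* = \theta/\nu$. Inconsistent
classifications are rejected with the offending comparisons listed, since
averaging over an inconsistent ordering has no meaning.

### The bundled example matrix

`example_weight_matrix()` ships a three-toxicity matrix (renal,
neurological, hematological) reconstructed from published constraints: a
single grade-3 renal/neurological or grade-4 hematological event scores 1,
a grade-4 renal/neurological event scores 1.5, the maximal profile scores
$\sqrt{5.5} \approx 2.345$, and two concurrent grade-2 events score about
one DLT. Those constraints pin the grade-3/4 weights exactly but not the
grade-1/2 weights; the shipped values (0.5 and 0.75 for renal/neurological,
0 and 0.5 for hematological) are one admissible choice, validated only
against the printed constraints. The matrix is a named fixture, never
hard-coded into any algorithm — every function takes the weight matrix as
an argument.

## Dose–toxicity models and skeleton calibration

Model-based designs model the mean nTTP at dose $d_k$ by a one-parameter
curve $\psi(x_k, b)$: logistic $1/(1+e^{-a-bx})$ with fixed intercept $a$,
empiric $x^b$, or complementary log-log. The intercept default is $a = 3$;
it is configurable, but values well below (2) or above (5) systematically
bias the recommended dose, which is why 3 is the default rather than a
free parameter users are expected to tune.

Pseudo-doses come from **backward substitution**: given a skeleton of
prior guesses $p_{01} < \dots < p_{0K}$, the $x_k$ solve
$\psi(x_k, b_{init}) = p_{0k}$ exactly (default $b_{init} = 1$), so the
model reproduces prior belief before any data arrive.

`indifference_skeleton()` generates the skeleton by the
indifference-interval construction: the prior RD guess gets the target
($p_{0,\nu_0} = \theta^*$), and moving outward the boundary slope between
preferring adjacent doses is made to place the two doses' modeled means at
exactly $\theta^* \pm \delta$. The defaults $\delta = 0.04$ and prior RD
$= d_3$ give, for $\theta^* = 0.28$ and the logistic model, the skeleton
`r paste(round(indifference_skeleton(0.28, 0.04, 3, 6, model_spec("logistic")), 3), collapse = ", ")`.
A larger $\delta$ pushes every skeleton value further from the target; note
that on the probability scale the gaps adjacent to the prior RD widen with
$\delta$ while the outermost gaps eventually shrink again as the values
saturate toward 0 and 1 — the invariant the tests assert is the per-dose
distance from the target, not the raw gaps.

## Estimation

Responses are fractional, so estimation uses a quasi-likelihood built from
a mean–variance assumption. With the **Bernoulli variance** $V(p) =
p(1-p)$ the objective is $\sum_i y_i \log p_i + (1-y_i)\log(1-p_i)$, which
collapses to the classic CRM likelihood for binary data. The **Wedderburn
variance** $V(p) = p^2(1-p)^2$ gives
$Q(y,p) = \int_y^p (y-t)/\{t^2(1-t)^2\}\,dt$, evaluated in closed form via
partial fractions with antiderivative
$F(y,t) = -y/t + y/(1-t) + (2y-1)\log\{t/(1-t)\} - 1/(1-t)$ and normalized
so $Q(y,y) = 0$. $Q$ diverges at $y \in \{0,1\}$, so responses are clamped
to $[10^{-6}, 1-10^{-6}]$ inside the Wedderburn objective only — the
Bernoulli objective handles $y = 0$ natively, which is one reason it is
the default.

**Frequentist** fitting (`mle_b()`) maximizes the objective over the slope
domain $(10^{-3}, 50)$ — wide enough for every skeleton/target geometry
used here while keeping the search bounded — by a deterministic 128-point
log-spaced grid bracket refined by `optimize()` to $10^{-8}$; a grid-based
bracket guards against the rare multimodality of quasi-likelihoods. No
interior maximizer exists while all responses are zero, so that case
raises a typed condition (`nttp_no_heterogeneity`) that the trial engine
interprets as "stay in the escalation stage".

**Bayesian** fitting (`posterior_mean_b()`) plugs the posterior mean of
$b$ into the curve, computing $E[b\,|\,\text{data}]$ by adaptive
quadrature (relative tolerance $10^{-8}$) over a range holding all but
$10^{-12}$ of prior mass per tail, stabilized by subtracting the grid
maximum of the log-density. Priors: exponential with mean 1 on $b$ (the
empiric-model default), or normal with mean 0 and variance 1.34 on
$\log b$ — placing the normal prior on the log keeps the slope positive
while preserving the intended prior shape; this is an interpretive choice,
flagged as such.

## The four designs

All designs accrue cohorts (default 3 patients) to a fixed total $n$
(default 36), never skip a dose on escalation (next dose $\le$ max tried
$+ 1$), start at $d_1$, and aim at the dose whose estimated mean nTTP is
closest to $\theta^*$.

* **QLCRM** — frequentist logistic quasi-CRM. Stage 1 escalates one level
  per cohort while all nTTPs are zero; any nonzero score (even a mild
  grade 1) triggers the permanent switch to model-based allocation, which
  is the practical advantage of a graded endpoint: the model starts
  working at the first event rather than the first DLT. Ties in
  $\arg\min_k |\hat p_k - \theta^*|$ go to the lower dose (conservative;
  the convention is ours).
* **QCRM** — Bayesian empiric quasi-CRM; the proper prior makes it
  model-based from the first cohort, with the same decision rule.
* **EID** — extended isotonic design. Per-dose mean nTTPs are isotonized
  by weighted PAVA (weights = patient counts); doses above the highest
  explored inherit the highest explored estimate. Escalate when the
  current and next estimates are both $\le \theta^*$; de-escalate when the
  current and next-lower estimates are both $> \theta^*$; otherwise stay.
  The published inequality typography is not machine-readable, so this
  rule is a declared reconstruction, isolated in `eid_next()` so an
  alternative can be swapped in; it reproduces the known over-escalation
  induced by the extrapolation, visible in the convergence study.
* **UA** — unified approach. After each cohort compute
  $T_k = (\bar y_k - \theta^*) / (s_k/\sqrt{n_k})$ from the current dose's
  observations only; escalate if $T_k \le -\Delta$, de-escalate if
  $T_k \ge \Delta$ (default $\Delta = 1$), else stay. Degenerate spread
  ($s_k = 0$, or a single observation) falls back to the sign of
  $\bar y_k - \theta^*$, the limit of $T_k$ as $s \to 0$. The final RD
  comes from a terminal PAVA over explored doses; tied estimates resolve
  to the lowest tied dose when the estimate is above the target and the
  highest when below (a tie straddling the target resolves low,
  conservatively).

**Final RD.** Model-based designs and the EID take the unrestricted
argmin over all $K$ doses — the RD may be a dose never allocated — under
the default `rd_rule = "any_dose"`; `"allocated_only"` is the sensitivity
variant restricting to allocated doses. A frequentist trial that ends with
every response zero has no fit; its RD is defined as the dose that would
have been allocated next (the highest tried dose under
`"allocated_only"`).

## Scenario construction and the synthetic-data generator

A scenario is one $K \times 5$ grade-probability matrix per toxicity type,
with toxicity types independent. With $L \le 4$ the package enumerates all
$5^L$ profiles for exact per-dose mean nTTP and DLT probability
(`scenario_moments()`); the cap exists because $5^L$ growth makes
enumeration pointless beyond that, and larger $L$ should use Monte Carlo.
Plausible scenarios are unimodal in each grade's probability across doses,
with grade 0 nonincreasing and grade 4 nondecreasing in dose
(`validate_unimodal()` diagnoses violations without failing).

The original study's eight scenario matrices are not published — only
their per-dose mean nTTP and $p(DLT)$ rows are. `benchmark_targets()`
stores those rows and `benchmark_scenario()` reconstructs look-alike
scenarios by calibration: one latent severity per dose, shared by the
three toxicity types, generates the five grade probabilities through a
proportional-odds model with fixed cutpoints $(1.4, 3.2, 5.0, 6.8)$
(chosen once to give realistically right-skewed grade distributions at low
severity); mean nTTP is continuous and increasing in the severity, so each
target row is matched by per-dose root finding to far better than the
advertised 0.01 tolerance. One degree of freedom per dose means only the
mean-nTTP row is matched; the implied DLT probabilities are reported in
the `"calibration"` attribute but differ from the originals (they are
generally lower, because the latent model spreads mass over mild grades).
Reconstructed scenarios are labelled as such and never claimed identical
to the unpublished originals — headline percentages simulated from them
are comparable in kind, not in digit, with the original tables.

What the generator does **not** emulate: correlated toxicity types,
time-to-toxicity, within-patient correlation across cycles, and
patient-level covariates. Passing simulations therefore demonstrate the
designs' behaviour under independent, stationary, correctly specified
toxicity generation — not robustness to the messier structure of real
trial data.

## Simulation machinery and reproducibility

`simulate_design()` runs replicated trials and aggregates the percentage
of correct selection (PCS, with its binomial Monte-Carlo standard error),
per-dose recommendation and allocation percentages, recommendations
relative to the true RD, per-trial DLT counts, and pooled nTTP scores.
`convergence_study()` sweeps the total sample size (the conventional grid
is 15 to 99 in steps of a cohort). Every replicate derives its own seed
deterministically from the base seed and replicate index, so any single
trial can be reproduced in isolation; two runs with the same configuration
are byte-identical, and `cli_simulate()` writes a JSON manifest (seed,
package version, full configuration and its hash) sufficient to reproduce
a run exactly.

Default replicate counts: 5000 is the conventional figure for publication-
grade operating characteristics; the package default is 1000, which puts
the Monte-Carlo standard error of a PCS near 80% at about 1.3 percentage
points, and the test suite uses 400–1000 replicates depending on the
property under test, sizes chosen so the whole suite stays fast while the
binomial error bars remain far smaller than the effects asserted.

On the reconstructed benchmark scenarios at $n = 36$ the implementation
reproduces the expected qualitative ordering: QLCRM and QCRM within a few
PCS points of each other, EID clearly behind with a wider allocation
spread, UA comparable to the model-based pair but more conservative in
allocation — and the convergence sweep shows the model-based and UA
designs improving with $n$ while the EID plateaus early.

## Numerical choices and degenerate inputs, collected

* Probabilities clamped to $[10^{-12}, 1-10^{-12}]$ inside likelihoods;
  Wedderburn responses to $[10^{-6}, 1-10^{-6}]$.
* Slope search: grid-bracketed bounded optimization, tolerance $10^{-8}$;
  estimates at the domain boundary are flagged `converged = FALSE`.
* Quadrature: `integrate()` at relative tolerance $10^{-8}$ on
  prior-quantile truncation ranges.
* Ties in dose argmins: lower dose, except the UA below-target rule above.
* PAVA: weighted stack algorithm; exact weighted-mean preservation per
  pooled block; validated against exhaustive block-partition least squares.
* Scenario rows must sum to 1 within $10^{-12}$ at construction; file
  round-trips renormalize deviations up to $10^{-6}$ (serialization
  round-off) and reject anything larger.
* All trial-level randomness flows through a single base seed and
  deterministic per-replicate substreams below $2^{31}$.

## Known limitations

The EID decision inequalities and the UA statistic are reconstructions
from prose, as noted. The analytical (delta-method) variance for the nTTP,
which would require joint modeling of the toxicity components, is out of
scope. Stopping rules beyond the fixed sample size, variable cohort sizes,
dose skipping, and alternative scores (arithmetic-sum burden scores,
equivalent-toxicity scores) are not implemented. The elicitation functions
implement the arithmetic only; running an actual elicitation with
clinicians is a human process the package does not attempt to replace.
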