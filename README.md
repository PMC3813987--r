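# nttp: dose-finding designs for a normalized total toxicity profile endpoint

Phase I oncology trials usually steer dose escalation with a binary
dose-limiting toxicity (DLT) indicator, discarding the grade, type, and
multiplicity of everything a patient actually experiences. For agents that
mostly cause several moderate toxicities — the typical profile of
molecularly targeted drugs — that is most of the information. `nttp`
implements a quasi-continuous alternative endpoint and the sequential
designs built on it, for statisticians designing and simulating phase I
trials.

Each patient's grades g₁…g_L over L prespecified toxicity types are scored
through a clinician-elicited weight matrix W = {w_{l,j}} as the **total
toxicity profile**, the Euclidean norm

> TTP = √( Σ_l w²_{l, g_l} ),

normalized by ν = TTP_max + ε into the **nTTP** ∈ [0, 1), a fractional
event modeled with a quasi-Bernoulli likelihood. The package provides:

* the score itself (`ttp()`, `nttp()`, `is_dlt()`), target elicitation
  from classified hypothetical cohorts (`elicit_target()`), and a
  reconstructed three-toxicity example matrix (`example_weight_matrix()`);
* one-parameter dose–toxicity models (logistic / empiric / cloglog) with
  pseudo-doses by backward substitution and indifference-interval skeleton
  calibration (`indifference_skeleton()`);
* quasi-likelihood slope estimation with Bernoulli or Wedderburn variance,
  frequentist (`mle_b()`) or Bayesian by adaptive quadrature
  (`posterior_mean_b()`);
* four sequential designs sharing one trial engine (`run_trial()`): the
  frequentist quasi-likelihood CRM (QLCRM), the Bayesian quasi-CRM (QCRM),
  the extended isotonic design (EID, via weighted `pava()`), and the
  unified approach (UA, t-statistic up-and-down);
* scenario construction from per-toxicity grade-probability matrices with
  exact moments by 5^L enumeration, calibration of scenarios to target
  mean-nTTP curves, and replicated-trial simulation of operating
  characteristics (`simulate_design()`, `convergence_study()`);
* YAML/CSV interfaces and a thin command-line front end
  (`inst/cli/nttp`: `score`, `moments`, `trial`, `simulate`).

## Worked example

Score patients, inspect a scenario, and simulate the QLCRM:

```r
library(nttp)
ex <- example_weight_matrix()
ex$weights
#> Toxicity weight matrix (3 types x grades 0-4)
#>               grade0 grade1 grade2 grade3 grade4
#> renal         0.00   0.50   0.75   1.00*  1.50*
#> neurological  0.00   0.50   0.75   1.00*  1.50*
#> hematological 0.00   0.00   0.50   0.75   1.00*
#> * dose-limiting (type, grade) cell; TTP_max = 2.345

# a hypothetical cohort: (2,2,2), (1,1,3), (0,0,0)
grades <- rbind(c(2, 2, 2), c(1, 1, 3), c(0, 0, 0))
round(nttp(grades, ex$weights, ex$nu), 3)
#> [1] 0.469 0.412 0.000        # cohort mean 0.294: a "repeat the dose" cohort
```

A reconstructed benchmark scenario whose exact mean-nTTP curve crosses the
target θ\* = 0.28 at dose 4:

```r
sc <- benchmark_scenario("F")
round(scenario_moments(sc, ex$weights, ex$nu), 3)
#>   dose mean_nttp p_dlt
#> 1    1     0.054 0.008
#> 2    2     0.108 0.018
#> 3    3     0.183 0.041
#> 4    4     0.280 0.098
#> 5    5     0.359 0.194
#> 6    6     0.409 0.292

cfg <- design_config("qlcrm", theta_star = ex$theta_star)
run_trial(sc, cfg, ex$weights, ex$nu, seed = 7)
#> Simulated QLCRM trial: 36 patients, 12 cohorts
#> dose path: 1 -> 2 -> 3 -> 3 -> 4 -> 4 -> 3 -> 4 -> 4 -> 4 -> 4 -> 4
#> recommended dose: 4 | DLTs observed: 3

simulate_design(sc, cfg, ex$weights, ex$nu, n_reps = 500, seed = 1)
#> Simulation: QLCRM x 500 trials of 36 patients
#> PCS at true RD (dose 4): 89.6% (MC SE 1.4)
#> recommendation %: 0.0 0.0 0.4 89.6 10.0 0.0
#> allocation %:     8.4 8.3 10.6 55.6 16.8 0.2
#> mean DLTs per trial: 3.30 | mean nTTP per patient: 0.250
```

The trial walks up one level per cohort while no toxicity is seen, switches
to model-based allocation at the first nonzero score, concentrates accrual
at the correct dose (over half the patients), and recommends it in ~90% of
replicates; the 8.3–8.4% allocations at the low doses are exactly one
cohort of three out of 36 spent passing through.

The methods vignette (`vignettes/nttp-methods.Rmd`) documents the models,
the design rules, every numerical convention, and what the scenario
generator does and does not emulate.

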