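# jmie — joint models for longitudinal and survival data with intermediate events

`jmie` is an R package for follow-up studies in which a repeatedly
measured biomarker predicts a clinical endpoint *and* some patients
experience an intermediate event during follow-up — a reintervention, a
serious adverse event — that changes both the biomarker trajectory and the
instantaneous risk. It is written for biostatisticians building
individualized dynamic prediction tools in such settings (valve-surgery
cohorts followed echocardiographically, blood-pressure trials with
adverse events, and the like).

## The model

With ρ the intermediate-event time, R(t) = I(t ≥ ρ) and
t⁺ = max(0, t − ρ), the package couples

- a mixed-effects longitudinal submodel

  η(t) = x(t)ᵀβ + z(t)ᵀb + R(t)·{x̃(t)ᵀβ̃ + z̃(t)ᵀb̃},  y(t) = η(t) + ε(t),

  where the post-event part is either a level drop plus slope change
  (columns R(t) and t⁺) or a B-spline in t⁺, with a joint covariance D
  over (b, b̃); and

- a relative-risk survival submodel

  h(t) = h₀(t) exp{γᵀw + R(t)·ζ + αᵀ f(t)},

  where f(t) holds trajectory functionals — current value η(t), slope
  dη/dt, area ∫₀ᵗ η(s) ds — whose active set may differ before and after
  ρ, and ζ is the direct effect of the intermediate event on risk.

Estimation is Bayesian MCMC (conjugate independence proposals for β and
b, Gibbs for σ² and D, adaptive Metropolis for the survival block), with
all cumulative hazards integrated by Gauss–Kronrod quadrature split at ρ.
From a fit the package derives scenario-adaptive dynamic predictions
π(u | t, ρ) — under "no intermediate event through u", "event now",
"event at time s", or the observed ρ — and evaluates predictive accuracy
with an intermediate-event-stratified time-dependent AUC decomposition
and a Henderson-type expected prediction error. A simulation engine
generates complete synthetic studies (biomarker-triggered intermediate
events, hazard-inversion event times, exponential censoring) and a
benchmark harness compares the joint model against an extrapolation
comparator and a time-dependent Cox model.

## A worked example

```r
library(jmie)

sim    <- simulate_study(simulation_config(n_subjects = 300, scenario = 1, seed = 1))
halves <- split_study(sim)
fit    <- fit_joint_model(model_spec(), halves$train)
print(fit)
```

```
Joint model fit (whole_trajectory), 150 subjects, 2 chains x 750 kept draws
          parameter     mean     sd     q2.5    q97.5 rhat    ess
  beta[(Intercept)]  20.5243 0.4541  19.6275  21.4250 1.01  106.2
         beta[time]   1.5641 0.0754   1.4086   1.7027 1.05   30.0
         beta[R(t)] -15.6898 0.5242 -16.6656 -14.6454 1.00  455.5
       beta[t_plus]  -0.9203 0.1025  -1.1236  -0.7362 1.01   77.2
              sigma   3.9967 0.0894   3.8210   4.1708 1.01 1023.9
 gamma[(Intercept)]  -6.8710 0.6690  -8.1934  -5.4997 1.02  106.3
               zeta  -0.7984 0.4004  -1.5884  -0.0226 1.02  111.3
       alpha[value]   0.0483 0.0142   0.0232   0.0822 1.00  148.9
          log_shape   0.5109 0.1493   0.2010   0.7966 1.02   96.9
```

The 150-subject training half was generated with intercept 20.7, slope
1.6, a drop of −15.5 and a slope change of −0.76 at the intermediate
event, σ = 4, ζ = −0.7 and a value association of 0.05 — each 95%
credible interval above covers its generating value. Predictions for a
new event-free subject, under two scenarios for a future intermediate
event:

```r
subj <- halves$test$subjects[[1]]
keep <- subj$obs_times <= 10          # history available at the landmark
subj$obs_times <- subj$obs_times[keep]; subj$y <- subj$y[keep]
predict_table(fit, subj, t = 10, u_grid = c(10, 12, 14, 16),
              scenarios = list(scenario_none(), scenario_immediate()),
              M = 500, seed = 3)
```

```
        scenario  t  u median lower upper
1 none_through_u 10 10  1.000 1.000 1.000
2 none_through_u 10 12  0.919 0.878 0.947
3 none_through_u 10 14  0.826 0.738 0.888
4 none_through_u 10 16  0.724 0.589 0.826
5      immediate 10 10  1.000 1.000 1.000
6      immediate 10 12  0.983 0.966 0.993
7      immediate 10 14  0.964 0.928 0.985
8      immediate 10 16  0.944 0.890 0.976
```

An immediate intervention improves this subject's predicted survival
(both ζ < 0 and the biomarker drop lower the hazard); a scheduled
`scenario_at(s)` curve would overlap the no-event curve up to s and
separate after it. Accuracy on the held-out half at landmark t = 20,
horizon Δt = 2:

```r
preds <- accuracy_predictions(fit, halves$test, t = 20, dt = 2, M = 300, seed = 4)
auc_dynamic(halves$test, preds, t = 20, dt = 2)
#> Time-dependent AUC(t = 20, dt = 2): 0.9000
#>   components (pooled): AUC1 = 0.9000, AUC2 = 0.7667, AUC3 = 1.0000, AUC4 = -
pe_dynamic(halves$test, preds, t = 20, u = 22)
#> Expected prediction error PE(u = 22 | t = 20): 0.0925
```

A command-line wrapper with `simulate`, `fit`, `predict`, `evaluate` and
`benchmark` subcommands is installed at `inst/cli/jmie`; every run writes
a JSON manifest tying seeds and configuration to output checksums.

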