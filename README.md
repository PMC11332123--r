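# effortmob

Effort-based decision-making under acute stress: simulation, model fitting,
and Bayesian model selection.

## What this is for

In forced-choice effort paradigms, participants repeatedly decide whether a
grip-force requirement (40–100% of their maximum sustainable grip force,
MGF) is worth an incentive: neutralizing a 20–50% threat-of-shock
("thunderstorm") or earning a 1–15 Eurocent reward ("high striker"). Each
session crosses 4 effort levels with 4 incentive levels into 16 offers,
repeated over 5 blocks (80 trials). The scientific question is how acute
stress shifts the subjective trade-off between minimizing effort and
maximizing safety — visible as a selective increase in accepting
*uneconomical* offers (high effort, low threat) and as more vigorous force
production.

`effortmob` implements the complete analysis pipeline for researchers in
computational psychiatry / decision neuroscience, with a synthetic-cohort
generator replacing human data so every stage is testable offline:

- **Choice models.** Subjective value of exerting effort
  `SV = T − cost(E; k)` with linear (`kE`), parabolic (`kE²`), hyperbolic
  (`1/(1−kE)`), or exponential (`e^{kE}`) effort costs, and softmax choice
  `p(accept) = 1/(1 + e^{−β(SV + c)})`.
- **Two-step hierarchical fitting.** Subject-level bounded maximum
  likelihood, then MAP re-fitting under an empirical Gaussian prior (mean
  and covariance of the whole sample's stage-1 estimates), AIC per fit.
- **Random-effects Bayesian model selection.** Variational Dirichlet
  posterior over family frequencies, exceedance probability (xp), Bayes
  omnibus risk (BOR), protected exceedance probability (pxp), per group.
- **Vigor metrics.** 100 ms rolling average of 60 Hz force traces, success
  epochs anchored at the 1.5 s-hold completion, overexertion (%MGF above
  threshold), and yank peak (maximal dF/dt).
- **Group contrasts.** Permutation tests on subject-level quadrant
  acceptance, predicted subjective value, and overexertion; plus a
  parameter/model recovery harness.

## Worked example

```r
library(effortmob)

res <- run_pipeline(cohort_spec(seed = 11))
res
```

```
effortmob pipeline result
  subjects: 80 (5 flagged inflexible)
  winning families: MAST_PLC=linear, MAST_EXP=hyperbolic
  contrasts:
       measure          quadrant    observed      p_value
1   acceptance high_eff_high_inc -0.02331081 0.7066466767
2   acceptance  high_eff_low_inc  0.26167417 0.0004997501
3   acceptance  low_eff_high_inc -0.12507508 0.0244877561
4   acceptance   low_eff_low_inc -0.04605856 0.2718640680
...
9 overexertion              <NA>  1.77561125 0.0004997501
```

Reading this: the pipeline simulated a two-group cohort (40 no-stress
controls, 40 stressed; 5 subjects flagged as inflexible responders and
excluded from modeling), fit all four discounting families per subject in
two stages, and ran per-group Bayesian model selection. The control group
is best explained by linear discounting and the stress group by hyperbolic
discounting. The stress group accepts high-effort/low-threat offers 26
percentage points more often than controls (permutation p ≈ 0.0005) — the
selective effect, maximal exactly in the uneconomical quadrant — and
overexerts by an extra 1.8 %MGF while holding force (p ≈ 0.0005).

Useful follow-ups:

```r
tidy(res$bms$MAST_EXP)        # alpha, expected frequencies, xp, pxp
glance(res$bms$MAST_EXP)      # winner, xp, BOR in one row
plot_acceptance_heatmap(res$trials)
autoplot(res$bms$MAST_EXP)
recovery_suite(cohort_spec(seed = 11))   # parameter + model recovery
```

A thin CLI over the same functions is installed at
`inst/scripts/effortmob` (`simulate`, `run-all`, `recover` subcommands).

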