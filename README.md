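# rhythmrep

Bayesian observer modelling of temporal pattern reproduction.

When people reproduce a short rhythmic sequence — four auditory intervals
marked by five beeps — their reproductions are systematically biased. Each
reproduced interval regresses toward the mean of the sequence (the *central
tendency* bias, an OLS slope < 1 of reproduced on sample duration), the first
interval drags the whole reproduction toward itself (primacy/assimilation),
and sequences that feel more volatile are shrunk more strongly. `rhythmrep`
is for psychophysicists studying interval and pattern timing: it implements a
generative observer model of these effects, the matching experimental design
and trial simulator, the behavioral summary pipeline, and a two-stage fitting
procedure.

## The model

A sequence presents intervals D₁…D₄ (ms) drawn from one of two fixed sets,
[400, 500, 900, 1000] or [400, 600, 700, 1100], both with mean 700 ms and SD
294.39 ms, in decelerating (DS, short→long), accelerating (AS, long→short) or
random (RS, any non-monotone) order. The observer:

- forms an **ensemble prior** whose mean weights the first interval against
  the design mean, μₑ = α·D₁ + 700·(1 − α), with SD σₑ = wf_p·μₑ;
- measures each interval with **volatility-scaled Weber noise**,
  σᵢ² = k_j·(wf_s·Dᵢ)², where k_j > 1 inflates uncertainty for sequence type
  *j*;
- reproduces each interval as the **precision-weighted fusion**
  Rᵢ = (1 − w)·μₑ + w·Dᵢ with w = σₑ²/(σₑ² + σᵢ²), and reproduction variance
  σ_r² = σᵢ²σₑ²/(σᵢ² + σₑ²).

Free parameters per participant: the sensory and prior Weber fractions wf_s
and wf_p, the first-interval weight α ∈ [0, 1], and one volatility factor per
condition (k_AS, k_DS, k_RS). Fitting is two-stage: wf_s, wf_p, α, k_AS and
k_DS are estimated from the structured sequences, then frozen while k_RS is
estimated from the random sequences. Note that the likelihood constrains wf_s
and the k's only through the products k_j·wf_s²; the prior on wf_s sets the
overall scale (see the methods vignette).

## Worked example

```r
library(rhythmrep)

# a 15-participant study (264 trials each) simulated at the default
# group-level parameters (wf_s 0.18, wf_p 0.35, alpha 0.195, k 2/2.4/2.13)
trials <- simulate_dataset(simulation_config(n_participants = 15,
                                             master_seed = 42))

res <- analyze_reproduction(trials)
aggregate(slope ~ condition, res$slopes, mean)
#>   condition     slope
#> 1        AS 0.7084192
#> 2        DS 0.5144483
#> 3        RS 0.6058775
aggregate(mean_ms ~ condition, res$means$means, mean)
#>   condition  mean_ms
#> 1        AS 682.6396
#> 2        DS 634.0660
#> 3        RS 657.0661

fit <- fit_observer(trials, seed = 42)
summary(fit)
#> Bayesian observer model, two-stage fit (map)
#> Participants: 15   outlier trials excluded: 176
#>
#> Group parameters (mean +/- between-subject SD):
#>   wf_s   0.191 +/- 0.005
#>   wf_p   0.342 +/- 0.015
#>   alpha  0.192 +/- 0.051
#>   k_AS   1.659 +/- 0.172
#>   k_DS   2.027 +/- 0.158
#>   k_RS   1.754 +/- 0.217
#>
#> R^2 (predicted vs observed interval means):
#>   AS = 0.988
#>   DS = 0.967
#>   RS = 0.985
```

All three behavioral signatures of the model are visible: the accelerating
sequences show the weakest central tendency (slope 0.71 vs 0.51 for DS), the
mean reproduction is assimilated to the first interval (AS highest, DS
lowest), and the two-stage fit recovers the shared parameters (α, wf_p) and
the ordering k_DS > k_AS from the data. `predict()`, `residuals()`,
`simulate()` and `plot()` work on the fitted object as for other R model
classes; real datasets in the same long CSV format load via `read_trials()`
(with a `map=` argument for foreign column names).

A small command line wraps the same functions:

```sh
inst/exec/rhythmrep simulate --seed 1 --out run/
inst/exec/rhythmrep analyze --input run/trials.csv --out run/summaries/
inst/exec/rhythmrep fit --input run/trials.csv --out run/fit/ --seed 1
```

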