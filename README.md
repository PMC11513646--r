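# sociomove

Tools for linking **energy availability, movement and sociality** in
group-living animals tracked with high-resolution biologgers. The package
was built around the analysis workflow used for wild chacma baboons carrying
GPS/accelerometer collars, with faecal triiodothyronine (fT3) as a
non-invasive proxy for energy availability, but every stage is generic:

1. **Movement metrics** (`daily_metrics_all`): per individual-day, total
   travel distance, and the medians of step length, sinuosity and residence
   time, computed on 60-s resampled path-segments restricted to natural
   habitat. Sinuosity is the corrected index
   `S = 2 [p (1 + c) / (1 - c)]^(-1/2)` (`p` mean step length, `c` mean
   cosine of turning angles); residence time is the time spent inside a disc
   of radius equal to the individual's mean step length, allowing
   excursions shorter than a 5-min cut-off.
2. **Social opportunities** (`detect_events`, `daily_counts`): dyadic
   episodes of close proximity (<= 2 m, boundary inclusive) from
   simultaneous 1 Hz GPS, with re-contacts within 2 s merged into a single
   event; daily per-individual frequencies restricted to days with >= 10
   active collars.
3. **Hormone covariates** (`daily_mean_ft3`, `apply_lag`,
   `decompose_energy`): daily mean fT3, a 48-h excretion lag (behaviour day
   `d` paired with the sample collected on `d + 2`), and the
   within-/between-individual split into each individual's mean and the
   mean-centred deviations.
4. **Grooming** (`daily_grooming_totals`): sunrise-to-sunset totals of
   grooming given and received from bout records, with the solar window
   computed from the standard NOAA solar-position algorithm.
5. **Mixed-model suite** (`run_suite`): seven LMMs fitted with `lme4` with
   crossed random intercepts for individual and date and focal random
   slopes —

   | model | response (transform) | focal predictor(s) |
   |-------|----------------------|--------------------|
   | LMM1–4 | distance, log step, log sinuosity, log residence | mean fT3 + mean-centred fT3 |
   | LMM5 | sqrt opportunity frequency | log residence time (females, >= 10 collars) |
   | LMM6 | sqrt receiving grooming | opportunity frequency |
   | LMM7 | sqrt giving grooming | opportunity x fT3 interaction |

   with z-scored continuous predictors, likelihood-ratio tests against
   null models (random intercepts + controls), and generalized VIFs.
6. **Synthetic generator** (`simulate_dataset`): an agent-based cohesive
   troop with a latent daily energy state, two-state movement
   (area-restricted search vs transit), mechanistic <= 2 m encounters at
   shared anchors, and grooming driven by the realised opportunity counts —
   so the whole chain can be tested end-to-end against known ground truth
   (`recovery_experiment`, `type1_experiment`).

## Worked example

```r
library(sociomove)

sim  <- simulate_dataset(generator_config(), seed = 42)   # four input streams
data <- run_pipeline(sim)                                 # joined analysis table
fit  <- fit_lmm(model_specs()$LMM4, data)                 # energy -> residence
fit
```

```
LMM4: n = 202 observations, N = 13 individuals (singular fit)
                          term estimate      se      t       p
                        <char>    <num>   <num>  <num>   <num>
1:                 (Intercept)  0.80214 0.01763 45.491 0.00000
2:    reproductive_statecyclic -0.02141 0.03087 -0.694 0.48793
3: reproductive_statelactating  0.02922 0.03777  0.774 0.43905
4:      reproductive_statemale -0.03573 0.02868 -1.246 0.21284
5:  reproductive_statepregnant -0.02021 0.02775 -0.728 0.46656
6:                    ft3_mean  0.00768 0.01103  0.696 0.48669
7:                 ft3_centred  0.02847 0.00965  2.949 0.00319
LRT vs null: df = 4, chi2 = 12.63, p = 0.0132
```

Read: on days when an individual's (lagged) fT3 sits above its own average,
its median residence time is longer (`ft3_centred` positive, p = 0.003 —
the generator's default `beta_EM > 0` made true), while the
between-individual term (`ft3_mean`) is weak; `n`/`N` count observations
and individuals after lag-matching and log-transform filtering. The
"singular fit" flag means the random-slope variance was estimated at zero,
which is common and harmless at this scale.

Ground-truth recovery across replicate worlds:

```r
rec <- recovery_experiment(generator_config(), n_replicates = 100,
                           seed = 1, reference = default_reference_truth())
rec$summary
```

reports, for each focal link (energy->residence, residence->opportunities,
opportunities->receiving, interaction->giving), the sign-recovery rate,
rejection rate, mean raw-scale estimate, relative bias and 95% CI coverage.

## Command line

```sh
Rscript inst/cli/sociomove simulate --seed 1 --out-dir sim/
Rscript inst/cli/sociomove metrics --gps sim/gps.csv --out metrics.csv
Rscript inst/cli/sociomove proximity --gps sim/gps.csv \
    --out-events events.csv --out-counts counts.csv
```

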