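# pirvae — household routines and anomalous days from ambient motion sensors

`pirvae` is an R package for public-health researchers and smart-home
analysts who want to turn the binary 5-minute activation streams of
passive-infrared (PIR) motion sensors — the kind bundled with smart
thermostats — into interpretable household behaviour: each household's
regular daily activity pattern, days that deviate from it, wake and sleep
times, sleep duration, minutes spent at home, and weekend-versus-weekday
contrasts. Everything is unsupervised: no activity labels, no wearables, no
cameras.

## The model

Per-sensor 5-minute reports are first denoised into a household-level
**motion state** per clock-aligned half-hour: positive iff the summed
activations over the window's 6 steps and all sensors reach 4. A year of
data becomes a stack of independent binary day sequences
$X = \{X_1, \dots, X_N\}$, $X_t \in \{0,1\}^{48}$.

Each household gets its own **LSTM variational autoencoder**: a 2-layer,
100-unit LSTM encoder reads the 48 slots and two linear heads emit the
Gaussian posterior $q(z \mid x) = N(\mu_x, \sigma_x^2)$ over a
7-dimensional latent; a draw $z = \mu_x + \sigma_x \odot \varepsilon$ feeds
a 2-layer LSTM decoder that emits per-slot motion probabilities
$\hat{x}$. Training minimizes the negative ELBO
$\sum_t \mathrm{BCE}(x_t, \hat{x}_t) + \mathrm{KL}(q \,\|\, N(0, I))$ plus
an L1 penalty (0.001) on the encoder LSTM kernels, with Adam (lr 0.001),
mini-batches of 7 days, 200 epochs by default. The network — forward,
backpropagation through time, Adam — is implemented in vectorized base R
and validated against finite-difference gradients in the test suite.

A day's **anomaly score** is its mean per-slot binary cross-entropy against
a stochastic reconstruction; a day is flagged when its score is at or above
**median + IQR** of the scored set (IQR = P75 − P25, linear-interpolation
quantiles). The **regular activity pattern** averages posterior-mean
reconstructions over all days; its longest circular motionless run gives
sleep time, wake time and sleep duration. A bundled synthetic-household
generator (schedules, weekend overrides, sensor noise, missing days, and
labelled anomaly days in absence / insomnia / shifted modes) makes the full
pipeline testable end to end.

## Worked example

Following the study design — learn the routine from one period, score a
later one — simulate a noisy household, train a reduced model on 180 clean
days, then score the following 90 days in which 8 "absence" days (nobody
home) are planted:

```r
library(pirvae)

# the household's routine: wake 7:00, away 9:30-16:30, sleep 22:30,
# no regular absence at weekends
base <- household_spec(
  n_sensors = 8, wake_slot = 14, depart_slot = 19, return_slot = 33,
  sleep_slot = 45,
  weekend_profile = list(depart_slot = NA, return_slot = NA),
  p_fire_active = 0.25, p_fire_idle = 0.005,
  n_days = 180, seed = 42)
train_dm <- build_day_matrix(generate_household(base, "DEMO"))

# the follow-up period: same routine plus 8 labelled absence days
follow <- base
follow$epoch <- as.Date("2018-07-01")
follow$n_days <- 90L
follow$anomaly_days <- seq(10, 80, by = 10)
follow$anomaly_mode <- "absence"
follow$seed <- 43L
score_dm <- build_day_matrix(generate_household(follow, "DEMO"))

model <- fit_lstm_vae(train_dm, vae_config(n_hidden_units = 24, latent_dim = 4,
                                           epochs = 60, seed = 1))
scores <- score_days(model, score_dm, seed = 1)
report <- summarize_household("DEMO", score_dm$dates, score_dm$day_of_week,
                              scores, auc = validation_auc(model, score_dm, seed = 1))
print(report)
cat("planted absence days flagged:",
    sum(report$flags == 1 & score_dm$anomaly_labels == 1), "of",
    sum(score_dm$anomaly_labels), "\n")

bs <- summarize_behavior(regular_pattern(model, train_dm), train_dm)
print(bs)
```

```
<anomaly_report> DEMO: 19/90 abnormal days (2 on weekends), mean loss 0.177, threshold 0.0331
planted absence days flagged: 8 of 8 
<behavior_summary> DEMO: wake 07:00, sleep 22:30, sleep duration 510 min, weekend-vs-weekday p = 8.24e-41
```

Reading the output: all 8 planted absence days score above the median+IQR
threshold (0.0331) and are flagged, along with 11 ordinary noisy days that
deviated most from the routine — an adaptive threshold always flags a
household's own extremes. The regular pattern recovers the generator's
schedule exactly (wake 07:00, sleep 22:30, a 510-minute nightly motionless
run), and time at home is significantly higher on weekends (the generator
removes the weekday away window on Saturdays and Sundays; Mann-Whitney
p ≈ 8e-41).

## The analysis workflow

The `analysis/` directory holds the full study flow as numbered scripts,
each a thin driver over the package that writes its tables under
`results/`:

| script | what it does |
|---|---|
| `01_simulate_cohort.R` | simulates a 6-household cohort (jittered schedules, one household with 20 labelled absence days, one under-instrumented) and exports raw sensor CSVs |
| `02_preprocess.R` | applies the inclusion criteria (≥ 8 sensors, ≥ 355 days online) and builds the daily 48-slot matrices |
| `03_train_models.R` | trains one LSTM-VAE per included household on a random 80% of its year |
| `04_detect_anomalies.R` | scores every day, applies the median+IQR flag, writes the per-household validation table |
| `05_behavior.R` | extracts regular patterns, wake/sleep times, minutes at home, and the weekend-vs-weekday test |

The methods vignette (`vignettes/household-routines.Rmd`) documents the
model, its assumptions, all tunable parameters, and what the synthetic
generator does and does not emulate.

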