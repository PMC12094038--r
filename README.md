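# thermofeed

Body-temperature phenotypes and feed efficiency in lactating dairy cows.

Thermoregulation costs energy: the heat increment of feeding — heat
produced by digestion, nutrient metabolism and product synthesis — should
be smaller in more efficient cows. `thermofeed` implements the full
analysis chain for testing that idea with high-frequency vaginal
temperature loggers: from raw 5-minute traces to cow-level phenotypes, from
feeder-visit logs to a data-driven meal criterion, from milk/BW records to
residual feed intake, and finally to cohort-adjusted association models.
It is aimed at researchers working with feed-efficiency trial data
(intake-recording herds) and, because no raw herd data are public, it
ships a synthetic herd generator with known ground truth so every stage is
verifiable.

## What it computes

**Temperature phenotypes** (after QC: ≥ 7 days of records per cow, single
3-SD outlier pass):

- mean body temperature, trial and daily;
- consistency = log(var × 100), the natural log of 100× the variance of
  record deviations from the cow's mean (lower = steadier);
- post-meal change: temperature 20 min after the end of the day's largest
  meal minus temperature at meal start, each a 3-record average.

**Meal criterion**: a two-component Gaussian mixture fitted by maximum
likelihood (EM, multiple restarts) to the log10 distribution of inter-visit
intervals; the criterion is 10^x\* at the weighted-density intersection x\*
between the component means. Visits closer than the criterion merge into
meals.

**Feed efficiency**:

- MilkE = (0.0929·fat% + 0.0585·true protein% + 0.0395·lactose%) × milk
  yield, weekly then averaged per cow;
- metabolic BW = (mean BW)^0.75 with missing BW days filled from an OLS
  line on day of trial; ΔBW = last − first fitted day;
- RFI = residual of `DMI = DIM + Lact + Cohort + b1·MilkE + b2·mBW +
  b3·ΔBW + e`, with DIM in nine 15-d classes over 60–195 d and lactation
  classes 1/2/3/4+.

**Associations**: trial-level OLS (temperature trait + cohort + THI +
THI×station), daily linear mixed models with a random cow intercept
(REML, `lme4`), partial correlations controlling for cohort, and
adjusted-R² comparison of the RFI model with and without each temperature
trait. THI = (1.8t + 32) − (0.55 − 0.0055·rh)(1.8t − 26), averaged over the
cow's recording window ± 3 days.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
herd (300 cows, 14 days, seed 42) and write every table under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_temperature_phenotypes.R
Rscript analysis/03_meal_criterion.R
Rscript analysis/04_efficiency_rfi.R
Rscript analysis/05_associations.R
```

`01_simulate.R` reports the generating truth:

```
synthetic herd: 300 cows, 14 d trial, 12 cohorts, 2 stations
  temperature records: 1,148,544; visits: 44,335
  true meal criterion: 30.64 min
ground truth: criterion 30.64 min, DMI~temp slope -2.50 kg/d/degC, b = (0.37, 0.10, 0.30)
```

`02`–`04` recover the phenotypes and the RFI model:

```
QC: 300 cows in, 0 excluded (<7 d), 3535 records removed (3-SD)
trial phenotypes: mean temp 38.63 degC (SD 0.109), logvar 1.31

estimated meal criterion: 30.67 min (truth 30.64 min)
20052 meals from 44335 visits; 4182 largest-of-day meals
post-meal change: mean -0.250 degC (SD 0.030) over 300 cows

RFI model: n = 300 cows, rank 26, adjusted R^2 = 0.918
  b1 (MilkE) = 0.3720, b2 (mBW) = 0.0773, b3 (dBW) = 0.3074
RFI: mean -3.17e-17, SD 1.10 kg/d
```

The mixture criterion lands within 0.1 min of the analytic intersection;
the MilkE and ΔBW coefficients sit on the generating values (the mBW
estimate is noisier at n = 300 — its regressor spans only ~12 kg^0.75).
Mean RFI is zero by construction of the residual. `05_associations.R` then
prints, among others:

```
   response temp_trait  slope     se  p_value   n
1       dmi  mean_temp -3.624  2.082 8.28e-02 300
...
daily mixed models (random cow intercept, REML):
  temp_trait  slope    se  p_value    n n_cows
1  mean_temp -2.881 0.280 7.95e-25 3988    300
```

i.e. the injected trial-level slope of −2.5 kg DMI per °C is recovered
within its (wide, n = 300) standard error, and the daily association is
sharply estimated from ~4,000 cow-days. Adding temperature traits to the
RFI model moves adjusted R² by < 0.005, mirroring the scientific finding
that temperature phenotypes correlate with intake but do not improve the
RFI model fit.

Everything the scripts do is exported: `simulate_herd()`, `qc_herd()`,
`temperature_phenotypes()`, `fit_interval_mixture()`, `meal_criterion()`,
`merge_visits_to_meals()`, `post_meal_deltas()`,
`build_efficiency_records()`, `compute_rfi()`, `thi()`, `window_thi()`,
`regress_trait()`, `daily_mixed_model()`, `partial_correlation()`,
`compare_rfi_models()`, `run_pipeline()`. See the methods vignette
(`vignettes/thermofeed-methods.Rmd`) for the models, assumptions and
design choices.

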