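# c14pop

Radiocarbon date frequencies as population proxies: summed probability
distributions (SPDs), demographic null models, and a Monte-Carlo
boom/bust significance test.

## The problem

Toward the end of the Pleistocene dozens of North American large-mammal
taxa went extinct, with human hunting and climate change the leading
proposed causes. One way to weigh them is demographic: reconstruct the
population trajectories of megafauna and of people from the temporal
frequency of radiocarbon dates — larger populations deposit more dateable
carbon — and ask *when* each megafaunal population's growth turned into
the decline that ended in extinction, and whether that decline coincided
with human population growth (negative correlation → hunting) or with
climatic deterioration (positive/no correlation → climate). `c14pop`
implements that whole inferential chain for anyone working with
radiocarbon compilations, plus a synthetic-data generator with known
ground truth so every stage can be validated without external downloads.

## The method

For a measurement $(x, \sigma_l)$ and a calibration curve
$\mu(\theta), \sigma_c(\theta)$ on an annual calendar grid, the
calibrated density is
$p(\theta) \propto \mathcal{N}(x \mid \mu(\theta),
\sqrt{\sigma_l^2 + \sigma_c^2(\theta)})$, normalised over the grid. The
SPD is the per-year sum of the normalised densities, smoothed with a
200-year centered moving average. A two-segment log-link quasi-Poisson
GLM profiled over candidate join years locates the growth-to-decline
breakpoint; the pre-breakpoint GLM extrapolated over the whole grid is
the exponential null ("the trajectory had growth never slowed"; a
five-parameter Richards logistic null is also available). `nsim` date
sets are simulated under the null, passed *back* through the curve,
rebuilt into SPDs exactly as the observed one, and used to Z-standardise
every series per year. Years where the observed Z-score leaves the
per-year 95% simulation envelope are flagged as booms/busts; the oldest
year of the youngest bust is the **terminal bust onset**; and a global
p-value ranks the observed exceedance area against the simulations'
(each measured, leave-one-out, against the ensemble of the others, so
the comparison is exchangeable under the null). Spearman rank
correlation compares two SPDs over a calendar window, and a power-law
taphonomic correction $s(t) = a(t+c)^b$ is available.

See `vignettes/radiocarbon-demography.Rmd` for assumptions, parameter
choices and limitations.

## Worked example

Simulate a population that grows exponentially but suffers a 60% bust
over 12,900–12,000 cal BP, observed through 100 dates and a wiggly
synthetic calibration curve; then run the full pipeline:

```r
library(c14pop)

curve <- make_synthetic_curve("wiggly", c(9500, 20500), sigma = 15)
sc <- scenario("exponential_with_bust", bust = c(12900, 12000),
               bust_depth = 0.6, n_dates = 100, seed = 7)
dates <- draw_scenario_dates(sc, curve)

cfg <- run_config(nsim = 500, seed = 42)
res <- run_model_pipeline(cfg, curve = curve, dates = dates)
print(res$mc)
```

```
Monte-Carlo null-model test: synthetic-exponential_with_bust
  nsim = 500  n = 100  alpha = 0.05  seed = 42
  reporting window: 15000 - 10000 cal BP
  global p = 0.3473
  booms: [13799, 13757], [11875, 11777], [11059, 10973]
  busts: [15000, 14821], [12827, 12557]
  terminal bust onset: 12827 cal BP
```

The imposed bust is recovered as the flagged interval 12,827–12,557 cal
BP: its onset misses the true onset (12,900) by 73 years, within the
±150-year resolution one expects after 200-year smoothing. The short
flagged intervals elsewhere are edge/noise artifacts of a single n = 100
realisation — the global p of 0.35 correctly reflects that a series
which *recovers* after its bust deviates only locally from a full-window
exponential null. `res$spd`, `res$null`, `res$breakpoint` hold the
intermediate objects; `write_pipeline_result(res, "out/")` serialises
everything (JSON + CSV) with the config hash and master seed embedded.

Real data enter the same way via `read_dates_csv()` +
`read_cal_curve()` (IntCal-style `.14c` files), with `vet_dates()`,
`filter_region()` and `select_taxa()` covering the standard compilation
rules (duplicate/anomalous/context/kill-site removal, one date per
individual, study regions, >20-dates-per-taxon inclusion).

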