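---
title: "Radiocarbon date frequencies as population proxies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiocarbon date frequencies as population proxies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The premise of date-frequency demography is that larger populations deposit
more dateable carbon, so the temporal density of radiocarbon dates tracks
relative population size. `c14pop` implements that inferential chain for
late-Pleistocene material — human occupation records and directly dated
megafauna — where the question of interest is *when a population's growth
turned into the decline that ended in extinction*, and whether that decline
co-occurred with human population growth.

A radiocarbon measurement is a pair (age, error) in ^14^C years. Given a
calibration curve with per-year mean $\mu(\theta)$ and error
$\sigma_c(\theta)$, the calendar-year likelihood of a measurement
$(x, \sigma_l)$ is

$$p(\theta) \propto
  \mathcal{N}\!\left(x \mid \mu(\theta),
  \sqrt{\sigma_l^2 + \sigma_c^2(\theta)}\right),$$

normalised over the annual grid. The summed probability distribution (SPD)
is the per-year sum of these normalised densities over all dates, smoothed
with a 200-year centered moving average. The SPD is then compared to a
*null model of undisturbed growth*:

1. a two-segment log-link quasi-Poisson GLM, joined at a breakpoint chosen
   by profiling total deviance over candidate years, locates the
   growth-to-decline transition;
2. a single log-link GLM fitted to the pre-breakpoint portion and
   extrapolated over the whole grid gives the expected trajectory had
   growth never slowed (the exponential null); a five-parameter Richards
   logistic null is available as a robustness check;
3. `nsim` date sets of the observed size are simulated under the null
   (calendar years drawn proportional to the null, "uncalibrated" through
   the curve with per-year curve error, lab errors resampled from the
   observed errors), rebuilt into SPDs identically to the observed one,
   and used to standardise every series per year into Z-scores;
4. years where the observed Z-score leaves the per-year 95% envelope of
   the simulated Z-scores are flagged as booms (above) or busts (below)
   and merged into maximal intervals; the *terminal bust onset* is the
   oldest year of the youngest bust interval;
5. a global p-value summarises overall deviation via the summed
   standardised exceedance area outside the envelope.

Z-standardising against the simulated ensemble de-trends artifacts that
the calibration curve imprints on *every* SPD (wiggles, plateaus), which
would otherwise masquerade as demographic signal.

## Exchangeability of the global statistic

The observed series is external to the simulated ensemble: its Z-scores
and exceedance are measured against a mean, SD and envelope computed from
the `nsim` simulations. If each simulation's statistic were measured
against that same envelope, simulations would be compared against bounds
they helped define, their statistics would be systematically deflated, and
the global p-value would be anti-conservative — in our calibration
experiments the rejection rate at a nominal 5% was roughly doubled.
`run_model_test()` therefore measures each simulation exactly as the
observed series is measured: against the ensemble of the *other*
simulations. Two closed-form leave-one-out corrections make this cheap
(one sort per year): removing a simulation from the per-year quantile is
an index shift on the order statistics, and removing it from the per-year
mean/SD reduces to a per-year rescaling of its exceedance by
$s/s_{-k}$. With these corrections the simulated and observed statistics
are exchangeable under the null up to the one-element difference in
reference-set size, which errs on the conservative side. Residual
miscalibration measured over 60 null-true replicates at `nsim = 100` was
a rejection rate of 8% at nominal 5%; the discreteness of small-ensemble
quantiles accounts for most of it and it shrinks as `nsim` grows toward
the 500 used in production runs.

## Parameters that matter

* **Grid**: 1 calendar year, fixed. All series are stored oldest to
  youngest in cal BP (years before 1950). Bust onsets are reported to the
  year, which is why no coarser grid is used.
* **Analysis window**: 20.0–10.0 ka cal BP by default; deviations are
  flagged over a 15.0–10.0 ka reporting window, and SPD correlations use
  15.0–11.7 ka. These mirror the compilation and reporting windows usual
  for terminal-Pleistocene work.
* **Smoothing**: "200-year moving average" is implemented as a centered
  ±100-year window (201 years; the parity must be fixed somehow and a
  centered window keeps ramps unchanged in the interior). At the series
  ends the half-width shrinks symmetrically; mass is conserved exactly
  for signal supported ≥100 years from the ends.
* **`nsim`** (default 500) and **`alpha`** (default 0.05): envelope and
  p-value resolution; the +1-corrected p-value floor is `1/(nsim+1)`.
* **Vetting rules**: duplicates (by lab id) → anomalous-flagged →
  excluded contexts → kill/scavenging sites → one date per individual,
  applied in that fixed order so audit counts are deterministic. "More
  than 20 dates" for taxon inclusion is a strict inequality; window
  membership of a date is decided by its modal calibrated year, the
  simplest reproducible rule.
* **Taphonomic correction**: survival $s(t) = a\,(t + c)^b$, defaults
  from the published power-law loss curve
  (`a = 5.726442e6, b = -1.3925309, c = 2176.4`); these are configuration,
  not constants baked into the code, because other loss curves exist.

## Numerical choices

* Calibrated densities are kept over the full analysis window and
  normalised there — no tail trimming, so no arbitrary cut-off tolerance.
  Densities are normalised *within* the window; a date whose density
  straddles a window edge concentrates its mass inside.
* The smoother uses a running cumulative sum: absolute accuracy is at
  machine precision relative to the series *total*, so tail values below
  ~1e-16 of the total are not resolved. Irrelevant for any statistic
  computed here, but visible if one inspects deep tails.
* Breakpoint profiling is exhaustive: candidates every 10 years, then a
  ±10-year refinement at 1-year steps. Deterministic, and cheap because
  the grid is small. A flat deviance profile (single-slope series) or an
  optimum on the search boundary is reported as "no interior optimum";
  the pipeline then falls back to fitting the exponential null over the
  whole window. The search interval must leave 500 years on each side of
  the window so both GLM segments are identifiable.
* Quasi-Poisson point estimates come from Poisson IRLS (`glm.fit`);
  dispersion affects no point estimate and is never needed downstream.
* The Richards fit maximises a Gaussian likelihood with the residual
  scale profiled out (least squares), via 25 seeded Nelder-Mead starts
  jittered around data-driven initial values; `K > A` and `nu > 0` are
  enforced by log-parameterisation. On series still in their exponential
  phase the fitted upper asymptote lands far above the data — the
  expected behaviour, and the reason the exponential null is the default.
* Ties exactly on an envelope bound are not flagged (strict
  inequalities).
* Years whose simulated SD is zero are excluded from flagging and from
  the global statistic, and listed in the result's diagnostics.
* Every stochastic step derives from one master seed; per-simulation
  seeds come from a counter-based rule (`(seed + 7919 k) mod 2147483629`)
  so any single simulation can be reproduced in isolation.

## The synthetic-data generator

`scenario()` + `draw_scenario_dates()` emulate the data a compilation
would supply, with known ground truth attached: calendar years drawn from
an exponential curve (default `r = 3e-4`/yr, a growth that multiplies a
population ~20-fold across the 20–10 ka window, in the range suggested by
terminal-Pleistocene SPDs), optionally carrying a multiplicative bust
(default depth 0.6 with 50-year linear edge ramps, so a population drops
to 40% of its counterfactual), or following a Richards curve. Dates are
"back-calibrated" through a synthetic curve — identity or with sinusoidal
wiggles (default amplitude 50 ^14^C yr, period 1000 yr, emulating
centennial-scale curve structure) — and lab errors are resampled from a
pool (default 30–100 ^14^C yr, the precision range typical of
late-Pleistocene assays).

What the generator does *not* emulate: spatial clustering of sites,
researcher submission bias, material-dependent error structure,
inter-laboratory offsets, and real curve features such as age reversals
at full strength (the generator flags a non-monotone curve but the
default wiggle keeps the curve monotone). Tests passing on synthetic data
therefore validate the *statistical machinery* — calibration, SPD
construction, breakpoint and rate recovery, envelope calibration, bust
detection — not the field-level robustness of any particular compilation.

## Problem sizes used in the test suite

The packaged experiments run at desk scale: type-I calibration uses 20
replicates of n = 100 dates at `nsim = 100`; bust recovery uses one run
of n = 100 dates at `nsim = 500` (a 60% bust over 12.9–12.0 ka is
recovered with onset within ±150 years); growth-rate recovery uses
n = 2000 dates, where the sampling standard error of the fitted log-slope
(~$r/\sqrt{n}$ for strongly tilted windows) is comfortably inside the 5%
check — at n = 100 the rate is simply not estimable to 5%, which is a
property of the estimand, not of the implementation.

## Known limitations

* SPD values on adjacent years are strongly autocorrelated (calibration
  spreads each date over decades-to-centuries and the smoother adds
  ±100 years). Correlations between SPDs are therefore reported with
  `n_years` but without an effective-sample-size adjustment, matching
  standard practice; treat the p-values as descriptive.
* The exponential null is fitted to the *smoothed* SPD; for strongly
  curved series the smoother's edge behaviour can leak into the fitted
  slope within ~100 years of the window edges. Fit windows inset from
  the edges avoid this.
* The breakpoint model assumes one growth-to-decline transition; series
  with a bust followed by recovery have no interior deviance optimum and
  fall back to the full-window null, which weakens (but in our
  experiments did not prevent) bust detection.
* `global_p` is computed from `nsim` simulations; with the +1 correction
  its smallest achievable value is `1/(nsim+1)`.
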