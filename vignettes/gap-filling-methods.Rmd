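---
title: "Forecast-based gap filling for RR-interval series: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecast-based gap filling for RR-interval series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvfill)
```

## The correction problem

An RR-interval series is the sequence of times between successive
heartbeats, in milliseconds. Motion artifacts during exercise corrupt runs
of intervals; once detected, the corrupted run is a *gap* to be refilled
before HRV metrics are computed. The quality of a filler is judged not by
how well it reproduces the individual intervals, but by how little it
distorts the downstream HRV summary metrics: RMSSD and SDNN in the time
domain, and the VLF/LF/HF band powers and their total TP in the frequency
domain. This package implements two forecasting fillers (ARIMA and kernel
SVR with chained prediction), four reference fillers (linear, cubic
spline, deletion, differenced Gaussian noise), the metric pipeline, the
evaluation protocol, and a hyperparameter grid search with the selection
criterion `argmin(LF_err + HF_err)`.

## The metric pipeline

**Time domain.** RMSSD is `sqrt(mean(diff(rr)^2))`; SDNN is the sample
standard deviation of the intervals with denominator `n − 1` (the
denominator is stated here because it changes the value at test-fixture
sizes and oracles must agree with it).

**Frequency domain.** The tachogram — interval length as a function of the
cumulative beat time — is irregularly sampled, so it is interpolated with
a cubic spline against beat time and evaluated on a uniform grid at
`fs = 4` Hz (the common choice in HRV work; any rate above twice the HF
upper edge of 0.4 Hz is accepted). The mean-removed resampled signal goes
through an FFT; the one-sided periodogram, in ms²/Hz, is integrated over
each band with the trapezoidal rule. Band edges are half-open `[lo, hi)`
— a bin at exactly 0.04 Hz counts as LF — and TP is computed literally as
`vlf + lf + hf` so that identity holds bit-exactly. No taper is applied by
default (the plain periodogram of the detrended signal); a Hann window is
available as an explicit option. Power is reported in absolute ms², with
no normalised units.

These defaults — interpolation order, resampling rate, windowing,
integrated density rather than summed bins — are genuinely open choices in
HRV practice; they are fixed here once, documented, and used identically
for the "truth" and "filled" sides of every comparison, so the *relative*
errors the package reports are insensitive to most of them.

## ARIMA filling

The model on the `d`-times differenced series is

`x_t = c + φ₁x_{t−1} + … + φ_p x_{t−p} + θ₁ε_{t−1} + … + θ_q ε_{t−q} + ε_t.`

`fit_arima()` estimates the coefficients by maximum likelihood
(`stats::arima`, CSS-ML with a fall-back to full ML when the CSS
initialisation lands in a non-stationary region) on exactly
`sequence_length` beats immediately preceding the gap. Conventions:

- the constant `c` is included only when `d = 0` (the usual
  identifiability convention; with differencing, a constant would encode a
  deterministic polynomial trend);
- forecasting iterates the recursion with future errors at their
  conditional mean of zero, then integrates back through the `d`
  undifferencing steps using the tail of the training window as seeds
  (`undifference()` is the exact inverse of `difference()`, and is tested
  as such);
- a window whose differenced values are exactly constant (e.g. a pure
  ramp with `d = 1`) has its ML optimum at zero innovation variance,
  which no numerical optimiser reaches; `fit_arima()` returns that limit
  model directly (constant = the differenced value, no AR/MA part);
- all other non-convergent or degenerate fits raise a classed error
  carrying the offending configuration — never a silent `NaN` — so grid
  searches can count and exclude them.

The in-package forecast recursion is cross-checked in the test suite
against `stats::predict.Arima` (a state-space implementation) on shared
fitted objects; the two agree to ~1e−7 relative, the residual difference
being their treatment of the pre-sample state.

The packaged preset is `ARIMA(2,0,2)` with sequence length 30: zero
differencing, MA order two and training windows of 15–30 beats are what
the hyperparameter search singles out, with the AR order mattering little;
within that range the preset fixes `p = 2` and the longer window.

## SVR filling with chained prediction

The ε-insensitive SVR fits `y(x) = Σᵢ (aᵢ⁺ − aᵢ⁻) K(x, xᵢ) + b` subject to
the dual box constraint `|aᵢ⁺ − aᵢ⁻| ≤ C`, penalising only deviations
beyond the margin ε. Four kernels are supported (linear, polynomial
`(γx·xᵢ + r)^β`, sigmoidal `tanh(γx·xᵢ + r)`, RBF `exp(−γ‖x−xᵢ‖²)`);
`kernel_eval()` exposes them directly, and the test suite verifies that
the stored dual expansion reproduces the solver's predictions for every
kernel. Fitting is delegated to `e1071::svm` (libsvm), with termination
tolerance 1e−3.

Procedural conventions, each fixed deliberately:

- **No input scaling by default.** Training uses the raw (differenced)
  values; `standardize = TRUE` is an explicit opt-in. Scaling interacts
  with ε, whose natural units here are milliseconds.
- **Lag rows are ordered oldest → newest.** Mathematically irrelevant for
  the kernels used, but fixed for reproducibility of stored models.
- **`n_train` counts lag rows** (input/target pairs), not raw beats; the
  history requirement before a gap is therefore
  `n_train + d + sequence_length` beats.
- **Chaining operates on the differenced scale.** Each one-step prediction
  is shifted into the input window; undifferencing happens once, after all
  `h` steps, not per step.
- **Degenerate fits are explicit.** When every target fits inside the
  ε-tube around a constant, the optimum has no support vectors; libsvm
  reports an "empty model", and `fit_svr()` returns the exact optimum
  instead: zero dual coefficients and `b` at the midrange of the targets.

The packaged preset is the linear kernel with `C = 1`, `ε = 0.01`,
`d = 0`, sequence length 5, trained on 200 rows: the search consistently
prefers the linear kernel and very short windows, with `C` nearly
irrelevant — chaining lets even a linear one-step map produce non-linear
multi-step trajectories.

## Reference fillers

Linear and cubic interpolation operate on the **beat index**, not on
time: once beats are missing, the true duration of the gap is unknown, so
an index axis is the only well-defined abscissa. This is the single
choice that most affects the cubic results. The cubic filler uses 10
context beats per side and Forsythe–Malcolm–Moler end conditions (exact
cubics through the four boundary points), so it reproduces cubic
polynomials of the index exactly — the natural-spline alternative with
zero second derivatives at the ends cannot, and would fail the
polynomial-exactness contract the tests enforce.

Deletion removes the gap beats; the series shortens, the cumulative time
axis contracts, and downstream metrics are computed on the shortened
window. This is the biggest interpretation choice for deletion and is
applied consistently.

The Gaussian filler estimates the standard deviation of the `d`-times
differenced pre-gap history (all of it by default; `d = 1` matches the
quasi-Gaussian distribution of successive RR differences), draws
increments from `Normal(0, sd)` — mean zero, because an empirical drift
term would double-count the trend — and integrates them from the last
pre-gap value. With `d = 0` the draws are used as raw values, a documented
degenerate case. The filler exists as a control: if it were competitive,
the differenced signal would be structureless and model-based correction
pointless.

## Evaluation protocol and grid search

The protocol takes the **last 250 beats** of a recording as the test
window (leaving everything earlier as training history), introduces a
10-beat gap at window position 121 (`middle_gap()` fixes the "centre of
the window" convention as `floor((250 − 10)/2) + 1` once and for all),
fills it, and reports `|corrected − true| / |true| × 100` per metric. A
zero true value with a zero corrected value counts as 0% (this happens
for degenerate constant series); a zero true value otherwise is flagged
`NA`, excluded from aggregation and countable.

`grid_search()` evaluates a configuration table (defaults reproduce the
full scopes: 525 ARIMA configurations from `p` 1–5 × `d` 0–2 × `q` 1–5 ×
7 sequence lengths; 12 432 SVR rows after collapsing kernel-irrelevant
axes — γ for linear, β and r where unused — so equivalent models are
fitted once), averages each metric's relative error across datasets
*first*, and then minimises mean LF + mean HF error. Ties break to the
earliest row in grid declaration order. Configurations that fail on any
dataset remain in the table with a failure count and are excluded from
the argmin; if every configuration fails, the search fails loudly.

## The synthetic generator

`generate_rr()` produces beat `k` (0-based) as

`rr_k = mean_rr + drift·k + A_LF sin(2π f_LF t_k) + A_HF sin(2π f_HF t_k) + N(0, σ)`

with `t_k` the running sum of the prior intervals. Oscillations are
functions of cumulative *time*, not beat index, so `f_LF` and `f_HF` are
true Hz on the metric module's frequency axis. Intervals are clipped at a
200 ms floor with a counted warning; the constructor rejects
configurations where `mean_rr − A_LF − A_HF − 5σ ≤ 0` outright. Two
presets are provided and are deliberately plausible rather than fitted:
`"rest"` (900 ms level, respiratory HF at 0.25 Hz, no drift) and
`"exercise"` (600 ms level, damped oscillations at 0.08/0.30 Hz, σ = 8 ms,
+0.05 ms/beat drift as in slow post-effort recovery). `generate_arma()`
supplies plain ARMA sequences (root-checked for stationarity and
invertibility, 500-sample burn-in) for estimator-recovery tests, and
`diff_moments()` verifies the quasi-Gaussian successive-difference claim
(|skewness| and |excess kurtosis| near zero at n = 5000).

**What the generator does and does not emulate.** It reproduces the level,
band-limited oscillatory content, drift and approximately Gaussian
beat-to-beat increments of exercise HRV. It does **not** reproduce the
serial correlation structure of real beat-to-beat noise: its noise term is
white. Two visible consequences, worth stating plainly:

- The SVR **training-size curve is flat** on synthetic data. With white
  increments, the learnable structure (sinusoids + level) is captured from
  roughly 50 lag rows, and the mean LF error at `n_train = 200` is not
  systematically below that at 50 (at 100-series replication the two
  differ by ~0.3 percentage points in either direction). On real
  recordings, where differenced RR series retain non-random structure,
  more training data demonstrably helps up to ~200 samples. A passing (or
  failing) flatness check on synthetic data therefore says nothing about
  real recordings.
- **Deletion scores deceptively well** on synthetic series. Removing 10 of
  250 beats shifts a stationary synthetic window's spectrum only mildly,
  whereas on real recordings deletion's time-axis contraction is among the
  worst correction choices. Comparisons on synthetic data are meaningful
  among the *filling* methods; deletion's rank should not be read off
  them.

The forecast-vs-interpolation ordering, by contrast, is robustly
reproduced: on 20 seeded exercise-like series, ARIMA, SVR and linear
interpolation each achieve lower mean LF+HF error than cubic
interpolation and than Gaussian-noise filling.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on generated data:
20 recordings of 1450 beats for the protocol comparisons, n = 1000 ARMA
sequences for coefficient recovery, 1000 random sequences for the
differencing round-trip, and a 6-configuration toy grid cross-checked
against a brute-force enumeration. These sizes make the whole suite run
in well under a minute while leaving the statistical assertions
comfortably inside their tolerances (coefficient recovery is asserted at
3 asymptotic standard errors). Every stochastic step is seeded;
`scripts/acceptance.R` derives all of its seeds from its `--seed`
argument and reproduces its JSON output bit for bit.

## Known limitations

- Artifact *detection* is out of scope: gaps are given, not found.
- No seasonal ARIMA, exogenous regressors, automatic order selection,
  Lomb–Scargle spectra, normalised band units or nonlinear HRV metrics.
- Interpolating fillers use the beat index; on data where gap duration is
  known from an external clock, a time-axis variant could differ.
- The synthetic generator's white-noise increments limit what protocol
  results on synthetic data imply for real recordings (see above).
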