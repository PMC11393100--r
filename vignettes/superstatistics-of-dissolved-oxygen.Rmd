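---
title: "Superstatistics of dissolved-oxygen fluctuations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superstatistics of dissolved-oxygen fluctuations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(superdo)
```

## The problem

High-frequency sondes in tidal rivers record dissolved oxygen (DO) every
15 minutes. The resulting series mix a slow, quasi-deterministic *trend* —
an annual cycle (summer-low, because warm water holds less oxygen and
respiration peaks), and a half-day cycle imposed by the tide — with fast,
strongly non-Gaussian *fluctuations* driven by the turbulent interplay of
physics, chemistry and biology. `superdo` provides the full analysis chain
for such records: sensor quality control, trend/fluctuation separation,
heavy-tailed distribution fitting, spatial comparison across sites, and
naive forecasting baselines against which any model must justify itself.

## Detrending: four variants

A series $y_t$ can be decomposed additively,
$y_t = T_t + F_t$, or multiplicatively, $y_t = \hat T_t \times \hat F_t$,
where any unexplained remainder is deliberately folded into the
fluctuation component — extreme events are part of what we want to
describe, not noise to be discarded. Two trend estimators are provided:

* **Seasonal**: a centered moving average with filtering frequency $f$
  (default 6 h). An even sample count uses the classical symmetric
  half-weighted window, so linear signals pass through unchanged and a
  tone of period exactly $f$ is annihilated. At the series ends the
  window shrinks to the valid range with renormalised weights; no data
  are fabricated by padding, at the price of extra variance in the first
  and last half-window.
* **EMD**: empirical mode decomposition by envelope sifting. IMFs are
  reported slow → fast; the $m$ fastest modes form the fluctuation and
  the rest, plus the residue, form the trend. Sifting uses cubic-spline
  envelopes with two mirrored extrema beyond each boundary, and stops
  when the Cauchy criterion ($SD < 0.2$) *and* the IMF
  extrema/zero-crossing property are both satisfied, with a 50-iteration
  cap.

Multiplicative detrending is defined as the exponential of additive
detrending of $\log y_t$ for **both** estimators. This makes the
reconstruction $y = \hat T \hat F$ exact, guarantees the identity
`multiplicative(y) == exp(additive(log y))` that the test suite asserts,
and requires strictly positive inputs (DO after QC is positive).

The residue goes to the trend by default, so fluctuations are centered
near 0 (additive) or 1 (multiplicative). The literal alternative —
residue kept with the fluctuation — is available via
`residue_to = "fluctuation"`, but it leaves the slowest component of the
signal inside the "fast" part and produces off-centre fluctuation
distributions, which is why it is not the default.

### Choosing the number of dropped modes

The cut between "trend modes" and "fluctuation modes" is a per-site
choice. A fixed $m = 3$ is the conventional default, but which IMF
carries the 12-h tidal oscillation depends on the noise level and the
seed (mode mixing), and accidentally dropping the tidal mode into the
fluctuation changes the fitted distribution qualitatively. We therefore
recommend — and use throughout our own analyses —
`m_dropped = "auto"`: drop exactly those IMFs whose dominant periodogram
period is shorter than a cutoff (default 6 h, matching the seasonal
filter frequency $f$), so the four detrending variants separate trend
from fluctuation at the same time scale and are comparable.

Note what a moving average can and cannot do: a 6-h window passes only a
fraction $2/\pi \approx 0.64$ of a 12-h tone into the trend, so with
seasonal detrending at $f = 6$ h roughly a third of the tidal amplitude
remains in the fluctuation. That is a property of the estimator, not a
bug; the EMD variants do not share it, which is one reason they fit the
fluctuation distribution better on tide-dominated series.

## q-Gaussian fluctuations and superstatistics

Detrended DO fluctuations are heavy-tailed. The package models them with
the q-Gaussian (Tsallis) density
$$p(x) = \frac{1}{C_q}\left[1 + (q-1)\beta (x-\mu)^2\right]^{\frac{1}{1-q}},$$
normalizable for $1 \le q < 3$, Gaussian at $q = 1$, with power-law
tails of exponent $2/(q-1)$ and a second moment $1/(\beta(5-3q))$ that
diverges for $q \ge 5/3$. The superstatistical rationale: locally the
fluctuations are Gaussian with an inverse variance $\hat\beta$ that
itself fluctuates slowly; when $\hat\beta$ follows a $\chi^2$ law with
$n$ degrees of freedom and mean $\hat\beta_0$, the marginal is exactly a
q-Gaussian with $q = 1 + 2/(n+1)$ and scale
$\beta = \hat\beta_0 (n+1)/(2n)$. `simulate_chi2_superposition()`
reproduces this construction and the tests verify both the quadrature
identity and the end-to-end recovery of $q$ from simulated mixtures.

### Maximum likelihood

The $(q, \beta)$ likelihood surface is ridge-shaped, so
`fit_qgauss_mle()` profiles $(\log\beta, \mu)$ by Nelder–Mead on a grid
of $q$ (started from moment- and quantile-based scales) and polishes the
best point with bounded L-BFGS-B. The box is
$q \in [1+10^{-6}, 3-10^{-3}]$, $\beta \in [10^{-12}, 10^{12}]$; a
solution pinned to the box reports `converged = FALSE`. $\mu$ is fitted,
not fixed, even though samples are centered first (additive: subtract
the mean; multiplicative: divide by the mean and subtract one).

### Comparing detrending variants

`compare_detrending_loglik()` fits each variant's own centered
fluctuation sample and ranks by mean per-observation log-likelihood, the
procedure used to select a detrending method in practice. Two caveats
are built into the output rather than hidden:

* per-observation means make variants with different trimming
  comparable;
* additive and multiplicative variants fit *differently scaled* samples
  — a dimensionless ratio fluctuation is narrower than its mg/L
  counterpart by about the trend level, inflating its own-sample
  likelihood by roughly $\log \hat T$ per point regardless of fit
  quality. The `mean_loglik_orig` column adds the change-of-variables
  Jacobian back, giving a likelihood on the original data scale on which
  the two modes can be compared fairly. The ranking column remains the
  own-sample one; treat it as a model-selection heuristic, not a formal
  likelihood-ratio test.

## Spatial trends

`fit_sites_qgauss()` + `fit_distance_trend()` regress a fitted parameter
($\beta$ or $q$) on distance-to-sea by ordinary least squares, per
detrending variant, reporting the Pearson correlation and a seeded
permutation p-value (10^4 permutations by default) — the trend drawn
through a nine-site scatter should carry its own significance check.

## Forecast baselines

`build_features()` emits exactly fourteen covariates: the seven measured
channels; hour-of-day, day-of-week, month-of-year affinely encoded into
$[-0.5, 0.5]$ (`hour/23 - 0.5`, `weekday/6 - 0.5`, `(month-1)/11 - 0.5`);
and sine/cosine of the half-day and year phases. The two periodic
encodings correspond to the dominant periodogram peaks of tidal DO
(near 1/year and 1/half-day), which `fft_dominant_frequencies()`
verifies.

`make_windows()` splits chronologically (default 70/20/10), computes
normalisation statistics from training rows only, and enumerates windows
that never cross a split boundary or a sampling gap. Three baselines are
provided:

* **Last** — persistence of the final observed DO;
* **Repeat** — copies the 48-step block ending half a day before the
  forecast origin, i.e. $\hat y_j = y_{o-96+j}$: the forecast repeats
  the initial steps of the *previous* half-day, equivalently the values
  exactly one day earlier. Any day-periodic signal is forecast exactly
  and the error distribution is identical at every horizon. (The
  alternative alignment, copying the block that ends at the origin, is
  `offset = 0`; note that alternative makes Repeat coincide with Last at
  horizon 48 by construction.)
* **Linear** — least-squares affine map from the final input step's
  fourteen normalised covariates to the horizon vector, with a tiny
  ridge fallback ($10^{-8}$ of the mean Gram diagonal) for rank-deficient
  designs.

`evaluate_forecast()` reports, per horizon $t$,
$MAE_t = \frac1n\sum_i |y_{i,t} - \hat y_{i,t}|$ and
$SMAPE_t = \frac{100}{n}\sum_i \frac{|y_{i,t} - \hat y_{i,t}|}{|y_{i,t}| + |\hat y_{i,t}|}$
— note the denominator $|y| + |\hat y|$ with *no* factor 2, so SMAPE is
bounded by 100 % for positive series; a 0/0 term counts as exact
agreement. Metrics are computed on the raw DO scale (mg/L), which keeps
MAE interpretable.

On a half-day-periodic series with a daily asymmetry — the realistic
case, where photosynthesis superimposes a 24-h shape on the 12-h tide —
Repeat beats Last and Linear at multi-step horizons, because it is the
only baseline that exploits the periodicity. On an *exactly* 12-h
periodic signal Last becomes equivalent to Repeat at horizon 48 (both
copy a value one tidal period back), which is why the packaged fixture
for this property carries both periods.

## The synthetic generator

`generate_site()` emulates what the analysis assumes about tidal-river
DO, so every stage is testable without proprietary telemetry data:

$$DO(t) = \hat T(t)\,e^{\sigma z_t},\qquad
\hat T(t) = b + A_{yr}\cos\!\big(2\pi\tfrac{doy-15}{365.25}\big)
          + A_{tide}\cos\!\big(2\pi\tfrac{t \bmod 12\,h}{12\,h}\big),$$

with $z_t$ a $\chi^2$-superstatistical Gaussian mixture. Defaults:
baseline $b = 9$ mg/L, annual amplitude 2 mg/L (winter-high — typical
temperate-river seasonality), tidal amplitude 1 mg/L, $\sigma = 0.04$
(4 % multiplicative fluctuations), mixture $n = 3$, $\hat\beta_0 = 1$,
window length 50 samples (a 12.5-h superstatistical time scale). These
are plausible magnitudes for a lowland tidal river; none is estimated
from data. Because the noise enters as the exponential of a
superstatistical mixture, multiplicative EMD detrending is the correctly
specified analysis — deliberately so, as the generator's job is to make
the pipeline's target structure recoverable. An `additive_noise` switch
provides the misspecified control.

Companion channels (temperature anticorrelated with DO annually, pH with
a diel component, conductivity, ammonium, turbidity, daily rainfall) are
coupled sinusoids plus noise. They exercise QC and feature building; they
are not a river-chemistry model, and passing tests on them says nothing
about real covariate dynamics.

`generate_multisite()` builds an ensemble whose fitted $\beta$ varies
linearly with distance to sea by inverting the mixture-scale relation:
$\sigma(d) = \sqrt{\hat\beta_0 (n+1) / (2n\,\beta(d))}$. Per-site seeds
derive from the base seed.

### What the generator does not emulate

No reaeration/metabolism dynamics, no rainfall–runoff coupling, no
sensor drift or fouling, no gaps (QC-related behaviour is tested with
constructed outages), and the tidal period is exactly 12 h rather than
the lunar 12.42 h. Tests passing on this generator demonstrate internal
consistency of the pipeline, not validity of any ecological conclusion
about a particular river.

## Numerical choices and problem sizes

* Sampling uses the Student-t representation
  ($\nu = (3-q)/(q-1)$, scale $1/\sqrt{(3-q)\beta}$); the density code
  never relies on it, so sampler and density cross-check each other.
* Quadrature oracles (`stats::integrate`) back every closed form:
  normalisation constant, variance, and the $\chi^2$-mixture marginal.
* Degenerate inputs fail loudly: constant samples (unbounded $\beta$),
  non-positive values under multiplicative modes, monotone signals in
  EMD ($N = 0$), all-equal distances in the spatial regression.
* Self-contained checks run at deliberately modest sizes — 45–60
  synthetic days per site for end-to-end fits (about $10^2$
  superstatistical windows per series, enough for a stable variant
  ranking), $2\times10^5$ samples for mixture-identity checks, $10^5$
  for parameter-recovery grids — sizes at which the MLE's sampling error
  is comfortably inside the asserted tolerances.

## Known limitations

* The EMD implementation is the classical single-realisation sift; no
  ensemble variants, so mode mixing under heavy noise is handled by the
  `"auto"` cut rather than by noise-assisted decomposition.
* Own-sample likelihood ranking between modes is a heuristic (see
  above); use `mean_loglik_orig` when the additive/multiplicative choice
  itself is the question.
* The moving-average boundary policy (shrinking windows) inflates
  fluctuation variance within half a window of the series ends; trim
  accordingly before distribution fitting on short series.
* SMAPE with the $|y|+|\hat y|$ denominator is scale-free only for
  series bounded away from zero; DO after QC satisfies this.
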