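# superdo

Superstatistical analysis of dissolved-oxygen (DO) sensor time series
from tidal rivers.

High-frequency water-quality sondes record DO every 15 minutes. The
records combine slow structure — an annual cycle (summer-low) and a
half-day tidal cycle — with fast, heavy-tailed fluctuations. `superdo`
is for limnologists and environmental data scientists who want to

* clean raw sonde records (implausible DO, non-positive readings, unit
  conversions, exclusion episodes),
* separate trend from fluctuations by four variants — additive or
  multiplicative mode × seasonal moving-average or empirical mode
  decomposition (EMD) —,
* fit the fluctuations with q-Gaussian (Tsallis) distributions by
  maximum likelihood and select the detrending variant by
  log-likelihood,
* relate the fitted scale parameter β and entropic index q to each
  site's distance to the sea,
* benchmark forecasts with the Last / Repeat / Linear baselines under
  per-horizon MAE and SMAPE.

## The model

Fluctuations are obtained from `y = T + F` (additive) or `y = T̂ × F̂`
(multiplicative, computed as the exponential of additive detrending of
`log y`). Their distribution is modelled by the q-Gaussian density

    p(x) = C_q^{-1} [1 + (q−1) β (x−µ)²]^{1/(1−q)},

the Gaussian at q = 1, normalizable for q < 3, with power-law tails of
exponent 2/(q−1) and infinite variance for q ≥ 5/3. The superstatistical
origin: locally Gaussian fluctuations whose inverse variance β̂ follows
a χ² law with n degrees of freedom yield exactly this marginal with
q = 1 + 2/(n+1). Forecast errors use

    MAE_t   = (1/n) Σ |y_t − ŷ_t|
    SMAPE_t = (100/n) Σ |y_t − ŷ_t| / (|y_t| + |ŷ_t|)   [percent]

(denominator |y| + |ŷ|, no factor 2). All stochastic steps take explicit
seeds. A built-in generator (`generate_site()`, `generate_multisite()`)
emulates tidal-river DO with χ²-superstatistical multiplicative noise,
so the entire pipeline is testable without proprietary telemetry data.

## Worked example

```r
library(superdo)

site <- generate_site(synthetic_config(n_days = 60, seed = 1))
cmp <- compare_detrending_loglik(site$do_mgl, m_dropped = "auto")
cmp[, c("variant", "q", "beta", "mean_loglik", "converged")]
#>                   variant     q    beta mean_loglik converged
#> 1      multiplicative-emd 1.467 342.715       1.391      TRUE
#> 2 multiplicative-seasonal 1.429 261.351       1.302      TRUE
#> 3            additive-emd 1.478   2.974      -0.997      TRUE
#> 4       additive-seasonal 1.437   2.237      -1.088      TRUE
```

Multiplicative EMD detrending gives the best q-Gaussian fit to the
fluctuations (highest mean log-likelihood per observation), and the
fitted q ≈ 1.47 is close to 1 + 2/(n+1) = 1.5 implied by the generator's
n = 3 mixture — the heavy tails are recovered, not assumed. The β
values of the two modes differ by orders of magnitude because additive
fluctuations are in mg/L while multiplicative ones are dimensionless
ratios; see the vignette on comparing across modes.

```r
glance(cmp$fit[[1]])
#> # A tibble: 1 × 8
#>       q  beta       mu logLik mean_logLik variance  nobs converged
#> 1  1.47  343. -0.00260  8011.        1.39  0.00486  5760 TRUE
```

A nine-site ensemble with β decreasing seaward-to-inland reversed
(slope −0.5 per km) is recovered by the spatial regression:

```r
base  <- synthetic_config(n_days = 45, seed = 11)
sites <- generate_multisite(base, seq(5, 45, by = 5),
                            beta_slope = -0.5, beta_intercept = 40)
rec <- fit_sites_qgauss(sites, m_dropped = "auto")
fit_distance_trend(rec, "beta")
#> Distance trend of beta: slope = -0.3901 (SE 0.0797) per km, r = -0.880,
#>   permutation p = 0.003 (n = 9)
```

Forecast baselines with per-horizon metrics:

```r
ds <- make_windows(build_features(site), input_len = 144, horizon = 48,
                   seed = 1)
evaluate_baselines(ds, horizons = c(1, 12, 24, 48))
#> # A tibble: 12 × 5   (model, horizon, mae [mg/L], smape [%], n)
#> 1 last         1 0.749  3.55   386
#> ...
#> 9 linear       1 0.528  2.50   386
```

On this smooth synthetic series the Linear baseline wins (its phase
covariates encode the tide); on day-asymmetric periodic DO the Repeat
baseline dominates at multi-step horizons — see the test suite and
vignette.

Plot helpers: `autoplot()` on decompositions, q-Gaussian fits and
distance trends; `plot_forecast_errors()` on metric tables. Tidiers:
`tidy()` / `glance()` on fits and trends.

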