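---
title: "Modelling crop-yield dynamics with R-functions, external perturbations and multi-model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling crop-yield dynamics with R-functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropdyn)
```

## The model

`cropdyn` treats an annual crop-yield series the way population
ecology treats an abundance series. Let $Y_t$ be the detrended
natural-log yield at harvest $t$ (one step = one harvest of the focal
crop; in a three-crop rotation successive harvests are three calendar
years apart), and let

$$R_t = Y_t - Y_{t-1}$$

be the *rate of yield increase*. The core model is the exponential
(Ricker-type) R-function

$$R_t = r_{\max} - \exp(a\,Y_{t-d} + c),$$

where $r_{\max}$ is the maximum rate of increase, $c$ measures the
supply/demand balance of limiting resources and $a$ is the shape of
the nonlinear feedback. The map $Y_t = Y_{t-1} + R_t$ has a nontrivial
equilibrium — the *yield potential* —

$$K = \frac{\log r_{\max} - c}{a},$$

and the local slope of the R-function at $K$ is $r_{\max}\,a$ in
magnitude. Because the map is first order, its eigenvalue is
$\lambda = 1 - |dR/dY|_K$: a slope in $(0,1)$ gives monotonic damped
approach to $K$, in $(1,2)$ oscillatory damped approach, and above 2
instability.

An external factor $Z$ (weed-community diversity, growing-season
climate) can perturb each parameter, giving three covariate families
with $x = \log Z$:

* **lateral (L)** — through $c$:
  $R_t = r_{\max} - \exp(aY_{t-d} + c + b\,x)$, translating the curve
  sideways; $K$ moves, the stability slope $r_{\max} a$ does not.
* **vertical (V)** — additively through $r_{\max}$:
  $R_t = r_{\max} - \exp(aY_{t-d} + c) + b\,x$; both $K$ and the slope
  $a(r_{\max} + b\,x)$ respond.
* **nonlinear (N)** — through $a$:
  $R_t = r_{\max} - \exp((a + b\,x)Y_{t-d} + c)$, reshaping the curve;
  slope $(a + b\,x)\,r_{\max}$.

Interaction covariates enter as the ratio $Z_1/Z_2$ formed before the
transform. When a ratio can be non-positive (e.g. a temperature ratio
involving freezing minima), the log transform is refused and the
identity transform must be requested explicitly; we never apply silent
offsets.

$r_{\max}$ is deliberately **not** a free parameter: it is fixed at
the maximum observed $R_t$ of the series being modelled. This keeps it
identical across all candidate models for a crop and removes one
direction of confounding from the nonlinear fit.

## Preprocessing

Log yields are detrended by ordinary least squares on calendar year
and year squared, pooled across treatments and replicates per crop (a
per-treatment option exists). The detrended level is the residual plus
the per-crop grand mean, so $Y_t$ keeps the log(kg/ha) scale and $c$
and $K$ remain interpretable in yield units. Rates are first
differences within a block and never cross block boundaries.

Growing-season climate summaries use the daily mean
$(t_{\min}+t_{\max})/2$ and report season means (`tM`, `tmax`,
`tmin`), extremes (`tMax`, `tMin`) and precipitation (`precM`,
`precMax`) over fixed planting–harvest windows (maize: early May to
late September; soybean: late May to early October).

## Feedback diagnosis

The order $d$ of the internal feedback is diagnosed with the partial
rate correlation function: PRCF(1) is the correlation of $R_t$ with
$Y_{t-1}$, and PRCF($i$) for $i>1$ is the partial correlation of $R_t$
with $Y_{t-i}$ given the intermediate lags, computed by correlating
the residuals of the two regressions on the conditioning set. Lagged
pairs are pooled across blocks without crossing block boundaries, and
a $\pm 2/\sqrt{n}$ band (with the per-lag number of usable pairs)
flags meaningful structure. A dominant negative PRCF(1) motivates the
first-order models used throughout.

```{r}
p <- rf_params(1.20, 0.93, -7.91)
equilibrium(model_spec("P"), p)          # yield potential, log(kg/ha)
stability_slope(model_spec("P"), p)
```

## Fitting and model selection

Each candidate is fitted by nonlinear least squares
(Levenberg–Marquardt) on the assembled frame of
$(R_t, Y_{t-d}, x_{t-d'})$ rows. Exponential-family NLS is sensitive
to initial values, so every fit runs a small multi-start grid —
$a_0 \in \{0.1, 0.5, 1, 2\}$, $c_0$ solving the pure-model equilibrium
at the sample mean of $Y_{t-d}$ for each $a_0$, and
$b_0 \in \{-0.5, 0, 0.5\}$ — and keeps the converged start with the
lowest residual sum of squares. Convergence tolerances are $10^{-10}$
on cost and parameters with at most 200 iterations per start; a model
for which no start converges is returned as a flagged failure record
and excluded from ranking with a warning, rather than raising an
error.

Candidates are compared with the small-sample corrected information
criterion under a Gaussian likelihood,

$$\mathrm{AICc} = n \log(RSS/n) + 2p' + \frac{2p'(p'+1)}{n-p'-1},
  \qquad p' = p_{\text{free}} + 1,$$

where the error variance counts as an estimated parameter. Akaike
weights $w_i \propto \exp(-\Delta_i/2)$ give each model's probability
of being best in the set, and the 99% confidence set is the shortest
weight-sorted prefix summing to the level. Ties in AICc are broken by
fewer parameters, then lexicographic spec id. Fit quality is reported
as the deviance-based pseudo-$R^2$, which for Gaussian errors is
$1 - RSS/TSS$. Note that absolute AICc magnitudes depend on constants
conventions; $\Delta$AICc and the weights are the comparable
quantities across software.

## Weed-community analysis

Diversity per sample uses biomass shares $p_i$: richness $S$, Shannon
$H=-\sum p_i \log p_i$ (natural log), Simpson $D = 1-\sum p_i^2$,
inverse Simpson $1/\sum p_i^2$, Pielou's $J = H/\log S$ (defined as 0
for a monoculture, where the denominator vanishes) and
$E = e^H/S$. Species whose occupancy does not exceed 5% of samples
are removed before screening; we read the rarity rule as an
occupancy criterion (present in at most that share of samples), the
standard dataset-level screen, and expose the threshold. The
correlation screen reports Pearson $r$ between each index and each
Hellinger-transformed species profile
($y'_{ij} = \sqrt{y_{ij}/\sum_j y_{ij}}$, unit sum of squares per
sample) when $|r| > 0.4$; no p-values are attached because the indices
are computed from the same species data.

Whether diversity covariates enter the yield models block-specific or
averaged per year across replicates is exposed as an option;
block-specific is the default, preserving replicate-level variation.

## The synthetic-data generator

Because the motivating long-term experiment's tables cannot be
redistributed here, the package generates datasets with the same
schema and known ground truth: yields per year × treatment ×
replicate, daily climate with seasonal sinusoidal structure, and
per-sample weed communities from an eight-species pool. The generator
iterates $Y_t = Y_{t-1} + R(Y_{t-1}, Z_t) + \varepsilon_t$ from the
chosen form. Design choices worth knowing:

* $\varepsilon_t$ is additive Gaussian on the rate scale, matching the
  least-squares error model; `noise_sd` defaults to 0.05.
* The covariate generator is lognormal for diversity-like factors —
  defaults `meanlog = -0.40`, `sdlog = 0.55`, matching the reported
  growing-season Shannon summary of the study system (mean 0.78,
  sd 0.46, by moment matching) — and Gaussian for temperature-like
  factors which may be negative.
* Yields are produced on the natural-log scale and exponentiated; an
  optional quadratic calendar-year trend is injected so the detrending
  stage has real work. Because OLS detrending is linear and the
  injected trend lies in the span of the trend basis, recovered rates
  are identical with and without the trend — a property the tests
  exploit.
* Weed communities are constructed so each sample's Shannon effective
  species number tracks the covariate value that drove the yields
  (geometric-series abundances with a decay ratio solved by
  root-finding), which keeps the dataset internally consistent.
* Every random draw flows from one integer seed; identical configs
  give bitwise-identical datasets, and $b=0$ collapses the L/V/N
  generators onto the pure one exactly.

What the generator does *not* emulate: spatial correlation among
blocks, treatment-specific management effects, weather
quality-control artefacts, and crop-rotation interactions beyond the
3-year harvest spacing. Passing tests on synthetic data therefore
demonstrate the estimators' correctness and power under the stated
noise model, not robustness to every feature of field data.

## Numerical choices and edge cases

* Closed-form equilibria and slopes are verified against numeric
  root-finding and central differences (at $10^{-8}$ in the test
  suite); `equilibrium()` re-checks its closed form against `uniroot`
  at each call unless disabled.
* The vertical form has no positive equilibrium when
  $r_{\max} + b\log Z \le 0$, and the nonlinear form degenerates when
  $a + b\log Z = 0$; both raise informative errors.
* Regime boundaries are half-open: slope exactly 1 classifies as
  oscillatory damped, exactly 2 as unstable.
* Problem sizes in the test suite: parameter recovery uses single
  500-cycle series; the model-identification study uses 100 replicates
  of 6 blocks × 60 cycles per generating form; oracle agreement uses
  1000 random parameter draws.

## Known limitations

Only first-order feedback ($d \le 2$ in frames, $d=1$ by default) is
modelled; delayed (second-order) R-functions, bootstrap or profile
confidence intervals, and mixed-effects block terms are out of scope.
Distinguishing lateral from nonlinear perturbations is intrinsically
hard when yields hover near equilibrium: the terms $b\,x$ and
$b\,x\,Y$ are nearly collinear until $Y$ varies appreciably, so
identification rates for the lateral form are the lowest of the three
families under the default simulation conditions. Growing-degree-day
climate summaries and weather gap-filling are not provided.
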