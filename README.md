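# cropdyn

Population-dynamics analysis of annual crop-yield time series.

Long-term cropping experiments produce block-replicated yield series in
which year-to-year fluctuations carry information about both internal
regulation (resource supply and demand feedbacks) and external
perturbations (weed-community diversity, growing-season climate).
`cropdyn` analyses such series the way population ecologists analyse
abundance series: the detrended log-yield level `Y_t` and its rate of
increase `R_t = Y_t − Y_{t−1}` are modelled with the exponential
(Ricker-type) R-function

    R_t = r_max − exp(a·Y_{t−d} + c)

with `r_max` fixed at the maximum observed rate. An external factor `Z`
can perturb each parameter, giving three candidate families (with
`x = log Z`):

| form | model | perturbs |
|------|-------|----------|
| L (lateral) | `R_t = r_max − exp(aY + c + b·x)` | `c` — shifts the curve sideways |
| V (vertical) | `R_t = r_max − exp(aY + c) + b·x` | `r_max` — additive effect |
| N (nonlinear) | `R_t = r_max − exp((a + b·x)Y + c)` | `a` — reshapes the feedback |

The package covers the full workflow: a synthetic-data generator with
known ground truth (yields, daily climate, weed communities in the
schema of a long-term rotation experiment), quadratic detrending of log
yields, growing-season climate summaries, weed diversity indices with
Hellinger transformation / rare-species filtering / correlation
screening, PRCF feedback diagnosis, nonlinear least-squares fitting of
all candidates, AICc ranking with Akaike weights and 99% confidence
sets, and equilibrium ("yield potential" `K`) and stability analysis of
the fitted first-order map.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
generated dataset (six blocks, ten harvests, vertical weed-diversity
effect with `a = 0.9`, `c = −7.9`, `b = 0.3`, rate noise sd 0.05):

```sh
Rscript analysis/01_simulate.R   # writes results/data/{yields,weeds,climate}.csv + truth.json
Rscript analysis/02_prep.R       # detrend, rates, climate summaries
Rscript analysis/03_diversity.R  # indices, rare filter, correlation screen
Rscript analysis/04_prcf.R       # feedback diagnosis
Rscript analysis/05_fit_select.R # fit all candidates, AICc selection
Rscript analysis/06_stability.R  # equilibria, slopes, regimes
```

Stage 4 prints the feedback diagnosis:

```
  lag        prcf  n      band
1   1 -0.61101388 54 0.2721655
2   2 -0.11325868 48 0.2886751
...
First-order negative feedback detected: fit first-order R-function models (d = 1).
```

PRCF(1) = −0.61 is far outside the ±2/√n band: the rate of increase
responds negatively to the previous harvest's level, the stabilising
feedback the R-function captures. Stage 5 then ranks the candidates:

```
   fit   variable     a      c       b AICc dAICc        w    R2 conf_set
1    V    shannon 2.597 -23.89  0.3676 -311   0.0 9.97e-01 0.963     TRUE
2    V invsimpson 0.938  -8.32  0.6507 -298  12.9 1.57e-03 0.953    FALSE
...
10   P            1.664 -15.10      NA -164 146.6 1.47e-32 0.421    FALSE

Best model: V (shannon) with Akaike weight 1
Generating form was: V with covariate shannon
```

The vertical Shannon model wins decisively (Akaike weight ≈ 1,
pseudo-R² 0.96 against 0.42 for the pure model) — the selection
recovers the generating structure. Stage 6 reports `K ≈ 8.78`
log(kg/ha) (≈ 6500 kg/ha) with slope magnitude 0.88 < 1: a monotonic
damped approach to the yield potential. For the vertical model the
partial effect of diversity is `∂R/∂Z = b/Z`, a hyperbola — each unit
of diversity adds less than the one before, so yield risk concentrates
in the least diverse communities.

Equivalent single-call orchestration:

```r
library(cropdyn)
cfg <- synthetic_config(form = "V", r_max = 1.0, a = 0.9, c = -7.9,
                        b = 0.3, n_blocks = 6, n_cycles = 10, seed = 1)
run <- run_pipeline(run_config(cfg, crop = "maize",
                               covariates = "shannon", seed = 1))
run$selection
run$stability
```

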