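mk_yields <- function(logy, years, reps = 1L, crop = "maize") {
  g <- expand.grid(replicate = seq_len(reps), year = years)
  data.frame(year = g$year, crop = crop, treatment = "T1",
             replicate = g$replicate,
             yield_kg_ha = exp(rep(logy, each = reps)))
}

test_that("a perfect quadratic trend detrends to the grand mean", {
  years <- 1996 + 0:5 * 3
  t <- seq_along(years)
  logy <- 7 + 0.1 * t + 0.01 * t^2
  out <- detrend_quadratic(mk_yields(logy, years))
  expect_equal(out$Y, rep(mean(logy), length(years)), tolerance = 1e-8)
})

test_that("detrended residuals are orthogonal to the trend basis", {
  set.seed(21)
  years <- 1996 + 0:7 * 3
  out <- detrend_quadratic(mk_yields(rnorm(8, 8, 0.4), years, reps = 3))
  res <- out$Y - mean(out$Y)
  expect_lt(abs(cor(res, out$year)), 1e-10)
  expect_lt(abs(cor(res, out$year^2)), 1e-10)
})

test_that("an injected trend is recovered by the pooled quadratic fit", {
  cfg <- synthetic_config(form = "P", noise_sd = 0.02, n_blocks = 6,
                          n_cycles = 8, trend = c(0.03, 0.002), seed = 13)
  ds <- generate_dataset(cfg)
  yr_c <- ds$yields$year - mean(unique(ds$yields$year))
  fit_with <- lm(log(yield_kg_ha) ~ yr_c + I(yr_c^2), data = ds$yields)
  cfg0 <- cfg; cfg0$trend <- c(0, 0)
  ds0 <- generate_dataset(cfg0)
  fit_without <- lm(log(yield_kg_ha) ~ yr_c + I(yr_c^2), data = ds0$yields)
  # injected coefficients = difference of the two fits, exactly (OLS linearity)
  expect_equal(unname(coef(fit_with) - coef(fit_without))[2:3],
               c(0.03, 0.002), tolerance = 1e-8)
})

test_that("detrending validates its preconditions", {
  expect_error(detrend_quadratic(mk_yields(c(7, 8, 7.5), 2000:2002)),
               ">= 4 distinct")
  y <- mk_yields(c(7, 8, 7.5, 7.2), 2000:2003)
  y$yield_kg_ha[2] <- 0
  expect_error(detrend_quadratic(y), "non-positive")
})

test_that("rates difference within blocks only", {
  lev <- data.frame(crop = "m", treatment = "T1",
                    replicate = rep(1:2, each = 3),
                    t = rep(1:3, 2),
                    Y = c(7.0, 7.5, 7.2, 6.0, 6.4, 6.1))
  r <- rate_of_increase(lev)
  expect_equal(nrow(r), 4)
  expect_equal(r$R[r$replicate == 1], c(0.5, -0.3), tolerance = 1e-12)
  expect_equal(r$R[r$replicate == 2], c(0.4, -0.3), tolerance = 1e-12)

  const <- data.frame(crop = "m", treatment = "T1", replicate = 1,
                      t = 1:6, Y = 8)
  expect_equal(rate_of_increase(const)$R, rep(0, 5))

  single <- rbind(lev, data.frame(crop = "m", treatment = "T1",
                                  replicate = 3, t = 1, Y = 7))
  expect_warning(r2 <- rate_of_increase(single), "single cycle")
  expect_equal(nrow(r2), 4)
})

test_that("detrend-then-difference equals difference of detrended values", {
  set.seed(5)
  years <- 2000 + 0:9
  out <- detrend_quadratic(mk_yields(rnorm(10, 8, 0.5), years))
  r <- rate_of_increase(out)
  expect_equal(r$R, diff(out$Y[order(out$t)]), tolerance = 1e-12)
})

test_that("growing-season summaries match direct arithmetic", {
  clim <- data.frame(date = c("2000-06-01", "2000-06-02", "2000-06-03"),
                     precip_mm = c(0, 5, 1),
                     tmin_c = c(10, 12, 8), tmax_c = c(20, 30, 25))
  w <- data.frame(crop = "maize", year = 2000,
                  start = "2000-06-01", end = "2000-06-03")
  s <- growing_season_summary(clim, w)
  expect_equal(s$tM, 17.5)
  expect_equal(s$tmax, 25)
  expect_equal(s$tmin, 10)
  expect_equal(s$tMax, 30)
  expect_equal(s$tMin, 8)
  expect_equal(s$precM, 2)
  expect_equal(s$precMax, 5)

  # one-day window: means equal that day's values
  w1 <- transform(w, end = "2000-06-01")
  s1 <- growing_season_summary(clim, w1)
  expect_equal(s1$tM, 15); expect_equal(s1$tMin, 10); expect_equal(s1$tMax, 20)

  # missing days are reported
  w2 <- transform(w, end = "2000-06-05")
  expect_error(growing_season_summary(clim, w2), "2000-06-04")
})

test_that("summary ordering invariants hold on random daily inputs", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    dates <- seq(as.Date("2001-05-01"), by = "day", length.out = n)
    tmin <- rnorm(n, 10, 4); tmax <- tmin + rexp(n, 1 / 8)
    clim <- data.frame(date = format(dates), precip_mm = rexp(n, 1 / 3),
                       tmin_c = tmin, tmax_c = tmax)
    w <- data.frame(crop = "x", year = 2001, start = dates[1],
                    end = dates[n])
    s <- growing_season_summary(clim, w)
    expect_true(s$tMin <= s$tmin && s$tmin <= s$tM &&
                  s$tM <= s$tmax && s$tmax <= s$tMax)
    expect_true(s$precMax >= s$precM && s$precM >= 0)
  }
})

test_that("frame assembly aligns lags and counts rows exactly", {
  lev <- data.frame(crop = "m", treatment = "T1", replicate = 1, t = 1:6,
                    Y = c(7, 7.5, 7.2, 7.4, 7.1, 7.3))
  rates <- rate_of_increase(lev)
  covs <- data.frame(t = 1:6, z = c(1, 2, 3, 4, 5, 6))
  fr <- assemble_frame(rates, lev, covs, d = 1, dprime = 0)
  expect_equal(nrow(fr), 5)
  expect_equal(fr$Y_lag, lev$Y[1:5], tolerance = 1e-12)
  expect_equal(fr$z, log(covs$z[2:6]), tolerance = 1e-12)

  fr2 <- assemble_frame(rates, lev, covs, d = 1, dprime = 1)
  expect_equal(nrow(fr2), 5)
  expect_equal(fr2$z, log(covs$z[1:5]), tolerance = 1e-12)

  fr3 <- assemble_frame(rates, lev, covs, d = 2, dprime = 0)
  expect_equal(nrow(fr3), 4)
})

test_that("frame row counts follow block lengths and lags on random inputs", {
  set.seed(14)
  for (i in 1:10) {
    lens <- sample(3:9, 3, replace = TRUE)
    lev <- do.call(rbind, lapply(seq_along(lens), function(b)
      data.frame(crop = "m", treatment = "T1", replicate = b,
                 t = seq_len(lens[b]), Y = rnorm(lens[b], 8, 0.3))))
    rates <- rate_of_increase(lev)
    covs <- unique(lev[c("t")]); covs$z <- rlnorm(nrow(covs))
    d <- sample(1:2, 1); dp <- sample(0:1, 1)
    fr <- assemble_frame(rates, lev, covs, d = d, dprime = dp)
    # usable t runs from max(d, dp, 1) + 1 to the block length
    expect_equal(nrow(fr), sum(pmax(0, lens - max(d, dp, 1))))
  }
})

test_that("interaction ratios are formed before the transform", {
  lev <- data.frame(crop = "m", treatment = "T1", replicate = 1, t = 1:5,
                    Y = c(7, 7.5, 7.2, 7.4, 7.1))
  rates <- rate_of_increase(lev)
  covs <- data.frame(t = 1:5, z1 = c(2, 3, 4, 5, 6), z2 = c(2, 3, 4, 5, 6))
  fr <- assemble_frame(rates, lev, covs, interactions = list(c("z1", "z2")))
  expect_equal(fr$z1.z2, rep(0, 4))   # log(Z/Z) = 0

  covs$z2[2] <- 0
  expect_error(assemble_frame(rates, lev, covs[c("t", "z2")]),
               "non-positive covariate 'z2'")
  fr_id <- assemble_frame(rates, lev, covs[c("t", "z2")],
                          transform = "identity")
  expect_equal(fr_id$z2, covs$z2[2:5])
})
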