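test_that("covariate forms reduce to the pure model when b = 0", {
  p0 <- rf_params(1.2, 0.93, -7.91)
  pb <- rf_params(1.2, 0.93, -7.91, b = 0)
  Y <- seq(6, 10, by = 0.5); Z <- c(0.5, 1, 2)
  base <- predict_rate(model_spec("P"), p0, Y)
  for (f in c("L", "V", "N")) {
    sp <- model_spec(f, covariate = "z")
    for (z in Z)
      expect_identical(predict_rate(sp, pb, Y, z), base)
  }
  # vertical shift at Z = e is exactly b (log e = 1)
  pb2 <- rf_params(1.2, 0.93, -7.91, b = 0.31)
  expect_equal(predict_rate(model_spec("V", covariate = "z"), pb2, 8, exp(1)) -
                 predict_rate(model_spec("P"), p0, 8),
               0.31, tolerance = 1e-12)
})

test_that("equilibrium closed forms are roots of the rate function", {
  # published maize pure-model parameters give K near 8.70 log(kg/ha)
  spP <- model_spec("P"); pP <- rf_params(1.20, 0.93, -7.91)
  K <- equilibrium(spP, pP)
  expect_equal(K, 8.70, tolerance = 0.005)
  expect_lt(abs(predict_rate(spP, pP, K)), 1e-10)
  # bisection oracle
  root <- uniroot(function(y) predict_rate(spP, pP, y), c(5, 12),
                  tol = 1e-12)$root
  expect_equal(K, root, tolerance = 1e-8)

  # lateral model at Z = 1 collapses to the pure K
  spL <- model_spec("L", covariate = "z")
  expect_equal(equilibrium(spL, rf_params(1.20, 0.93, -7.91, 5), Z = 1),
               K, tolerance = 1e-12)

  set.seed(42)
  for (f in c("P", "L", "V", "N")) for (i in 1:25) {
    cs <- random_model_case(f)
    K <- equilibrium(cs$spec, cs$params, cs$Z, check = FALSE)
    expect_lt(abs(predict_rate(cs$spec, cs$params, K, cs$Z)), 1e-10)
  }
})

test_that("equilibrium errors on degenerate parameter regions", {
  expect_error(equilibrium(model_spec("V", covariate = "z"),
                           rf_params(0.5, 0.9, -7, b = -2), Z = exp(1)),
               "no positive equilibrium")
  expect_error(equilibrium(model_spec("N", covariate = "z"),
                           rf_params(1, 0.5, -7, b = -0.5), Z = exp(1)),
               "degenerate")
})

test_that("stability slope matches the analytic r_max*a forms and a numeric derivative", {
  # lateral slope is invariant to Z
  spL <- model_spec("L", covariate = "z")
  pL <- rf_params(1.20, 0.37, -5.49, 12.58)
  s1 <- stability_slope(spL, pL, Z = 0.7)$slope_magnitude
  s2 <- stability_slope(spL, pL, Z = 2.9)$slope_magnitude
  expect_equal(s1, 1.20 * 0.37, tolerance = 1e-12)
  expect_equal(s1, s2, tolerance = 1e-12)

  # V with b = 0 equals P
  pV0 <- rf_params(1.2, 0.93, -7.91, 0)
  expect_equal(stability_slope(model_spec("V", covariate = "z"), pV0,
                               Z = 2)$slope_magnitude,
               stability_slope(model_spec("P"),
                               rf_params(1.2, 0.93, -7.91))$slope_magnitude)

  # central-difference oracle on random draws
  set.seed(7)
  h <- 1e-6
  for (f in c("P", "L", "V", "N")) for (i in 1:25) {
    cs <- random_model_case(f)
    st <- stability_slope(cs$spec, cs$params, cs$Z)
    num <- (predict_rate(cs$spec, cs$params, st$K + h, cs$Z) -
              predict_rate(cs$spec, cs$params, st$K - h, cs$Z)) / (2 * h)
    expect_equal(st$slope_magnitude, abs(num), tolerance = 1e-6)
    expect_equal(st$eigenvalue, 1 - st$slope_magnitude)
  }
})

test_that("stability regime tracks the slope magnitude", {
  mk <- function(a, r_max) stability_slope(model_spec("P"),
                                           rf_params(r_max, a, -7))
  expect_equal(mk(0.4, 1.2)$regime, "monotonic damped")
  expect_equal(mk(1.2, 1.2)$regime, "oscillatory damped")
  expect_equal(mk(2.0, 1.2)$regime, "unstable")
})

test_that("noise-free trajectories approach K as the eigenvalue dictates", {
  # slope in (0,1): monotonic approach; slope in (1,2): alternating sign
  # offsets stay in the near-linear neighbourhood of K
  for (case in list(list(a = 0.5, mono = TRUE, off = 0.8),
                    list(a = 1.5, mono = FALSE, off = 0.1))) {
    cfg <- synthetic_config(form = "P", r_max = 1.0, a = case$a, c = -7.9,
                            noise_sd = 0, n_blocks = 1, n_cycles = 12,
                            Y0 = (log(1.0) + 7.9) / case$a - case$off, seed = 1)
    K <- (log(1.0) + 7.9) / case$a
    dev <- simulate_rate_series(cfg)[, 1] - K
    if (case$mono) {
      expect_true(all(diff(abs(dev)) < 0))
      expect_true(all(sign(dev) == sign(dev[1])))
    } else {
      expect_true(all(sign(dev[-1]) == -sign(dev[-length(dev)])))
      expect_true(all(diff(abs(dev)) < 0))
    }
  }
})

test_that("partial slope wrt the covariate matches b/Z and numeric differentiation", {
  # vertical form: b/Z independent of Y
  spV <- model_spec("V", covariate = "z")
  pV <- rf_params(0.97, 0.63, -4.09, 0.31)
  expect_equal(partial_slope_z(spV, pV, Z = 0.5), 0.62, tolerance = 1e-12)
  expect_equal(partial_slope_z(spV, pV, Y = 5, Z = 0.5),
               partial_slope_z(spV, pV, Y = 9, Z = 0.5))
  # strictly decreasing in Z for b > 0
  zs <- seq(0.2, 2, by = 0.1)
  expect_true(all(diff(partial_slope_z(spV, pV, Z = zs)) < 0))

  expect_error(partial_slope_z(model_spec("P"), rf_params(1, 0.9, -7), Z = 1),
               "no covariate")

  set.seed(11)
  h <- 1e-7
  for (f in c("L", "V", "N")) for (i in 1:20) {
    cs <- random_model_case(f)
    Y <- runif(1, 6, 10)
    num <- (predict_rate(cs$spec, cs$params, Y, cs$Z + h) -
              predict_rate(cs$spec, cs$params, Y, cs$Z - h)) / (2 * h)
    expect_equal(partial_slope_z(cs$spec, cs$params, Y, cs$Z), num,
                 tolerance = 1e-5)
  }
})

test_that("PRCF(1) is the plain correlation and higher lags match brute force", {
  set.seed(3)
  y <- cumsum(rnorm(40, 0, 0.3))
  tab <- prcf(y, max_lag = 3)
  R <- diff(y)
  expect_equal(tab$prcf[1], cor(R, y[-length(y)]), tolerance = 1e-12)

  # brute-force partial correlation at lag 3 via explicit regressions
  n <- length(y)
  t_idx <- 4:n
  R3 <- y[t_idx] - y[t_idx - 1]
  Y1 <- y[t_idx - 1]; Y2 <- y[t_idx - 2]; Y3 <- y[t_idx - 3]
  r1 <- residuals(lm(R3 ~ Y1 + Y2))
  r2 <- residuals(lm(Y3 ~ Y1 + Y2))
  expect_equal(tab$prcf[3], cor(r1, r2), tolerance = 1e-10)
})

test_that("PRCF flags first-order negative feedback in a long Ricker simulation", {
  cfg <- synthetic_config(form = "P", r_max = 1.2, a = 0.93, c = -7.91,
                          noise_sd = 0.05, n_blocks = 1, n_cycles = 500,
                          seed = 5)
  y <- simulate_rate_series(cfg)[, 1]
  tab <- prcf(y, max_lag = 4)
  expect_lt(tab$prcf[1], 0)
  expect_gt(abs(tab$prcf[1]), tab$band[1])
})

test_that("PRCF pools across blocks without crossing boundaries", {
  set.seed(9)
  blocks <- list(cumsum(rnorm(10)), cumsum(rnorm(8)))
  tab <- prcf(blocks, max_lag = 2)
  expect_equal(tab$n[1], 9 + 7)
  expect_equal(tab$n[2], 8 + 6)
  # manual pooled lag-1 computation
  pairs <- do.call(rbind, lapply(blocks, function(y)
    cbind(diff(y), y[-length(y)])))
  expect_equal(tab$prcf[1], cor(pairs[, 1], pairs[, 2]), tolerance = 1e-12)
})
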