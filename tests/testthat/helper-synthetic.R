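# Shared builders: simulate a series from known parameters and shape it
# into the modelling frame, bypassing the trend/detrend stage so tests
# compare against the generating truth directly.

sim_frame <- function(form, n_cycles, n_blocks = 1L, noise_sd = 0.05,
                      seed = 1L, r_max = 1.0, a = 0.9, c = -7.9, b = 0.3,
                      Y0 = NULL, sdlog = 0.55) {
  cfg <- synthetic_config(form = form, r_max = r_max, a = a, c = c, b = b,
                          noise_sd = noise_sd, n_blocks = n_blocks,
                          n_cycles = n_cycles, Y0 = Y0, seed = seed)
  set.seed(seed + 7777L)
  Z <- matrix(stats::rlnorm(n_cycles * n_blocks, -0.40, sdlog),
              n_cycles, n_blocks)
  Y <- simulate_rate_series(cfg, if (form == "P") NULL else Z)
  lev <- data.frame(crop = "syn", treatment = "T1",
                    replicate = rep(seq_len(n_blocks), each = n_cycles),
                    t = rep(seq_len(n_cycles), n_blocks),
                    Y = as.vector(Y))
  rates <- rate_of_increase(lev)
  covs <- data.frame(crop = "syn", treatment = "T1",
                     replicate = rep(seq_len(n_blocks), each = n_cycles),
                     t = rep(seq_len(n_cycles), n_blocks),
                     z = as.vector(Z))
  frame <- assemble_frame(rates, lev,
                          if (form == "P") NULL else covs,
                          d = 1L, dprime = 0L, transform = "log")
  list(frame = frame, lev = lev, rates = rates, Z = Z, cfg = cfg)
}

# Which form wins on AICc for a replicate generated from `true_form`.
# r_max follows the method's convention: the maximum observed rate.
identify_form <- function(true_form, seed, n_cycles = 60L, n_blocks = 6L,
                          noise_sd = 0.05) {
  s <- sim_frame(true_form, n_cycles, n_blocks, noise_sd, seed)
  r_max <- estimate_rmax(s$rates)
  specs <- list(model_spec("P"),
                model_spec("L", covariate = "z"),
                model_spec("V", covariate = "z"),
                model_spec("N", covariate = "z"))
  aiccs <- vapply(specs, function(sp) fit_model(sp, s$frame, r_max)$AICc,
                  numeric(1))
  c("P", "L", "V", "N")[which.min(aiccs)]
}

# draw a random valid parameter set + covariate for oracle checks
random_model_case <- function(form) {
  r_max <- stats::runif(1, 0.5, 2)
  a <- stats::runif(1, 0.2, 1.5)
  cc <- stats::runif(1, -12, -4)
  b <- stats::runif(1, -0.4, 0.4)
  Z <- stats::rlnorm(1, 0, 0.4)
  x <- log(Z)
  if (form == "V" && r_max + b * x <= 0.05) b <- abs(b)
  if (form == "N" && a + b * x <= 0.05) b <- abs(b)
  list(spec = model_spec(form,
                         covariate = if (form == "P") NULL else "z"),
       params = rf_params(r_max, a, cc, if (form == "P") NULL else b),
       Z = if (form == "P") NULL else Z)
}
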