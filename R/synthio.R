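#' Configuration for a synthetic long-term cropping dataset
#'
#' Defines the generating conditions for block-replicated annual yield
#' series driven by a chosen R-function form, together with the daily
#' climate and weed-community tables that emulate the schema of a
#' long-term cropping-systems experiment. One time step is one harvest
#' of the focal crop; with a three-crop rotation successive harvests are
#' \code{cycle_years} calendar years apart.
#'
#' @param crop crop label, e.g. \code{"maize"}.
#' @param form generating R-function form: \code{"P"}, \code{"L"},
#'   \code{"V"} or \code{"N"}.
#' @param r_max,a,c,b true parameters on the natural-log yield scale.
#' @param noise_sd standard deviation of the additive Gaussian process
#'   noise \eqn{\epsilon_t} on the rate scale.
#' @param covariate list describing the covariate generator:
#'   \code{name}, \code{distribution} (\code{"lognormal"} for positive
#'   diversity-like series, \code{"gaussian"} for temperature-like
#'   series), distribution parameters (\code{meanlog}, \code{sdlog} or
#'   \code{mean}, \code{sd}), and \code{lag} (d', 0 or 1).
#' @param transform covariate transform used by the generator
#'   (\code{"log"} or \code{"identity"}).
#' @param n_blocks number of replicate blocks.
#' @param n_cycles number of successive harvests per block (>= 3).
#' @param Y0 initial log yield; defaults to the equilibrium K at the
#'   covariate generator's central value.
#' @param d feedback lag of the generator.
#' @param trend quadratic calendar-year trend coefficients
#'   \code{c(linear, quadratic)} injected into log yields (per year and
#'   per year squared, centred on the series midpoint) so the
#'   detrending stage has work to do; \code{c(0, 0)} for none.
#' @param start_year first harvest year.
#' @param cycle_years calendar years between successive harvests.
#' @param seed integer seed; every random draw flows from it.
#' @return an object of class \code{cropdyn_config}.
#' @export
synthetic_config <- function(crop = "maize", form = "P",
                             r_max = 1.2, a = 0.93, c = -7.91, b = 0,
                             noise_sd = 0.05,
                             covariate = list(name = "shannon",
                                              distribution = "lognormal",
                                              meanlog = -0.40, sdlog = 0.55,
                                              lag = 0L),
                             transform = "log",
                             n_blocks = 6L, n_cycles = 6L, Y0 = NULL,
                             d = 1L,
                             trend = c(0, 0),
                             start_year = 1996L, cycle_years = 3L,
                             seed = 1L) {
  stopifnot(form %in% c("P", "L", "V", "N"))
  if (r_max <= 0) stop("r_max must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (n_cycles < 3) stop("n_cycles must be >= 3", call. = FALSE)
  if (a <= 0) stop("a must be positive for stationary simulations",
                   call. = FALSE)
  cfg <- list(crop = crop, form = form,
              r_max = r_max, a = a, c = c, b = b,
              noise_sd = noise_sd, covariate = covariate,
              transform = transform,
              n_blocks = as.integer(n_blocks),
              n_cycles = as.integer(n_cycles),
              Y0 = Y0, d = as.integer(d), trend = trend,
              start_year = as.integer(start_year),
              cycle_years = as.integer(cycle_years),
              seed = as.integer(seed))
  class(cfg) <- "cropdyn_config"
  cfg
}

.config_spec <- function(config) {
  if (config$form == "P") model_spec("P", d = config$d)
  else model_spec(config$form, covariate = config$covariate$name,
                  transform = config$transform, d = config$d,
                  dprime = as.integer(config$covariate$lag %||% 0L))
}

.config_params <- function(config) {
  rf_params(config$r_max, config$a, config$c,
            if (config$form == "P") NULL else config$b)
}

# central covariate value of the generator, used for the default Y0
.covariate_center <- function(cov) {
  switch(cov$distribution %||% "lognormal",
         lognormal = exp(cov$meanlog %||% -0.40),
         gaussian  = cov$mean %||% 15,
         stop("unknown covariate distribution", call. = FALSE))
}

.draw_covariate <- function(cov, n) {
  switch(cov$distribution %||% "lognormal",
         lognormal = stats::rlnorm(n, cov$meanlog %||% -0.40,
                                   cov$sdlog %||% 0.55),
         gaussian  = stats::rnorm(n, cov$mean %||% 15, cov$sd %||% 2),
         stop("unknown covariate distribution", call. = FALSE))
}

#' Simulate per-block log-yield series from an R-function
#'
#' Iterates \eqn{Y_t = Y_{t-1} + R(Y_{t-1}, Z_t) + \epsilon_t} with the
#' configured form. The covariate value applied at step \eqn{t} is
#' \code{covariate_series[t]}; the configured covariate lag describes
#' how downstream frames align the observable covariate against the
#' rate, not a shift inside the generator. With \code{noise_sd = 0} and
#' \code{Y0 = K} the series is constant at K. Setting \code{b = 0}
#' makes forms L, V, N bitwise identical to P under the same seed
#' because the noise stream is drawn identically.
#'
#' @param config a \code{cropdyn_config}.
#' @param covariate_series positive covariate values, length >=
#'   \code{n_cycles}; required for forms L/V/N, ignored for P. May be a
#'   matrix with one column per block.
#' @return a numeric matrix, \code{n_cycles} rows x \code{n_blocks}
#'   columns, of log-yield levels.
#' @export
simulate_rate_series <- function(config, covariate_series = NULL) {
  stopifnot(inherits(config, "cropdyn_config"))
  nb <- config$n_blocks; nc <- config$n_cycles
  spec <- .config_spec(config)
  params <- .config_params(config)
  needs_z <- config$form != "P"
  if (needs_z) {
    if (is.null(covariate_series))
      stop("covariate series required for form ", config$form, call. = FALSE)
    Zm <- if (is.matrix(covariate_series)) covariate_series
          else matrix(covariate_series, nrow = length(covariate_series),
                      ncol = nb)
    if (nrow(Zm) < nc)
      stop("covariate series shorter than n_cycles", call. = FALSE)
    if (config$transform == "log") {
      bad <- which(Zm[seq_len(nc), , drop = FALSE] <= 0, arr.ind = TRUE)
      if (nrow(bad))
        stop("non-positive covariate at cycle ", bad[1, 1],
             ", block ", bad[1, 2], " with log transform", call. = FALSE)
    }
  }
  Z0 <- if (needs_z) Zm[1L, 1L] else NULL
  Y0 <- config$Y0 %||%
    equilibrium(spec, params,
                Z = if (needs_z) .covariate_center(config$covariate) else NULL,
                check = FALSE)
  set.seed(config$seed)
  Y <- matrix(NA_real_, nrow = nc, ncol = nb)
  for (b in seq_len(nb)) {
    y <- Y0
    for (t in seq_len(nc)) {
      z <- if (needs_z) Zm[t, b] else NULL
      r <- predict_rate(spec, params, y, z)
      eps <- if (config$noise_sd > 0) stats::rnorm(1L, 0, config$noise_sd)
             else {
               stats::rnorm(1L)  # keep the stream position seed-stable
               0
             }
      y <- y + r + eps
      Y[t, b] <- y
    }
  }
  colnames(Y) <- paste0("R", seq_len(nb))
  Y
}

#' Generate a complete synthetic dataset
#'
#' Produces the four linked tables of the emulated experiment schema:
#' block-replicated annual yields (kg/ha) generated by the configured
#' R-function (with an optional quadratic calendar-year trend injected
#' on the log scale), a daily climate table spanning each growing
#' season, a weed-community biomass table whose per-sample diversity is
#' consistent with the covariate that drove the yields, and the ground
#' truth (form, parameters, covariate values, seed).
#'
#' The covariate series is drawn per block from the configured
#' generator; the weed table is then constructed around it (species
#' biomasses re-scaled so each sample's Shannon-based effective
#' richness tracks the drawn value when the covariate is
#' diversity-like).
#'
#' @param config a \code{cropdyn_config}.
#' @return a list of class \code{cropdyn_dataset} with elements
#'   \code{yields}, \code{climate}, \code{weeds}, \code{truth}.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "cropdyn_config"))
  nb <- config$n_blocks; nc <- config$n_cycles
  years <- config$start_year + (seq_len(nc) - 1L) * config$cycle_years

  set.seed(config$seed + 1000L)
  Zm <- matrix(.draw_covariate(config$covariate, nc * nb), nrow = nc, ncol = nb)

  Y <- simulate_rate_series(config, if (config$form == "P") NULL else Zm)

  # quadratic trend centred on the series midpoint, injected on log scale
  yr_c <- years - mean(years)
  trend_term <- config$trend[1] * yr_c + config$trend[2] * yr_c^2

  yields <- expand.grid(replicate = seq_len(nb), year = years,
                        KEEP.OUT.ATTRS = FALSE)
  yields <- yields[order(yields$year, yields$replicate), ]
  t_idx <- match(yields$year, years)
  yields <- data.frame(year = yields$year, crop = config$crop,
                       treatment = "T1", replicate = yields$replicate,
                       yield_kg_ha = exp(Y[cbind(t_idx, yields$replicate)] +
                                           trend_term[t_idx]))
  rownames(yields) <- NULL

  set.seed(config$seed + 2000L)
  climate <- .generate_climate(years, config$crop)
  set.seed(config$seed + 3000L)
  weeds <- .generate_weeds(years, nb, config$crop, Zm, config$covariate)

  truth <- list(crop = config$crop, form = config$form,
                params = list(r_max = config$r_max, a = config$a,
                              c = config$c, b = config$b),
                noise_sd = config$noise_sd,
                covariate_name = config$covariate$name,
                covariate = Zm, log_yield = Y,
                trend = config$trend, seed = config$seed)

  structure(list(yields = yields, climate = climate, weeds = weeds,
                 truth = truth),
            class = "cropdyn_dataset")
}

# daily climate with seasonal sinusoidal structure over Apr-Oct of each
# harvest year (covers both maize and soybean planting-harvest windows)
.generate_climate <- function(years, crop) {
  out <- lapply(years, function(yr) {
    dates <- seq(as.Date(sprintf("%d-04-01", yr)),
                 as.Date(sprintf("%d-10-31", yr)), by = "day")
    doy <- as.integer(format(dates, "%j"))
    mid <- 16 + 10 * sin(2 * pi * (doy - 105) / 365)
    spread <- pmax(4, 9 + stats::rnorm(length(dates), 0, 1.5))
    tmax <- mid + spread / 2 + stats::rnorm(length(dates), 0, 2)
    tmin <- mid - spread / 2 + stats::rnorm(length(dates), 0, 2)
    swap <- tmin > tmax
    if (any(swap)) { tmp <- tmin[swap]; tmin[swap] <- tmax[swap]; tmax[swap] <- tmp }
    wet <- stats::rbinom(length(dates), 1L, 0.35)
    precip <- wet * round(stats::rgamma(length(dates), shape = 0.9,
                                        scale = 8), 1)
    data.frame(date = format(dates, "%Y-%m-%d"), precip_mm = precip,
               tmin_c = round(tmin, 1), tmax_c = round(tmax, 1))
  })
  do.call(rbind, out)
}

# Weed community per (year, replicate): species drawn from a fixed pool;
# when the covariate is diversity-like its drawn value sets the target
# effective richness exp(H) of the sample.
.weed_pool <- c("TRIPR", "BARVU", "CAPBU", "DIGSA", "SETFA", "TAROF",
                "CHEAL", "ABUTH")
.generate_weeds <- function(years, nb, crop, Zm, cov) {
  diversity_like <- (cov$name %||% "") %in%
    c("shannon", "simpson", "invsimpson", "richness", "Jevenness",
      "Eevenness")
  rows <- list()
  for (t in seq_along(years)) for (b in seq_len(nb)) {
    z <- Zm[t, b]
    target_eff <- if (diversity_like) max(1.05, min(z + 1, length(.weed_pool)))
                  else stats::runif(1, 1.5, 6)
    S <- max(2L, min(length(.weed_pool), ceiling(target_eff)))
    sp <- sample(.weed_pool, S)
    # geometric-series abundances tuned so exp(H) ~ target_eff
    alpha <- .evenness_decay(target_eff, S)
    w <- alpha^(seq_len(S) - 1)
    total <- stats::rlnorm(1, meanlog = log(30), sdlog = 0.5)
    rows[[length(rows) + 1L]] <-
      data.frame(year = years[t], crop = crop, treatment = "T1",
                 replicate = b, species_code = sp,
                 biomass_g_m2 = round(total * w / sum(w), 4))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# decay ratio of a geometric abundance series whose Shannon effective
# number of species is close to `eff` with S species available
.evenness_decay <- function(eff, S) {
  eff <- min(eff, S - 1e-6)
  f <- function(alpha) {
    w <- alpha^(seq_len(S) - 1); p <- w / sum(w)
    exp(-sum(p * log(p))) - eff
  }
  if (f(1 - 1e-9) <= 0) return(1)
  stats::uniroot(f, c(1e-6, 1 - 1e-9), tol = 1e-9)$root
}

#' Write a synthetic dataset to CSV + JSON files
#'
#' @param dataset a \code{cropdyn_dataset}.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths
#'   (\code{yields.csv}, \code{weeds.csv}, \code{climate.csv},
#'   \code{truth.json}).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cropdyn_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(yields = file.path(dir, "yields.csv"),
             weeds = file.path(dir, "weeds.csv"),
             climate = file.path(dir, "climate.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(dataset$yields, paths["yields"], row.names = FALSE)
  utils::write.csv(dataset$weeds, paths["weeds"], row.names = FALSE)
  utils::write.csv(dataset$climate, paths["climate"], row.names = FALSE)
  truth <- dataset$truth
  truth$covariate <- as.vector(truth$covariate)
  truth$log_yield <- as.vector(truth$log_yield)
  truth$dim <- dim(dataset$truth$log_yield)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a synthetic dataset from files
#'
#' Validates the documented schema: required columns present, yields
#' and biomasses non-negative (offending row reported).
#'
#' @param dir directory containing \code{yields.csv}, \code{weeds.csv},
#'   \code{climate.csv} and optionally \code{truth.json}.
#' @return a \code{cropdyn_dataset} (with \code{truth = NULL} when no
#'   truth file is present).
#' @export
read_dataset <- function(dir) {
  yields <- .read_checked(file.path(dir, "yields.csv"),
                          c("year", "crop", "treatment", "replicate",
                            "yield_kg_ha"))
  .check_nonneg(yields, "yield_kg_ha", "yields.csv")
  weeds <- .read_checked(file.path(dir, "weeds.csv"),
                         c("year", "crop", "treatment", "replicate",
                           "species_code", "biomass_g_m2"))
  .check_nonneg(weeds, "biomass_g_m2", "weeds.csv")
  climate <- .read_checked(file.path(dir, "climate.csv"),
                           c("date", "precip_mm", "tmin_c", "tmax_c"))
  truth_path <- file.path(dir, "truth.json")
  truth <- NULL
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    if (!is.null(truth$dim)) {
      truth$log_yield <- matrix(truth$log_yield, nrow = truth$dim[1])
      truth$covariate <- matrix(truth$covariate, nrow = truth$dim[1])
    }
  }
  structure(list(yields = yields, climate = climate, weeds = weeds,
                 truth = truth),
            class = "cropdyn_dataset")
}

.read_checked <- function(path, required) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(basename(path), " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

.check_nonneg <- function(df, col, file) {
  bad <- which(df[[col]] < 0)
  if (length(bad))
    stop("negative ", col, " in ", file, " at row ", bad[1], call. = FALSE)
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
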