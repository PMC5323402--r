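#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end analysis: the data source
#' (paths to CSVs in the documented schema, or a
#' \code{\link{synthetic_config}} to generate from), the candidate
#' covariates and forms, and the screening/selection thresholds.
#'
#' @param input directory of input CSVs, or a \code{cropdyn_config}.
#' @param crop focal crop label.
#' @param covariates character vector of covariate names taken from
#'   the diversity indices (\code{richness}, \code{shannon},
#'   \code{simpson}, \code{invsimpson}, \code{Jevenness},
#'   \code{Eevenness}) and/or climate summaries (\code{tM},
#'   \code{tmax}, \code{tmin}, \code{tMax}, \code{tMin}, \code{precM},
#'   \code{precMax}).
#' @param forms candidate perturbation forms, subset of
#'   \code{c("L", "V", "N")}.
#' @param dprimes covariate lags to try.
#' @param interactions list of covariate pairs for ratio terms.
#' @param transform covariate transform(s), as in
#'   \code{\link{assemble_frame}}.
#' @param d feedback lag.
#' @param level confidence-set level (default 0.99).
#' @param rare_threshold rare-species occupancy threshold (default
#'   0.05).
#' @param cor_threshold correlation-screen threshold (default 0.4).
#' @param block_covariates keep diversity covariates block-specific
#'   (default) instead of averaging across replicates per year.
#' @param outdir output directory for the CSV bundle (NULL = no files).
#' @param seed root seed for any generation step.
#' @return list of class \code{cropdyn_runconfig}.
#' @export
run_config <- function(input, crop = "maize",
                       covariates = c("shannon"),
                       forms = c("L", "V", "N"),
                       dprimes = 0L, interactions = list(),
                       transform = "log", d = 1L,
                       level = 0.99, rare_threshold = 0.05,
                       cor_threshold = 0.4,
                       block_covariates = TRUE,
                       outdir = NULL, seed = 1L) {
  stopifnot(level > 0, level <= 1,
            rare_threshold > 0, rare_threshold < 1,
            cor_threshold > 0, cor_threshold < 1)
  structure(list(input = input, crop = crop, covariates = covariates,
                 forms = forms, dprimes = as.integer(dprimes),
                 interactions = interactions, transform = transform,
                 d = as.integer(d), level = level,
                 rare_threshold = rare_threshold,
                 cor_threshold = cor_threshold,
                 block_covariates = block_covariates,
                 outdir = outdir, seed = as.integer(seed)),
            class = "cropdyn_runconfig")
}

.diversity_names <- c("richness", "shannon", "simpson", "invsimpson",
                      "Jevenness", "Eevenness")
.climate_names <- c("tM", "tmax", "tmin", "tMax", "tMin", "precM",
                    "precMax")

#' Run the full analysis pipeline
#'
#' simulate/read -> detrend -> rates -> diversity -> PRCF -> candidate
#' fitting -> AICc selection -> stability report. Deterministic for a
#' fixed config and seed. When \code{outdir} is set, writes
#' \code{diversity.csv}, \code{screen.csv}, \code{prcf.csv},
#' \code{frame.csv}, \code{selection.csv}, \code{stability.csv} and a
#' plain-text run log.
#'
#' @param config a \code{cropdyn_runconfig}.
#' @return list of class \code{cropdyn_run} with elements
#'   \code{dataset}, \code{levels}, \code{rates}, \code{frame},
#'   \code{diversity}, \code{screen}, \code{prcf}, \code{fits},
#'   \code{selection}, \code{stability}, \code{r_max}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cropdyn_runconfig"))
  dataset <- if (inherits(config$input, "cropdyn_config")) {
    generate_dataset(config$input)
  } else if (inherits(config$input, "cropdyn_dataset")) {
    config$input
  } else {
    read_dataset(config$input)
  }

  yields <- dataset$yields[dataset$yields$crop == config$crop, ]
  if (!nrow(yields)) stop("no yields for crop '", config$crop, "'",
                          call. = FALSE)
  levels <- detrend_quadratic(yields)
  rates <- rate_of_increase(levels)
  years <- sort(unique(levels$year))

  # weed diversity per sample, plus the correlation screen
  weeds <- dataset$weeds[dataset$weeds$crop == config$crop, ]
  diversity <- screen <- NULL
  if (nrow(weeds)) {
    cm <- community_matrix(weeds)
    div <- diversity_indices(cm)
    diversity <- cbind(.split_sample_key(rownames(cm)), div)
    cm_red <- filter_rare(cm, config$rare_threshold)
    if (ncol(cm_red))
      screen <- correlation_screen(div, hellinger(cm_red),
                                   config$cor_threshold)
  }

  covs <- .build_covariates(config, dataset, diversity, levels, years)
  prcf_tab <- prcf(levels, max_lag = min(4L, length(years) - 2L))

  frame <- assemble_frame(rates, levels, covariates = covs,
                          d = config$d, dprime = max(config$dprimes),
                          transform = config$transform,
                          interactions = config$interactions)
  # frames per dprime differ in row alignment; fit on the one matching
  # each candidate's lag
  frames <- lapply(unique(config$dprimes), function(dp)
    assemble_frame(rates, levels, covariates = covs, d = config$d,
                   dprime = dp, transform = config$transform,
                   interactions = config$interactions))
  names(frames) <- as.character(unique(config$dprimes))

  r_max <- estimate_rmax(rates)
  specs <- enumerate_candidates(config$covariates, config$forms,
                                config$dprimes, config$interactions,
                                include_pure = TRUE,
                                transform = config$transform,
                                d = config$d)
  fits <- lapply(specs, function(sp) {
    fr <- frames[[as.character(sp$dprime)]] %||% frames[[1]]
    fit_model(sp, fr, r_max = r_max)
  })

  selection <- selection_table(fits, crop = config$crop,
                               level = config$level)

  stability <- .stability_table(fits, covs, config)

  run <- structure(list(dataset = dataset, levels = levels, rates = rates,
                        frame = frame, diversity = diversity,
                        screen = screen, prcf = prcf_tab, fits = fits,
                        selection = selection, stability = stability,
                        r_max = r_max, config = config),
                   class = "cropdyn_run")
  if (!is.null(config$outdir)) .write_bundle(run, config$outdir)
  run
}

.split_sample_key <- function(ids) {
  parts <- do.call(rbind, strsplit(ids, ".", fixed = TRUE))
  data.frame(year = as.integer(parts[, 1]), treatment = parts[, 2],
             replicate = as.integer(parts[, 3]))
}

# covariate table keyed by (block key, t): diversity indices from the
# weed table (block-specific or year-averaged) and/or climate summaries
.build_covariates <- function(config, dataset, diversity, levels, years) {
  want <- unique(c(config$covariates, unlist(config$interactions)))
  if (!length(want)) return(NULL)
  base <- unique(levels[c("crop", "treatment", "replicate", "t", "year")])
  out <- base
  div_want <- intersect(want, .diversity_names)
  if (length(div_want)) {
    if (is.null(diversity))
      stop("diversity covariates requested but no weed data", call. = FALSE)
    if (config$block_covariates) {
      key_d <- paste(diversity$year, diversity$treatment,
                     diversity$replicate)
      key_b <- paste(base$year, base$treatment, base$replicate)
      m <- match(key_b, key_d)
    } else {
      agg <- stats::aggregate(diversity[div_want],
                              by = list(year = diversity$year), mean)
      m <- match(base$year, agg$year)
      diversity <- agg
    }
    for (nm in div_want) out[[nm]] <- diversity[[nm]][m]
  }
  cl_want <- intersect(want, .climate_names)
  if (length(cl_want)) {
    cs <- growing_season_summary(dataset$climate,
                                 default_windows(config$crop, years))
    m <- match(base$year, cs$year)
    for (nm in cl_want) out[[nm]] <- cs[[nm]][m]
  }
  unknown <- setdiff(want, c(.diversity_names, .climate_names))
  if (length(unknown))
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out
}

# stability report for every converged covariate model at the sample
# mean of its (transformed) covariate, and for the pure model
.stability_table <- function(fits, covs, config) {
  rows <- lapply(fits, function(f) {
    if (!isTRUE(f$converged)) return(NULL)
    sp <- f$spec
    if (sp$form == "P") {
      st <- stability_slope(sp, f$params)
    } else {
      zraw <- covs[[sp$covariate]]
      if (is.null(zraw)) {
        pair <- strsplit(sp$covariate, ".", fixed = TRUE)[[1]]
        zraw <- covs[[pair[1]]] / covs[[pair[2]]]
      }
      zbar <- mean(zraw, na.rm = TRUE)
      st <- tryCatch(stability_slope(sp, f$params, Z = zbar),
                     error = function(e) NULL)
      if (is.null(st)) return(NULL)
    }
    data.frame(model = spec_id(sp), K = st$K,
               slope = st$slope_magnitude, eigenvalue = st$eigenvalue,
               regime = st$regime)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

.write_bundle <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) if (!is.null(x))
    utils::write.csv(x, file.path(outdir, f), row.names = FALSE)
  wr(run$diversity, "diversity.csv")
  wr(run$screen, "screen.csv")
  wr(run$prcf, "prcf.csv")
  wr(run$frame, "frame.csv")
  wr(run$selection, "selection.csv")
  wr(run$stability, "stability.csv")
  writeLines(c(sprintf("cropdyn %s", as.character(utils::packageVersion("cropdyn"))),
               sprintf("R %s", getRversion()),
               sprintf("seed %d", run$config$seed),
               sprintf("crop %s", run$config$crop),
               sprintf("r_max %.6f", run$r_max),
               sprintf("candidates %d", length(run$fits))),
             file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' @export
print.cropdyn_run <- function(x, ...) {
  cat("cropdyn run:", x$config$crop, "-", length(x$fits), "candidates,",
      "r_max =", round(x$r_max, 4), "\n")
  print(utils::head(x$selection, 5))
  invisible(x)
}
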