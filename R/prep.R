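#' Quadratic detrending of log yields
#'
#' Removes slowly varying non-climatic influences (management,
#' genetics) by ordinary least squares of natural-log yield on calendar
#' year and year squared, pooled across treatments and replicates per
#' crop. The detrended level is the residual plus the per-crop grand
#' mean of log yield, so the series keeps the log(kg/ha) scale and the
#' supply/demand parameter c of downstream models stays interpretable.
#'
#' @param yields long yield table with columns \code{year},
#'   \code{crop}, \code{treatment}, \code{replicate},
#'   \code{yield_kg_ha}.
#' @param per_treatment fit a separate trend per treatment instead of
#'   pooling (off by default; pooling matches the larger-N design).
#' @return data frame (\code{LogYieldSeries}) with columns \code{crop},
#'   \code{treatment}, \code{replicate}, \code{t} (cycle index within
#'   block, by increasing year), \code{year}, \code{Y}.
#' @export
detrend_quadratic <- function(yields, per_treatment = FALSE) {
  req <- c("year", "crop", "treatment", "replicate", "yield_kg_ha")
  missing <- setdiff(req, names(yields))
  if (length(missing))
    stop("yields table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(yields$yield_kg_ha <= 0))
    stop("non-positive yields cannot be log-transformed", call. = FALSE)
  group_of <- function(df) if (per_treatment)
    interaction(df$crop, df$treatment, drop = TRUE) else factor(df$crop)
  pieces <- lapply(split(yields, group_of(yields)), function(df) {
    if (length(unique(df$year)) < 4L)
      stop("need >= 4 distinct calendar years to fit a quadratic trend (",
           df$crop[1], ")", call. = FALSE)
    ly <- log(df$yield_kg_ha)
    fit <- stats::lm(ly ~ year + I(year^2), data = df)
    df$Y <- stats::residuals(fit) + mean(ly)
    df
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$crop, out$treatment, out$replicate, out$year), ]
  out$t <- stats::ave(out$year, out$crop, out$treatment, out$replicate,
                      FUN = seq_along)
  rownames(out) <- NULL
  out[c("crop", "treatment", "replicate", "t", "year", "Y")]
}

#' Rate of increase of detrended log yield
#'
#' \eqn{R_t = Y_t - Y_{t-1}} within each block (crop x treatment x
#' replicate); never differenced across block boundaries. Blocks with a
#' single cycle are dropped with a warning.
#'
#' @param levels a \code{LogYieldSeries} data frame
#'   (\code{\link{detrend_quadratic}} output, or any table with the
#'   block key columns plus \code{t} and \code{Y}).
#' @return data frame (\code{RateSeries}) with the block key, \code{t}
#'   (index of the later cycle in the difference), \code{R}.
#' @export
rate_of_increase <- function(levels) {
  stopifnot(all(c("t", "Y") %in% names(levels)))
  key_cols <- intersect(c("crop", "treatment", "replicate"), names(levels))
  key <- if (length(key_cols)) interaction(levels[key_cols], drop = TRUE)
         else factor(rep(1, nrow(levels)))
  dropped <- 0L
  pieces <- lapply(split(levels, key), function(d) {
    d <- d[order(d$t), ]
    if (nrow(d) < 2L) { dropped <<- dropped + 1L; return(NULL) }
    out <- d[-1L, c(key_cols, "t"), drop = FALSE]
    out$R <- diff(d$Y)
    out
  })
  if (dropped > 0L)
    warning(dropped, " block(s) with a single cycle dropped")
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Growing-season climate summaries
#'
#' Per crop-year summaries of the daily weather table over the
#' planting-harvest window: the daily mean temperature is
#' \code{(tmin + tmax)/2}; \code{tM}/\code{tmax}/\code{tmin} are season
#' means of the daily mean/maximum/minimum, \code{tMax}/\code{tMin} the
#' season extremes, \code{precM}/\code{precMax} the mean and maximum
#' daily precipitation.
#'
#' @param climate daily table with columns \code{date} (ISO-8601),
#'   \code{precip_mm}, \code{tmin_c}, \code{tmax_c}.
#' @param windows data frame with columns \code{crop}, \code{year},
#'   \code{start}, \code{end} (Date or ISO strings), one row per
#'   crop-year.
#' @return data frame with columns \code{crop}, \code{year}, \code{tM},
#'   \code{tmax}, \code{tmin}, \code{tMax}, \code{tMin}, \code{precM},
#'   \code{precMax}.
#' @export
growing_season_summary <- function(climate, windows) {
  stopifnot(all(c("date", "precip_mm", "tmin_c", "tmax_c") %in%
                  names(climate)),
            all(c("crop", "year", "start", "end") %in% names(windows)))
  dates <- as.Date(climate$date)
  out <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    span <- seq(as.Date(w$start), as.Date(w$end), by = "day")
    idx <- match(span, dates)
    if (anyNA(idx))
      stop("missing daily records in window ", w$crop, " ", w$year, ": ",
           paste(utils::head(format(span[is.na(idx)]), 5L), collapse = ", "),
           call. = FALSE)
    d <- climate[idx, ]
    dm <- (d$tmin_c + d$tmax_c) / 2
    data.frame(crop = w$crop, year = w$year,
               tM = mean(dm), tmax = mean(d$tmax_c), tmin = mean(d$tmin_c),
               tMax = max(d$tmax_c), tMin = min(d$tmin_c),
               precM = mean(d$precip_mm), precMax = max(d$precip_mm))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Default planting-harvest windows
#'
#' Maize: early May to late September; soybean: late May to early
#' October.
#'
#' @param crop crop label (\code{"maize"} or \code{"soybean"}).
#' @param years harvest years.
#' @return data frame usable as \code{windows} in
#'   \code{\link{growing_season_summary}}.
#' @export
default_windows <- function(crop, years) {
  dates <- if (identical(crop, "soybean")) c("05-25", "10-05")
           else c("05-05", "09-25")
  data.frame(crop = crop, year = years,
             start = sprintf("%d-%s", years, dates[1]),
             end = sprintf("%d-%s", years, dates[2]))
}

#' Assemble the modelling frame
#'
#' Aligns rates, lagged levels and lagged covariates into the flat
#' table the fitting step consumes: one row per (block, t) with
#' \eqn{R_t}, \eqn{Y_{t-d}} and each requested covariate at lag d'.
#' Interaction covariates are built as the ratio \eqn{Z_1/Z_2}
#' \emph{before} the transform (named \code{"Z1.Z2"}). The log
#' transform is applied here, so frame covariate columns are already on
#' the \eqn{x}-scale; it errors on non-positive values unless
#' \code{"identity"} is requested for that covariate. Rows with any
#' unavailable lag are dropped and counted in the
#' \code{"dropped_rows"} attribute.
#'
#' @param rates \code{RateSeries} data frame.
#' @param levels \code{LogYieldSeries} data frame.
#' @param covariates \code{NULL}, or a data frame keyed by \code{t}
#'   plus optionally the block key columns (block-less covariates are
#'   broadcast across blocks), with one column per covariate.
#' @param d feedback lag (1 or 2).
#' @param dprime covariate lag (0 or 1).
#' @param transform single string or named character vector
#'   (\code{"log"}/\code{"identity"}) per covariate.
#' @param interactions list of length-2 character vectors naming
#'   covariate pairs to form as ratios.
#' @return data frame (\code{ModelFrame}) with the block key, \code{t},
#'   \code{R}, \code{Y_lag} and one column per covariate; attributes
#'   \code{d}, \code{dprime}, \code{dropped_rows}.
#' @export
assemble_frame <- function(rates, levels, covariates = NULL,
                           d = 1L, dprime = 0L, transform = "log",
                           interactions = NULL) {
  if (!d %in% c(1L, 2L)) stop("d must be 1 or 2", call. = FALSE)
  if (!dprime %in% c(0L, 1L)) stop("dprime must be 0 or 1", call. = FALSE)
  key_cols <- intersect(c("crop", "treatment", "replicate"), names(rates))
  frame <- rates

  # lagged level Y_{t-d}, joined within block
  lev_key <- do.call(paste, c(levels[key_cols], list(levels$t), sep = "\r"))
  tgt_key <- do.call(paste, c(frame[key_cols], list(frame$t - d), sep = "\r"))
  frame$Y_lag <- levels$Y[match(tgt_key, lev_key)]

  cov_names <- character(0)
  if (!is.null(covariates)) {
    stopifnot("t" %in% names(covariates))
    cov_key_cols <- intersect(key_cols, names(covariates))
    cov_names <- setdiff(names(covariates), c(cov_key_cols, "t", "year"))
    cov <- covariates
    for (pair in interactions) {
      stopifnot(length(pair) == 2L, all(pair %in% cov_names))
      nm <- paste(pair[1], pair[2], sep = ".")
      cov[[nm]] <- cov[[pair[1]]] / cov[[pair[2]]]
      cov_names <- c(cov_names, nm)
    }
    ck <- if (length(cov_key_cols))
      do.call(paste, c(cov[cov_key_cols], list(cov$t), sep = "\r"))
    else as.character(cov$t)
    fk <- if (length(cov_key_cols))
      do.call(paste, c(frame[cov_key_cols], list(frame$t - dprime), sep = "\r"))
    else as.character(frame$t - dprime)
    m <- match(fk, ck)
    for (nm in cov_names) {
      z <- cov[[nm]][m]
      tr <- if (length(transform) > 1L) unname(transform[nm]) else transform
      if (is.null(tr) || is.na(tr)) tr <- "log"
      if (tr == "log") {
        bad <- which(!is.na(z) & z <= 0)
        if (length(bad))
          stop("log transform of non-positive covariate '", nm,
               "' at frame row ", bad[1], " (block ",
               paste(unlist(frame[bad[1], key_cols]), collapse = "/"),
               ", t=", frame$t[bad[1]] - dprime, ")", call. = FALSE)
        z <- log(z)
      }
      frame[[nm]] <- z
    }
  }

  complete <- stats::complete.cases(frame)
  dropped <- sum(!complete)
  frame <- frame[complete, ]
  rownames(frame) <- NULL
  attr(frame, "d") <- as.integer(d)
  attr(frame, "dprime") <- as.integer(dprime)
  attr(frame, "dropped_rows") <- dropped
  attr(frame, "covariates") <- cov_names
  frame
}
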