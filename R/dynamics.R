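#' Royama R-function model specification
#'
#' Describes one candidate model for the crop-yield rate of increase
#' \eqn{R_t}. The pure form (\code{"P"}) is the exponential (Ricker-type)
#' feedback \eqn{R_t = r_{max} - \exp(a Y_{t-d} + c)}. External
#' perturbations by a covariate \eqn{Z} enter in one of three ways
#' (Royama's classification):
#' \describe{
#'   \item{L (lateral)}{through \eqn{c}: \eqn{R_t = r_{max} -
#'     \exp(a Y_{t-d} + c + b\,x)}, translating the curve sideways;}
#'   \item{V (vertical)}{additively through \eqn{r_{max}}: \eqn{R_t =
#'     r_{max} - \exp(a Y_{t-d} + c) + b\,x};}
#'   \item{N (nonlinear)}{through \eqn{a}: \eqn{R_t = r_{max} -
#'     \exp((a + b\,x) Y_{t-d} + c)}, reshaping the curve.}
#' }
#' Here \eqn{x} is the transformed covariate, \eqn{x = \log Z} by default
#' (natural log), or \eqn{x = Z} with \code{transform = "identity"} —
#' the documented fallback for ratio covariates that can be non-positive.
#'
#' @param form one of \code{"P"}, \code{"L"}, \code{"V"}, \code{"N"}.
#' @param covariate covariate column name (\code{NULL} for form P). A
#'   ratio covariate created by frame assembly is named \code{"Z1.Z2"}.
#' @param transform \code{"log"} or \code{"identity"}; how the raw
#'   covariate is mapped to \eqn{x} before entering the model.
#' @param d feedback lag (harvests); the level entering the feedback is
#'   \eqn{Y_{t-d}}.
#' @param dprime covariate lag (0 = same harvest, 1 = previous harvest).
#' @return an object of class \code{cropdyn_spec}.
#' @export
model_spec <- function(form = c("P", "L", "V", "N"), covariate = NULL,
                       transform = c("log", "identity"), d = 1L, dprime = 0L) {
  form <- match.arg(form)
  transform <- match.arg(transform)
  if (form == "P" && !is.null(covariate))
    stop("form 'P' takes no covariate", call. = FALSE)
  if (form != "P" && is.null(covariate))
    stop("form '", form, "' requires a covariate", call. = FALSE)
  if (d < 1) stop("feedback lag d must be >= 1", call. = FALSE)
  if (!dprime %in% c(0L, 1L)) stop("dprime must be 0 or 1", call. = FALSE)
  structure(
    list(form = form, covariate = covariate, transform = transform,
         d = as.integer(d), dprime = as.integer(dprime)),
    class = "cropdyn_spec"
  )
}

#' @export
print.cropdyn_spec <- function(x, ...) {
  cat(spec_id(x), "\n")
  invisible(x)
}

#' Compact identifier for a model specification
#'
#' @param spec a \code{cropdyn_spec}.
#' @return a single string, e.g. \code{"L:shannon:log:d1:d'0"}.
#' @export
spec_id <- function(spec) {
  if (spec$form == "P") return(sprintf("P:d%d", spec$d))
  sprintf("%s:%s:%s:d%d:d'%d", spec$form, spec$covariate, spec$transform,
          spec$d, spec$dprime)
}

#' R-function parameters
#'
#' @param r_max maximum rate of increase; fixed at the maximum observed
#'   \eqn{R_t}, not a free parameter.
#' @param a feedback shape parameter (per log-yield unit).
#' @param c supply/demand measure (log scale).
#' @param b perturbation coefficient (absent for the pure form).
#' @return an object of class \code{cropdyn_params}.
#' @export
rf_params <- function(r_max, a, c, b = NULL) {
  stopifnot(is.numeric(r_max), length(r_max) == 1L)
  if (r_max <= 0) stop("r_max must be positive", call. = FALSE)
  structure(list(r_max = r_max, a = a, c = c, b = b),
            class = "cropdyn_params")
}

# Core evaluation in x-space (x = already-transformed covariate).
# Vectorised over Y and x. Kept internal so fitting and prediction share
# one definition of the family.
.rate_fn <- function(form, r_max, a, c, b, Y, x = NULL) {
  switch(form,
    P = r_max - exp(a * Y + c),
    L = r_max - exp(a * Y + c + b * x),
    V = r_max - exp(a * Y + c) + b * x,
    N = r_max - exp((a + b * x) * Y + c),
    stop("unknown form '", form, "'", call. = FALSE)
  )
}

.apply_transform <- function(Z, transform, what = "covariate") {
  if (transform == "identity") return(Z)
  bad <- which(!is.na(Z) & Z <= 0)
  if (length(bad))
    stop("log transform of non-positive ", what, " at index ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  log(Z)
}

#' Predicted rate of increase
#'
#' Evaluates the selected R-function form at log-yield level \code{Y} and
#' raw covariate value \code{Z} (transformed internally according to the
#' spec). Vectorised; \code{Y} and \code{Z} are recycled to a common
#' length.
#'
#' @param spec a \code{cropdyn_spec}.
#' @param params a \code{cropdyn_params} (with \code{b} for forms L/V/N).
#' @param Y log-yield level(s) \eqn{Y_{t-d}}.
#' @param Z raw covariate value(s); ignored for form P.
#' @return numeric vector of rates \eqn{R_t}.
#' @export
predict_rate <- function(spec, params, Y, Z = NULL) {
  stopifnot(inherits(spec, "cropdyn_spec"))
  if (spec$form == "P") {
    if (!is.null(Z) && length(Z))
      stop("form 'P' takes no covariate value", call. = FALSE)
    return(.rate_fn("P", params$r_max, params$a, params$c, NULL, Y))
  }
  if (is.null(Z)) stop("form '", spec$form, "' needs a covariate value",
                       call. = FALSE)
  if (is.null(params$b)) stop("params$b required for form ", spec$form,
                              call. = FALSE)
  x <- .apply_transform(Z, spec$transform, spec$covariate)
  .rate_fn(spec$form, params$r_max, params$a, params$c, params$b, Y, x)
}

#' Equilibrium log yield (yield potential K)
#'
#' The nontrivial root of \eqn{R_t = 0}: the log-yield level the fitted
#' map settles to. Closed forms per model family (with \eqn{x} the
#' transformed covariate):
#' P: \eqn{K = (\log r_{max} - c)/a};
#' L: \eqn{K = (\log r_{max} - c - b x)/a};
#' V: \eqn{K = (\log(r_{max} + b x) - c)/a};
#' N: \eqn{K = (\log r_{max} - c)/(a + b x)}.
#' Each result is verified against a numeric root of
#' \code{predict_rate = 0} (disable with \code{check = FALSE} in tight
#' loops).
#'
#' @inheritParams predict_rate
#' @param check verify the closed form against a numeric root.
#' @return equilibrium K on the log(kg/ha) scale.
#' @export
equilibrium <- function(spec, params, Z = NULL, check = TRUE) {
  stopifnot(inherits(spec, "cropdyn_spec"))
  r_max <- params$r_max; a <- params$a; cc <- params$c; b <- params$b
  x <- if (spec$form == "P") NULL
       else .apply_transform(Z, spec$transform, spec$covariate)
  K <- switch(spec$form,
    P = (log(r_max) - cc) / a,
    L = (log(r_max) - cc - b * x) / a,
    V = {
      eff <- r_max + b * x
      if (any(eff <= 0))
        stop("no positive equilibrium: r_max + b*x <= 0", call. = FALSE)
      (log(eff) - cc) / a
    },
    N = {
      aeff <- a + b * x
      if (any(abs(aeff) < .Machine$double.eps))
        stop("degenerate nonlinear model: a + b*x = 0", call. = FALSE)
      (log(r_max) - cc) / aeff
    })
  if (check && length(K) == 1L && is.finite(K)) {
    f <- function(y) predict_rate(spec, params, y, Z)
    root <- stats::uniroot(f, interval = K + c(-1, 1), tol = 1e-12)$root
    if (abs(root - K) > 1e-6)
      warning("closed-form equilibrium disagrees with numeric root")
  }
  K
}

#' Stability of the yield equilibrium
#'
#' The local stability of the first-order map \eqn{Y_t = Y_{t-1} + R_t}
#' is governed by the slope of the R-function at K. The slope magnitude
#' is \eqn{a\,r_{max}} for forms P and L (invariant to the covariate),
#' \eqn{a\,(r_{max} + b x)} for V and \eqn{(a + b x)\,r_{max}} for N.
#' The map eigenvalue is \eqn{\lambda = 1 - |dR/dY|_K}: slope in (0,1)
#' gives monotonic damped approach, (1,2) oscillatory damped, above 2
#' unstable.
#'
#' @inheritParams predict_rate
#' @return list of class \code{cropdyn_stability} with elements
#'   \code{K}, \code{slope_magnitude}, \code{eigenvalue}, \code{regime}.
#' @export
stability_slope <- function(spec, params, Z = NULL) {
  K <- equilibrium(spec, params, Z, check = FALSE)
  r_max <- params$r_max; a <- params$a; b <- params$b
  x <- if (spec$form == "P") NULL
       else .apply_transform(Z, spec$transform, spec$covariate)
  s <- switch(spec$form,
    P = a * r_max,
    L = a * r_max,
    V = a * (r_max + b * x),
    N = (a + b * x) * r_max)
  s <- abs(s)
  regime <- ifelse(s < 1, "monotonic damped",
            ifelse(s < 2, "oscillatory damped", "unstable"))
  structure(list(K = K, slope_magnitude = s, eigenvalue = 1 - s,
                 regime = regime),
            class = "cropdyn_stability")
}

#' @export
print.cropdyn_stability <- function(x, ...) {
  cat(sprintf("K = %.4f  |dR/dY| = %.4f  lambda = %.4f  (%s)\n",
              x$K[1], x$slope_magnitude[1], x$eigenvalue[1], x$regime[1]))
  invisible(x)
}

#' Partial slope of the rate with respect to the covariate
#'
#' \eqn{\partial R_t / \partial Z} at given \eqn{(Y, Z)}. For the
#' vertical form with log transform this is \eqn{b/Z}, independent of
#' the yield level; lateral and nonlinear forms carry the exponential
#' factor. With \code{transform = "identity"} the \eqn{1/Z} factor from
#' the chain rule is absent.
#'
#' @inheritParams predict_rate
#' @return numeric vector \eqn{\partial R/\partial Z}.
#' @export
partial_slope_z <- function(spec, params, Y = NULL, Z) {
  stopifnot(inherits(spec, "cropdyn_spec"))
  if (spec$form == "P")
    stop("pure model has no covariate: partial slope undefined",
         call. = FALSE)
  if (any(Z <= 0) && spec$transform == "log")
    stop("Z must be positive under log transform", call. = FALSE)
  b <- params$b; a <- params$a; cc <- params$c
  x <- .apply_transform(Z, spec$transform, spec$covariate)
  dx <- if (spec$transform == "log") 1 / Z else rep(1, length(Z))
  switch(spec$form,
    V = b * dx,
    L = -(b * dx) * exp(a * Y + cc + b * x),
    N = -(b * dx) * Y * exp((a + b * x) * Y + cc))
}

#' Partial rate correlation function (PRCF)
#'
#' Diagnoses the order of the feedback acting on the rate of increase:
#' PRCF(1) is the Pearson correlation between \eqn{R_t} and
#' \eqn{Y_{t-1}}; PRCF(i > 1) is the partial correlation of \eqn{R_t}
#' with \eqn{Y_{t-i}} given the intermediate lags
#' \eqn{Y_{t-1}, \dots, Y_{t-i+1}}, computed by correlating the
#' residuals of the two regressions on the conditioning set. Lagged
#' pairs are pooled across blocks and never cross a block boundary.
#' The Bartlett-style band \eqn{\pm 2/\sqrt{n}} uses the number of
#' usable pairs at each lag.
#'
#' @param levels either a numeric vector (one block) or a list of
#'   numeric vectors (per-block detrended log-yield series), or a
#'   data frame with columns \code{block} (or \code{crop}/
#'   \code{treatment}/\code{replicate}), \code{t} and \code{Y}.
#' @param max_lag largest lag to evaluate.
#' @return data frame with columns \code{lag}, \code{prcf}, \code{n},
#'   \code{band}; lags with too few pairs get \code{NA}.
#' @export
prcf <- function(levels, max_lag = 4L) {
  series <- .as_block_series(levels)
  out <- data.frame(lag = seq_len(max_lag), prcf = NA_real_,
                    n = 0L, band = NA_real_)
  for (i in seq_len(max_lag)) {
    mat <- .lag_matrix(series, i)
    n <- nrow(mat)
    out$n[i] <- n
    if (n < i + 2L) next   # not enough pairs to identify this lag
    out$band[i] <- 2 / sqrt(n)
    R <- mat[, 1L]
    Yi <- mat[, i + 1L]
    if (i == 1L) {
      out$prcf[i] <- stats::cor(R, Yi)
    } else {
      cond <- mat[, 2:i, drop = FALSE]
      r1 <- stats::lm.fit(cbind(1, cond), R)$residuals
      r2 <- stats::lm.fit(cbind(1, cond), Yi)$residuals
      out$prcf[i] <- stats::cor(r1, r2)
    }
  }
  out
}

# rows: (R_t, Y_{t-1}, ..., Y_{t-lag}) pooled across blocks
.lag_matrix <- function(series, lag) {
  rows <- lapply(series, function(y) {
    m <- length(y)
    if (m < lag + 1L) return(NULL)
    t_idx <- (lag + 1L):m
    cbind(y[t_idx] - y[t_idx - 1L],
          vapply(seq_len(lag), function(j) y[t_idx - j], numeric(length(t_idx))))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

.as_block_series <- function(levels) {
  if (is.numeric(levels)) return(list(levels))
  if (is.list(levels) && !is.data.frame(levels)) return(levels)
  if (is.data.frame(levels)) {
    stopifnot(all(c("t", "Y") %in% names(levels)))
    key_cols <- intersect(c("block", "crop", "treatment", "replicate"),
                          names(levels))
    if (!length(key_cols)) {
      ord <- order(levels$t)
      return(list(levels$Y[ord]))
    }
    key <- interaction(levels[key_cols], drop = TRUE)
    return(lapply(split(levels[c("t", "Y")], key),
                  function(d) d$Y[order(d$t)]))
  }
  stop("cannot interpret 'levels' as block series", call. = FALSE)
}

#' Maximum observed rate of increase
#'
#' \eqn{r_{max}} is fixed at the maximum observed \eqn{R_t} rather than
#' estimated by regression; this keeps it identical across all candidate
#' models fitted to the same series.
#'
#' @param rates numeric vector of rates or a data frame with column
#'   \code{R}.
#' @return the maximum rate.
#' @export
estimate_rmax <- function(rates) {
  R <- if (is.data.frame(rates)) rates$R else rates
  r <- max(R, na.rm = TRUE)
  if (r <= 0) stop("maximum observed rate is not positive; r_max undefined",
                   call. = FALSE)
  r
}
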