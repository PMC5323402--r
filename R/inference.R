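#' Enumerate candidate model specifications
#'
#' Cartesian product of covariates x forms x covariate lags, plus the
#' requested interaction ratios, plus (optionally) the pure model once.
#'
#' @param covariates character vector of covariate names (columns the
#'   frame will carry).
#' @param forms subset of \code{c("L", "V", "N")}.
#' @param dprimes covariate lags, subset of \code{c(0, 1)}.
#' @param interactions list of length-2 character vectors; each pair
#'   becomes the ratio covariate \code{"Z1.Z2"}.
#' @param include_pure append the pure (covariate-free) model.
#' @param transform transform passed to every covariate spec (single
#'   string or named vector, as in \code{\link{assemble_frame}}).
#' @param d feedback lag.
#' @return list of \code{cropdyn_spec}.
#' @export
enumerate_candidates <- function(covariates = character(0),
                                 forms = c("L", "V", "N"),
                                 dprimes = c(0L, 1L),
                                 interactions = list(),
                                 include_pure = TRUE,
                                 transform = "log", d = 1L) {
  if (length(covariates) && !length(forms))
    stop("no forms given for the covariates", call. = FALSE)
  stopifnot(all(forms %in% c("L", "V", "N")))
  cov_all <- c(covariates,
               vapply(interactions, function(p) {
                 stopifnot(length(p) == 2L)
                 if (!all(p %in% covariates))
                   stop("unknown covariate in interaction: ",
                        paste(setdiff(p, covariates), collapse = ", "),
                        call. = FALSE)
                 paste(p[1], p[2], sep = ".")
               }, character(1)))
  specs <- list()
  for (cv in cov_all) for (f in forms) for (dp in dprimes) {
    tr <- if (length(transform) > 1L) unname(transform[cv]) else transform
    if (is.na(tr)) tr <- "log"
    specs[[length(specs) + 1L]] <-
      model_spec(f, covariate = cv, transform = tr, d = d, dprime = dp)
  }
  ids <- vapply(specs, spec_id, character(1))
  specs <- specs[!duplicated(ids)]
  if (include_pure) specs[[length(specs) + 1L]] <- model_spec("P", d = d)
  specs
}

#' Gaussian-likelihood corrected AIC
#'
#' \eqn{AICc = n \log(RSS/n) + 2p' + 2p'(p'+1)/(n - p' - 1)} with
#' \eqn{p' = p_{free} + 1}: the residual variance counts as an
#' estimated parameter.
#'
#' @param RSS residual sum of squares.
#' @param n number of observations.
#' @param p_free number of free mean-model parameters.
#' @return the AICc value (\code{-Inf} with a warning when RSS is 0).
#' @export
aicc <- function(RSS, n, p_free) {
  p <- p_free + 1
  if (n <= p + 1) stop("n too small for AICc (need n > p_free + 2)",
                       call. = FALSE)
  if (any(RSS < 0)) stop("RSS must be non-negative", call. = FALSE)
  if (any(RSS == 0)) {
    warning("RSS = 0: AICc is -Inf")
    return(ifelse(RSS == 0, -Inf,
                  n * log(RSS / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)))
  }
  n * log(RSS / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Akaike weights
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_i = AICc_i - \min AICc}; interpreted as the probability
#' that model i is the best in the candidate set.
#'
#' @param aicc_values numeric vector of AICc values (\code{NA} allowed;
#'   propagated as weight \code{NA} and excluded from the sum).
#' @return weights summing to 1 over the non-missing entries.
#' @export
akaike_weights <- function(aicc_values) {
  ok <- !is.na(aicc_values)
  if (!any(ok)) stop("no AICc values", call. = FALSE)
  if (any(aicc_values[ok] == -Inf)) {
    # a perfect fit dominates: split all weight among the -Inf entries
    w <- ifelse(aicc_values == -Inf, 1, 0)
    w[!ok] <- NA_real_
    return(w / sum(w[ok]))
  }
  delta <- aicc_values - min(aicc_values[ok])
  ew <- exp(-delta / 2)
  ew[!ok] <- NA_real_
  ew / sum(ew[ok])
}

#' Confidence set of models
#'
#' The smallest subset of weight-sorted candidates whose Akaike
#' weights sum to at least \code{level}.
#'
#' @param weights Akaike weights (summing to 1).
#' @param level target cumulative weight; default 0.99.
#' @return logical membership flags in the original order.
#' @export
confidence_set <- function(weights, level = 0.99) {
  ord <- order(weights, decreasing = TRUE)
  cum <- cumsum(weights[ord])
  k <- which(cum >= level - 1e-12)[1]
  if (is.na(k)) k <- length(weights)
  member <- logical(length(weights))
  member[ord[seq_len(k)]] <- TRUE
  member
}

#' Deviance-based pseudo R-squared
#'
#' For Gaussian errors the deviance reduces to sums of squares, so the
#' measure is \eqn{1 - RSS/TSS} with TSS about the mean rate.
#'
#' @param fitted a \code{cropdyn_fit}, or an RSS value.
#' @param frame the model frame the fit used (for the response), or a
#'   TSS value when \code{fitted} is numeric.
#' @return pseudo R-squared (\code{NA} when TSS is 0).
#' @export
pseudo_r2 <- function(fitted, frame) {
  if (is.numeric(fitted)) { RSS <- fitted; TSS <- frame }
  else {
    RSS <- fitted$RSS
    TSS <- sum((frame$R - mean(frame$R))^2)
  }
  if (TSS <= 0) return(NA_real_)
  1 - RSS / TSS
}

# model formula/start bookkeeping for nlsLM, in x-space
.fit_rhs <- function(form) {
  switch(form,
    P = R ~ r_max - exp(a * Y_lag + cc),
    L = R ~ r_max - exp(a * Y_lag + cc + b * x),
    V = R ~ r_max - exp(a * Y_lag + cc) + b * x,
    N = R ~ r_max - exp((a + b * x) * Y_lag + cc))
}

#' Fit one R-function model by nonlinear least squares
#'
#' Minimises \eqn{\sum (R_t - f(Y_{t-d}, x_t))^2} with
#' Levenberg-Marquardt (\code{minpack.lm::nlsLM}) from a multi-start
#' grid: a in \{0.1, 0.5, 1, 2\}, c solving the pure-model equilibrium
#' at the sample mean of \eqn{Y_{t-d}} for each a, b in
#' \{-0.5, 0, 0.5\}; the start with the lowest converged RSS wins.
#' \eqn{r_{max}} is fixed (maximum observed rate), not estimated.
#' Standard errors come from the Jacobian-based covariance at the
#' optimum and p-values from asymptotic t statistics.
#'
#' @param spec a \code{cropdyn_spec}.
#' @param frame a \code{ModelFrame} (from \code{\link{assemble_frame}});
#'   covariate columns are already transformed.
#' @param r_max fixed maximum rate; defaults to
#'   \code{\link{estimate_rmax}} on the frame.
#' @return object of class \code{cropdyn_fit}: spec, params, se,
#'   p_value, RSS, n, p_free, AICc, pseudo_r2, converged. On total
#'   non-convergence a record with \code{converged = FALSE} is
#'   returned (not an error).
#' @export
fit_model <- function(spec, frame, r_max = NULL) {
  stopifnot(inherits(spec, "cropdyn_spec"))
  r_max <- r_max %||% estimate_rmax(frame)
  p_free <- if (spec$form == "P") 2L else 3L
  dat <- data.frame(R = frame$R, Y_lag = frame$Y_lag)
  if (spec$form != "P") {
    if (!spec$covariate %in% names(frame))
      stop("frame has no covariate column '", spec$covariate, "'",
           call. = FALSE)
    dat$x <- frame[[spec$covariate]]
  }
  if (nrow(dat) < p_free + 2L)
    stop("frame has too few rows (", nrow(dat), ") for ", p_free,
         " free parameters", call. = FALSE)
  dat$r_max <- r_max

  a_grid <- c(0.1, 0.5, 1, 2)
  b_grid <- if (spec$form == "P") 0 else c(-0.5, 0, 0.5)
  ybar <- mean(dat$Y_lag)
  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10,
                                     ptol = 1e-10)
  for (a0 in a_grid) for (b0 in b_grid) {
    c0 <- log(r_max) - a0 * ybar   # pure-model equilibrium at mean Y
    start <- if (spec$form == "P") list(a = a0, cc = c0)
             else list(a = a0, cc = c0, b = b0)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(.fit_rhs(spec$form), data = dat,
                                         start = start, control = ctrl)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  n <- nrow(dat)
  if (is.null(best)) {
    return(structure(list(spec = spec,
                          params = rf_params(r_max, NA_real_, NA_real_,
                                             if (p_free == 3L) NA_real_),
                          se = NULL, p_value = NULL, RSS = NA_real_,
                          n = n, p_free = p_free, AICc = NA_real_,
                          pseudo_r2 = NA_real_, converged = FALSE),
                     class = "cropdyn_fit"))
  }
  sm <- summary(best$fit)$coefficients
  cf <- stats::coef(best$fit)
  nm_map <- c(a = "a", cc = "c", b = "b")
  se <- stats::setNames(sm[, "Std. Error"], nm_map[rownames(sm)])
  pv <- stats::setNames(sm[, "Pr(>|t|)"], nm_map[rownames(sm)])
  params <- rf_params(r_max, cf[["a"]], cf[["cc"]],
                      if (p_free == 3L) cf[["b"]])
  rss <- best$rss
  structure(list(spec = spec, params = params, se = se, p_value = pv,
                 RSS = rss, n = n, p_free = p_free,
                 AICc = aicc(rss, n, p_free),
                 pseudo_r2 = pseudo_r2(rss, sum((dat$R - mean(dat$R))^2)),
                 converged = TRUE),
            class = "cropdyn_fit")
}

#' @export
print.cropdyn_fit <- function(x, ...) {
  cat(spec_id(x$spec),
      sprintf(" a=%.3f c=%.3f%s  RSS=%.4g AICc=%.2f R2=%.3f\n",
              x$params$a, x$params$c,
              if (!is.null(x$params$b)) sprintf(" b=%.3f", x$params$b) else "",
              x$RSS, x$AICc, x$pseudo_r2))
  invisible(x)
}

#' Multi-model selection table
#'
#' Ranks converged fits by AICc and reports the standard multi-model
#' quantities: delta-AICc, Akaike weights, 99% confidence-set
#' membership, pseudo R-squared, with significance markers for the
#' parameter p-values (* p < 0.05, ** p < 0.01). Ties in AICc are
#' broken by fewer parameters, then by spec id.
#'
#' @param fits list of \code{cropdyn_fit}.
#' @param crop crop label carried into the table.
#' @param level confidence-set level; default 0.99.
#' @return data frame sorted ascending by AICc with columns
#'   \code{crop}, \code{fit}, \code{variable}, \code{r_max}, \code{a},
#'   \code{c}, \code{b}, \code{sig_a}, \code{sig_c}, \code{sig_b},
#'   \code{AICc}, \code{dAICc}, \code{w}, \code{R2}, \code{conf_set}.
#' @export
selection_table <- function(fits, crop = "", level = 0.99) {
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(conv))
    warning(sum(!conv), " non-converged fit(s) excluded from selection")
  fits <- fits[conv]
  if (!length(fits)) stop("no successful fits to rank", call. = FALSE)
  mark <- function(p) if (is.na(p)) "" else if (p < 0.01) "**"
                      else if (p < 0.05) "*" else ""
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(crop = crop, fit = f$spec$form,
               variable = f$spec$covariate %||% "",
               r_max = f$params$r_max, a = f$params$a, c = f$params$c,
               b = if (is.null(f$params$b)) NA_real_ else f$params$b,
               sig_a = mark(f$p_value[["a"]] %||% NA),
               sig_c = mark(f$p_value[["c"]] %||% NA),
               sig_b = if (is.null(f$params$b)) ""
                       else mark(f$p_value[["b"]] %||% NA),
               AICc = f$AICc, R2 = f$pseudo_r2, p_free = f$p_free,
               id = spec_id(f$spec))
  }))
  ord <- order(tab$AICc, tab$p_free, tab$id)
  tab <- tab[ord, ]
  tab$dAICc <- tab$AICc - tab$AICc[1]
  tab$w <- akaike_weights(tab$AICc)
  tab$conf_set <- confidence_set(tab$w, level)
  rownames(tab) <- NULL
  tab[c("crop", "fit", "variable", "r_max", "a", "c", "b",
        "sig_a", "sig_c", "sig_b", "AICc", "dAICc", "w", "R2",
        "conf_set")]
}
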