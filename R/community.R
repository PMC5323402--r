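#' Cast the long weed table to a sample x species matrix
#'
#' @param weeds long table with columns \code{year}, \code{treatment},
#'   \code{replicate}, \code{species_code}, \code{biomass_g_m2}
#'   (optionally \code{crop}).
#' @return numeric matrix, rows = samples (named
#'   \code{year.treatment.replicate}), columns = species codes; absent
#'   species are 0.
#' @export
community_matrix <- function(weeds) {
  req <- c("year", "treatment", "replicate", "species_code", "biomass_g_m2")
  missing <- setdiff(req, names(weeds))
  if (length(missing))
    stop("weeds table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(weeds$biomass_g_m2 < 0))
    stop("negative biomass at row ", which(weeds$biomass_g_m2 < 0)[1],
         call. = FALSE)
  sample_id <- paste(weeds$year, weeds$treatment, weeds$replicate, sep = ".")
  tab <- tapply(weeds$biomass_g_m2, list(sample_id, weeds$species_code),
                sum, default = 0)
  m <- as.matrix(tab)
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}

#' Community diversity indices
#'
#' For biomass shares \eqn{p_i}: richness S (species with biomass > 0),
#' Shannon \eqn{H = -\sum p_i \log p_i} (nats), Simpson
#' \eqn{D = 1 - \sum p_i^2}, inverse Simpson \eqn{1/\sum p_i^2},
#' Pielou's J-evenness \eqn{H/\log S} (0 for a monoculture) and
#' E-evenness \eqn{e^H/S}. Shannon, Simpson and inverse Simpson are
#' computed with \code{vegan::diversity}; the evenness measures follow
#' directly from H and S.
#'
#' @param x non-negative biomass vector (one sample), or a sample x
#'   species matrix (one row per sample).
#' @return one-row (or per-row) data frame with columns
#'   \code{richness}, \code{shannon}, \code{simpson},
#'   \code{invsimpson}, \code{Jevenness}, \code{Eevenness}.
#' @export
diversity_indices <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) {
    m <- as.matrix(x)
    out <- do.call(rbind, lapply(seq_len(nrow(m)),
                                 function(i) diversity_indices(m[i, ])))
    rownames(out) <- rownames(m)
    return(out)
  }
  if (any(x < 0)) stop("negative biomass", call. = FALSE)
  if (sum(x) <= 0) stop("all-zero sample: no community", call. = FALSE)
  S <- sum(x > 0)
  H <- as.numeric(vegan::diversity(x, index = "shannon"))
  D <- as.numeric(vegan::diversity(x, index = "simpson"))
  invD <- as.numeric(vegan::diversity(x, index = "invsimpson"))
  J <- if (S > 1L) H / log(S) else 0
  E <- exp(H) / S
  data.frame(richness = S, shannon = H, simpson = D, invsimpson = invD,
             Jevenness = J, Eevenness = E)
}

#' Hellinger transformation
#'
#' Per-sample square root of relative abundance:
#' \eqn{y'_{ij} = \sqrt{y_{ij} / \sum_j y_{ij}}}, so every nonzero row
#' has unit sum of squares — a standardization that makes species
#' profiles comparable for correlation analysis. All-zero rows pass
#' through as zeros with a warning.
#'
#' @param m sample x species biomass matrix.
#' @return matrix of the same shape.
#' @export
hellinger <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative cell in community matrix", call. = FALSE)
  zero <- rowSums(m) == 0
  if (any(zero)) warning(sum(zero), " all-zero row(s) passed through")
  out <- m
  if (any(!zero))
    out[!zero, ] <- as.matrix(vegan::decostand(m[!zero, , drop = FALSE],
                                               method = "hellinger"))
  out
}

#' Remove rare species by occupancy
#'
#' Drops species whose occupancy (samples with biomass > 0) does not
#' exceed \code{threshold} x n_samples, so incidental occurrences do
#' not dominate the correlation screen.
#'
#' @param m sample x species biomass matrix.
#' @param threshold occupancy fraction in (0, 1); default 0.05.
#' @return the reduced matrix, with attribute \code{"removed"} listing
#'   the dropped species codes.
#' @export
filter_rare <- function(m, threshold = 0.05) {
  m <- as.matrix(m)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  occ <- colSums(m > 0)
  keep <- occ > threshold * nrow(m)
  if (!any(keep)) warning("all species removed by the rarity filter")
  out <- m[, keep, drop = FALSE]
  attr(out, "removed") <- colnames(m)[!keep]
  out
}

#' Index-species correlation screen
#'
#' Pearson correlations between each diversity index and each
#' (Hellinger-transformed) species column, reported when
#' \eqn{|r|} exceeds the threshold. Identifies the species contributing
#' most to high or low diversity. No p-values are attached: the indices
#' are computed from the species data, so the pairs are not
#' independent.
#'
#' @param indices per-sample data frame of diversity indices (rows
#'   aligned with \code{m}).
#' @param m Hellinger-transformed sample x species matrix.
#' @param threshold absolute-correlation cutoff; default 0.4.
#' @return data frame \code{index}, \code{species}, \code{r}, sorted by
#'   decreasing \eqn{|r|}.
#' @export
correlation_screen <- function(indices, m, threshold = 0.4) {
  m <- as.matrix(m)
  indices <- as.data.frame(indices)
  if (nrow(indices) != nrow(m))
    stop("indices and community matrix have different sample counts",
         call. = FALSE)
  if (nrow(m) < 3L) stop("need >= 3 samples", call. = FALSE)
  res <- list()
  for (ix in names(indices)) {
    iv <- indices[[ix]]
    if (stats::sd(iv) == 0) { warning("zero-variance index '", ix,
                                      "' skipped"); next }
    for (sp in colnames(m)) {
      sv <- m[, sp]
      if (stats::sd(sv) == 0) { warning("zero-variance species '", sp,
                                        "' skipped"); next }
      r <- stats::cor(iv, sv)
      if (abs(r) > threshold)
        res[[length(res) + 1L]] <- data.frame(index = ix, species = sp, r = r)
    }
  }
  if (!length(res))
    return(data.frame(index = character(0), species = character(0),
                      r = numeric(0)))
  out <- do.call(rbind, res)
  out <- out[order(-abs(out$r)), ]
  rownames(out) <- NULL
  out
}
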