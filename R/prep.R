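#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution differences (the dominant nuisance in spot
#' urine metabolomics) by dividing each sample by its probabilistic quotient:
#' the median, over a set of well-measured reference metabolites, of the ratio
#' between the sample's value and that metabolite's across-sample median.
#'
#' The reference spectrum is the per-metabolite median across samples.
#' Reference metabolites should be chosen by the caller to have (close to)
#' complete measurements; a check at the 1% missingness level is applied.
#'
#' @param x numeric matrix, samples in rows, metabolites in columns
#'   (dimnames recommended). `NA` encodes missing values and is preserved.
#' @param reference_metabolites character or integer vector selecting the
#'   columns that form the reference spectrum.
#' @param max_reference_missing maximum tolerated missingness proportion per
#'   reference metabolite (default 0.01).
#' @return a matrix of the same shape with attributes `quotients` (per-sample
#'   dilution factors) and `flagged` (logical; samples whose quotient was
#'   undefined or non-positive, returned unchanged).
#' @examples
#' m <- matrix(rlnorm(200), 10, 20)
#' pq <- pqn_normalize(m, seq_len(20))
#' @export
pqn_normalize <- function(x, reference_metabolites,
                          max_reference_missing = 0.01) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix (samples x metabolites)")
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("'x' must have at least one sample and one metabolite")
  if (length(reference_metabolites) == 0L)
    stop("reference metabolite set is empty")
  ref <- x[, reference_metabolites, drop = FALSE]
  miss <- colMeans(is.na(ref))
  if (any(miss >= max_reference_missing + 1e-12))
    stop(sprintf("%d reference metabolite(s) exceed %.1f%% missingness",
                 sum(miss >= max_reference_missing + 1e-12),
                 100 * max_reference_missing))
  ref_spectrum <- apply(ref, 2L, stats::median, na.rm = TRUE)
  if (any(!is.finite(ref_spectrum)) || any(ref_spectrum <= 0))
    stop("reference spectrum contains non-positive or undefined medians")
  ratios <- sweep(ref, 2L, ref_spectrum, "/")
  q <- apply(ratios, 1L, stats::median, na.rm = TRUE)
  flagged <- !is.finite(q) | q <= 0
  out <- x
  ok <- which(!flagged)
  if (length(ok)) out[ok, ] <- x[ok, , drop = FALSE] / q[ok]
  if (any(flagged))
    warning(sprintf("%d sample(s) with undefined or non-positive quotient left unnormalized",
                    sum(flagged)))
  attr(out, "quotients") <- q
  attr(out, "flagged") <- flagged
  out
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of their (Blom-offset) ranks,
#' `qnorm((r - 3/8) / (n + 1/4))`, the standard transformation applied to
#' semi-quantitative metabolite levels before gene-based aggregation testing
#' so that effect sizes are in standard-deviation units. Ties receive average
#' ranks (and hence equal transformed values); missing values stay missing
#' and do not consume ranks.
#'
#' @param values numeric vector, `NA` allowed.
#' @param offset rank offset; 3/8 (Blom) by default.
#' @return numeric vector of the same length.
#' @export
inverse_normal <- function(values, offset = 3 / 8) {
  obs <- !is.na(values)
  n <- sum(obs)
  if (n == 0L) stop("all values are missing")
  if (n < 2L) stop("need at least 2 non-missing values")
  r <- rank(values[obs], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[obs] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Effective number of independent tests in a metabolite panel
#'
#' Principal-component count needed to explain a given share of the panel's
#' variance, used to correct significance thresholds for the correlation
#' between metabolites. The matrix is inverse-normal transformed per
#' metabolite and missing entries are mean-imputed (i.e. set to the
#' metabolite mean, which is variance-conservative) before the PCA.
#'
#' The returned count is the smallest number of components whose cumulative
#' explained variance reaches the threshold (evaluated with a small numeric
#' tolerance, so that exactly-attained thresholds count).
#'
#' @param x numeric samples x metabolites matrix.
#' @param variance_threshold proportion of variance to explain (default 0.95).
#' @param transform apply [inverse_normal()] per metabolite first (default
#'   `TRUE`).
#' @return integer count of components.
#' @export
effective_tests <- function(x, variance_threshold = 0.95, transform = TRUE) {
  if (!is.matrix(x) || !is.numeric(x)) stop("'x' must be a numeric matrix")
  if (variance_threshold < 0 || variance_threshold > 1)
    stop("'variance_threshold' must be in [0, 1]")
  if (transform) x <- apply(x, 2L, inverse_normal)
  # mean-imputation of residual missingness
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2L]]
  }
  vars <- apply(x, 2L, stats::var)
  if (all(vars < .Machine$double.eps))
    stop("degenerate matrix: no metabolite has positive variance")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cumvar <- cumsum(ev) / sum(ev)
  which(cumvar >= variance_threshold - 1e-9)[1L]
}

#' Multiple-testing significance threshold for gene x metabolite scans
#'
#' Nominal alpha corrected for the number of tested genes and the effective
#' number of metabolite tests: `alpha / n_genes / n_effective`. With the
#' 16,525 genes of an exome-wide scan and 600 (plasma) or 679 (urine)
#' effective metabolite components this yields 5.04e-9 and 4.46e-9.
#'
#' @param n_genes number of genes tested.
#' @param n_effective effective number of metabolite tests
#'   (see [effective_tests()]).
#' @param alpha nominal significance level (default 0.05).
#' @return the corrected threshold.
#' @examples
#' significance_threshold(16525, 600)  # 5.04e-9
#' @export
significance_threshold <- function(n_genes, n_effective, alpha = 0.05) {
  if (n_genes < 1 || n_effective < 1) stop("counts must be positive")
  if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]")
  alpha / n_genes / n_effective
}
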