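#' Encode per-sample rare-allele burden with X-chromosome dosage coding
#'
#' Sums coded qualifying-variant dosages per sample. Autosomal (and
#' X pseudo-autosomal) dosages count copies of the rare allele (0, 1, 2).
#' On the X non-pseudo-autosomal region, male calls are haploid (0, 1) and
#' are coded as (0, 2), so a hemizygous male expresses the full per-genotype
#' effect. Missing dosages are imputed by their coded expectation, 2 x MAF,
#' with allele frequencies estimated from the observed calls (sex-aware on
#' X non-PAR).
#'
#' @param genotypes numeric samples x variants matrix of raw dosages in
#'   \{0, 1, 2, NA\}; male X non-PAR entries must be haploid (0, 1, NA).
#' @param sex character/factor vector, `"male"` / `"female"`, one per sample.
#' @param chrom_class per-variant vector, one of `"autosome"`, `"X_nonPAR"`,
#'   `"X_PAR"`.
#' @return numeric vector of per-sample burden scores, with attribute
#'   `maf_hat` (estimated MAFs used for imputation).
#' @export
encode_burden <- function(genotypes, sex, chrom_class) {
  g <- as.matrix(genotypes)
  if (length(sex) != nrow(g))
    stop("'sex' must have one entry per sample")
  if (length(chrom_class) == 1L) chrom_class <- rep(chrom_class, ncol(g))
  if (length(chrom_class) != ncol(g))
    stop("'chrom_class' must have one entry per variant")
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    stop("'sex' entries must be \"male\" or \"female\"")
  if (!all(chrom_class %in% c("autosome", "X_nonPAR", "X_PAR")))
    stop("unknown chromosome class")
  male <- sex == "male"
  xnp <- chrom_class == "X_nonPAR"
  if (any(xnp)) {
    bad <- g[male, xnp, drop = FALSE] > 1
    if (any(bad, na.rm = TRUE))
      stop("diploid call for a male on X non-PAR: haploid (0/1) input required")
  }
  # allele-frequency estimates for imputation
  maf_hat <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]
    if (xnp[j]) {
      ac <- sum(x[!male], na.rm = TRUE) + sum(x[male], na.rm = TRUE)
      an <- 2 * sum(!male & !is.na(x)) + sum(male & !is.na(x))
    } else {
      ac <- sum(x, na.rm = TRUE)
      an <- 2 * sum(!is.na(x))
    }
    if (an == 0) 0 else ac / an
  }, numeric(1))
  coded <- g
  if (any(xnp)) coded[male, xnp] <- 2 * coded[male, xnp]
  if (anyNA(coded)) {
    idx <- which(is.na(coded), arr.ind = TRUE)
    coded[idx] <- 2 * maf_hat[idx[, 2L]]
  }
  out <- rowSums(coded)
  attr(out, "maf_hat") <- maf_hat
  out
}

#' Gene-based burden test of a metabolite level
#'
#' Linear-model association between a per-sample burden score and an
#' (inverse-normal transformed) phenotype, adjusting for covariates. The
#' p value is a 1-df chi-square score test of the burden term evaluated under
#' the covariate-only null fit; the effect size and standard error come from
#' the corresponding least-squares fit, so `beta` is in phenotype
#' standard-deviation units per coded rare allele. p values are carried in
#' -log10 space (`neg_log10_p`) so that extremely strong signals survive
#' floating-point underflow.
#'
#' Samples with a missing phenotype, burden or covariate are dropped
#' (complete-case per test; the count is recorded). A constant burden (no
#' carriers) yields `p = 1` with flag `"no_carriers"` rather than an error.
#'
#' @param burden numeric per-sample burden (or dosage) vector.
#' @param phenotype numeric phenotype vector, pre-transformed.
#' @param covariates optional data.frame/matrix of covariates (no intercept
#'   column; one is added). Collinear covariates are an error.
#' @param gene,metabolite,mask optional labels carried into the result.
#' @param cmaf optional cumulative MAF carried into the result.
#' @return object of class `burden_result`: list with `beta`, `se`, `p`,
#'   `neg_log10_p`, `score_stat`, `n`, `n_carriers`, `n_dropped`, `flag`
#'   and the labels.
#' @export
burden_test <- function(burden, phenotype, covariates = NULL,
                        gene = NA_character_, metabolite = NA_character_,
                        mask = NA_character_, cmaf = NA_real_) {
  g <- as.numeric(burden)
  y <- as.numeric(phenotype)
  if (length(g) != length(y)) stop("burden and phenotype lengths differ")
  X0 <- matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    X0 <- cbind(X0, cv)
  }
  keep <- stats::complete.cases(g, y, X0)
  n_dropped <- sum(!keep)
  g <- g[keep]; y <- y[keep]; X0 <- X0[keep, , drop = FALSE]
  n <- length(y)
  if (n <= ncol(X0) + 2L) stop("too few complete samples for the model")
  qr0 <- qr(X0)
  if (qr0$rank < ncol(X0)) stop("collinear covariates")
  n_carriers <- sum(g > 0)
  res <- list(gene = gene, metabolite = metabolite, mask = mask,
              cmaf = cmaf, n = n, n_carriers = n_carriers,
              n_dropped = n_dropped)
  if (stats::var(g) < .Machine$double.eps) {
    res <- c(res, list(beta = NA_real_, se = NA_real_, score_stat = 0,
                       p = 1, neg_log10_p = 0, flag = "no_carriers"))
    class(res) <- "burden_result"
    return(res)
  }
  r0 <- qr.resid(qr0, y)
  g_perp <- qr.resid(qr0, g)
  df0 <- n - qr0$rank
  sigma2_0 <- sum(r0^2) / df0
  gg <- sum(g_perp^2)
  U <- sum(g_perp * y)
  stat <- U^2 / (sigma2_0 * gg)
  log_p <- stats::pchisq(stat, df = 1, lower.tail = FALSE, log.p = TRUE)
  neg_log10_p <- -log_p / log(10)
  beta <- U / gg
  rss_full <- sum(r0^2) - beta^2 * gg
  df_full <- n - qr0$rank - 1L
  se <- sqrt(max(rss_full, 0) / df_full / gg)
  res <- c(res, list(beta = beta, se = se, score_stat = stat,
                     p = max(exp(log_p), .Machine$double.xmin),
                     neg_log10_p = neg_log10_p, flag = ""))
  class(res) <- "burden_result"
  res
}

#' @export
print.burden_result <- function(x, ...) {
  lab <- paste(stats::na.omit(c(x$gene, x$metabolite, x$mask)), collapse = " / ")
  if (nzchar(lab)) cat(lab, "\n")
  cat(sprintf("beta = %.4g (se %.4g), p = %.3g (-log10 p = %.2f), n = %d, carriers = %d%s\n",
              x$beta, x$se, x$p, x$neg_log10_p, x$n, x$n_carriers,
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.burden_result <- function(x, ...) {
  data.frame(gene = x$gene, metabolite = x$metabolite, mask = x$mask,
             beta = x$beta, se = x$se, p = x$p,
             neg_log10_p = x$neg_log10_p, n = x$n,
             n_carriers = x$n_carriers, cmaf = x$cmaf, flag = x$flag,
             stringsAsFactors = FALSE)
}

#' Single-variant association tests under additive modeling
#'
#' One [burden_test()] per dosage column; a gene with a single qualifying
#' variant gives statistics identical to its burden test. Zero-variance
#' dosages are flagged with `p = 1`.
#'
#' @param dosages samples x variants numeric matrix (coded dosages).
#' @param phenotype,covariates as in [burden_test()].
#' @return data.frame, one row per variant: `variant_id, beta, se, p,
#'   neg_log10_p, n, n_carriers, flag`.
#' @export
single_variant_test <- function(dosages, phenotype, covariates = NULL) {
  d <- as.matrix(dosages)
  ids <- colnames(d)
  if (is.null(ids)) ids <- paste0("v", seq_len(ncol(d)))
  rows <- lapply(seq_len(ncol(d)), function(j) {
    r <- burden_test(d[, j], phenotype, covariates)
    data.frame(variant_id = ids[j], beta = r$beta, se = r$se, p = r$p,
               neg_log10_p = r$neg_log10_p, n = r$n,
               n_carriers = r$n_carriers, flag = r$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Male-female difference of stratified burden effects
#'
#' Two-sample z test for equality of sex-stratified burden effect sizes,
#' `z = (beta_m - beta_f) / sqrt(se_m^2 + se_f^2)`, with a two-sided normal
#' p value. Used to test whether hemizygous males show a different (typically
#' about twofold) metabolite shift than heterozygous females for X-linked
#' genes.
#'
#' @param result_m,result_f `burden_result` objects (or lists with `beta`
#'   and `se`) fitted on disjoint male/female strata.
#' @return list with `z`, `p`, `beta_m`, `beta_f`.
#' @export
sex_stratified_difference <- function(result_m, result_f) {
  if (is.null(result_m$beta) || is.null(result_f$beta) ||
      is.na(result_m$beta) || is.na(result_f$beta))
    stop("both strata must carry a fitted effect size")
  z <- (result_m$beta - result_f$beta) /
    sqrt(result_m$se^2 + result_f$se^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       beta_m = result_m$beta, beta_f = result_f$beta)
}
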