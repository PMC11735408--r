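#' Firth penalized logistic regression for rare-variant trait association
#'
#' Logistic regression with Jeffreys-prior penalization
#' (`l*(b) = l(b) + 1/2 log det I(b)`), which keeps estimates finite under
#' the complete or quasi-complete separation that rare carriers routinely
#' produce. Newton iterations use the hat-diagonal-corrected score
#' `U*_j = sum_i (y_i - p_i + h_i (1/2 - p_i)) x_ij` with step-halving on
#' the penalized log-likelihood. The dosage term is coded additively
#' (0/1/2); Wald 95% confidence intervals and p value are the default, with
#' profile-penalized-likelihood intervals available via `ci = "profile"`.
#'
#' Associations are only fitted when at least `carrier_min` carriers are
#' present among both individuals with and without the outcome; otherwise
#' the fit is refused (unstable odds ratios).
#'
#' @param dosage numeric vector of additive genotype dosages.
#' @param outcome binary 0/1 outcome vector.
#' @param covariates optional covariate data.frame/matrix.
#' @param carrier_min minimum carriers in each outcome group (default 2).
#' @param ci `"wald"` (default) or `"profile"`.
#' @param max_iter,tol Newton iteration cap and modified-score convergence
#'   tolerance.
#' @param variant_id,trait optional labels carried into the result.
#' @return object of class `trait_association`: list with `odds_ratio`,
#'   `ci_low`, `ci_high`, `p`, `beta`, `se`, `n_carriers_case`,
#'   `n_carriers_control`, `n`, `method = "firth_additive"`, `converged`,
#'   `iterations`, plus all penalized coefficients in `coef`.
#' @export
firth_logistic <- function(dosage, outcome, covariates = NULL,
                           carrier_min = 2L, ci = c("wald", "profile"),
                           max_iter = 100L, tol = 1e-6,
                           variant_id = NA_character_, trait = NA_character_) {
  ci <- match.arg(ci)
  g <- as.numeric(dosage)
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  X <- cbind("(Intercept)" = 1, dosage = g)
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    X <- cbind(X, cv)
  }
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]; g <- g[keep]
  carriers <- g > 0
  ncc <- sum(carriers & y == 1); ncn <- sum(carriers & y == 0)
  if (ncc < carrier_min || ncn < carrier_min)
    stop(sprintf("carrier filter: %d carrier(s) with and %d without the outcome (need >= %d each)",
                 ncc, ncn, carrier_min))
  if (qr(X)$rank < ncol(X)) stop("collinear design (covariates)")
  fit <- .firth_fit(X, y, max_iter = max_iter, tol = tol)
  if (!fit$converged)
    stop("Firth fit did not converge after ", max_iter,
         " iterations (max |U*| = ", format(fit$max_score), ")")
  j <- 2L  # dosage column
  beta <- unname(fit$beta[j]); se <- unname(fit$se[j])
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  if (ci == "wald") {
    lo <- beta - stats::qnorm(0.975) * se
    hi <- beta + stats::qnorm(0.975) * se
  } else {
    pr <- .firth_profile_ci(X, y, j, fit, level = 0.95,
                            max_iter = max_iter, tol = tol)
    lo <- pr[1L]; hi <- pr[2L]
  }
  out <- list(variant_id = variant_id, trait = trait,
              odds_ratio = exp(beta), ci_low = exp(lo), ci_high = exp(hi),
              p = p, beta = beta, se = se,
              n_carriers_case = ncc, n_carriers_control = ncn,
              n = length(y), method = "firth_additive",
              converged = fit$converged, iterations = fit$iterations,
              coef = fit$beta, ci_method = ci)
  class(out) <- "trait_association"
  out
}

#' @export
print.trait_association <- function(x, ...) {
  cat(sprintf("%s: OR = %.3g (95%% CI %.3g-%.3g), p = %.3g [%s, %d/%d carriers case/control]\n",
              x$method, x$odds_ratio, x$ci_low, x$ci_high, x$p,
              x$ci_method %||% "exact", x$n_carriers_case, x$n_carriers_control))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# penalized log-likelihood
.firth_pll <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  info <- crossprod(X, X * w)
  sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(info)$modulus
}

.firth_fit <- function(X, y, max_iter = 100L, tol = 1e-6) {
  k <- ncol(X)
  beta <- numeric(k)
  pll <- .firth_pll(X, y, beta)
  it <- 0L
  max_score <- Inf
  converged <- FALSE
  repeat {
    it <- it + 1L
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    XW <- X * w
    info <- crossprod(X, XW)
    info_inv <- tryCatch(solve(info), error = function(e)
      stop("singular information matrix"))
    h <- rowSums((X %*% info_inv) * XW)
    score <- drop(crossprod(X, y - p + h * (0.5 - p)))
    max_score <- max(abs(score))
    # relative criterion: the score scales with the sample size
    score_tol <- tol * max(1, sqrt(length(y)) / 10)
    if (max_score < score_tol) { converged <- TRUE; break }
    step <- drop(info_inv %*% score)
    s <- 1
    for (half in 1:25) {
      cand <- beta + s * step
      pll_new <- .firth_pll(X, y, cand)
      if (pll_new > pll - 1e-12) break
      s <- s / 2
    }
    beta <- beta + s * step
    pll <- .firth_pll(X, y, beta)
    if (max(abs(s * step)) < 1e-10) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  info <- crossprod(X, X * w)
  se <- sqrt(diag(solve(info)))
  list(beta = stats::setNames(beta, colnames(X)), se = se,
       pll = pll, converged = converged, iterations = it,
       max_score = max_score)
}

# profile-penalized-likelihood CI for coefficient j: roots of
# 2 (pll_max - pll_profile(b)) = qchisq(level, 1)
.firth_profile_ci <- function(X, y, j, fit, level, max_iter, tol) {
  target <- fit$pll - stats::qchisq(level, 1) / 2
  prof <- function(bj) {
    Xo <- X[, -j, drop = FALSE]
    off <- X[, j] * bj
    # maximize penalized likelihood over other coefficients (full-info penalty)
    obj <- function(bo) {
      beta <- numeric(ncol(X)); beta[j] <- bj; beta[-j] <- bo
      -.firth_pll(X, y, beta)
    }
    opt <- stats::optim(fit$beta[-j], obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    -opt$value
  }
  root <- function(lo, hi) stats::uniroot(function(b) prof(b) - target,
                                          c(lo, hi), tol = 1e-6)$root
  b <- fit$beta[j]; s <- fit$se[j]
  lo_start <- b - 1e-4
  k <- 1
  while (prof(b - k * 4 * s) > target && k < 16) k <- 2 * k
  lower <- root(b - k * 4 * s, lo_start)
  k <- 1
  while (prof(b + k * 4 * s) > target && k < 16) k <- 2 * k
  upper <- root(b + 1e-4, b + k * 4 * s)
  c(lower, upper)
}

#' Fisher's exact test under dominant carrier modeling
#'
#' Two-sided conditional (hypergeometric) exact test of the 2x2
#' carrier-status x outcome table, with the sample odds ratio
#' (`ad/bc`); a 0.5 continuity correction is applied to the reported OR
#' only when a cell is zero, and flagged.
#'
#' @param carrier_status logical/0-1 vector (any rare allele carried).
#' @param outcome binary 0/1 outcome vector.
#' @return list with `odds_ratio`, `p`, `table`, `continuity_corrected`,
#'   `n_carriers_case`, `n_carriers_control`, `method = "fisher_dominant"`.
#' @export
fisher_dominant <- function(carrier_status, outcome) {
  cs <- as.integer(as.logical(carrier_status))
  y <- as.integer(outcome)
  if (!all(y %in% c(0L, 1L))) stop("outcome must be binary 0/1")
  tab <- table(factor(cs, 0:1), factor(y, 0:1))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in the 2x2 table")
  ft <- stats::fisher.test(tab)
  a <- tab[2, 2]; b <- tab[2, 1]; c_ <- tab[1, 2]; d <- tab[1, 1]
  corrected <- any(tab == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  list(odds_ratio = (a * d) / (b * c_), p = ft$p.value,
       table = tab, continuity_corrected = corrected,
       n_carriers_case = tab[2, 2], n_carriers_control = tab[2, 1],
       method = "fisher_dominant")
}

#' Allelic-series correlation of per-variant effects across two traits
#'
#' Pearson correlation of paired per-variant effect sizes (e.g. metabolite
#' effect vs anthropometric effect), quantifying a dose-response allelic
#' series. An inverse-variance weighted variant is available (non-default;
#' clearly labeled in the result).
#'
#' @param effects_a,effects_b paired numeric effect vectors (same variants,
#'   n >= 3).
#' @param weights optional positive weights (e.g. inverse variances).
#' @return list with `r`, `p` (`NA` for the weighted variant), `n`,
#'   `weighted`.
#' @export
allelic_series <- function(effects_a, effects_b, weights = NULL) {
  if (length(effects_a) != length(effects_b))
    stop("effect vectors must be paired")
  if (length(effects_a) < 3L) stop("need at least 3 variants")
  if (stats::sd(effects_a) == 0 || stats::sd(effects_b) == 0)
    stop("zero variance in an effect vector")
  if (is.null(weights)) {
    ct <- stats::cor.test(effects_a, effects_b, method = "pearson")
    return(list(r = unname(ct$estimate), p = ct$p.value,
                n = length(effects_a), weighted = FALSE))
  }
  w <- weights / sum(weights)
  ma <- sum(w * effects_a); mb <- sum(w * effects_b)
  cov <- sum(w * (effects_a - ma) * (effects_b - mb))
  r <- cov / sqrt(sum(w * (effects_a - ma)^2) * sum(w * (effects_b - mb)^2))
  list(r = r, p = NA_real_, n = length(effects_a), weighted = TRUE)
}

#' Age- and sex-specific z scores
#'
#' Inverse normal transformation within sex x age strata, so that each
#' person's value is expressed relative to peers of the same sex and
#' (pooled) age. Strata are integer years of age, greedily pooled with
#' neighboring ages (within sex) until each stratum holds at least
#' `min_stratum` individuals; a trailing small stratum is merged backwards.
#'
#' @param values numeric measurement vector (e.g. standing height).
#' @param age numeric age in years (floored to integer years).
#' @param sex `"male"`/`"female"` vector.
#' @param min_stratum minimum stratum size (default 100).
#' @return numeric z-score vector with attribute `stratum` (the sex:age-bin
#'   label per individual).
#' @export
age_sex_zscore <- function(values, age, sex, min_stratum = 100L) {
  n <- length(values)
  if (length(age) != n || length(sex) != n)
    stop("values, age and sex must be aligned")
  sex <- as.character(sex)
  yrs <- floor(age)
  stratum <- character(n)
  for (s in unique(sex)) {
    in_s <- which(sex == s)
    tb <- table(yrs[in_s])
    ages <- as.integer(names(tb))
    counts <- as.integer(tb)
    # greedy pooling into consecutive-age bins of >= min_stratum
    bin <- integer(length(ages))
    b <- 1L; acc <- 0L
    for (i in seq_along(ages)) {
      bin[i] <- b
      acc <- acc + counts[i]
      if (acc >= min_stratum && i < length(ages)) { b <- b + 1L; acc <- 0L }
    }
    if (acc < min_stratum && b > 1L) bin[bin == b] <- b - 1L
    lab <- paste0(s, ":bin", bin[match(yrs[in_s], ages)])
    stratum[in_s] <- lab
  }
  z <- rep(NA_real_, n)
  for (st in unique(stratum)) {
    idx <- which(stratum == st)
    if (sum(!is.na(values[idx])) < 2L)
      stop("stratum ", st, " unresolvable after pooling (fewer than 2 values)")
    z[idx] <- inverse_normal(values[idx])
  }
  attr(z, "stratum") <- stratum
  z
}
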