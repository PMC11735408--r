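#' Minimum-norm quadratic-programming flux distribution
#'
#' Minimizes `1/2 v' Q v` with `Q = q_diag * I` subject to steady state
#' `S v = 0` and the flux bounds. Strict convexity makes the minimizer
#' unique, which is what turns a degenerate flux cone into a single
#' representative flux distribution per (personalized) model. The scale of
#' `Q` affects only the objective value, never the argmin; the conventional
#' diagonal of 1e-6 is the default. Solved with [pracma::quadprog()];
#' infinite bounds are capped far outside the attainable flux range (the
#' minimum-norm solution never sits on such an artificial cap).
#'
#' @param model a [metabolic_model()].
#' @param q_diag diagonal of `Q` (default 1e-6).
#' @return list with `status` (`"optimal"` or `"infeasible"`), `flux`
#'   (named vector) and `objective`.
#' @export
solve_qp <- function(model, q_diag = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"))
  r <- ncol(model$S)
  cap <- .flux_cap(model)
  lb <- pmax(model$lb, -cap)
  ub <- pmin(model$ub, cap)
  sol <- tryCatch(
    pracma::quadprog(C = diag(q_diag, r), d = rep(0, r),
                     Aeq = model$S, beq = rep(0, nrow(model$S)),
                     lb = lb, ub = ub),
    error = function(e) e
  )
  if (inherits(sol, "error") || sol$eflag != 1)
    return(list(status = "infeasible", flux = NULL, objective = NA_real_,
                message = if (inherits(sol, "error"))
                  conditionMessage(sol) else "no convergence"))
  v <- stats::setNames(as.numeric(sol$xmin), colnames(model$S))
  resid <- if (nrow(model$S)) max(abs(model$S %*% v)) else 0
  if (resid > 1e-8 * max(1, max(abs(v))))
    return(list(status = "infeasible", flux = NULL, objective = NA_real_,
                message = sprintf("steady-state residual %.3g", resid)))
  list(status = "optimal", flux = v, objective = sol$fval)
}

#' Knockout effect sizes across a personalized model ensemble
#'
#' For each individual model, solves the minimum-norm QP for the wild type
#' and for the gene knockout (all gene reactions blocked), reads the urine
#' secretion flux of each reporter metabolite, and estimates the effect of
#' knockout status on `ln(secretion flux)` by fixed-effect (within-
#' individual) panel regression with the individual as the fixed effect.
#' With one wild-type and one knockout solution per individual the
#' coefficient equals the mean paired log-difference; the standard error is
#' the classical within-regression one. Individuals whose wild-type or
#' knockout QP fails are dropped pairwise. A metabolite is excluded when any
#' used flux is non-positive (no epsilon flooring, to avoid fabricating
#' signal) or when fewer than `min_pairs` solved pairs remain.
#'
#' Significance is declared at `alpha / n` where `n` is the number of
#' metabolites analyzed.
#'
#' @param models list of personalized [metabolic_model()]s (e.g. from
#'   [gen_personalized_bounds()]).
#' @param gene gene id to knock out.
#' @param metabolites reporter metabolites (default: those of the first
#'   model).
#' @param min_pairs minimum solved pairs per metabolite (default 3).
#' @param alpha family-wise alpha for the per-metabolite flag (default 0.05).
#' @return data.frame of class `ensemble_effects`: `metabolite, beta_ko, se,
#'   p, n_pairs, significant, reason` with attribute `n_analyzed`.
#' @export
ensemble_knockout <- function(models, gene,
                              metabolites = reporter_metabolites(models[[1L]]),
                              min_pairs = 3L, alpha = 0.05) {
  stopifnot(length(models) >= 1L)
  flux_of <- function(sol, model, met) {
    rx <- secretion_reaction(model, met, "urine")
    if (is.na(rx)) NA_real_ else sol$flux[[rx]]
  }
  wt_flux <- ko_flux <- matrix(NA_real_, length(models), length(metabolites),
                               dimnames = list(NULL, metabolites))
  for (i in seq_along(models)) {
    m <- models[[i]]
    wt <- solve_qp(m)
    ko <- solve_qp(knockout_model(m, gene))
    if (wt$status != "optimal" || ko$status != "optimal") next
    for (met in metabolites) {
      wt_flux[i, met] <- flux_of(wt, m, met)
      ko_flux[i, met] <- flux_of(ko, m, met)
    }
  }
  rows <- lapply(metabolites, function(met) {
    paired <- which(!is.na(wt_flux[, met]) & !is.na(ko_flux[, met]))
    base <- data.frame(metabolite = met, beta_ko = NA_real_, se = NA_real_,
                       p = NA_real_, n_pairs = length(paired),
                       significant = NA, reason = "", stringsAsFactors = FALSE)
    if (length(paired) < min_pairs) {
      base$reason <- sprintf("only %d solved pair(s)", length(paired))
      return(base)
    }
    fw <- wt_flux[paired, met]; fk <- ko_flux[paired, met]
    if (any(fw <= 0) || any(fk <= 0)) {
      base$reason <- "non-positive flux in a used pair"
      return(base)
    }
    est <- .within_estimate(fw, fk)
    base$beta_ko <- est$beta; base$se <- est$se; base$p <- est$p
    base
  })
  out <- do.call(rbind, rows)
  analyzed <- !is.na(out$beta_ko)
  n_analyzed <- sum(analyzed)
  out$significant <- ifelse(analyzed, out$p < alpha / max(n_analyzed, 1L), NA)
  attr(out, "n_analyzed") <- n_analyzed
  class(out) <- c("ensemble_effects", "data.frame")
  out
}

# within (fixed-effect) estimator for one WT and one KO observation per
# individual: demean ln-flux within individual, regress on demeaned
# knockout indicator; classical panel se with df = N - n_individuals - 1.
.within_estimate <- function(flux_wt, flux_ko) {
  n <- length(flux_wt)
  y <- c(log(flux_wt), log(flux_ko))
  x <- rep(c(0, 1), each = n)
  id <- rep(seq_len(n), 2L)
  ybar <- stats::ave(y, id)
  xbar <- stats::ave(x, id)
  yd <- y - ybar; xd <- x - xbar
  sxx <- sum(xd^2)
  beta <- sum(xd * yd) / sxx
  rss <- sum((yd - beta * xd)^2)
  df <- 2L * n - n - 1L
  se <- sqrt(rss / df / sxx)
  if (se == 0) {
    # degenerate: identical pairs everywhere
    p <- if (beta == 0) 1 else 0
  } else {
    p <- if (df > 0) 2 * stats::pt(-abs(beta / se), df) else NA_real_
  }
  list(beta = beta, se = se, p = p)
}

#' Correlate in-silico knockout effects with observed burden effects
#'
#' Pearson correlation with the standard two-sided t test, used to ask
#' whether quantitative in-silico knockout effect sizes track the observed
#' gene-metabolite association effects.
#'
#' @param insilico_betas,observed_betas paired numeric vectors (n >= 3).
#' @return list with `r`, `p`, `n`.
#' @export
correlate_effects <- function(insilico_betas, observed_betas) {
  keep <- is.finite(insilico_betas) & is.finite(observed_betas)
  x <- insilico_betas[keep]; y <- observed_betas[keep]
  if (length(x) < 3L) stop("need at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the effect vectors")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
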