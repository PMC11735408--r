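#' Solve a flux-balance linear program
#'
#' Maximizes (or minimizes) a linear objective `c'v` over the steady-state
#' flux cone: `S v = 0`, `v_l <= v <= v_u`. The simplex method of
#' [pracma::linprog()] does the pivoting on the non-negative standard form
#' (fluxes shifted by their lower bounds, upper bounds as inequality rows);
#' infinite bounds are replaced by a large cap and unboundedness is detected
#' by re-solving with a 100x larger cap and checking whether the optimum
#' moves.
#'
#' @param model a [metabolic_model()].
#' @param objective named numeric vector of reaction weights (missing
#'   reactions get weight 0), or a full-length vector in reaction order.
#' @param maximize maximize (default) or minimize.
#' @param extra_eq optional extra equality constraints as
#'   `list(A = <matrix over reactions>, b = <rhs>)`.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"` or
#'   `"error"`), `flux` (named optimal flux vector, `NULL` unless optimal)
#'   and `objective` (optimal value).
#' @export
solve_lp <- function(model, objective, maximize = TRUE, extra_eq = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  r <- ncol(model$S)
  obj <- .expand_weights(objective, colnames(model$S))
  has_inf <- !all(is.finite(model$lb)) || !all(is.finite(model$ub))
  cap <- .flux_cap(model)
  sol1 <- .lp_core(model, obj, maximize, extra_eq, cap)
  if (sol1$status != "optimal" || !has_inf) return(sol1)
  sol2 <- .lp_core(model, obj, maximize, extra_eq, 100 * cap)
  if (sol2$status == "optimal" &&
      abs(sol2$objective - sol1$objective) >
        1e-6 * (1 + abs(sol1$objective))) {
    return(list(status = "unbounded", flux = NULL, objective = NA_real_))
  }
  sol1
}

.expand_weights <- function(objective, rxn_ids) {
  r <- length(rxn_ids)
  if (!is.null(names(objective))) {
    bad <- setdiff(names(objective), rxn_ids)
    if (length(bad)) stop("objective names unknown: ",
                          paste(bad, collapse = ", "))
    obj <- stats::setNames(numeric(r), rxn_ids)
    obj[names(objective)] <- objective
    obj
  } else {
    if (length(objective) != r)
      stop("unnamed objective must have one weight per reaction")
    stats::setNames(as.numeric(objective), rxn_ids)
  }
}

.flux_cap <- function(model) {
  fin <- c(model$lb[is.finite(model$lb)], model$ub[is.finite(model$ub)])
  max(1e6, if (length(fin)) 1e3 * max(abs(fin), 1) else 1)
}

.lp_core <- function(model, obj, maximize, extra_eq, cap) {
  r <- ncol(model$S)
  lb <- pmax(model$lb, -cap)
  ub <- pmin(model$ub, cap)
  # shift to x = v - lb >= 0; upper bounds become inequality rows
  Aeq <- model$S
  beq <- as.numeric(-model$S %*% lb)
  if (!is.null(extra_eq)) {
    A <- matrix(extra_eq$A, ncol = r)
    Aeq <- rbind(Aeq, A)
    beq <- c(beq, extra_eq$b - as.numeric(A %*% lb))
  }
  cc <- if (maximize) obj else -obj
  res <- tryCatch(
    pracma::linprog(cc, A = diag(r), b = ub - lb, Aeq = Aeq, beq = beq,
                    maximize = TRUE, maxiter = 200 * (r + nrow(Aeq))),
    error = function(e) e
  )
  if (inherits(res, "error"))
    return(list(status = "error", flux = NULL, objective = NA_real_,
                message = conditionMessage(res)))
  if (!is.null(res$errno) && res$errno == -4)
    return(list(status = "infeasible", flux = NULL, objective = NA_real_))
  if (is.null(res$x) || anyNA(res$x) || res$errno != 1)
    return(list(status = "error", flux = NULL, objective = NA_real_,
                message = res$message))
  v <- stats::setNames(as.numeric(res$x) + lb, colnames(model$S))
  resid <- if (nrow(model$S)) max(abs(model$S %*% v)) else 0
  scale <- max(1, max(abs(v)))
  if (resid > 1e-8 * scale)
    return(list(status = "error", flux = NULL, objective = NA_real_,
                message = sprintf("steady-state residual %.3g too large", resid)))
  list(status = "optimal", flux = v, objective = sum(obj * v))
}

#' Wild-type flux capacity of a gene
#'
#' Maximal total flux through all reactions mapped to a gene,
#' `S_G = max sum_k v_{G_k}` over the steady-state feasible set, together
#' with the viability check `S_G > 1e-6` (can the gene's reactions carry any
#' flux at all). Genes that are not exclusively causal for their reactions
#' are refused.
#'
#' @param model a [metabolic_model()].
#' @param gene gene id.
#' @return list with `s_g`, `viable`, `status` and `flux`.
#' @export
wildtype_capacity <- function(model, gene) {
  if (is.null(model$gene_map[[gene]])) stop("unknown gene: ", gene)
  if (!gene_is_exclusive(model, gene))
    stop("gene ", gene, " is not exclusively causal for its reactions; ",
         "knockout simulation refused")
  rg <- model$gene_map[[gene]]
  sol <- solve_lp(model, stats::setNames(rep(1, length(rg)), rg))
  list(s_g = sol$objective, viable = isTRUE(sol$objective > 1e-6),
       status = sol$status, flux = sol$flux)
}

#' Maximal secretion flux of a metabolite under a gene-activity constraint
#'
#' Maximizes the urine-excretion (EX) or blood-demand (DM) flux of a
#' metabolite subject to steady state, bounds and the additional equality
#' `sum_k v_{G_k} = s_g` that pins total flux through the gene's reactions
#' at its wild-type capacity (or at 0 for a knockout). The upper bound of
#' the target excretion reaction is unbounded for the solve; for the blood
#' compartment an unbounded demand reaction is added when the model lacks
#' one.
#'
#' @param model a [metabolic_model()].
#' @param gene gene id (or `NULL` to skip the activity constraint).
#' @param metabolite reporter metabolite id.
#' @param compartment `"urine"` or `"blood"`.
#' @param s_g pinned total gene flux (usually the `s_g` from
#'   [wildtype_capacity()], or 0 under knockout).
#' @return list with `flux` (the maximal secretion), `status`, `reaction`.
#' @export
max_secretion <- function(model, gene, metabolite,
                          compartment = c("urine", "blood"), s_g = NULL) {
  compartment <- match.arg(compartment)
  rx <- secretion_reaction(model, metabolite, compartment)
  if (is.na(rx)) {
    if (compartment == "blood") {
      rx <- paste0("DM_", metabolite, "_bc")
      model <- .add_drain(model, metabolite, rx, "blood_demand")
    } else {
      stop("no urine-excretion reaction for metabolite ", metabolite)
    }
  }
  model$ub[rx] <- Inf
  extra <- NULL
  if (!is.null(gene) && !is.null(s_g)) {
    rg <- model$gene_map[[gene]]
    if (is.null(rg)) stop("unknown gene: ", gene)
    a <- stats::setNames(numeric(ncol(model$S)), colnames(model$S))
    a[rg] <- 1
    extra <- list(A = matrix(a, 1L), b = s_g)
  }
  sol <- solve_lp(model, stats::setNames(1, rx), extra_eq = extra)
  list(flux = sol$objective, status = sol$status, reaction = rx)
}

.add_drain <- function(model, metabolite, rx_id, role) {
  col <- stats::setNames(numeric(nrow(model$S)), rownames(model$S))
  col[metabolite] <- -1
  S <- cbind(model$S, col)
  colnames(S) <- c(colnames(model$S), rx_id)
  metabolic_model(S,
                  c(model$lb, 0), c(model$ub, Inf),
                  c(model$roles, role), model$gene_map)
}

#' Predict the qualitative effect of a gene knockout on metabolite secretion
#'
#' A "virtual inborn error of metabolism": compares the constrained maximal
#' secretion flux of each reporter metabolite between the wild-type model
#' (total gene flux pinned at its capacity `S_G`) and the knockout model
#' (all gene reactions blocked). The predicted sign is `no_change` when
#' `|flux_ko - flux_wt| <= max(1e-9, 1e-6 |flux_wt|)`, otherwise `increase`
#' or `decrease`. Sign decisions use optimal objective values only, never
#' the (possibly non-unique) flux vectors.
#'
#' @param model a [metabolic_model()].
#' @param gene gene id; must pass the viability check (`S_G > 1e-6`).
#' @param metabolites reporter metabolite ids (default: all metabolites with
#'   a urine-excretion reaction).
#' @param compartments which secretion compartments to simulate.
#' @return data.frame of class `knockout_prediction` with columns `gene,
#'   metabolite, compartment, flux_wt, flux_ko, sign, s_g`.
#' @export
knockout_predict <- function(model, gene,
                             metabolites = reporter_metabolites(model),
                             compartments = c("urine", "blood")) {
  wc <- wildtype_capacity(model, gene)
  if (wc$status != "optimal")
    stop("wild-type capacity LP not optimal (status ", wc$status, ")")
  if (!wc$viable)
    stop("gene ", gene, " fails the viability check (S_G = ",
         format(wc$s_g), " <= 1e-6); its reactions cannot carry flux")
  ko <- knockout_model(model, gene)
  grid <- expand.grid(metabolite = metabolites, compartment = compartments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    met <- grid$metabolite[i]; comp <- grid$compartment[i]
    wt_s <- max_secretion(model, gene, met, comp, s_g = wc$s_g)
    ko_s <- max_secretion(ko, gene, met, comp, s_g = 0)
    if (wt_s$status != "optimal" || ko_s$status != "optimal")
      stop("secretion LP failed for ", met, " (", comp, "): wt status ",
           wt_s$status, ", ko status ", ko_s$status)
    d <- ko_s$flux - wt_s$flux
    tol <- max(1e-9, 1e-6 * abs(wt_s$flux))
    sign <- if (abs(d) <= tol) "no_change" else
      if (d > 0) "increase" else "decrease"
    data.frame(gene = gene, metabolite = met, compartment = comp,
               flux_wt = wt_s$flux, flux_ko = ko_s$flux, sign = sign,
               s_g = wc$s_g, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("knockout_prediction", "data.frame")
  out
}

#' Concordance of predicted and observed effect directions
#'
#' Accuracy of qualitative knockout predictions against observed association
#' directions (the sign of the burden effect): an `increase` prediction
#' matches a positive observed effect, a `decrease` a negative one.
#' Predictions of `no_change` enter the contingency table but are excluded
#' from the accuracy numerator and denominator (both counts are reported).
#' Significance comes from the Freeman-Halton exact test on the observed x
#' predicted table (which reduces to Fisher's exact test on 2x2).
#'
#' @param predictions a [knockout_predict()] result (or data.frame with
#'   `gene`, `metabolite`, `sign`).
#' @param observed data.frame with `gene`, `metabolite` and `direction`
#'   (`"+"`/`"-"`, or a numeric effect whose sign is used).
#' @param ... passed to [freeman_halton()] (e.g. `mc_budget`, `seed`).
#' @return list with `accuracy` (percent), `n_compared`, `n_no_change`,
#'   `table`, `p`.
#' @export
concordance <- function(predictions, observed, ...) {
  pred <- as.data.frame(predictions)
  if (nrow(pred) == 0L) stop("empty prediction set")
  obs <- as.data.frame(observed)
  if (is.numeric(obs$direction))
    obs$direction <- ifelse(obs$direction > 0, "+", "-")
  if (!all(obs$direction %in% c("+", "-")))
    stop("observed directions must be \"+\" or \"-\"")
  m <- merge(pred, obs, by = c("gene", "metabolite"))
  if (nrow(m) == 0L) stop("no overlapping gene-metabolite pairs")
  called <- m$sign != "no_change"
  match_ok <- (m$sign == "increase" & m$direction == "+") |
    (m$sign == "decrease" & m$direction == "-")
  tab <- table(observed = m$direction,
               predicted = factor(m$sign,
                                  c("increase", "decrease", "no_change")))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  ft <- freeman_halton(unclass(tab), ...)
  list(accuracy = 100 * sum(match_ok[called]) / sum(called),
       n_compared = sum(called), n_no_change = sum(!called),
       table = tab, p = ft$p)
}
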