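#' Generate an analytically solvable toy metabolic network
#'
#' Small stoichiometric models whose optimal fluxes are known in closed
#' form, standing in for organ-resolved whole-body reconstructions in tests
#' and simulations. All topologies have a diet uptake reaction, urine
#' excretion (`EX_*_u`, bounds `[0, Inf)`) and a blood demand (`DM_*_bc`,
#' closed by default and opened by the secretion solver) for each reporter
#' metabolite, and a gene mapped exclusively to its reaction set:
#'
#' \describe{
#'   \item{`linear_pathway`}{chain `M1 -> ... -> Mk` fed by diet; the gene
#'     catalyzes the first step, so wild-type maximal excretion of the end
#'     product equals the uptake bound and knockout drops it to 0.}
#'   \item{`branched`}{`A -> B` (gene) competing with `A -> C`; pinning the
#'     gene's flux at capacity starves the C branch, so knockout flips the
#'     maximal excretion of C from 0 to the uptake bound (an "increase"
#'     prediction) while B drops to 0.}
#'   \item{`parallel_symmetric`}{two identical routes `A -> B` with the
#'     uptake flux forced; the minimum-norm quadratic program splits the
#'     flux 50/50 between the routes.}
#'   \item{`consumption_coupled`}{the gene consumes the diet metabolite M
#'     (`M -> P`); wild-type capacity forces consumption so maximal M
#'     excretion is 0, and knockout raises it to the uptake bound - the
#'     mechanism that lets a knockout increase a metabolite.}
#' }
#'
#' The stored analytic solution (a feasible optimal flux vector plus the
#' expected wild-type/knockout maximal urine excretions) is verified against
#' `S v = 0` and the bounds at emission; an inconsistent specification is a
#' construction error.
#'
#' @param topology one of the four topologies above.
#' @param diet_uptake_bound uptake flux bound in mmol/day (> 0).
#' @param gene gene id for the gene of interest.
#' @param n_internal_metabolites chain length for `linear_pathway` (>= 2).
#' @return a [metabolic_model()] with an extra `analytic` element:
#'   `list(topology, uptake, reporter, feasible_flux, wt_max_excretion,
#'   ko_max_excretion, qp_split)`.
#' @export
gen_toy_model <- function(topology = c("linear_pathway", "branched",
                                       "parallel_symmetric",
                                       "consumption_coupled"),
                          diet_uptake_bound = 1.0, gene = "G1",
                          n_internal_metabolites = 2L) {
  topology <- match.arg(topology)
  u <- diet_uptake_bound
  if (!is.finite(u) || u <= 0)
    stop("construction error: diet uptake bound must be positive, got ", u)
  m <- switch(topology,
    linear_pathway = {
      k <- max(2L, as.integer(n_internal_metabolites))
      mets <- sprintf("M%d", seq_len(k))
      rxn <- c("R_UP", sprintf("R_STEP%d", seq_len(k - 1L)),
               sprintf("EX_M%d_u", k), sprintf("DM_M%d_bc", k))
      S <- matrix(0, k, length(rxn), dimnames = list(mets, rxn))
      S["M1", "R_UP"] <- 1
      for (i in seq_len(k - 1L)) {
        S[i, i + 1L] <- -1; S[i + 1L, i + 1L] <- 1
      }
      S[k, length(rxn) - 1L] <- -1
      S[k, length(rxn)] <- -1
      lb <- rep(0, length(rxn))
      ub <- c(u, rep(Inf, k - 1L), Inf, 0)
      roles <- c("uptake", rep("internal", k - 1L),
                 "urine_excretion", "blood_demand")
      mod <- metabolic_model(S, lb, ub, roles,
                             stats::setNames(list("R_STEP1"), gene))
      feas <- stats::setNames(c(u, rep(u, k - 1L), u, 0), rxn)
      mod$analytic <- list(
        topology = topology, uptake = u, reporter = mets[k],
        feasible_flux = feas,
        wt_max_excretion = stats::setNames(u, mets[k]),
        ko_max_excretion = stats::setNames(0, mets[k]),
        qp_split = NULL)
      mod
    },
    branched = {
      mets <- c("A", "B", "C")
      rxn <- c("R_UP", "R_B", "R_C", "EX_B_u", "EX_C_u",
               "DM_B_bc", "DM_C_bc")
      S <- matrix(0, 3, 7, dimnames = list(mets, rxn))
      S["A", "R_UP"] <- 1
      S["A", "R_B"] <- -1; S["B", "R_B"] <- 1
      S["A", "R_C"] <- -1; S["C", "R_C"] <- 1
      S["B", "EX_B_u"] <- -1; S["C", "EX_C_u"] <- -1
      S["B", "DM_B_bc"] <- -1; S["C", "DM_C_bc"] <- -1
      mod <- metabolic_model(S, rep(0, 7),
                             c(u, Inf, Inf, Inf, Inf, 0, 0),
                             c("uptake", "internal", "internal",
                               "urine_excretion", "urine_excretion",
                               "blood_demand", "blood_demand"),
                             stats::setNames(list("R_B"), gene))
      feas <- stats::setNames(c(u, u, 0, u, 0, 0, 0), rxn)
      mod$analytic <- list(
        topology = topology, uptake = u, reporter = c("B", "C"),
        feasible_flux = feas,
        wt_max_excretion = c(B = u, C = 0),
        ko_max_excretion = c(B = 0, C = u),
        qp_split = NULL)
      mod
    },
    parallel_symmetric = {
      mets <- c("A", "B")
      rxn <- c("R_UP", "R_ROUTE1", "R_ROUTE2", "EX_B_u", "DM_B_bc")
      S <- matrix(0, 2, 5, dimnames = list(mets, rxn))
      S["A", "R_UP"] <- 1
      S["A", "R_ROUTE1"] <- -1; S["B", "R_ROUTE1"] <- 1
      S["A", "R_ROUTE2"] <- -1; S["B", "R_ROUTE2"] <- 1
      S["B", "EX_B_u"] <- -1; S["B", "DM_B_bc"] <- -1
      mod <- metabolic_model(S, c(u, 0, 0, 0, 0),
                             c(u, Inf, Inf, Inf, 0),
                             c("uptake", "internal", "internal",
                               "urine_excretion", "blood_demand"),
                             stats::setNames(list(c("R_ROUTE1", "R_ROUTE2")),
                                             gene))
      feas <- stats::setNames(c(u, u / 2, u / 2, u, 0), rxn)
      mod$analytic <- list(
        topology = topology, uptake = u, reporter = "B",
        feasible_flux = feas,
        wt_max_excretion = c(B = u),
        ko_max_excretion = c(B = NA_real_),  # knockout infeasible: uptake forced
        qp_split = stats::setNames(c(u / 2, u / 2),
                                   c("R_ROUTE1", "R_ROUTE2")))
      mod
    },
    consumption_coupled = {
      mets <- c("M", "P")
      rxn <- c("R_UP", "R_G", "EX_M_u", "EX_P_u", "DM_M_bc")
      S <- matrix(0, 2, 5, dimnames = list(mets, rxn))
      S["M", "R_UP"] <- 1
      S["M", "R_G"] <- -1; S["P", "R_G"] <- 1
      S["M", "EX_M_u"] <- -1
      S["P", "EX_P_u"] <- -1
      S["M", "DM_M_bc"] <- -1
      mod <- metabolic_model(S, rep(0, 5),
                             c(u, 10 * u, Inf, Inf, 0),
                             c("uptake", "internal", "urine_excretion",
                               "urine_excretion", "blood_demand"),
                             stats::setNames(list("R_G"), gene))
      feas <- stats::setNames(c(u, u, 0, u, 0), rxn)
      mod$analytic <- list(
        topology = topology, uptake = u, reporter = "M",
        feasible_flux = feas,
        wt_max_excretion = c(M = 0),
        ko_max_excretion = c(M = u),
        qp_split = NULL)
      mod
    })
  .verify_analytic(m)
  m
}

.verify_analytic <- function(model) {
  v <- model$analytic$feasible_flux
  if (!identical(names(v), colnames(model$S)))
    stop("construction error: analytic flux vector misaligned")
  resid <- max(abs(model$S %*% v))
  if (resid > 1e-10)
    stop("construction error: analytic solution violates steady state (|Sv| = ",
         format(resid), ")")
  if (any(v < model$lb - 1e-10) || any(v > model$ub + 1e-10))
    stop("construction error: analytic solution violates bounds")
  invisible(model)
}

#' Personalize a model ensemble by jittering exchange bounds
#'
#' Emulates between-individual (e.g. microbiome-driven) variation by
#' multiplying the bounds of every uptake-role reaction by an independent
#' lognormal factor per individual and reaction. Wild-type/knockout pairs of
#' the same individual share these bounds by construction (knockout is
#' applied afterwards via [knockout_model()]).
#'
#' @param model base [metabolic_model()].
#' @param n_individuals ensemble size.
#' @param jitter lognormal sigma of the bound multipliers (>= 0; 0 gives
#'   identical copies).
#' @param seed integer seed; same seed, same bounds.
#' @return list of `metabolic_model`s with attribute `factors`
#'   (individual x uptake-reaction matrix of multipliers).
#' @export
gen_personalized_bounds <- function(model, n_individuals, jitter = 0.3,
                                    seed = 1L) {
  stopifnot(inherits(model, "metabolic_model"))
  if (jitter < 0) stop("'jitter' must be non-negative")
  if (n_individuals < 1L) stop("need at least one individual")
  up <- names(model$roles)[model$roles == "uptake"]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  factors <- matrix(stats::rlnorm(n_individuals * length(up), 0, jitter),
                    n_individuals, length(up),
                    dimnames = list(NULL, up))
  models <- lapply(seq_len(n_individuals), function(i) {
    m <- model
    for (rx in up) {
      m$lb[rx] <- m$lb[rx] * factors[i, rx]
      m$ub[rx] <- m$ub[rx] * factors[i, rx]
    }
    m
  })
  attr(models, "factors") <- factors
  models
}
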