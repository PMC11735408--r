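#' Construct a stoichiometric metabolic model
#'
#' A constraint-based model: stoichiometric matrix `S` (metabolites x
#' reactions), flux bounds in mmol/day, per-reaction role tags and a
#' gene-to-reaction map. Reaction roles are `internal`, `uptake` (diet
#' exchange), `urine_excretion` (EX-type drain into urine) and
#' `blood_demand` (DM-type drain representing accumulation in the blood
#' compartment). The reporter metabolite of an excretion/demand reaction is
#' inferred as the metabolite it consumes.
#'
#' A gene is "exclusively causal" for its reaction set if no other gene maps
#' to any of those reactions; knockout simulation refuses non-exclusive
#' genes because blocking their reactions would confound several genes.
#'
#' @param S numeric matrix with metabolite row names and reaction column
#'   names.
#' @param lb,ub numeric flux bounds, one per reaction (named or positional);
#'   infinite bounds are allowed and handled by the solvers.
#' @param roles character vector of reaction roles.
#' @param gene_map named list: gene id -> character vector of reaction ids.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(S, lb, ub, roles, gene_map = list()) {
  S <- as.matrix(S)
  if (is.null(rownames(S)) || is.null(colnames(S)))
    stop("'S' needs metabolite row names and reaction column names")
  r <- ncol(S)
  if (length(lb) != r || length(ub) != r || length(roles) != r)
    stop("bounds/roles must have one entry per reaction")
  lb <- stats::setNames(as.numeric(lb), colnames(S))
  ub <- stats::setNames(as.numeric(ub), colnames(S))
  if (any(lb > ub)) stop("lb > ub for some reaction")
  roles <- stats::setNames(as.character(roles), colnames(S))
  ok_roles <- c("internal", "uptake", "urine_excretion", "blood_demand")
  if (!all(roles %in% ok_roles))
    stop("unknown reaction role(s): ",
         paste(setdiff(roles, ok_roles), collapse = ", "))
  if (length(gene_map)) {
    bad <- setdiff(unlist(gene_map), colnames(S))
    if (length(bad)) stop("gene_map refers to unknown reaction(s): ",
                          paste(bad, collapse = ", "))
  }
  m <- list(S = S, lb = lb, ub = ub, roles = roles,
            gene_map = lapply(gene_map, as.character))
  class(m) <- "metabolic_model"
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model: %d metabolites x %d reactions, %d gene(s)\n",
              nrow(x$S), ncol(x$S), length(x$gene_map)))
  invisible(x)
}

#' @rdname metabolic_model
#' @param model a `metabolic_model`.
#' @param gene gene id.
#' @return `gene_is_exclusive()`: logical flag.
#' @export
gene_is_exclusive <- function(model, gene) {
  rg <- model$gene_map[[gene]]
  if (is.null(rg) || !length(rg)) stop("gene ", gene, " maps to no reaction")
  others <- model$gene_map[setdiff(names(model$gene_map), gene)]
  !any(unlist(others) %in% rg)
}

#' Drain reaction of a metabolite in a compartment
#'
#' @param model a `metabolic_model`.
#' @param metabolite metabolite id.
#' @param compartment `"urine"` or `"blood"`.
#' @return reaction id, or `NA` if absent.
#' @export
secretion_reaction <- function(model, metabolite,
                               compartment = c("urine", "blood")) {
  compartment <- match.arg(compartment)
  role <- if (compartment == "urine") "urine_excretion" else "blood_demand"
  cand <- names(model$roles)[model$roles == role]
  cand <- cand[model$S[metabolite, cand] < 0]
  if (!length(cand)) return(NA_character_)
  cand[1L]
}

#' Fix all reactions of a gene to zero flux (in silico knockout)
#'
#' @param model a `metabolic_model`.
#' @param gene gene id present in the model's gene map.
#' @return the knockout `metabolic_model`.
#' @export
knockout_model <- function(model, gene) {
  rg <- model$gene_map[[gene]]
  if (is.null(rg)) stop("unknown gene: ", gene)
  model$lb[rg] <- 0
  model$ub[rg] <- 0
  model
}

#' Reporter metabolites of a model
#'
#' Metabolites that have a urine-excretion reaction.
#' @param model a `metabolic_model`.
#' @return character vector of metabolite ids.
#' @export
reporter_metabolites <- function(model) {
  ex <- names(model$roles)[model$roles == "urine_excretion"]
  mets <- unique(unlist(lapply(ex, function(rx)
    rownames(model$S)[model$S[, rx] < 0])))
  mets
}

#' Write / read a metabolic model as JSON
#'
#' Plain-text serialization:
#' `{"metabolites": [...], "reactions": [{"id", "stoich": {met: coef},
#' "lb", "ub", "role"}], "genes": {gene: [reaction ids]}}`.
#' Infinite bounds are stored as `null`.
#'
#' @param model a `metabolic_model`.
#' @param path JSON file path.
#' @return `write_model_json()`: `path` invisibly; `read_model_json()`: a
#'   `metabolic_model`.
#' @export
write_model_json <- function(model, path) {
  rxns <- lapply(colnames(model$S), function(rx) {
    st <- model$S[, rx]
    st <- st[st != 0]
    list(id = rx,
         stoich = as.list(st),
         lb = if (is.finite(model$lb[[rx]])) model$lb[[rx]] else NULL,
         ub = if (is.finite(model$ub[[rx]])) model$ub[[rx]] else NULL,
         role = model$roles[[rx]])
  })
  obj <- list(metabolites = rownames(model$S),
              reactions = rxns,
              genes = model$gene_map)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  mets <- unlist(obj$metabolites)
  rids <- vapply(obj$reactions, function(r) r$id, character(1))
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  lb <- ub <- numeric(length(rids))
  roles <- character(length(rids))
  for (i in seq_along(obj$reactions)) {
    r <- obj$reactions[[i]]
    st <- unlist(r$stoich)
    S[names(st), i] <- st
    lb[i] <- if (is.null(r$lb)) -Inf else r$lb
    ub[i] <- if (is.null(r$ub)) Inf else r$ub
    roles[i] <- r$role
  }
  gm <- lapply(obj$genes, function(g) unlist(g))
  metabolic_model(S, lb, ub, roles, gm)
}
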