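#' Leave-one-out contribution of each qualifying variant
#'
#' For every QV v of a gene, runs the burden test aggregating all QVs other
#' than v, giving `p_loo` (P_v). The contribution is `delta = P_v - P_all`
#' on the p scale: removing an influential variant weakens the signal, so a
#' large positive delta marks a strong contributor, while a negative delta
#' marks a variant whose inclusion damages the signal (neutral or
#' opposite-effect). Variants are ranked by delta in signed descending order;
#' because P_all is a per-gene constant this equals ranking by P_v, and the
#' comparison is done in -log10 space so that it remains exact for
#' arbitrarily small p. Ties are broken by larger absolute single-variant
#' effect, then lexicographically by variant id, so the ordering is
#' deterministic.
#'
#' @param dosages samples x QVs matrix of coded dosages for one gene
#'   (see [encode_burden()] for X coding); at least 2 columns.
#' @param phenotype,covariates as in [burden_test()].
#' @return object of class `variant_contributions`: data.frame with columns
#'   `variant_id, rank, p_loo, neg_log10_p_loo, delta, single_beta`, ordered
#'   by rank, with attributes `p_all` and `neg_log10_p_all`.
#' @export
contributions <- function(dosages, phenotype, covariates = NULL) {
  d <- as.matrix(dosages)
  k <- ncol(d)
  if (k < 2L) stop("need at least 2 qualifying variants")
  ids <- colnames(d)
  if (is.null(ids)) ids <- paste0("v", seq_len(k))
  full <- burden_test(rowSums(d), phenotype, covariates)
  loo <- lapply(seq_len(k), function(j) {
    r <- tryCatch(burden_test(rowSums(d[, -j, drop = FALSE]),
                              phenotype, covariates),
                  error = function(e)
                    stop("leave-one-out burden test failed for variant ",
                         ids[j], ": ", conditionMessage(e)))
    c(p = r$p, nlp = r$neg_log10_p)
  })
  p_loo <- vapply(loo, `[[`, numeric(1), "p")
  nlp_loo <- vapply(loo, `[[`, numeric(1), "nlp")
  sv <- single_variant_test(d, phenotype, covariates)
  abs_beta <- abs(sv$beta)
  abs_beta[is.na(abs_beta)] <- 0
  # greatest delta == largest P_v == smallest -log10 P_v
  ord <- order(nlp_loo, -abs_beta, ids)
  out <- data.frame(variant_id = ids[ord], rank = seq_len(k),
                    p_loo = p_loo[ord], neg_log10_p_loo = nlp_loo[ord],
                    delta = p_loo[ord] - full$p,
                    single_beta = sv$beta[ord],
                    stringsAsFactors = FALSE)
  attr(out, "p_all") <- full$p
  attr(out, "neg_log10_p_all") <- full$neg_log10_p
  class(out) <- c("variant_contributions", "data.frame")
  out
}

#' Select driver variants by forward aggregation
#'
#' Re-runs the burden test on growing prefixes of the contribution-ranked QV
#' list and designates as "driver variants" the prefix whose burden p value
#' is smallest. By default all prefixes are scanned and the global minimum
#' taken (smallest prefix on ties); `stop_at_first_rise = TRUE` instead
#' stops at the first increase of the p value, implementing the stricter
#' local-minimum reading of the procedure.
#'
#' The minimized p value is a prioritization device, not an inference p:
#' minimizing over prefixes is anti-conservative on null genes, which is why
#' `p_all` (the ordinary all-QV burden p) is always reported alongside
#' `p_min`.
#'
#' @param contrib a [contributions()] result.
#' @param dosages,phenotype,covariates the same inputs used for `contrib`.
#' @param stop_at_first_rise stop scanning at the first p-value rise.
#' @return object of class `driver_selection`: list with `ordered_variants`,
#'   `p_trajectory` (data.frame `prefix_size, variant_id, p, neg_log10_p`),
#'   `driver_set`, `p_min`, `neg_log10_p_min`, `p_all`, `neg_log10_p_all`.
#' @export
select_drivers <- function(contrib, dosages, phenotype, covariates = NULL,
                           stop_at_first_rise = FALSE) {
  stopifnot(inherits(contrib, "variant_contributions"))
  d <- as.matrix(dosages)
  ids <- colnames(d)
  if (is.null(ids)) ids <- paste0("v", seq_len(ncol(d)))
  ord_ids <- contrib$variant_id
  if (!setequal(ord_ids, ids))
    stop("contributions and dosage columns refer to different variant sets")
  k <- length(ord_ids)
  nlp <- numeric(k)
  scanned <- k
  for (i in seq_len(k)) {
    b <- rowSums(d[, ids %in% ord_ids[seq_len(i)], drop = FALSE])
    nlp[i] <- burden_test(b, phenotype, covariates)$neg_log10_p
    if (stop_at_first_rise && i > 1L && nlp[i] < nlp[i - 1L]) {
      scanned <- i
      break
    }
  }
  nlp <- nlp[seq_len(scanned)]
  best <- which.max(nlp)  # ties -> smallest prefix
  traj <- data.frame(prefix_size = seq_len(scanned),
                     variant_id = ord_ids[seq_len(scanned)],
                     p = 10^(-nlp), neg_log10_p = nlp,
                     stringsAsFactors = FALSE)
  out <- list(ordered_variants = ord_ids,
              p_trajectory = traj,
              driver_set = ord_ids[seq_len(best)],
              p_min = 10^(-nlp[best]),
              neg_log10_p_min = nlp[best],
              # same 10^-x transform as p_min so p_min <= p_all holds exactly
              p_all = 10^(-attr(contrib, "neg_log10_p_all")),
              neg_log10_p_all = attr(contrib, "neg_log10_p_all"))
  class(out) <- "driver_selection"
  out
}

#' @export
print.driver_selection <- function(x, ...) {
  cat(sprintf("driver_selection: %d/%d QVs selected; p_min = %.3g, p_all = %.3g\n",
              length(x$driver_set), length(x$ordered_variants),
              x$p_min, x$p_all))
  invisible(x)
}
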