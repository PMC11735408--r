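#' Freeman-Halton exact test for r x c contingency tables
#'
#' Exact conditional test of independence given both margins: the p value is
#' the total multivariate-hypergeometric probability of all tables with the
#' observed margins whose probability does not exceed that of the observed
#' table (with the usual small relative tolerance so that ties count). On a
#' 2x2 table this is Fisher's exact test. Tables are enumerated by
#' depth-first search; when the number of tables exceeds
#' `mc_budget` the p value is estimated by seeded Monte-Carlo sampling from
#' the null (Patefield's algorithm, [stats::r2dtable()]).
#'
#' Degenerate tables whose informative part collapses to a single row or
#' column (e.g. all predictions in one category) return `p = 1` with a
#' warning.
#'
#' @param x integer matrix of counts.
#' @param mc_budget maximum number of tables to enumerate before switching
#'   to Monte Carlo (default 1e6).
#' @param mc_samples Monte-Carlo sample count (default 1e5).
#' @param seed integer seed for the Monte-Carlo fallback.
#' @return list with `p`, `method` (`"enumeration"` or `"monte_carlo"`) and
#'   `n_tables` (tables enumerated, or samples drawn).
#' @export
freeman_halton <- function(x, mc_budget = 1e6, mc_samples = 1e5, seed = 1L) {
  x <- as.matrix(x)
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
  if (nrow(x) < 2L || ncol(x) < 2L) {
    warning("degenerate contingency table (single informative row/column); p = 1")
    return(list(p = 1, method = "degenerate", n_tables = 0L))
  }
  rs <- rowSums(x); cs <- colSums(x); n <- sum(x)
  const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  logp_obs <- const - sum(lgamma(x + 1))
  cutoff <- logp_obs + log1p(1e-7)
  enum <- .fh_enumerate(rs, cs, cutoff, budget = mc_budget, const = const)
  if (!is.null(enum))
    return(list(p = min(1, enum$p), method = "enumeration",
                n_tables = enum$n_tables))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sims <- stats::r2dtable(mc_samples, rs, cs)
  logp <- vapply(sims, function(tb) const - sum(lgamma(tb + 1)), numeric(1))
  hits <- sum(logp <= cutoff)
  list(p = (hits + 1) / (mc_samples + 1), method = "monte_carlo",
       n_tables = mc_samples)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
}

# Depth-first enumeration of tables with fixed margins; accumulates the
# probability of tables at or below the cutoff. Returns NULL if the leaf
# count exceeds the budget. The final row is forced by the column
# remainders (margin balance guarantees it sums to rs[r]).
.fh_enumerate <- function(rs, cs, cutoff, budget, const) {
  r <- length(rs); c <- length(cs)
  p_sum <- 0
  n_tables <- 0L
  overflow <- FALSE
  lg <- function(k) lgamma(k + 1)
  rec_row <- function(i, col_rem, acc_lg) {
    if (overflow) return(invisible())
    if (i == r) {
      n_tables <<- n_tables + 1L
      if (n_tables > budget) { overflow <<- TRUE; return(invisible()) }
      lp <- const - acc_lg - sum(lg(col_rem))
      if (lp <= cutoff) p_sum <<- p_sum + exp(lp)
      return(invisible())
    }
    fill <- function(j, row_rem, col_rem, acc_row) {
      if (overflow) return(invisible())
      if (j == c) {
        if (row_rem > col_rem[c]) return(invisible())
        col_rem[c] <- col_rem[c] - row_rem
        rec_row(i + 1L, col_rem, acc_lg + acc_row + lg(row_rem))
        return(invisible())
      }
      hi <- min(row_rem, col_rem[j])
      for (v in 0:hi) {
        cr <- col_rem; cr[j] <- cr[j] - v
        fill(j + 1L, row_rem - v, cr, acc_row + lg(v))
      }
      invisible()
    }
    fill(1L, rs[i], col_rem, 0)
  }
  rec_row(1L, cs, 0)
  if (overflow) return(NULL)
  list(p = p_sum, n_tables = n_tables)
}
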