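# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by different routes than the package implementation.

# straightforward PQN re-implementation: explicit loops, no sweep/apply tricks
oracle_pqn <- function(x, ref_cols) {
  ref_med <- numeric(length(ref_cols))
  for (j in seq_along(ref_cols))
    ref_med[j] <- median(x[, ref_cols[j]], na.rm = TRUE)
  out <- x
  for (i in seq_len(nrow(x))) {
    ratios <- numeric(0)
    for (j in seq_along(ref_cols)) {
      v <- x[i, ref_cols[j]]
      if (!is.na(v)) ratios <- c(ratios, v / ref_med[j])
    }
    q <- median(ratios)
    out[i, ] <- x[i, ] / q
  }
  out
}

# rank-based INT, re-derived with order statistics instead of rank()
oracle_int <- function(v) {
  obs <- which(!is.na(v))
  n <- length(obs)
  r <- numeric(n)
  for (i in seq_len(n)) {
    vi <- v[obs[i]]
    r[i] <- sum(v[obs] < vi) + (sum(v[obs] == vi) + 1) / 2
  }
  out <- rep(NA_real_, length(v))
  out[obs] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

# vertex enumeration for max c'v s.t. Sv = 0, l <= v <= u (finite bounds):
# fix (r - rank(S)) variables at a bound, solve the square system for the
# rest, keep feasible points, return the best objective.
oracle_lp_vertex <- function(S, lb, ub, obj, tol = 1e-9) {
  r <- ncol(S)
  rk <- qr(S)$rank
  nfix <- r - rk
  best <- -Inf
  if (nfix == 0L) {
    v <- qr.solve(S, rep(0, nrow(S)))
    if (all(v >= lb - tol) && all(v <= ub + tol)) best <- sum(obj * v)
    return(best)
  }
  for (B in utils::combn(r, nfix, simplify = FALSE)) {
    free <- setdiff(seq_len(r), B)
    M <- S[, free, drop = FALSE]
    if (qr(M)$rank < length(free)) next
    grid <- expand.grid(rep(list(c(1L, 2L)), nfix))
    for (gidx in seq_len(nrow(grid))) {
      vB <- ifelse(unlist(grid[gidx, ]) == 1L, lb[B], ub[B])
      rhs <- -S[, B, drop = FALSE] %*% vB
      vF <- tryCatch(qr.solve(M, rhs), error = function(e) NULL)
      if (is.null(vF)) next
      v <- numeric(r)
      v[B] <- vB; v[free] <- vF
      if (max(abs(S %*% v)) > tol * max(1, max(abs(v)))) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      best <- max(best, sum(obj * v))
    }
  }
  best
}

# exact conditional p for an r x c table by direct cell-loop enumeration
# (independent of the package's DFS): only implemented for 2 rows.
oracle_fh_2xc <- function(tab, tol = 1e-7) {
  stopifnot(nrow(tab) == 2L)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  lconst <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  lp_tab <- function(row1) {
    row2 <- cs - row1
    if (any(row2 < 0)) return(NA_real_)
    lconst - sum(lgamma(c(row1, row2) + 1))
  }
  lp_obs <- lp_tab(tab[1, ])
  cells <- lapply(seq_along(cs), function(j) 0:cs[j])
  grid <- as.matrix(expand.grid(cells))
  p <- 0
  for (i in seq_len(nrow(grid))) {
    row1 <- grid[i, ]
    if (sum(row1) != rs[1]) next
    lp <- lp_tab(row1)
    if (!is.na(lp) && lp <= lp_obs + log1p(tol)) p <- p + exp(lp)
  }
  p
}

# all permutations of 1..n (n small), as a matrix with one permutation per row
oracle_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- oracle_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

# penalized (Jeffreys) logistic log-likelihood, re-implemented plainly
oracle_firth_pll <- function(X, y, beta) {
  eta <- as.numeric(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  W <- diag(p * (1 - p), nrow = length(p))
  info <- t(X) %*% W %*% X
  sum(y * eta - log(1 + exp(eta))) + 0.5 * log(det(info))
}

# random small bounded flux model: v = 0 always feasible, bounds finite
random_toy_flux_model <- function(n_mets = 3L, n_rxns = 6L) {
  repeat {
    S <- matrix(sample(c(-1L, 0L, 0L, 1L), n_mets * n_rxns, replace = TRUE),
                n_mets, n_rxns)
    if (all(colSums(abs(S)) > 0) && all(rowSums(abs(S)) > 0)) break
  }
  dimnames(S) <- list(paste0("m", seq_len(n_mets)),
                      paste0("r", seq_len(n_rxns)))
  metabolic_model(S, lb = rep(0, n_rxns),
                  ub = runif(n_rxns, 0.5, 3),
                  roles = rep("internal", n_rxns))
}
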