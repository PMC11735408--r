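test_that("Firth fit on balanced null data gives OR near 1", {
  set.seed(71)
  x <- rep(c(0, 1), each = 100)
  y <- rep(c(0, 1, 0, 1), each = 50)
  r <- firth_logistic(x, y)
  expect_equal(r$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(r$p, 1, tolerance = 1e-6)
  expect_true(r$converged)
})

test_that("Firth estimates stay finite under complete separation", {
  x <- c(rep(0, 20), rep(1, 5))
  y <- c(rep(0, 10), rep(1, 10), rep(1, 5))
  # unpenalized ML diverges here
  ml <- suppressWarnings(glm(y ~ x, family = binomial))
  expect_gt(abs(coef(ml)["x"]), 10)
  r <- firth_logistic(x, y, carrier_min = 0)
  expect_true(is.finite(r$beta))
  expect_true(is.finite(r$ci_high))
  # matches direct maximization of the penalized likelihood
  X <- cbind(1, x)
  opt <- optim(c(0, 0), function(b) -oracle_firth_pll(X, y, b),
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  expect_lt(abs(r$beta - opt$par[2]), 1e-3)
})

test_that("Firth and ML estimates converge for common variants", {
  set.seed(72)
  n <- 40000
  x <- rbinom(n, 2, 0.15)  # ~10,000+ carriers
  y <- rbinom(n, 1, plogis(-2 + 0.4 * x))
  r <- firth_logistic(x, y)
  ml <- glm(y ~ x, family = binomial)
  expect_lt(abs(r$beta - coef(ml)["x"]) / abs(coef(ml)["x"]), 0.01)
})

test_that("profile-penalized-likelihood intervals are available behind a flag", {
  set.seed(73)
  x <- rbinom(400, 1, 0.1)
  y <- rbinom(400, 1, plogis(-1 + 1 * x))
  w <- firth_logistic(x, y, ci = "wald")
  p <- firth_logistic(x, y, ci = "profile")
  expect_equal(w$beta, p$beta)
  expect_true(p$ci_low < p$odds_ratio && p$odds_ratio < p$ci_high)
  # in regular data profile and Wald intervals roughly agree
  expect_equal(log(p$ci_low), log(w$ci_low), tolerance = 0.35)
})

test_that("the carrier-count filter refuses unstable associations", {
  x <- c(rep(0, 50), rep(1, 3))
  y <- c(rep(0, 25), rep(1, 25), 1, 1, 1)  # no carrier without disease
  expect_error(firth_logistic(x, y), "carrier filter")
  y2 <- rbinom(53, 1, 0.5) * 0 + c(rep(0, 26), rep(1, 27))
  expect_error(firth_logistic(rep(0, 53), y2), "carrier filter")
})

test_that("an odds ratio of 30 for rare carriers is recovered", {
  set.seed(74)
  n <- 100000
  carrier <- as.numeric(seq_len(n) <= 500)
  y <- gen_outcomes(carrier, log(30), baseline_prevalence = 0.01, seed = 75)
  r <- firth_logistic(carrier, as.numeric(y))
  expect_lt(abs(r$beta - log(30)), 3 * r$se)
  expect_true(r$ci_low > 1)
})

test_that("the dominant-model exact test matches the hypergeometric sum", {
  # balanced table: no association
  r <- fisher_dominant(rep(c(1, 0), each = 20),
                       rep(c(1, 0, 1, 0), each = 10))
  expect_equal(r$p, 1)
  expect_equal(r$odds_ratio, 1)
  # [[4,1],[2,8]]: enumerate the conditional distribution directly
  cs <- c(rep(1, 5), rep(0, 10))
  yy <- c(1, 1, 1, 1, 0, 0, 0, 1, 1, rep(0, 6))
  tab <- table(cs, yy)
  r2 <- fisher_dominant(cs, yy)
  m <- sum(tab[2, ]); nn <- sum(tab[1, ]); k <- sum(tab[, 2])
  probs <- dhyper(0:min(m, k), m, nn, k)
  p_manual <- sum(probs[probs <= dhyper(tab[2, 2], m, nn, k) * (1 + 1e-7)])
  expect_equal(r2$p, p_manual, tolerance = 1e-12)
  # transposition invariance of the p value
  expect_equal(fisher_dominant(yy, cs)$p, r2$p, tolerance = 1e-12)
  # cross-module consistency with the Freeman-Halton implementation
  expect_equal(freeman_halton(unclass(tab))$p, r2$p, tolerance = 1e-12)
  expect_error(fisher_dominant(rep(1, 10), rep(c(0, 1), 5)), "margin")
})

test_that("zero cells trigger a flagged continuity-corrected odds ratio", {
  cs <- c(rep(1, 4), rep(0, 16))
  yy <- c(1, 1, 1, 1, rep(0, 10), rep(1, 6))
  r <- fisher_dominant(cs, yy)
  expect_true(r$continuity_corrected)
  expect_true(is.finite(r$odds_ratio))
})

test_that("allelic series correlations follow the direct formula", {
  a <- c(-0.95, -0.60, -0.41, -0.33, -0.21, -0.10)
  b <- c(-0.080, -0.055, -0.030, -0.040, -0.015, -0.005)
  r <- allelic_series(a, b)
  rr <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r$r, rr, tolerance = 1e-12)
  # proportional effects correlate perfectly; sign flip negates r
  expect_equal(allelic_series(a, 2 * a)$r, 1)
  expect_equal(allelic_series(a, -b)$r, -r$r)
  expect_error(allelic_series(a, rep(0, 6)), "variance")
  # weighted variant is labeled and bounded
  w <- allelic_series(a, b, weights = 1 / seq(0.1, 0.6, 0.1))
  expect_true(w$weighted)
  expect_true(abs(w$r) <= 1)
})

test_that("age/sex z scores are inverse normal within pooled strata", {
  set.seed(76)
  n <- 1200
  age <- sample(40:70, n, replace = TRUE)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  h <- ifelse(sex == "male", 178, 165) + rnorm(n, 0, 7)
  z <- age_sex_zscore(h, age, sex, min_stratum = 100)
  strat <- attr(z, "stratum")
  for (st in unique(strat)) {
    idx <- strat == st
    expect_gte(sum(idx), 100)
    expect_equal(mean(z[idx]), 0, tolerance = 0.02)
    # the stratum median sits near z = 0
    med <- which.min(abs(h[idx] - median(h[idx])))
    expect_lt(abs(z[idx][med]), 0.1)
  }
  # the smallest value in a 289-person stratum has the Blom minimum score
  v <- rnorm(289)
  z289 <- age_sex_zscore(v, rep(50, 289), rep("male", 289),
                         min_stratum = 100)
  expect_equal(min(z289), qnorm((1 - 3 / 8) / (289 + 1 / 4)))
  # the same measurement maps to different z in different sexes
  hh <- c(rep(170, 1), rnorm(199, 178, 7), rep(170, 1), rnorm(199, 165, 7))
  sx <- rep(c("male", "female"), each = 200)
  zz <- age_sex_zscore(hh, rep(50, 400), sx, min_stratum = 50)
  expect_false(isTRUE(all.equal(zz[1], zz[201])))
  expect_error(age_sex_zscore(1, 50, "male", min_stratum = 10),
               "unresolvable")
})
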