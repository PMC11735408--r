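test_that("linear pathway: bottleneck at the diet uptake bound", {
  m <- gen_toy_model("linear_pathway", diet_uptake_bound = 1.0)
  sol <- solve_lp(m, c(EX_M2_u = 1))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 1.0, tolerance = 1e-9)
  # all bounds zero: the only flux vector is 0
  m0 <- m; m0$lb[] <- 0; m0$ub[] <- 0
  sol0 <- solve_lp(m0, c(EX_M2_u = 1))
  expect_equal(sol0$objective, 0)
  expect_equal(max(abs(sol0$flux)), 0)
})

test_that("solve_lp reports infeasible and unbounded statuses distinctly", {
  # forced uptake with every drain closed is infeasible
  S <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("R_UP", "R_OUT")))
  m <- metabolic_model(S, lb = c(1, 0), ub = c(1, 0),
                       roles = c("uptake", "internal"))
  expect_equal(solve_lp(m, c(R_UP = 1))$status, "infeasible")
  # a free two-cycle makes any objective on it unbounded
  S2 <- matrix(c(-1, 1, 1, -1), 2, 2,
               dimnames = list(c("A", "B"), c("R_FWD", "R_BWD")))
  m2 <- metabolic_model(S2, lb = c(0, 0), ub = c(Inf, Inf),
                        roles = c("internal", "internal"))
  expect_equal(solve_lp(m2, c(R_FWD = 1))$status, "unbounded")
})

test_that("LP optima match vertex enumeration on random small models", {
  set.seed(41)
  n_checked <- 0
  for (i in 1:30) {
    m <- random_toy_flux_model(n_mets = sample(2:3, 1), n_rxns = 6L)
    obj <- rnorm(6)
    sol <- solve_lp(m, setNames(obj, colnames(m$S)))
    best <- oracle_lp_vertex(m$S, m$lb, m$ub, obj)
    if (sol$status == "optimal" && is.finite(best)) {
      expect_equal(sol$objective, best,
                   tolerance = 1e-6 * max(1, abs(best)))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 20)
})

test_that("wild-type capacity handles sole-route, parallel and blocked genes", {
  m <- gen_toy_model("linear_pathway", diet_uptake_bound = 2.5)
  wc <- wildtype_capacity(m, "G1")
  expect_equal(wc$s_g, 2.5, tolerance = 1e-9)
  expect_true(wc$viable)
  # two-reaction gene on parallel routes: capacity is the sum of the route
  # capacities when uptake is not limiting
  S <- matrix(0, 2, 4, dimnames = list(c("A", "B"),
                                       c("R_UP", "R_1", "R_2", "EX_B_u")))
  S["A", "R_UP"] <- 1
  S["A", "R_1"] <- -1; S["B", "R_1"] <- 1
  S["A", "R_2"] <- -1; S["B", "R_2"] <- 1
  S["B", "EX_B_u"] <- -1
  mp <- metabolic_model(S, rep(0, 4), c(10, 0.75, 1.5, Inf),
                        c("uptake", "internal", "internal",
                          "urine_excretion"),
                        list(G1 = c("R_1", "R_2")))
  expect_equal(wildtype_capacity(mp, "G1")$s_g, 2.25, tolerance = 1e-9)
  # gene whose reactions are bounded to zero fails the viability check
  mz <- m; mz$ub["R_STEP1"] <- 0
  wcz <- wildtype_capacity(mz, "G1")
  expect_equal(wcz$s_g, 0)
  expect_false(wcz$viable)
  expect_error(knockout_predict(mz, "G1"), "viability")
})

test_that("non-exclusive genes are refused", {
  m <- gen_toy_model("linear_pathway")
  m$gene_map$G2 <- "R_STEP1"  # second gene on the same reaction
  expect_false(gene_is_exclusive(m, "G1"))
  expect_error(wildtype_capacity(m, "G1"), "exclusively")
})

test_that("knockout predictions cover decrease, increase and no_change", {
  # product of the only route: decrease
  kp <- knockout_predict(gen_toy_model("linear_pathway"), "G1",
                         compartments = "urine")
  expect_equal(kp$sign, "decrease")
  expect_equal(kp$flux_wt, 1, tolerance = 1e-9)
  expect_equal(kp$flux_ko, 0, tolerance = 1e-9)
  # consumption-coupled substrate: increase by the stored analytic margin
  mc <- gen_toy_model("consumption_coupled", diet_uptake_bound = 1.5)
  kpc <- knockout_predict(mc, "G1", metabolites = "M",
                          compartments = "urine")
  expect_equal(kpc$sign, "increase")
  expect_equal(kpc$flux_wt, unname(mc$analytic$wt_max_excretion["M"]),
               tolerance = 1e-9)
  expect_equal(kpc$flux_ko, unname(mc$analytic$ko_max_excretion["M"]),
               tolerance = 1e-9)
  # gene disconnected from a metabolite: no_change
  mb <- gen_toy_model("linear_pathway")
  S2 <- rbind(cbind(mb$S, R_UP2 = 0, EX_D_u = 0), D = 0)
  S2["D", "R_UP2"] <- 1
  S2["D", "EX_D_u"] <- -1
  m2 <- metabolic_model(S2,
                        c(mb$lb, 0, 0),
                        c(mb$ub, 2, Inf),
                        c(mb$roles, "uptake", "urine_excretion"),
                        mb$gene_map)
  kp2 <- knockout_predict(m2, "G1", metabolites = "D",
                          compartments = "urine")
  expect_equal(kp2$sign, "no_change")
  expect_equal(kp2$flux_wt, 2, tolerance = 1e-9)
})

test_that("knockout can only shrink secretion without the capacity equality", {
  set.seed(42)
  for (i in 1:40) {
    m <- random_toy_flux_model(n_mets = sample(2:4, 1),
                               n_rxns = sample(5:8, 1))
    target <- sample(colnames(m$S), 1)
    ko_rxns <- sample(setdiff(colnames(m$S), target),
                      sample(1:2, 1))
    wt <- solve_lp(m, setNames(1, target))
    mko <- m; mko$lb[ko_rxns] <- 0; mko$ub[ko_rxns] <- 0
    ko <- solve_lp(mko, setNames(1, target))
    expect_equal(wt$status, "optimal")
    expect_equal(ko$status, "optimal")
    expect_lte(ko$objective, wt$objective + 1e-8)
  }
})

test_that("blood demand reactions are added or opened on demand", {
  m <- gen_toy_model("consumption_coupled")
  # DM_M_bc exists but closed; blood secretion must open it
  r <- max_secretion(m, "G1", "M", "blood", s_g = 0)
  expect_equal(r$reaction, "DM_M_bc")
  expect_equal(r$flux, 1, tolerance = 1e-9)
  # P has no demand reaction: one is created on the fly
  r2 <- max_secretion(m, "G1", "P", "blood",
                      s_g = wildtype_capacity(m, "G1")$s_g)
  expect_equal(r2$reaction, "DM_P_bc")
  expect_equal(r2$flux, 1, tolerance = 1e-9)
})

test_that("toy model analytic solutions are feasible as emitted", {
  for (tp in c("linear_pathway", "branched", "parallel_symmetric",
               "consumption_coupled")) {
    m <- gen_toy_model(tp, diet_uptake_bound = 1.3)
    v <- m$analytic$feasible_flux
    expect_equal(max(abs(m$S %*% v)), 0)
    expect_true(all(v >= m$lb - 1e-12 & v <= m$ub + 1e-12))
  }
  expect_error(gen_toy_model("linear_pathway", diet_uptake_bound = 0),
               "construction error")
})

test_that("model JSON round-trips exactly", {
  m <- gen_toy_model("branched", diet_uptake_bound = 2)
  f <- tempfile(fileext = ".json")
  write_model_json(m, f)
  back <- read_model_json(f)
  expect_equal(back$S, m$S)
  expect_equal(back$lb, m$lb)
  expect_equal(back$ub, m$ub)
  expect_equal(back$roles, m$roles)
  expect_equal(back$gene_map, m$gene_map)
  unlink(f)
})
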