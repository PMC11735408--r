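test_that("cohort generation is seed-deterministic, byte for byte", {
  sp <- cohort_spec(n_samples = 300, n_genes = 3, seed = 81)
  a <- gen_cohort(sp)
  b <- gen_cohort(sp)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$metabolites, b$metabolites)
  expect_identical(a$annotations, b$annotations)
  # serialized forms agree too
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  # a different seed changes the data
  c <- gen_cohort(cohort_spec(n_samples = 300, n_genes = 3, seed = 82))
  expect_false(identical(a$genotypes, c$genotypes))
})

test_that("generated QVs are rare and Hardy-Weinberg consistent", {
  sp <- cohort_spec(n_samples = 12000, n_genes = 4, seed = 83,
                    variants_per_gene = c(5L, 10L))
  co <- gen_cohort(sp)
  expect_true(all(co$annotations$maf < 0.01))
  expect_true(all(co$annotations$maf > 0))
  # autosomal allele counts within binomial tolerance of 2*n*maf
  for (j in sample(ncol(co$genotypes), 10)) {
    maf <- co$annotations$maf[j]
    ac <- sum(co$genotypes[, j])
    expect_lt(abs(ac - 2 * 12000 * maf), 5 * sqrt(2 * 12000 * maf) + 3)
    # homozygote count consistent with maf^2 (HWE, small-count slack)
    n_hom <- sum(co$genotypes[, j] == 2)
    expect_lte(n_hom, qbinom(0.9999, 12000, maf^2) + 2)
  }
})

test_that("all synthetic QVs qualify under the masks and genes are testable", {
  co <- gen_cohort(cohort_spec(n_samples = 400, n_genes = 3, seed = 84,
                               variants_per_gene = c(6L, 10L)))
  ms <- build_mask_sets(co$annotations)
  expect_true(all(ms$genes$retained))
  # drivers are high-confidence LoF: they appear in both masks
  drv <- unlist(co$truth$drivers)
  lof_ids <- ms$sets$variant_id[ms$sets$mask == "LoF_mis"]
  hi_ids <- ms$sets$variant_id[ms$sets$mask == "HI_mis"]
  expect_true(all(drv %in% lof_ids))
  expect_true(all(drv %in% hi_ids))
})

test_that("a null cohort yields uniform burden-test p values", {
  sp <- cohort_spec(n_samples = 600, n_genes = 12,
                    effect_size_per_allele = 0, driver_fraction = 0,
                    seed = 85)
  co <- gen_cohort(sp)
  y <- inverse_normal(co$metabolites[, 1])
  ps <- sapply(unique(co$annotations$gene), function(g) {
    ids <- co$annotations$variant_id[co$annotations$gene == g]
    burden_test(encode_burden(co$genotypes[, ids, drop = FALSE], co$sex,
                              co$annotations$chrom_class[match(ids, co$annotations$variant_id)]),
                y, co$covariates)$p
  })
  expect_gt(min(ps), 1e-4)  # no spurious strong hits among 12 null genes
})

test_that("the simulated effect is recovered by regression on the true burden", {
  sp <- cohort_spec(n_samples = 5000, n_genes = 1,
                    effect_size_per_allele = 0.8, driver_fraction = 1,
                    variants_per_gene = c(8L, 8L), seed = 87,
                    maf_shape1 = 1, maf_shape2 = 50)
  co <- gen_cohort(sp)
  burden <- rowSums(co$genotypes[, co$truth$drivers$GENE1, drop = FALSE])
  # oracle: direct least squares of the phenotype on the true burden
  beta_hat <- coef(lm(co$metabolites[, 1] ~ burden +
                        scale(as.matrix(co$covariates))))["burden"]
  expect_lt(abs(beta_hat - 0.8), 0.1)
  # and the packaged burden test agrees
  r <- burden_test(encode_burden(co$genotypes[, co$truth$drivers$GENE1,
                                              drop = FALSE],
                                 co$sex, "autosome"),
                   co$metabolites[, 1], co$covariates)
  expect_lt(abs(r$beta - 0.8), 0.1)
})

test_that("X-linked effects show the hemizygote dose-response pattern", {
  sp <- cohort_spec(n_samples = 12000, n_genes = 1,
                    effect_size_per_allele = -0.5, driver_fraction = 1,
                    variants_per_gene = c(8L, 8L), x_linked_genes = 1,
                    seed = 87, covariate_effects = c(age = 0, ln_egfr = 0,
                                                     pc1 = 0, pc2 = 0,
                                                     pc3 = 0))
  co <- gen_cohort(sp)
  male <- co$sex == "male"
  carrier <- rowSums(co$genotypes[, co$truth$drivers$GENE1, drop = FALSE]) > 0
  y <- co$metabolites[, 1]
  shift_m <- mean(y[carrier & male]) - mean(y[!carrier & male])
  shift_f <- mean(y[carrier & !male]) - mean(y[!carrier & !male])
  # hemizygous male carriers shift about twice as far as heterozygous women
  expect_lt(abs(shift_m - 2 * (-0.5)), 0.15)
  expect_lt(abs(shift_f - (-0.5) * mean(rowSums(
    co$genotypes[carrier & !male, co$truth$drivers$GENE1, drop = FALSE]))),
    0.2)
  expect_gt(shift_f, shift_m)  # both negative, male more extreme
})

test_that("male X genotypes are emitted haploid and sex is ~40% female", {
  sp <- cohort_spec(n_samples = 4000, n_genes = 1, x_linked_genes = 1,
                    seed = 88)
  co <- gen_cohort(sp)
  male <- co$sex == "male"
  expect_true(all(co$genotypes[male, ] <= 1))
  expect_equal(mean(!male), 0.4, tolerance = 0.1)
})

test_that("spec validation rejects impossible parameters", {
  expect_error(cohort_spec(n_samples = 1), "at least 2")
  expect_error(cohort_spec(driver_fraction = 1.2), "driver_fraction")
  expect_error(cohort_spec(noise_sd = 0), "noise_sd")
  expect_error(cohort_spec(x_linked_genes = 99), "index")
  expect_error(cohort_spec(variants_per_gene = c(5L, 2L)), "range")
})

test_that("urine dilution is multiplicative and undone by PQN", {
  # covariate effects off: they act multiplicatively on the exponentiated
  # abundances and would be (correctly) absorbed into the quotient
  co <- gen_cohort(cohort_spec(n_samples = 200, n_genes = 2, seed = 89,
                               n_null_metabolites = 80L,
                               covariate_effects = c(age = 0, ln_egfr = 0,
                                                     pc1 = 0, pc2 = 0,
                                                     pc3 = 0)))
  ur <- gen_urine_matrix(co$metabolites, dilution_sdlog = 0.6, seed = 90)
  f <- attr(ur, "dilution")
  expect_equal(ur, exp(co$metabolites) * f, ignore_attr = TRUE)
  norm <- pqn_normalize(ur, seq_len(ncol(ur)))
  # normalized values are proportional to the undiluted abundances
  q <- attr(norm, "quotients")
  expect_gt(cor(log(q), log(f)), 0.95)
})

test_that("outcome generation follows the logistic carrier model", {
  set.seed(91)
  carrier <- rbinom(5000, 1, 0.5)
  y0 <- gen_outcomes(carrier, 0, 0.3, seed = 92)
  expect_lt(abs(mean(y0[carrier == 1]) - mean(y0[carrier == 0])), 0.05)
  y1 <- gen_outcomes(carrier, 2, 0.1, seed = 93)
  expect_gt(mean(y1[carrier == 1]), mean(y1[carrier == 0]))
  expect_identical(gen_outcomes(carrier, 2, 0.1, seed = 93), y1)
  expect_error(gen_outcomes(carrier, 0, 1.5), "prevalence")
  # no carriers at all: downstream association refuses via carrier filter
  y2 <- gen_outcomes(rep(0, 200), log(30), 0.5, seed = 94)
  expect_error(firth_logistic(rep(0, 200), as.numeric(y2)), "carrier filter")
})
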