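#' Specification of a synthetic exome-metabolomics cohort
#'
#' Parameters of the generative model used by [gen_cohort()]. Defaults mirror
#' a mid-size nephrology cohort: a few thousand participants, 40% women,
#' rare variants (MAF < 1%) with a singleton-heavy frequency spectrum drawn
#' from a truncated beta law on (1/(2n), 0.01), and per-gene qualifying
#' variants split into phenotype-driving and effectively neutral ones.
#'
#' @param n_samples number of participants (>= 2).
#' @param n_genes number of genes.
#' @param variants_per_gene inclusive range (length-2) of QV counts per gene.
#' @param maf_shape1,maf_shape2 beta shape parameters of the allele-frequency
#'   law before truncation to (1/(2 n_samples), 0.01); the default (0.3, 30)
#'   gives the singleton excess seen in empirical exomes.
#' @param driver_fraction proportion of each gene's QVs that carry the
#'   effect (the rest are neutral); per gene at least one driver whenever
#'   the fraction is positive.
#' @param effect_size_per_allele phenotype shift per coded rare allele, in
#'   residual-standard-deviation units; scalar or one value per gene.
#' @param x_linked_genes indices of genes placed on the X non-pseudo-
#'   autosomal region (male calls haploid, coded 0/2 downstream).
#' @param covariate_effects named numeric vector of effects for the
#'   standardized covariates `age`, `ln_egfr`, `pc1`, `pc2`, `pc3`.
#' @param n_null_metabolites extra metabolites with covariate structure but
#'   no genetic effect (the signal metabolite is always column `M1`).
#' @param noise_sd residual standard deviation (> 0).
#' @param female_fraction probability of being female (default 0.4).
#' @param seed integer seed; fully determines the output.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 4737L, n_genes = 20L,
                        variants_per_gene = c(4L, 16L),
                        maf_shape1 = 0.3, maf_shape2 = 30,
                        driver_fraction = 0.5,
                        effect_size_per_allele = 0.5,
                        x_linked_genes = integer(),
                        covariate_effects = c(age = 0.1, ln_egfr = -0.2,
                                              pc1 = 0.05, pc2 = 0, pc3 = 0),
                        n_null_metabolites = 4L,
                        noise_sd = 1,
                        female_fraction = 0.4,
                        seed = 1L) {
  if (n_samples < 2L) stop("need at least 2 samples")
  if (length(variants_per_gene) != 2L ||
      any(variants_per_gene < 1L) ||
      variants_per_gene[1L] > variants_per_gene[2L])
    stop("'variants_per_gene' must be an increasing range of positive counts")
  if (driver_fraction < 0 || driver_fraction > 1)
    stop("'driver_fraction' must be in [0, 1]")
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  if (female_fraction < 0 || female_fraction > 1)
    stop("'female_fraction' must be in [0, 1]")
  if (any(x_linked_genes < 1L) || any(x_linked_genes > n_genes))
    stop("'x_linked_genes' must index genes")
  beta <- rep_len(effect_size_per_allele, n_genes)
  if (driver_fraction > 0 && any(beta != 0) &&
      ceiling(driver_fraction * variants_per_gene[1L]) < 1L)
    stop("driver_fraction too small to give signal genes at least one driver")
  spec <- list(n_samples = as.integer(n_samples),
               n_genes = as.integer(n_genes),
               variants_per_gene = as.integer(variants_per_gene),
               maf_shape1 = maf_shape1, maf_shape2 = maf_shape2,
               driver_fraction = driver_fraction,
               beta_per_gene = beta,
               x_linked_genes = as.integer(x_linked_genes),
               covariate_effects = covariate_effects,
               n_null_metabolites = as.integer(n_null_metabolites),
               noise_sd = noise_sd,
               female_fraction = female_fraction,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a synthetic annotated cohort
#'
#' Draws sex, rare-variant genotypes (Hardy-Weinberg on autosomes; haploid
#' male calls on X non-PAR), a VEP-like annotation table in which driver
#' variants are high-confidence LoF and neutral variants are
#' score-qualifying missense (so all emitted variants qualify under both
#' masks), covariates, and a metabolite matrix whose first column carries
#' the genetic signal:
#' `M1 = sum_g beta_g * (coded driver burden_g) + C gamma + N(0, noise_sd^2)`.
#' Because the phenotype is built from the coded dose (male X non-PAR
#' carriers count 2), a hemizygous male shifts by twice the female
#' heterozygote shift, the dose-response signature of X-linked enzyme
#' defects.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `synthetic_cohort`: list with `genotypes` (raw
#'   dosages, male X non-PAR haploid), `annotations`, `sex`, `covariates`,
#'   `metabolites` and `truth` (per-gene effect, driver ids, MAFs).
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_samples
  sex <- ifelse(stats::rbinom(n, 1L, spec$female_fraction) == 1L,
                "female", "male")
  male <- sex == "male"
  lo <- 1 / (2 * n); hi <- 0.01
  genes <- sprintf("GENE%d", seq_len(spec$n_genes))
  k_per_gene <- spec$variants_per_gene[1L] +
    sample.int(spec$variants_per_gene[2L] - spec$variants_per_gene[1L] + 1L,
               spec$n_genes, replace = TRUE) - 1L
  ann_rows <- list(); geno_cols <- list(); truth_drivers <- list()
  for (g in seq_len(spec$n_genes)) {
    k <- k_per_gene[g]
    on_x <- g %in% spec$x_linked_genes
    chrom <- if (on_x) "X" else as.character(1L + (g - 1L) %% 22L)
    u <- stats::runif(k, stats::pbeta(lo, spec$maf_shape1, spec$maf_shape2),
                      stats::pbeta(hi, spec$maf_shape1, spec$maf_shape2))
    maf <- stats::qbeta(u, spec$maf_shape1, spec$maf_shape2)
    pos <- 1e6 * g + seq_len(k) * 100L
    ids <- sprintf("%s:%d:A:G", chrom, pos)
    n_driver <- if (spec$driver_fraction > 0 && spec$beta_per_gene[g] != 0)
      max(1L, ceiling(spec$driver_fraction * k)) else
        ceiling(spec$driver_fraction * k)
    is_driver <- seq_len(k) <= n_driver
    G <- matrix(0L, n, k, dimnames = list(NULL, ids))
    for (j in seq_len(k)) {
      if (on_x) {
        G[!male, j] <- stats::rbinom(sum(!male), 2L, maf[j])
        G[male, j] <- stats::rbinom(sum(male), 1L, maf[j])
      } else {
        G[, j] <- stats::rbinom(n, 2L, maf[j])
      }
    }
    ann_rows[[g]] <- data.frame(
      variant_id = ids, gene = genes[g], canonical = TRUE,
      chrom_class = if (on_x) "X_nonPAR" else "autosome",
      maf = maf,
      consequence = ifelse(is_driver, "stop_gained", "missense_variant"),
      lof_confidence = ifelse(is_driver, "high_confidence", "none"),
      metasvm = ifelse(is_driver, NA_real_, stats::runif(k, 0.5, 1)),
      fathmm_xf = NA_real_,
      revel = ifelse(is_driver, NA_real_, stats::runif(k, 0.6, 0.99)),
      cadd_phred = ifelse(is_driver, NA_real_, stats::runif(k, 25, 40)),
      mcap = ifelse(is_driver, NA_real_, stats::runif(k, 0.05, 0.4)),
      is_driver = is_driver,
      stringsAsFactors = FALSE)
    geno_cols[[g]] <- G
    truth_drivers[[genes[g]]] <- ids[is_driver]
  }
  genotypes <- do.call(cbind, geno_cols)
  rownames(genotypes) <- sprintf("S%05d", seq_len(n))
  annotations <- do.call(rbind, ann_rows)
  covariates <- data.frame(
    age = stats::rnorm(n, 60, 10),
    ln_egfr = stats::rnorm(n, log(45), 0.25),
    pc1 = stats::rnorm(n), pc2 = stats::rnorm(n), pc3 = stats::rnorm(n))
  Cz <- scale(as.matrix(covariates))
  gamma <- spec$covariate_effects[colnames(covariates)]
  gamma[is.na(gamma)] <- 0
  cov_part <- drop(Cz %*% gamma)
  signal <- numeric(n)
  for (g in seq_len(spec$n_genes)) {
    drv <- truth_drivers[[genes[g]]]
    if (!length(drv) || spec$beta_per_gene[g] == 0) next
    D <- genotypes[, drv, drop = FALSE]
    if (g %in% spec$x_linked_genes) D[male, ] <- 2L * D[male, ]
    signal <- signal + spec$beta_per_gene[g] * rowSums(D)
  }
  mets <- matrix(NA_real_, n, 1L + spec$n_null_metabolites,
                 dimnames = list(rownames(genotypes),
                                 sprintf("M%d", seq_len(1L + spec$n_null_metabolites))))
  mets[, 1L] <- signal + cov_part + stats::rnorm(n, 0, spec$noise_sd)
  for (j in seq_len(spec$n_null_metabolites))
    mets[, j + 1L] <- cov_part + stats::rnorm(n, 0, spec$noise_sd)
  out <- list(genotypes = genotypes, annotations = annotations,
              sex = sex, covariates = covariates, metabolites = mets,
              truth = list(genes = genes, beta_per_gene = spec$beta_per_gene,
                           drivers = truth_drivers,
                           x_linked = genes[spec$x_linked_genes],
                           maf = stats::setNames(annotations$maf,
                                                 annotations$variant_id)),
              spec = spec)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d genes, %d variants, %d metabolites\n",
              nrow(x$genotypes), length(x$truth$genes), ncol(x$genotypes),
              ncol(x$metabolites)))
  invisible(x)
}

#' Simulate a urine-like metabolite matrix with per-sample dilution
#'
#' Multiplies every metabolite of a sample by a lognormal dilution factor,
#' emulating spot-urine concentration differences, so that probabilistic
#' quotient normalization has real work to undo. Values are exponentiated
#' first (abundances are non-negative).
#'
#' @param metabolites numeric samples x metabolites matrix (e.g. from
#'   [gen_cohort()]).
#' @param dilution_sdlog lognormal sd of the per-sample dilution factor.
#' @param seed integer seed.
#' @return matrix of diluted abundances with attribute `dilution` (the true
#'   factors).
#' @export
gen_urine_matrix <- function(metabolites, dilution_sdlog = 0.5, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ab <- exp(metabolites)
  f <- stats::rlnorm(nrow(ab), 0, dilution_sdlog)
  out <- ab * f
  attr(out, "dilution") <- f
  out
}

#' Simulate binary outcomes from carrier status
#'
#' Bernoulli outcomes from a logistic model on rare-variant carrier status:
#' `logit P(Y=1) = logit(baseline_prevalence) + carrier_log_odds * carrier`.
#'
#' @param genotypes dosage matrix (carrier = any rare allele) or a
#'   logical/0-1 carrier vector.
#' @param carrier_log_odds log odds ratio for carriers.
#' @param baseline_prevalence non-carrier outcome probability, in (0, 1).
#' @param seed integer seed.
#' @return integer 0/1 outcome vector with attribute `carrier`.
#' @export
gen_outcomes <- function(genotypes, carrier_log_odds, baseline_prevalence,
                         seed = 1L) {
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1)
    stop("'baseline_prevalence' must be in (0, 1)")
  carrier <- if (is.matrix(genotypes))
    rowSums(genotypes, na.rm = TRUE) > 0 else as.logical(genotypes)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  eta <- stats::qlogis(baseline_prevalence) + carrier_log_odds * carrier
  y <- stats::rbinom(length(carrier), 1L, stats::plogis(eta))
  attr(y, "carrier") <- carrier
  y
}
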