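---
title: "Methods: rare-variant burden testing of metabolite levels and in silico knockout modeling"
author: "exomet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant burden testing of metabolite levels and in silico knockout modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomet)
```

# Overview

`exomet` implements a coupled exome-metabolomics analysis: rare, putatively
damaging variants are collected into per-gene qualifying-variant (QV) sets,
their aggregate effect on metabolite levels is estimated by burden
regression, the QVs driving each signal are isolated by forward selection,
and the implied loss of gene function is cross-examined *in silico* by
knocking the gene out of a constraint-based metabolic model and asking
whether the predicted change in the metabolite's maximal secretion flux
matches the observed association direction. A final group of routines
relates the same variants to binary clinical outcomes (penalized logistic
regression for rare carriers, exact tests, allelic-series correlations,
age/sex-standardized scores).

Everything is exercised on synthetic data with known ground truth; this
vignette documents the models, the defaults and why they were chosen, the
numerical decisions, and what the synthetic benchmarks do and do not show
about real cohort data.

# Qualifying-variant masks

Two masks encode complementary beliefs about genetic architecture. Both
restrict to canonical-transcript variants with minor allele frequency (MAF)
below 1% (strict inequality, as are all score cutoffs):

* **LoF_mis** — high-confidence loss-of-function calls, missense variants
  with MetaSVM score > 0, and in-frame nonsynonymous variants with
  fathmm-XF coding score > 0.5. "In-frame nonsynonymous" is interpreted as
  the VEP terms `inframe_insertion`, `inframe_deletion` and
  `protein_altering_variant`, the closest controlled-vocabulary reading of
  that phrase.
* **HI_mis** — high-impact consequences (transcript ablation or
  amplification, splice acceptor/donor, stop gained, frameshift, start or
  stop lost) and missense variants with REVEL > 0.5, CADD PHRED > 20 or
  M-CAP > 0.025.

A missing score never passes a cutoff: deleteriousness must be positively
evidenced, and only by the scores named for that mask (no cross-mask
rescue). A gene is retained for testing when it holds **more than three**
QVs in at least one mask; both masks of a retained gene are emitted, since
a mask with fewer QVs is still a valid aggregation unit once the gene is
testable. High-confidence LoF variants with high-impact consequences
intentionally appear in both masks.

# Metabolite preprocessing

**Probabilistic quotient normalization** (`pqn_normalize`) corrects urine
dilution: for each sample, the quotient is the median ratio between its
values and a reference spectrum over caller-selected, well-measured
reference metabolites (< 1% missing), and the whole sample is divided by
it. The reference spectrum is the per-metabolite median across samples —
the canonical choice where only the reference *set* is prescribed. Samples
with an undefined or non-positive quotient are flagged and left untouched
rather than silently rescaled.

**Inverse normal transformation** (`inverse_normal`) maps ranks to normal
quantiles with the Blom offset, `qnorm((r - 3/8)/(n + 1/4))`; Blom is the
common biobank convention where no offset is named. Ties get average ranks,
missing values stay missing, and downstream burden effects are therefore in
standard-deviation units.

**Effective number of tests** (`effective_tests`) is the smallest number of
principal components explaining at least the target share (default 95%) of
the panel's variance, computed on the transformed, mean-imputed matrix
(mean imputation is variance-conservative). The threshold comparison uses a
1e-9 tolerance so that a cumulative share that attains the threshold
exactly (as with equal eigenvalues) is counted; this also fixes the
boundary convention `threshold = 0 -> 1 component`. With 16,525 genes and
600 (plasma) or 679 (urine) effective tests,
`significance_threshold(16525, 600)` gives 5.04e-9 and
`significance_threshold(16525, 679)` gives 4.46e-9. Whether the effective
count should come from the tested matrix or a larger panel is left to the
caller: it is an explicit argument, so either convention is reproducible.

# Burden association

`encode_burden` codes autosomal dosages as rare-allele copies (0, 1, 2).
On the X non-pseudo-autosomal region male calls are haploid in the input
and coded (0, 2), so a hemizygous male expresses the full per-genotype
effect — the mechanism by which X-linked genes act as a readout of variant
homozygosity. Missing dosages are imputed by the coded expectation
2 x MAF (estimated sex-aware from the observed calls), which keeps carrier
counts conservative. QVs are unweighted: no weighting scheme is prescribed
for the aggregation, and flat weights match the default of standard
aggregation tools.

`burden_test` regresses the (pre-transformed) phenotype on the per-sample
QV sum with covariates. The p value is a 1-df chi-square **score test**
evaluated under the covariate-only null fit; effect and standard error come
from the matching least-squares fit. Score and Wald p agree asymptotically
(a property test checks 10% agreement in -log10 units at n >= 1000), but
the score form is the one used by the aggregation tools this mirrors. All p
values are carried in -log10 space so that signals far below the smallest
representable double survive; `p` itself is floored at the smallest
positive double. Samples missing a phenotype, dosage or covariate are
dropped per test and counted (complete-case; the dropping rule is not
prescribed anywhere, so it is at least explicit here). A gene with no
carriers returns p = 1 with a `no_carriers` flag rather than an error,
and perfectly collinear covariates are a hard error.

Sex-stratified effects are compared with
`z = (beta_m - beta_f) / sqrt(se_m^2 + se_f^2)` on disjoint strata.

# Driver-variant forward selection

For each QV *v*, `contributions` runs the burden test on all QVs except
*v*, giving `P_v`, and the contribution `delta_v = P_v - P_all`. Since
`P_all` is constant within a gene, ranking by `delta_v` equals ranking by
`P_v`; the comparison happens in -log10 space, so the ordering remains
exact for arbitrarily extreme p. Ranking is **signed** descending — a
negative `delta_v` marks a variant whose inclusion damages the signal, and
such variants belong at the end; ranking by absolute value was rejected
because it would promote signal-damaging variants. Ties (e.g. duplicated
dosage columns) are broken by larger absolute single-variant effect, then
lexicographic variant id, making the procedure deterministic and
order-independent.

`select_drivers` then re-tests every prefix of the ranking and designates
the prefix with the smallest burden p as the driver set (smallest prefix on
ties). The stopping rule in the source description is ambiguous ("until the
lowest P value is reached"); the default scans **all** prefixes and takes
the global minimum, with `stop_at_first_rise = TRUE` implementing the
local-minimum reading. Because the full QV set is itself a prefix,
`p_min <= p_all` always — and both are computed through the same
`10^(-log10 p)` transform so the inequality holds to the last bit.

`p_min` is a prioritization device, not an inference p: minimizing over
prefixes is anti-conservative on null genes, which is why `p_all` is
always reported alongside.

# In silico knockouts: linear programming

A `metabolic_model` is a stoichiometric matrix with flux bounds (mmol/day),
role tags (`uptake`, `internal`, `urine_excretion` EX-type,
`blood_demand` DM-type) and a gene-to-reaction map. Knockout simulation is
restricted to genes **exclusively causal** for their reactions — if another
gene shares a reaction, blocking it would confound the two, so such genes
are refused.

All linear programs have the flux-balance form: optimize a linear
objective subject to steady state `S v = 0` and bounds. The wild-type
capacity of gene *G* is `S_G = max sum_k v_Gk`; a gene passes the viability
check if `S_G > 1e-6` (its reactions can carry flux at all). Maximal
secretion of metabolite *M* is then the maximum of the EX (urine) or DM
(blood) flux under the **additional equality** `sum_k v_Gk = S_G`, with the
EX upper bound opened for the solve and a DM reaction added (unbounded)
when the model lacks one. The knockout run blocks all gene reactions
(bounds 0) and repeats the same maximization; the equality is then trivially
`= 0`. Pinning the wild type at full capacity is what makes *increase*
predictions possible: a gene that consumes its substrate holds wild-type
excretion down, and removing it releases the substrate (the
`consumption_coupled` toy topology isolates exactly this mechanism).
Without the pin, knockout can only shrink the feasible set, so knockout
secretion can never exceed wild type — a property asserted on 200 random
networks.

Sign calls use optimal objective *values* only, never the (possibly
non-unique) flux vectors: `no_change` iff
`|flux_ko - flux_wt| <= max(1e-9, 1e-6 |flux_wt|)`, mirroring the 1e-6
viability epsilon since no explicit tolerance is prescribed.

Numerically, LPs are solved with `pracma::linprog` on the shifted
non-negative form (fluxes minus lower bounds; upper bounds as inequality
rows). Infinite bounds are replaced by a cap far outside the attainable
range, and unboundedness is detected by re-solving with a 100x larger cap:
if the optimum moves, the program is reported `unbounded`, distinctly from
`infeasible`. Optima are verified against a vertex-enumeration oracle on
all small fixtures (<= 6 reactions) to 1e-6 relative, and every solution is
checked for a steady-state residual below 1e-8 (scaled).

Concordance between predicted signs and observed association directions
(sign of the burden beta) is summarized as accuracy over the pairs with a
called direction; `no_change` predictions enter the contingency table but
are excluded from the accuracy numerator and denominator, with both counts
reported, since the reference analysis does not state which convention it
used. Significance comes from the Freeman-Halton exact test: full
enumeration of tables with fixed margins, with a seeded Monte-Carlo
fallback (Patefield sampling) above an enumeration budget; on 2x2 tables it
reduces exactly to Fisher's test. Degenerate tables (a single informative
row or column) return p = 1 with a warning rather than failing, so a run
in which every prediction lands in one category still completes.

# In silico knockouts: quadratic programming

Where the LP gives qualitative capacity answers, the minimum-norm QP gives
one *representative* flux distribution per model: minimize `1/2 v'Qv` with
`Q = 1e-6 I` under the same constraints. Strict convexity makes the
minimizer unique; the scale of `Q` moves only the objective value, never
the argmin (asserted numerically), and 1e-6 is the conventional diagonal.
Solved with `pracma::quadprog`; infeasible knockouts (e.g. a blocked sole
route with forced uptake) are reported as such and dropped pairwise, just
as unsolved personalized models are in practice.

`gen_personalized_bounds` emulates between-individual variation by
multiplying every uptake-role bound by an independent lognormal factor per
individual and reaction — a deliberately minimal stand-in for
microbiome-personalized models, which are out of scope. Wild-type and
knockout share an individual's bounds by construction.

`ensemble_knockout` estimates the effect of knockout status on
`ln(urine secretion flux)` by a within-individual fixed-effect panel
regression (the individual is the fixed effect). With one wild-type and one
knockout solve per individual, the coefficient equals the mean paired
log-difference exactly (verified against a general `lm` fixed-effects
oracle to machine precision); the standard error is the classical within
formula with `N - n_individuals - 1` degrees of freedom — no robust
correction, as none is prescribed. A metabolite is excluded when *any* used
flux is non-positive (no epsilon flooring: flooring would fabricate
signal), or when fewer than 3 solved pairs remain. Per-metabolite
significance is declared at `0.05 / n_metabolites_analyzed`, and the panel
regression is run per metabolite (the per-metabolite threshold convention
implies per-metabolite models). In-silico effect sizes are compared with
observed burden effects by a Pearson correlation t test.

For effect-recovery benchmarks the four analytic topologies are
insufficient — their knockouts are all-or-nothing, and a log flux of an
exactly zero flux is undefined. The benchmark model therefore feeds one
metabolite from two sources, diet `u` and a gene-controlled influx
`u (e^{1.2} - 1)`, so knockout multiplies the excretion flux by exactly
`e^{-1.2}` in the unperturbed model; with lognormal personalization
(sigma 0.3) the ensemble estimate recovers -1.2 within 0.1 at 500
individuals (and tends to the single-model log ratio as sigma tends to 0).

# Clinical readouts

**Firth regression** (`firth_logistic`) fits the logistic model with the
Jeffreys-prior penalty `l*(b) = l(b) + 1/2 log det I(b)`, Newton steps on
the hat-corrected modified score with step-halving, additive dosage coding.
Estimates remain finite under the complete separation that rare carriers
routinely produce (verified against direct maximization of the penalized
likelihood, and against plain ML convergence at common allele
frequencies). Convergence uses a sample-size-relative score tolerance plus
a parameter-plateau stop — an absolute score cutoff is meaningless when the
score scales with n. Wald 95% intervals are the default (the common
default); profile-penalized-likelihood intervals sit behind
`ci = "profile"`. Associations require at least two carriers among both
individuals with and without the outcome; anything less is refused, not
estimated. The sex x age covariate, where used, is the raw product of the
supplied columns (no centering).

**`fisher_dominant`** tests the 2x2 carrier-by-outcome table with the
conditional hypergeometric two-sided p (via `stats::fisher.test`) and
reports the *sample* odds ratio, continuity-corrected by 0.5 only when a
cell is zero and flagged as such. Its p matches the package's
Freeman-Halton implementation on 2x2 tables — a deliberate cross-module
consistency check.

**`allelic_series`** correlates per-variant effect sizes across two traits
(Pearson, t test); an inverse-variance weighted variant exists but is
non-default and labeled in the output, because the reference quantity is
the unweighted correlation.

**`age_sex_zscore`** inverse-normal transforms within sex x age strata.
Strata are integer years greedily pooled (within sex, in age order) until
each holds at least 100 individuals by default, with a trailing small
stratum merged backwards; no stratification scheme is prescribed, so the
pooling is explicit and configurable.

# Synthetic cohorts

`gen_cohort` draws, from a single seed that fully determines the output:

* **Sex**: Bernoulli with 40% women, matching the cohort structure being
  emulated.
* **MAFs**: a beta(0.3, 30) law truncated to `(1/(2n), 0.01)` — an
  invented stand-in (the empirical QV spectrum is not published beyond
  MAF < 1%) whose singleton excess resembles empirical exomes.
* **Genotypes**: Hardy-Weinberg binomials on autosomes; on X non-PAR,
  females are binomial(2) and males binomial(1), *emitted haploid* — the
  (0, 2) coding is applied by `encode_burden`, and the phenotype is built
  from the coded dose, which is what produces the hemizygote 2x
  dose-response.
* **Annotations**: driver variants are stop-gained/high-confidence LoF
  (qualifying under both masks); neutral variants are missense with
  scores drawn above the cutoffs, so they are genuine QVs that dilute the
  signal — exactly the situation forward selection is meant to resolve.
* **Phenotype**: `M1 = sum_g beta_g (coded driver burden) + C gamma +
  N(0, noise_sd^2)`, with standardized covariates (age, ln eGFR, three
  genetic PCs); further metabolites carry only covariate structure.
* **Urine**: `gen_urine_matrix` exponentiates abundances and multiplies
  each sample by a lognormal dilution factor, giving PQN real work to do.

Default scale is 4,737 participants and 20 genes with 4-16 QVs each;
benchmarks state their own sizes (calibration: n = 1,000 with 5 covariates,
2,000 null replicates; recovery: n = 5,000; X dose-response: n = 12,000;
ensembles: 500 individuals; the personalization writer also reproduces the
569-model ensemble scale).

What passing these benchmarks shows: the estimators are unbiased and
calibrated *under the generating model*. What they cannot show: robustness
to linkage disequilibrium, realistic metabolite correlation structure,
population stratification, batch effects or genotyping error — none of
which the generator attempts to emulate (deliberately: ground truth must
stay analytic).

# Numerical choices, degenerate inputs, limitations

* p values: -log10 bookkeeping everywhere beyond the burden test's own
  floor; exact-test p in (0, 1] by construction.
* LP/QP: caps at `max(1e6, 1000 x largest finite bound)`; steady-state
  residual checks at 1e-8 scaled; sign tolerance `max(1e-9, 1e-6 |wt|)`.
* Degenerate inputs that return flagged results instead of errors:
  no-carrier burden (p = 1), zero-variance single variants, degenerate
  contingency tables (p = 1 + warning), non-positive PQN quotients
  (sample flagged, untouched), non-positive ensemble fluxes (metabolite
  excluded with reason).
* Hard errors: collinear covariates, non-exclusive genes, viability
  failures, empty reference sets, carrier-filter violations, female-coded
  diploid inconsistencies on male X input.
* Known limitations: the toy networks have no organ structure, coupling
  constraints or curated diet, so accuracies computed on them are
  mechanism demonstrations, not whole-body predictions; the burden test
  assumes concordant effect directions (by design — that is the LoF
  model); no kinship correction (cohorts are assumed relatedness-pruned
  upstream); SKAT-type dispersion tests are out of scope.

# Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates every
synthetic input, runs the full pipeline and writes the headline quantities
(thresholds, calibration, recovery, oracle agreement) as JSON. The test
suite (`testthat::test_dir("tests/testthat")`) runs the same checks plus
the per-module unit and property tests.
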