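# exomet

Rare-variant burden testing of metabolite levels, driver-variant forward
selection, and in silico gene-knockout flux modeling — the statistical and
constraint-based machinery for asking whether rare, damaging, mostly
heterozygous variants seen in a population cohort carry the same
information about a gene's function as its full loss would (a "virtual
inborn error of metabolism").

## Who this is for

Statistical geneticists and systems biologists working with paired
exome-sequencing and metabolomics data who need, in one place:

* **QV masks** — classify annotated variants into `LoF_mis`
  (high-confidence LoF; missense with MetaSVM > 0; in-frame nonsynonymous
  with fathmm-XF > 0.5) and `HI_mis` (high-impact consequences; missense
  with REVEL > 0.5, CADD PHRED > 20 or M-CAP > 0.025), all at MAF < 1% on
  canonical transcripts, keeping genes with > 3 QVs in some mask.
* **Burden tests** — score-test regression of inverse-normal metabolite
  levels on the per-gene QV sum with covariate adjustment, male X non-PAR
  dosages coded (0, 2), single-variant tests, sex-stratified comparison
  `z = (β_m − β_f)/√(se_m² + se_f²)`.
* **Driver selection** — leave-one-out contributions Δ_v = P_v − P_all,
  signed ranking, and the prefix of the ranking minimizing the burden p.
* **Virtual IEMs** — for a gene G with reactions R_G in a stoichiometric
  model: wild-type capacity `S_G = max Σ v_Gk` s.t. `Sv = 0`,
  `v_l ≤ v ≤ v_u`; maximal urine/blood secretion of a metabolite under
  `Σ v_Gk = S_G`; knockout (`v_Gk = 0`) re-solve; sign prediction and
  Freeman–Halton exact concordance testing. Minimum-norm flux
  distributions (`min ½v'Qv`, `Q = 10⁻⁶ I`) across personalized model
  ensembles, with within-individual fixed-effect estimation of knockout
  effects on ln(secretion flux).
* **Clinical readouts** — Firth penalized logistic regression (finite
  under separation), dominant-model exact tests, allelic-series Pearson
  correlations, age/sex-specific z scores.
* **Synthetic data** — seed-deterministic cohorts (rare-variant
  genotypes with driver/neutral structure, X hemizygosity, covariates,
  urine dilution), analytically solvable toy metabolic networks, and
  personalized bound ensembles, so every estimator can be checked against
  known truth.

## Worked example

```r
library(exomet)

spec <- cohort_spec(n_samples = 3000, n_genes = 2,
                    effect_size_per_allele = c(-0.6, 0),
                    driver_fraction = 0.5, variants_per_gene = c(8L, 12L),
                    seed = 11)
cohort <- gen_cohort(spec)

masks <- build_mask_sets(cohort$annotations)
masks
#> gene_mask_sets: 2 gene(s) retained, 0 dropped, 0 variant(s) skipped

qvs  <- masks$sets$variant_id[masks$sets$gene == "GENE1" &
                              masks$sets$mask == "HI_mis"]
geno <- cohort$genotypes[, qvs]
cls  <- cohort$annotations$chrom_class[match(qvs, cohort$annotations$variant_id)]
y    <- inverse_normal(cohort$metabolites[, "M1"])

burden <- encode_burden(geno, cohort$sex, cls)
burden_test(burden, y, cohort$covariates,
            gene = "GENE1", metabolite = "M1", mask = "HI_mis")
#> GENE1 / M1 / HI_mis
#> beta = -0.4068 (se 0.07255), p = 2.41e-08 (-log10 p = 7.62), n = 3000, carriers = 163

ct  <- contributions(geno, y, cohort$covariates)
select_drivers(ct, geno, y, cohort$covariates)
#> driver_selection: 5/8 QVs selected; p_min = 1.36e-12, p_all = 2.41e-08

model <- gen_toy_model("consumption_coupled")
knockout_predict(model, "G1", metabolites = "M", compartments = "urine")
#>   gene metabolite compartment flux_wt flux_ko     sign s_g
#> 1   G1          M       urine       0       1 increase   1
```

Reading the output: the gene carries a true per-allele effect of −0.6
diluted by neutral QVs; the all-QV burden beta is −0.41 s.d. per coded
allele (p = 2.4e-08). Forward selection keeps 5 of 8 QVs and drops the
burden p by four orders of magnitude to 1.4e-12 — the driver set, of which
80% are the truly simulated causal variants. The knockout prediction shows
the mechanism by which a gene *knockout* can **increase** a metabolite:
the gene consumes its substrate, wild-type capacity pins consumption at
maximum (maximal excretion 0), and blocking the gene releases the full
diet influx (1 mmol/day) into urine.

The exome-wide significance thresholds reproduce their printed values:

```r
significance_threshold(16525, 600)   # 5.04e-09 (plasma)
significance_threshold(16525, 679)   # 4.46e-09 (urine)
```

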