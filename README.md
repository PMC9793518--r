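# archivalgeno

Germline genotyping evaluation from archival-tissue low-coverage WGS, and
an incidence-reweighted survival analysis of polygenic risk in pre-cancer
cohorts.

## The problem

Retrospective genetic studies of slowly progressing disease (the motivating
case is ductal carcinoma in situ, DCIS, and its breast-cancer subsequent
events) rarely have banked blood: the only germline DNA source is the
archived FFPE diagnostic specimen. Low-coverage whole-genome sequencing
(lc-WGS, < 1x) plus statistical imputation can recover genome-wide
genotypes from such tissue, but its output must be validated against
blood-derived truth before any downstream inference is trusted. This
package provides the evaluation machinery for that validation and the
downstream use-case statistics, for statistical geneticists and
biostatisticians working with paired blood/tissue panels:

* **Dosage concordance.** For paired panels, the aggregate squared Pearson
  correlation r² of imputed allele dosages per sample within minor-allele
  frequency (MAF) bins, with percentile-bootstrap 95% CIs (1000 resamples
  of variants), a minimum of 1000 SNPs per reported cell, and
  stratification by imputation quality (INFO-style score > 0.80) and by
  the copy-number state (neutral / gain / loss) of the variant's segment.
* **Polygenic risk scores.** PRS = Σᵢ βᵢ xᵢ over the sites of a
  PGS-Catalog-style weight file, where βᵢ is the per-allele log odds ratio
  and xᵢ ∈ [0,2] the imputed dosage of the effect allele; scores are
  z-normalized within the analysis cohort, missing sites are skipped and
  reported as coverage, never mean-imputed.
* **HLA concordance.** 2- and 4-field allele agreement between imputed and
  clinical gold-standard typings, scored as a maximum matching of
  unordered allele pairs, summarized per class (I = A/B/C, II =
  DRB1/DQB1), with posterior-probability comparison between perfect and
  error-carrying calls.
* **Copy-number burden.** Segment classification (gain: log₂ ratio > 0.3,
  loss: < −0.3, artifact: < −15), genomic burden = altered length / total
  length, and burden-tertile imputation of missing nuclear grade.
* **Weighted survival model.** A Cox proportional-hazards model fitted
  from first principles — Newton–Raphson on the weighted Breslow log
  partial likelihood with step-halving, robust (sandwich) variance from
  weighted score residuals — with case-control reweighting to a stated
  population incidence (cases weight 1, controls 1/p), Breslow baseline
  hazard and PRS-percentile survival curves, Harrell's C-index by pairwise
  enumeration, scaled-Schoenfeld PH diagnostics, Fisher's exact test by
  hypergeometric enumeration, and the Li–Ji effective number of tests
  (m_eff = Σ [I(λᵢ ≥ 1) + (λᵢ − ⌊λᵢ⌋)]) for Bonferroni q-values over
  correlated PRS models.

A synthetic-data module generates every input with the qualitative error
structure real lc-WGS imputation exhibits — dosage error growing as MAF
and coverage shrink and in copy-loss regions — so the full pipeline is
testable without access to restricted patient data.

## Worked example

```r
library(archivalgeno)

cfg <- dosage_sim_config(n_variants = 20000, n_samples = 4,
                         coverage = 0.7, error_scale = 0.15, seed = 42)
truth <- simulate_true_genotypes(cfg)
profiles <- setNames(lapply(1:4, function(i)
  simulate_cn_profile(0.05, 0.15, seed = 42 + i)),
  colnames(truth$genotypes))
cfg$cn_profile <- profiles
panels <- simulate_imputed_dosages(truth, cfg)   # blood-like + tissue-like

conc <- binned_concordance(panels$blood, panels$tissue,
                           bins = c(0.0005, 0.01, 0.1, 0.5),
                           segments = profiles[["S01"]],
                           min_snps = 500, n_boot = 200, seed = 42)
summ <- summarize_binned_concordance(conc)
summ[summ$stratum %in% c("high_quality", "loss", "neutral"), ]
#>    maf_lo maf_hi      stratum n_samples mean_r2
#> 7   5e-04   0.01 high_quality         0      NA
#> 8   1e-02   0.10 high_quality         4   0.635
#> 9   1e-01   0.50 high_quality         4   0.881
#> 12  1e-01   0.50         loss         4   0.861
#> 14  1e-02   0.10      neutral         4   0.634
#> 15  1e-01   0.50      neutral         4   0.885
```

Concordance rises with MAF, the rare-variant cell is suppressed by the
1000-SNP (here 500) rule, and copy-loss regions are less concordant than
copy-neutral ones — the structure the evaluation is designed to expose.

The survival use case, on a simulated outcome-enriched cohort with a true
hazard ratio of 2 per SD of PRS:

```r
co <- simulate_cohort(cohort_sim_config(n_patients = 300,
                                        true_log_hr_per_sd = log(2),
                                        control_fraction = 0.3, seed = 42))
cw <- control_weight(sum(co$event), sum(!co$event), incidence = 0.15)
cw$control_weight
#> [1] 6.166667
X <- cbind(prs = zscore(co$prs), grade = co$grade, size = co$size_cm,
           age = age_band_midpoint(co$age_group) / 10,
           ancestry = as.numeric(co$european_ancestry))
fit <- fit_weighted_cox(co$time, co$event, X,
                        weights = ifelse(co$event, 1, cw$control_weight))
fit
#> weighted Cox fit: n = 142, events = 74, converged in 5 iteration(s)
#>   covariate    coef    hr se_robust hr_lo hr_hi      z        p
#> 1       prs  0.7023 2.018     0.181 1.417  2.88  3.889 0.000101
#> 2     grade  0.8883 2.431     0.268 1.437  4.11  3.314 0.000921
#> 3      size -0.1165 0.890     0.323 0.473  1.68 -0.361 0.718268
#> 4       age -0.0706 0.932     0.151 0.693  1.25 -0.469 0.639336
#> 5  ancestry -0.7021 0.496     0.577 0.160  1.54 -1.217 0.223651
harrell_c(drop(X %*% fit$coefficients), co$time, co$event, fit$weights)
#> [1] 0.7064118
```

The fitted PRS hazard ratio (2.02, 95% CI 1.42–2.88) recovers the
simulated log 2 effect; controls are up-weighted 6.17-fold so the
case-enriched sample reflects a 15% incidence at the study horizon.

## Command line

Each stage is also a CLI subcommand (`simulate`, `concordance`, `prs`,
`hla`, `survival`) with global `--seed`, `--log-level` and `--config`:

```sh
Rscript -e 'archivalgeno::run_cli()' simulate --out-prefix run --seed 7
Rscript -e 'archivalgeno::run_cli()' concordance \
    --blood-vcf run_blood.vcf --tissue-vcf run_tissue.vcf \
    --out-prefix run --seed 7
```

Outputs are tab-delimited report tables plus a `*_summary.json` run
summary.

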