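---
title: "Evaluating archival-tissue germline genotyping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating archival-tissue germline genotyping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archivalgeno)
```

# Scope and model

`archivalgeno` evaluates germline genotypes imputed from low-coverage
whole-genome sequencing (lc-WGS, < 1x mean depth) of archival FFPE tissue
against blood-derived truth, and carries the validated scores into an
outcome model. The package deliberately does **not** perform imputation,
HLA typing, or copy-number segmentation — those are upstream tools whose
*outputs* (dosage VCFs, typing tables, segment tables) are the package's
inputs. What the package owns is the evaluation and inference layer:
concordance scoring, PRS computation, HLA concordance, copy-number burden
rules, and the weighted survival model.

## Dosage concordance

For one sample, concordance between two panels is the squared Pearson
correlation of the paired per-variant dosages (`aggregate_r2()`). It is
reported per sample x MAF bin x stratum (`binned_concordance()`):

* **MAF bins.** Default edges 0.0005, 0.001, 0.005, 0.01, 0.05, 0.1, 0.2,
  0.3, 0.4, 0.5 — a log-spaced ladder over the imputable range. The
  published figures this mirrors show a log MAF axis without printing
  edges, so the edges are configurable and nothing downstream depends on
  them.
* **Minimum cell size.** Cells with fewer than 1000 SNPs (default) are
  emitted with a missing r² but a reported count, so under-filled cells
  are visible rather than silently absent.
* **Strata.** `all`, `high_quality` (imputation quality > 0.80 in both
  panels), and — when segments are supplied — `neutral`/`gain`/`loss` by
  the copy-number state of the variant's containing segment, computed on
  high-quality variants. Artifact segments (log2 ratio < −15) exclude
  their variants from the CN strata.
* **Confidence intervals.** Percentile bootstrap (2.5/97.5) over variants
  resampled with replacement, 1000 iterations by default. Percentile
  rather than BCa because it is the simplest method consistent with "95%
  CI from bootstrap iterations", and CI consumers here are visual.
* **Aggregation.** r² is computed per sample; `summarize_binned_concordance()`
  additionally averages per-sample r² across samples. Whether a pooled-
  variant or averaged-per-sample aggregate is "the" summary is left to
  the caller — both views are emitted, neither is asserted as canonical.
* **Degenerate cells.** A constant dosage vector has undefined
  correlation; such cells return missing with a warning, never 0.

Coordinate conventions are fixed once: variants are 1-based (VCF),
segments 0-based half-open (BED), and a variant at position p lies in
segment [start, end) iff start ≤ p − 1 < end. Chromosome labels are
compared after stripping any "chr" prefix.

## Polygenic risk scores

`compute_prs()` evaluates PRS = Σᵢ βᵢ xᵢ with βᵢ the per-allele log odds
ratio from a PGS-Catalog-style scoring file and xᵢ the dosage of the
*effect* allele: if the effect allele is the panel's ALT the dosage is
used as-is, if it is the REF the complement 2 − dosage is used, and a
site matching neither allele is excluded and counted (never an error).
Missing sites are skipped, not mean-imputed — the coverage report
(`prs_site_coverage()`) is the honest account of what was scored, at both
integer and one-decimal rounding since published coverage figures use
both. Strand flips are never attempted. Scores are z-normalized within
the analysis cohort (`zscore()`); the choice of normalization cohort is
per-analysis, which matches how such scores are compared within a study
rather than against an external reference population. Duplicate sites in
a scoring file keep the first occurrence with a warning; models sharing
sites are scored independently with no cross-model deduplication.

## HLA concordance

Typings carry no phase, so a gene's two alleles are compared as unordered
pairs: `gene_concordance()` takes the maximum matching between the
truncated predicted and gold pairs (0, 1 or 2), which prevents a
homozygous prediction from double-matching a single gold allele.
Truncation to 2 fields removes trailing fields only; an allele typed at
fewer fields than requested is compared at its available resolution and
flagged. Expression-suffix letters (N, L, S, C, A, Q) are stripped with a
log message. Class summaries divide summed matches by 2 x genes compared
— a homozygous gold pair counts as two comparable alleles in the
denominator. Posterior probabilities are compared between perfect and
error-carrying gene calls with a two-sided Wilcoxon rank-sum test; fully
tied posteriors report p = 1.

## Copy-number burden and grade imputation

Segments are classified by strict thresholds on the log2 copy ratio:
gain > 0.3, loss < −0.3, artifact < −15 (removed from every computation);
the boundary values are neutral because the rules as printed are strict
inequalities. Burden is the altered length over the total length of
non-artifact segments — lengths, not bin counts. Missing nuclear grade is
imputed from burden tertiles (bottom/middle/top → 1/2/3) because grade
and genomic instability are strongly correlated; tertile cut points use
the inclusive linear-interpolation quantile (`type = 7`), ties break
toward the lower grade, observed grades are never overwritten, and fully
degenerate burden distributions assign grade 2 with a warning. The
quantile rule is a package choice — the source analysis names tertiles
without fixing a definition.

## The weighted Cox model

The outcome model is a Cox proportional-hazards fit written from first
principles (`fit_weighted_cox()`), because the reweighting scheme and the
diagnostics must be transparent:

* **Weights.** An outcome-enriched case-control cohort over-represents
  events. Cases get weight 1; each control gets 1/p where p is the
  proportion of controls sampled out of the number needed to reflect the
  target incidence at the horizon (`control_weight()`; e.g. 15% at 10
  years for surgically treated DCIS). Coefficients are invariant to
  rescaling all weights, which the tests assert.
* **Ties.** Breslow pooling only (Efron is a non-goal). The weighted
  Breslow log partial likelihood is maximized by Newton–Raphson with
  step-halving; convergence when the max absolute score < 1e−7 (default)
  within 100 iterations. Step-halving guarantees the likelihood never
  decreases; a singular information matrix errors with the offending
  covariate named.
* **Variance.** Model-based (inverse information) and robust sandwich
  variance from weighted per-subject score residuals (dfbeta); reported
  CIs use the robust SEs, exp(β ± 1.96 SE).
* **Baseline.** Weighted Breslow cumulative hazard
  H₀(t) = Σ_{tₖ ≤ t} d̃ₖ / S₀(tₖ); profile survival
  S(t|x) = exp(−H₀(t))^{exp(β'x)}. `prs_percentile_curves()` sweeps the
  PRS covariate over cohort quantiles with other covariates at their
  weighted means — the reference profile is a package choice, since
  "keeping all other covariates the same" does not name one.
* **Diagnostics.** Scaled Schoenfeld residuals correlated against the
  event-time rank, with a t-test p-value, report-only. At the fitted
  coefficients the residuals sum to ~0 over all events (the score
  identity); they do not vanish per event time, and the tests assert the
  identity in its correct form. Type-I error of the check is verified by
  simulation to sit near the nominal 5%.
* **Discrimination.** Harrell's C by direct pairwise enumeration:
  comparable pairs are those where the earlier time is an event (pairs
  tied on event time are not comparable); predictor ties count 1/2; pair
  weights multiply member weights.

Patients missing lesion size are excluded from the fit; patients missing
grade get it imputed from burden tertiles before fitting; the ordinal
age band enters as its decade midpoint.

## Multiple testing over correlated PRS

P-values from per-model Cox fits are corrected by Bonferroni with the
Li–Ji effective number of tests: eigenvalues λ of the score columns'
correlation matrix give m_eff = Σ [I(λᵢ ≥ 1) + (λᵢ − ⌊λᵢ⌋)], and
q = min(1, p · m_eff). The integer-part term is discontinuous, so
eigenvalues are rounded to 9 decimals before flooring — otherwise four
perfectly correlated columns yield λ = 4 − ε and m_eff ≈ 2 instead of the
closed-form 1. m_eff is computed over the models actually fitted in a
run, since the number of PRS models is a runtime input.

Fisher's exact test (`fisher_exact_2x2()`) enumerates the hypergeometric
support with fixed margins and sums the probabilities of all tables no
more probable than the observed one, within relative tolerance 1e−7 —
the standard two-sided definition, validated exhaustively against
`stats::fisher.test`.

# The synthetic-data generator

The generator produces every input the pipeline consumes. It is a
*stated world*, not a calibration claim: its defaults encode the
qualitative structure the real data is described to have, and where no
quantitative value is published the defaults are fixed once at values a
practitioner would call realistic.

* **Genotypes.** Per variant, MAF is drawn from a Beta(0.2, 1.8) spectrum
  folded to the minor allele and truncated to [0.0005, 0.5] — strongly
  skewed toward rare variants, as a neutral site-frequency spectrum is.
  Genotypes are Hardy–Weinberg draws from {0, 1, 2} with probabilities
  (1−q)², 2q(1−q), q².
* **Dosage noise.** Gaussian on the dosage scale with clipping to [0,2]:
  SD = error_scale · f(MAF) · g(coverage) · h(state), with
  f(m) = (0.5/m)^0.3 (1 at MAF 0.5, rising as MAF falls),
  g(c) = 1/√c (1 at 1x), h = 2 in copy-loss segments and 1 elsewhere.
  A full genotype-likelihood model is deliberately out of scope: the
  evaluation consumes dosage concordance only, so the generator needs
  only controllable dosage error with the right qualitative shape. The
  default error_scale 0.15 at tissue coverage 0.7x puts common-SNP
  paired-panel r² in the 0.85–0.95 range and rare-SNP r² far lower.
* **Quality scores.** exp(−2·rmse²) of the realized per-variant noise —
  a monotone *emulation* of an imputation INFO score (whose formula the
  upstream tool does not publish), calibrated so typical common-SNP noise
  (~0.2 dosage SD) scores ~0.92 and rare-SNP noise (~0.6 SD) falls below
  the 0.80 filter.
* **Copy-number profiles.** A toy genome (2 chromosomes x 5 Mb, 100-kb
  bins) tiled with contiguous gain (+0.58, three copies) and loss (−1.0,
  one copy) runs hitting the requested genome fractions to within one
  bin; placement is seeded.
* **HLA typings.** Gold alleles drawn per gene from a bundled frequency
  table (`hla_allele_freqs_synthetic.tsv` — real nomenclature, synthetic
  round-number frequencies); each imputed allele independently corrupted
  with its class error rate (defaults 5% Class I, 18% Class II, matching
  the reported ordering of class accuracies); posteriors Beta(12, 2) for
  perfect calls vs Beta(4, 3) for calls with errors.
* **Cohorts.** PRS ~ N(0,1); covariates from clinical-table-like
  marginals (grade 35/45/20%, lesion size log-normal around 0.9 cm,
  diagnosis decades 41–90, 90% European ancestry); event times
  exponential with rate baseline_rate · exp(linear predictor), covariates
  centered so the baseline applies to an average patient; administrative
  censoring (default 15 years). The default baseline_rate 0.016/year
  gives ~15% cumulative incidence at 10 years — the incidence the
  weighting scheme targets. Case-control subsampling keeps all events
  and a stated fraction of non-events, mirroring outcome-based
  retrospective selection.

What a green test does **not** establish: the generator has no linkage
disequilibrium, no haplotype structure, no read-level error process, and
its quality score is not the INFO formula. Tests on it validate the
*evaluation machinery* (binning, filtering, bootstrap, matching rules,
estimators) and the qualitative error structure — they do not reproduce
the numerical accuracy of any real imputation pipeline, and no published
real-data headline number (r² > 0.94, PRS r = 0.93, HR 2.07, C-index
0.63) is asserted by the test suite.

# Numerical and interface choices

* Convergence: Newton tolerance 1e−7 on the score max-norm; Fisher
  two-sided inclusion tolerance 1e−7 relative; VCF round-trip preserves
  dosages to 6 decimals (the writer's precision).
* Duplicate scoring-file sites keep the first occurrence (warned);
  overlapping segments on a chromosome are a hard error; mismatched
  variant sets in paired panels are a hard error naming the first five
  offenders.
* The dosage FORMAT tag (default `DS`) and quality INFO tag (default
  `INFO_SCORE`) are configurable because imputation tools differ in
  dialect and the upstream tool's tags are not pinned.
* `simulate_imputed_dosages()` returns the blood-like and tissue-like
  panels in one call so they share a truth and a seed; blood coverage
  defaults to 0.92x vs tissue 0.7x, the typical asymmetry between the
  two arms.
* The CLI is an exported function (`run_cli()`) driven by
  `Rscript -e 'archivalgeno::run_cli()'`, with `--config` key=value files
  supplying defaults that explicit flags override.

# Known limitations

* No LD or haplotype structure in the generator; concordance structure
  across nearby variants is independent by construction.
* The Cox fitter handles moderate cohort sizes (it is O(events x n) per
  Newton iteration with dense risk-set scans); it is not tuned for
  biobank-scale data.
* Efron ties, competing risks, and time-varying coefficients are
  intentionally absent.
* rsID-only matching of scoring files is supported for file parsing, but
  panels produced by the generator carry coordinates, and ambiguous A/T,
  C/G sites are excluded rather than strand-resolved.
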