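test_that("true genotypes follow HWE closed form and the seed contract", {
  n <- 10000
  cfg <- dosage_sim_config(n_variants = n, n_samples = 1, seed = 3)
  tr <- simulate_true_genotypes(cfg, maf = rep(0.5, n))
  het <- mean(tr$genotypes == 1)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(het - 0.5), 3 * se)

  # maf 0: monomorphic reference
  tr0 <- simulate_true_genotypes(cfg, maf = rep(0, n))
  expect_true(all(tr0$genotypes == 0))

  # general HWE check at maf 0.2: genotype frequencies within 3 binomial SD
  q <- 0.2
  trq <- simulate_true_genotypes(cfg, maf = rep(q, n))
  for (g in 0:2) {
    p_exp <- c((1 - q)^2, 2 * q * (1 - q), q^2)[g + 1]
    expect_lt(abs(mean(trq$genotypes == g) - p_exp),
              3 * sqrt(p_exp * (1 - p_exp) / n))
  }

  # determinism
  a <- simulate_true_genotypes(cfg)
  b <- simulate_true_genotypes(cfg)
  expect_identical(a, b)
  pan_a <- simulate_imputed_dosages(a)
  pan_b <- simulate_imputed_dosages(b)
  expect_identical(pan_a$tissue$dosages, pan_b$tissue$dosages)
})

test_that("error_scale = 0 reproduces the truth exactly", {
  cfg <- dosage_sim_config(n_variants = 500, n_samples = 2,
                           error_scale = 0, seed = 4)
  tr <- simulate_true_genotypes(cfg)
  pan <- simulate_imputed_dosages(tr)
  expect_equal(unname(pan$tissue$dosages), unname(tr$genotypes) + 0)
  expect_equal(unname(pan$blood$dosages), unname(tr$genotypes) + 0)
})

test_that("dosage error grows as MAF shrinks and as coverage shrinks", {
  n <- 10000
  maf <- rep(c(0.005, 0.4), each = n / 2)
  cfg <- dosage_sim_config(n_variants = n, n_samples = 2, seed = 5)
  tr <- simulate_true_genotypes(cfg, maf = maf)
  pan <- simulate_imputed_dosages(tr)
  err <- abs(pan$tissue$dosages - tr$genotypes)
  rare <- tr$variants$maf < 0.01
  expect_gt(mean(err[rare, ]), mean(err[!rare, ]))

  # lower coverage, same seed and spectrum: larger error
  cfg_lo <- dosage_sim_config(n_variants = n, n_samples = 2,
                              coverage = 0.3, seed = 5)
  cfg_hi <- dosage_sim_config(n_variants = n, n_samples = 2,
                              coverage = 1.2, seed = 5)
  tr2 <- simulate_true_genotypes(cfg_lo)
  e_lo <- mean(abs(simulate_imputed_dosages(tr2, cfg_lo)$tissue$dosages -
                     tr2$genotypes))
  e_hi <- mean(abs(simulate_imputed_dosages(tr2, cfg_hi)$tissue$dosages -
                     tr2$genotypes))
  expect_gt(e_lo, e_hi)
})

test_that("copy-loss regions carry larger dosage error", {
  n <- 10000
  cfg <- dosage_sim_config(n_variants = n, n_samples = 1, seed = 6)
  tr <- simulate_true_genotypes(cfg, maf = rep(0.3, n))
  # loss over all of chromosome 1 (half the toy genome)
  loss_seg <- data.frame(chrom = "1", start = 0, end = 5e6, log2_ratio = -1)
  cfg$cn_profile <- list(S01 = loss_seg)
  pan <- simulate_imputed_dosages(tr, cfg)
  err <- abs(pan$tissue$dosages[, 1] - tr$genotypes[, 1])
  in_loss <- tr$variants$chrom == "1"
  expect_gt(mean(err[in_loss]), mean(err[!in_loss]))
  # blood panel is unaffected by the tissue CN profile
  err_b <- abs(pan$blood$dosages[, 1] - tr$genotypes[, 1])
  expect_lt(abs(mean(err_b[in_loss]) - mean(err_b[!in_loss])),
            3 * sd(err_b) / sqrt(n / 2))
  # mismatched profile chromosomes are a hard error
  cfg$cn_profile <- list(S01 = data.frame(chrom = "7", start = 0, end = 100,
                                          log2_ratio = -1))
  expect_error(simulate_imputed_dosages(tr, cfg), "chromosome")
})

test_that("quality scores decrease with realized error", {
  n <- 5000
  cfg <- dosage_sim_config(n_variants = n, n_samples = 4, seed = 7)
  tr <- simulate_true_genotypes(cfg)
  pan <- simulate_imputed_dosages(tr)
  rmse <- sqrt(rowMeans((pan$tissue$dosages - tr$genotypes)^2))
  expect_lt(cor(pan$tissue$variants$quality, rmse), -0.5)
  expect_true(all(pan$tissue$variants$quality >= 0 &
                    pan$tissue$variants$quality <= 1))
})

test_that("cn profile tiles the toy genome at the requested burden", {
  p0 <- simulate_cn_profile(0, 0, seed = 1)
  expect_equal(nrow(p0), 2)             # one neutral segment per chromosome
  expect_equal(cn_burden(p0)$burden, 0)

  p <- simulate_cn_profile(0.25, 0.25, seed = 2)
  expect_lt(abs(cn_burden(p)$burden - 0.5), 0.01)
  check <- function(s) expect_true(all(s$end > s$start))
  check(p)

  expect_error(simulate_cn_profile(0.6, 0.5), "exceed 1")
  p_a <- simulate_cn_profile(0.2, 0.2, seed = 10)
  p_b <- simulate_cn_profile(0.2, 0.2, seed = 11)
  expect_false(identical(p_a, p_b))     # placement is seed-dependent
})

test_that("HLA generator hits its class error rates and posterior ordering", {
  sim0 <- simulate_hla_truth_and_calls(20, 0, 0, seed = 1)
  gc0 <- score_hla_concordance(sim0$imputed, sim0$gold)
  expect_true(all(gc0$n_matched == 2))

  n <- 500
  sim <- simulate_hla_truth_and_calls(n, class1_error = 0.05,
                                      class2_error = 0.2, seed = 2)
  gc <- score_hla_concordance(sim$imputed, sim$gold)
  summ <- summarize_concordance(gc)
  pct2 <- summ$pct_concordant[summ$class_label == "II"]
  # 2 genes x 2 alleles x n draws at 80% per-allele accuracy
  se <- 100 * sqrt(0.8 * 0.2 / (4 * n))
  expect_lt(abs(pct2 - 80), 3 * se)
  pb <- posterior_by_concordance(gc)
  expect_gt(pb$mean_perfect, pb$mean_errors)
})

test_that("cohort simulator recovers a null PRS effect and handles degeneracy", {
  cfg <- cohort_sim_config(n_patients = 2000, true_log_hr_per_sd = 0,
                           seed = 8)
  cohort <- simulate_cohort(cfg)
  fit <- fit_weighted_cox(cohort$time, cohort$event,
                          cbind(prs = cohort$prs))
  se <- sqrt(diag(fit$robust_var))
  expect_lt(abs(fit$coefficients[["prs"]]), 3 * se)

  # near-instant censoring: cohort generates, the downstream fit errors
  cfg0 <- cohort_sim_config(n_patients = 100, censor_time_years = 0.001,
                            seed = 9)
  cens <- simulate_cohort(cfg0)
  expect_false(any(cens$event))
  expect_error(fit_weighted_cox(cens$time, cens$event,
                                cbind(prs = cens$prs)),
               "no events")
  # a configuration with essentially zero expected events refuses to run
  expect_error(simulate_cohort(cohort_sim_config(n_patients = 100,
                                                 baseline_rate = 1e-15,
                                                 seed = 9)),
               "zero expected events")

  # case-control subsampling keeps every event
  cfg_cc <- cohort_sim_config(n_patients = 400, control_fraction = 0.25,
                              seed = 10)
  full <- simulate_cohort(cohort_sim_config(n_patients = 400, seed = 10))
  cc <- simulate_cohort(cfg_cc)
  expect_equal(sum(cc$event), sum(full$event))
  expect_lt(sum(!cc$event), sum(!full$event))
})
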