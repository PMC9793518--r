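test_that("fisher_exact_2x2 reproduces worked tables", {
  expect_equal(fisher_exact_2x2(9, 22, 5, 14), 1.0, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1.0, tolerance = 1e-12)
  # extreme table: p = P(X=10) + P(X=0) under the margins
  expect_equal(fisher_exact_2x2(10, 0, 0, 10),
               dhyper(10, 10, 10, 10) + dhyper(0, 10, 10, 10),
               tolerance = 1e-12)
  expect_error(fisher_exact_2x2(0, 0, 3, 4), "empty margin")
})

test_that("fisher enumeration agrees with the stats::fisher.test oracle", {
  # exhaustive over all 2x2 tables with N <= 16, sampled beyond
  for (N in 2:16) {
    for (a in 0:N) for (b in 0:(N - a)) for (cc in 0:(N - a - b)) {
      d <- N - a - b - cc
      if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) next
      expect_equal(fisher_exact_2x2(a, b, cc, d),
                   fisher.test(rbind(c(a, b), c(cc, d)))$p.value,
                   tolerance = 1e-7)
    }
  }
  set.seed(61)
  for (i in 1:150) {
    N <- sample(17:30, 1)
    cells <- as.vector(rmultinom(1, N, runif(4, 0.05, 1)))
    if (cells[1] + cells[2] == 0 || cells[3] + cells[4] == 0 ||
        cells[1] + cells[3] == 0 || cells[2] + cells[4] == 0) next
    expect_equal(do.call(fisher_exact_2x2, as.list(cells)),
                 fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("control weights follow the incidence rule", {
  w <- control_weight(22, 14, 0.15)
  expect_equal(w$controls_needed, 22 * 0.85 / 0.15, tolerance = 1e-12)
  expect_equal(w$control_weight, (22 * 0.85 / 0.15) / 14, tolerance = 1e-12)
  expect_equal(round(w$control_weight, 3), 8.905)
  # sampled exactly what is needed -> weight 1
  expect_equal(control_weight(30, 30 * 0.85 / 0.15, 0.15)$control_weight, 1)
  # incidence 0.5 with equal arms -> weight 1
  expect_equal(control_weight(10, 10, 0.5)$control_weight, 1)
  expect_warning(control_weight(10, 1000, 0.15), "weight < 1")
})

test_that("symmetric risk sets give beta = 0", {
  fit <- fit_weighted_cox(time = c(1, 2, 1, 2),
                          event = rep(TRUE, 4),
                          X = cbind(g = c(0, 0, 1, 1)))
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-9)
})

test_that("the Newton fit matches the grid-search likelihood maximizer", {
  set.seed(62)
  for (i in 1:5) {
    fx <- random_cox_fixture(12)
    fit <- fit_weighted_cox(fx$time, fx$event, cbind(x = fx$x))
    b_grid <- grid_cox_beta(fx$time, fx$event, fx$x)
    expect_lt(abs(unname(fit$coefficients) - b_grid), 1e-4)
  }
})

test_that("weighted fit matches survival::coxph with Breslow ties and robust SEs", {
  skip_if_not_installed("survival")
  set.seed(63)
  n <- 150
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4), c = runif(n))
  tt <- rexp(n, 0.15 * exp(0.6 * X[, 1] - 0.4 * X[, 2]))
  tt <- round(tt, 1) + 0.05          # induce ties
  ev <- tt < 6; tt <- pmin(tt, 6)
  w <- ifelse(ev, 1, 4.7)
  fit <- fit_weighted_cox(tt, ev, X, w)
  or <- survival::coxph(survival::Surv(tt, ev) ~ a + b + c,
                        data = as.data.frame(X), weights = w,
                        ties = "breslow", robust = TRUE)
  expect_equal(unname(fit$coefficients), unname(coef(or)), tolerance = 1e-7)
  expect_equal(unname(sqrt(diag(fit$robust_var))),
               unname(sqrt(diag(vcov(or)))), tolerance = 1e-6)
  # model-based variance too
  expect_equal(unname(diag(fit$var)),
               unname(diag(or$naive.var)), tolerance = 1e-6)
  # score at the optimum vanishes
  cs <- archivalgeno:::cox_sums(tt, ev, X, w, fit$coefficients)
  expect_lt(max(abs(cs$U)), 1e-7)
})

test_that("coefficients are invariant to rescaling all weights", {
  set.seed(64)
  fx <- random_cox_fixture(25)
  w <- runif(25, 0.5, 4)
  f1 <- fit_weighted_cox(fx$time, fx$event, cbind(x = fx$x), w)
  f2 <- fit_weighted_cox(fx$time, fx$event, cbind(x = fx$x), 10 * w)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("baseline hazard reduces to Nelson-Aalen at beta = 0 and matches hand computation", {
  # 5-subject toy set, hand-computed Breslow increments
  time <- c(1, 2, 3, 4, 5)
  event <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  x <- cbind(z = c(0.5, -0.5, 1, 0, -1))
  fit <- fit_weighted_cox(time, event, x)
  b <- unname(fit$coefficients)
  r <- exp(b * x[, 1])
  h1 <- 1 / sum(r)                  # risk set {1..5}
  h2 <- 1 / sum(r[2:5])
  h3 <- 1 / sum(r[4:5])             # event at t=4; subject 3 censored before
  expect_equal(fit$baseline$dH0, c(h1, h2, h3), tolerance = 1e-9)

  # beta = 0 reduction (symmetric groups force beta-hat = 0): survival
  # equals the pooled Nelson-Aalen-based survival, Breslow tie pooling
  fit0 <- fit_weighted_cox(c(1, 2, 1, 2), rep(TRUE, 4),
                           cbind(z = c(0, 0, 1, 1)))
  expect_equal(unname(fit0$coefficients), 0, tolerance = 1e-9)
  surv <- baseline_survival(fit0, covariate_profile = 0)
  expect_equal(surv$S_profile1,
               exp(-cumsum(c(2 / 4, 2 / 2))), tolerance = 1e-9)

  # higher PRS percentile -> pointwise lower survival when beta > 0
  set.seed(65)
  co <- simulate_cohort(cohort_sim_config(n_patients = 300, seed = 65))
  fitp <- fit_weighted_cox(co$time, co$event, cbind(prs = co$prs))
  curves <- prs_percentile_curves(fitp, "prs", percentiles = c(0.1, 0.5, 0.9))
  expect_true(all(curves$S_p90 <= curves$S_p50 + 1e-12))
  expect_true(all(curves$S_p50 <= curves$S_p10 + 1e-12))
})

test_that("Harrell's C handles the canonical cases and matches oracles", {
  tt <- c(3, 1, 4, 2, 5)
  expect_equal(harrell_c(-tt, tt, rep(TRUE, 5)), 1.0)
  expect_equal(harrell_c(rep(1, 5), tt, rep(TRUE, 5)), 0.5)
  set.seed(66)
  lp <- rnorm(50); time <- rexp(50, exp(0.8 * lp)); ev <- runif(50) < 0.7
  expect_equal(harrell_c(lp, time, ev), c_index_oracle(lp, time, ev))
  skip_if_not_installed("survival")
  or <- survival::concordance(survival::Surv(time, ev) ~ lp, reverse = TRUE)
  expect_equal(harrell_c(lp, time, ev), unname(or$concordance))
  expect_error(harrell_c(c(1, 2), c(1, 2), c(FALSE, FALSE)), "no events")
})

test_that("PH check: score identity at the fit, power against violation", {
  set.seed(67)
  fx <- random_cox_fixture(80)
  fit <- fit_weighted_cox(fx$time, fx$event, cbind(x = fx$x))
  res <- ph_assumption_check(fit)
  sch <- attr(res, "schoenfeld")
  expect_lt(max(abs(colSums(sch))), 1e-6)   # residuals sum to ~0 at beta-hat
  # a coefficient that flips sign over time violates PH and is detected:
  # before t0 the hazard is exp(-x), after t0 it is exp(+x)
  n <- 1000
  x <- rnorm(n)
  t0 <- 0.7
  t1 <- rexp(n, exp(-x))
  t2 <- t0 + rexp(n, exp(x))
  tt <- ifelse(t1 < t0, t1, t2)
  fit2 <- fit_weighted_cox(tt, rep(TRUE, n), cbind(x = x))
  res2 <- ph_assumption_check(fit2)
  expect_lt(res2$p, 0.01)
})

test_that("Li-Ji effective number of tests hits its closed forms", {
  set.seed(68)
  # k independent columns: identity correlation -> m_eff = k
  id5 <- diag(5)
  X <- matrix(rnorm(500), 100, 5)
  X <- X %*% solve(chol(cov(X)))          # exactly uncorrelated sample
  m5 <- li_ji_meff(X)
  expect_equal(m5$m_eff, 5, tolerance = 1e-9)
  # perfectly correlated columns -> 1
  base <- rnorm(50)
  m1 <- li_ji_meff(cbind(base, 2 * base, base + 3, 5 * base - 1))
  expect_equal(m1$m_eff, 1, tolerance = 1e-9)
  expect_equal(sort(m1$eigenvalues, decreasing = TRUE)[1], 4, tolerance = 1e-9)
  # two columns at rho = 0.5: eigenvalues 1.5, 0.5 -> m_eff = 2.0
  m2 <- li_ji_meff(exact_cor_columns(60, 0.5))
  expect_equal(sort(m2$eigenvalues), c(0.5, 1.5), tolerance = 1e-9)
  expect_equal(m2$m_eff, 2.0, tolerance = 1e-9)
  # q-values and guards
  expect_equal(li_ji_meff(X, p_values = c(0.01, 0.4))$q_values,
               pmin(1, c(0.01, 0.4) * 5), tolerance = 1e-9)
  expect_error(li_ji_meff(cbind(rep(1, 10), rnorm(10))), "constant")
})

test_that("PRS group comparison reports means, fold change and a rank test", {
  x <- c(1.2, 0.8, 1.0, 1.1, 0.9)
  same <- prs_group_comparison(c(x, x), rep(c(TRUE, FALSE), each = 5))
  expect_equal(same$fold_change, 1)
  expect_gt(same$p, 0.9)
  set.seed(69)
  shifted <- prs_group_comparison(c(rnorm(200, 1), rnorm(200, 0)),
                                  rep(c(TRUE, FALSE), each = 200))
  expect_lt(shifted$p, 0.01)
  expect_gt(shifted$fold_change, 1)
  solo <- prs_group_comparison(c(0.4, rnorm(10)), c(TRUE, rep(FALSE, 10)))
  expect_true(is.na(solo$p))
  expect_equal(solo$mean_event, 0.4)
})
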