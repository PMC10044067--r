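test_that("inner_map returns the prior mode with no or uninformative data", {
  m <- final_model()
  # zero observations -> eta-hat = 0
  s0 <- pk_subject(1, list(CLCR = 99.24), ci_regimen(12))
  expect_equal(unname(inner_map(m, s0)), 0)

  # single observation exactly at the typical prediction -> eta-hat = 0
  # (under additive error; with proportional error the interaction term
  # log g2(eta) shifts the mode slightly off zero by construction)
  m_add <- pop_model(structural_pk(2),
                     theta = c(CL = 12, Vc = 20.7, Vp = 62.4, CLD = 4.77),
                     covariates = list(
                       CL = covariate_relation("CLCR", "proportional",
                                               reference = 99.24)),
                     bpv = list(CL = list(omega2 = 0.19)),
                     residual = residual_spec("additive", sigma2_add = 4))
  f <- predict_concentration(table2_params(), ci_regimen(12), 10)
  s1 <- pk_subject(2, list(CLCR = 99.24), ci_regimen(12), 10, f)
  expect_equal(unname(inner_map(m_add, s1)), 0, tolerance = 1e-5)
})

test_that("inner_map on a linear toy equals the closed-form ridge solution", {
  m <- linear_toy_model(mu = 5, omega2 = 2, sigma2 = 1.5)
  s <- pk_subject(1, list(), dosing_regimen(numeric(0), numeric(0),
                                            numeric(0)),
                  times = 1:3, dv = c(6.1, 7.4, 5.2))
  # posterior mode of eta | y: (sum(y - mu)/sigma2) / (n/sigma2 + 1/omega2)
  expected <- (sum(s$dv - 5) / 1.5) / (3 / 1.5 + 1 / 2)
  expect_equal(unname(inner_map(m, s)), expected, tolerance = 1e-5)
})

test_that("FOCEI OFV equals the exact -2LL on linear-Gaussian models", {
  m <- linear_toy_model()
  d <- linear_toy_data()
  expect_equal(as.numeric(ofv(m, d)), linear_toy_m2ll(d, 5, 2, 1.5),
               tolerance = 1e-6)
  # also at other parameter values (the fit objective, not just the truth)
  m2 <- linear_toy_model(mu = 4.2, omega2 = 1.1, sigma2 = 2.3)
  expect_equal(as.numeric(ofv(m2, d)), linear_toy_m2ll(d, 4.2, 1.1, 2.3),
               tolerance = 1e-6)
})

test_that("OFV limits and additivity", {
  d <- simulate_cohort(cohort_spec(n_subjects = 12), final_model(),
                       seed = 31)
  # omega2 -> 0 converges to the fixed-effects WLS -2LL
  m_eps <- final_model(omega2_CL = 1e-9)
  m_zero <- final_model(omega2_CL = 0)
  expect_equal(as.numeric(ofv(m_eps, d)), as.numeric(ofv(m_zero, d)),
               tolerance = 1e-4)

  # duplicating every subject doubles the OFV exactly
  m <- final_model()
  d2 <- pk_data(c(d$subjects, lapply(d$subjects, function(s) {
    s$id <- paste0(s$id, "b")
    s
  })))
  expect_equal(2 * as.numeric(ofv(m, d)), as.numeric(ofv(m, d2)),
               tolerance = 1e-8)

  # invariance to subject ordering
  d_rev <- pk_data(rev(d$subjects))
  expect_equal(as.numeric(ofv(m, d)), as.numeric(ofv(m, d_rev)),
               tolerance = 1e-10)
})

test_that("fast and generic OFV paths agree on the final model", {
  d <- simulate_cohort(cohort_spec(n_subjects = 15), final_model(),
                       seed = 33)
  m <- final_model()
  expect_equal(as.numeric(cippk:::ofv_fast(m, cippk:::stack_data(d))),
               as.numeric(cippk:::ofv_generic(m, d)), tolerance = 1e-6)
})

test_that("OFV tracks an independent Gauss-Hermite oracle on a toy set", {
  d <- simulate_cohort(cohort_spec(n_subjects = 10), final_model(),
                       seed = 37)
  for (m in list(final_model(),
                 final_model(CL = 10, omega2_CL = 0.25, sigma2 = 0.1))) {
    expect_lt(abs(as.numeric(ofv(m, d)) - gh_m2ll(m, d)), 0.5)
  }
})

test_that("noise-free data are recovered to < 1%", {
  spec <- cohort_spec(n_subjects = 30)
  gen <- final_model(omega2_CL = 0, sigma2 = 1e-6)
  d <- simulate_cohort(spec, gen, seed = 41)
  f <- fit_model(final_model(CL = 9, Vc = 16, Vp = 45, CLD = 3.5,
                             omega2_CL = 1e-4, sigma2 = 1e-4),
                 d, hessian = FALSE, control = fast_ctrl)
  est <- f$estimates
  for (p in c("CL", "Vc", "Vp", "CLD")) {
    expect_equal(unname(est[p]), table2[[p]], tolerance = 0.01)
  }
})

test_that("residual diagnostics: zero residuals on noise-free data and
           exact standardized residuals on the linear toy", {
  spec <- cohort_spec(n_subjects = 10)
  gen <- final_model(omega2_CL = 0, sigma2 = 1e-12)
  d <- simulate_cohort(spec, gen, seed = 43)
  ft <- as_fit(final_model(omega2_CL = 1e-12, sigma2 = 1e-6), d)
  rt <- residual_tables(ft)
  expect_equal(rt$PRED, rt$DV, tolerance = 1e-4)
  expect_lt(max(abs(rt$IWRES)), 1e-2)
  expect_lt(max(abs(rt$CWRES)), 1e-2)

  # linear toy: CWRES equal exact standardized marginal residuals
  m <- linear_toy_model()
  dlin <- linear_toy_data(n = 6, seed = 9)
  rt2 <- residual_tables(as_fit(m, dlin))
  exact <- unlist(lapply(dlin$subjects, function(s) {
    ni <- length(s$dv)
    V <- matrix(2, ni, ni) + diag(1.5, ni)
    backsolve(chol(V), s$dv - 5, transpose = TRUE)
  }))
  expect_equal(rt2$CWRES, exact, tolerance = 1e-6)
})

test_that("CWRES is calibrated (mean ~ 0, variance ~ 1) at the study size", {
  d <- simulate_cohort(cohort_spec(), final_model(), seed = 47)
  rt <- residual_tables(as_fit(final_model(), d))
  expect_lt(abs(mean(rt$CWRES)), 0.1)
  expect_lt(abs(var(rt$CWRES) - 1), 0.15)
})

test_that("shrinkage behaves as data richness changes", {
  # no data information -> eta-shrinkage 100%
  subs <- lapply(1:5, function(i) pk_subject(i, list(CLCR = 99), ci_regimen(12)))
  ft <- as_fit(final_model(), pk_data(subs))
  expect_equal(unname(shrinkage(ft)$eta_shrinkage), 100)

  # rich data -> low shrinkage; sparse study design -> moderate
  spec_rich <- cohort_spec(n_subjects = 25)
  covs <- draw_covariates(spec_rich, seed = 51)
  des <- build_design(spec_rich, covs, seed = 52)
  des$sample_times <- lapply(des$sample_times, function(x) {
    sort(runif(20, 0.25, 48))
  })
  d_rich <- simulate_observations(des, final_model(), seed = 53)
  expect_lt(shrinkage(as_fit(final_model(), d_rich))$eta_shrinkage, 10)

  d_sparse <- simulate_cohort(cohort_spec(), final_model(), seed = 54)
  shr <- shrinkage(as_fit(final_model(), d_sparse))
  expect_gt(shr$eta_shrinkage, 5)
  expect_lt(shr$eta_shrinkage, 35)
  expect_error(shrinkage(as_fit(final_model(),
                                pk_data(subs[1]))), "2 subjects")
})

test_that("condition number follows its closed forms", {
  expect_equal(condition_number(diag(3)), 1)
  expect_equal(condition_number(matrix(c(1, 0.6, 0.6, 1), 2)), 2)
  expect_equal(condition_number(matrix(c(1, 1, 1, 1), 2)), Inf)
})

test_that("the full fit reports SEs and a well-conditioned covariance", {
  d <- simulate_cohort(cohort_spec(n_subjects = 80), final_model(),
                       seed = 61)
  f <- fit_model(start_far(), d, control = fast_ctrl)
  expect_match(f$status, "^converged")
  expect_true(all(is.finite(f$se)))
  expect_true(all(f$rse > 0))
  cn <- condition_number(f)
  expect_lt(cn, 1000)
  expect_equal(unname(f$rse["CL"]), 100 * f$se[["CL"]] / f$estimates[["CL"]])
})

test_that("parameter recovery across replicates of the final design", {
  # 40 replicates of the full 106-subject design (~1.5 s per refit)
  ests <- vapply(13:52, function(sd) {
    d <- simulate_cohort(cohort_spec(), final_model(), seed = sd)
    f <- fit_model(start_far(), d, hessian = FALSE, control = fast_ctrl)
    f$estimates[c("CL", "omega2_CL")]
  }, numeric(2))
  expect_lt(abs(median(ests[1, ]) - 12) / 12, 0.05)
  expect_lt(abs(median(ests[2, ]) - 0.19) / 0.19, 0.15)
})
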