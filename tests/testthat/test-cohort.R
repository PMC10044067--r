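test_that("covariate marginals match the reported medians and IQRs", {
  spec <- cohort_spec(n_subjects = 1e5)
  covs <- draw_covariates(spec, seed = 77)
  expect_equal(median(covs$CLCR), 97.1, tolerance = 1.5 / 97.1)
  q <- quantile(covs$CLCR, c(0.25, 0.75), names = FALSE)
  expect_lt(abs(q[1] - 86), 3)
  expect_lt(abs(q[2] - 114), 3)
  expect_gte(min(covs$CLCR), 60)            # inclusion criterion
  expect_lte(max(covs$CLCR), 200)
  expect_equal(mean(covs$MALE), 0.6698, tolerance = 0.02)
  # the 18-90 truncation clips the upper age tail, shifting the median down
  expect_equal(median(covs$AGE), 65, tolerance = 0.05)
  expect_equal(median(covs$WT), 72, tolerance = 0.03)

  # renal formulas are mutually consistent through the back-solved creatinine
  i <- 1:50
  back <- vapply(i, function(j) {
    renal_function(renal_panel(covs$AGE[j],
                               if (covs$MALE[j] == 1) "male" else "female",
                               covs$WT[j], covs$SCR[j]), "CKD-EPI")
  }, numeric(1))
  expect_equal(back, covs$CLCR[i], tolerance = 1e-6)
})

test_that("covariate generation is deterministic under a seed", {
  spec <- cohort_spec(n_subjects = 50)
  expect_identical(draw_covariates(spec, seed = 9), draw_covariates(spec, seed = 9))
  expect_error(
    draw_covariates(cohort_spec(covariates = list(
      CLCR = list(type = "lognormal", median = 50, iqr = c(40, 60),
                  trunc = c(60, 200))))),
    "infeasible truncation")
})

test_that("the sampling design reproduces the two-window 2.1-sample layout", {
  spec <- cohort_spec()
  covs <- draw_covariates(spec, seed = 81)
  des <- build_design(spec, covs, seed = 82)
  n_samples <- sum(lengths(des$sample_times))
  # expected 106 * (1 + 0.5 + 0.556) ~ 218; allow 3 binomial SDs
  expect_lt(abs(n_samples - 218), 3 * sqrt(106 * 0.5 * 0.5 * 2) + 1)

  for (i in seq_along(des$sample_times)) {
    tt <- des$sample_times[[i]]
    ok <- (tt >= 0.5 & tt <= 1) | (tt >= 6 & tt <= 24) |
      (tt >= spec$ss2_window[1] & tt <= spec$ss2_window[2])
    expect_true(all(ok))
    expect_gte(sum(tt >= 6), 1)             # everyone has an SS sample
  }
  # every subject receives the LD + CI regimen by default
  expect_true(all(vapply(des$regimens, nrow, 1L) == 2))

  # no peak samples and a one-sample target -> exactly one per subject
  spec1 <- cohort_spec(cmax_fraction = 0, samples_per_subject = 1)
  des1 <- build_design(spec1, draw_covariates(spec1, seed = 83), seed = 84)
  expect_true(all(lengths(des1$sample_times) == 1))
})

test_that("simulated observations follow the generative model", {
  spec <- cohort_spec(n_subjects = 20)
  covs <- draw_covariates(spec, seed = 85)
  des <- build_design(spec, covs, seed = 86)

  # no variability -> observations equal typical predictions exactly
  d0 <- simulate_observations(des, final_model(omega2_CL = 0, sigma2 = 1e-18),
                              seed = 87)
  for (i in 1:20) {
    s <- d0$subjects[[i]]
    tv <- typical_clearance(covariate_relation("CLCR", "proportional",
                                               reference = 99.24),
                           12.0, covs$CLCR[i])
    p <- pk_parameters(tv, 20.7, 62.4, 4.77)
    expect_equal(s$dv, predict_concentration(p, s$events, s$times),
                 tolerance = 1e-6)
  }

  # same seed -> byte-identical CSV; different seeds differ
  da <- simulate_cohort(cohort_spec(n_subjects = 10), final_model(), seed = 88)
  db <- simulate_cohort(cohort_spec(n_subjects = 10), final_model(), seed = 88)
  dc <- simulate_cohort(cohort_spec(n_subjects = 10), final_model(), seed = 89)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_nonmem(da, fa); write_nonmem(db, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_false(identical(da$subjects[[1]]$dv, dc$subjects[[1]]$dv))

  # truth sidecar decomposes the variance of log individual clearance
  spec_big <- cohort_spec(n_subjects = 4000)
  covs_big <- draw_covariates(spec_big, seed = 90)
  des_big <- build_design(spec_big, covs_big, seed = 91)
  dbig <- simulate_observations(des_big, final_model(), seed = 92)
  tr <- attr(dbig, "truth")
  v_cl <- var(log(tr$CL_i))
  v_expected <- 0.190 + var(log(covs_big$CLCR / 99.24))
  expect_equal(v_cl, v_expected, tolerance = 0.03)
})

test_that("steady-state observations have the predicted geometric mean", {
  # samples far out (true steady state): GM of free concentration is
  # fu * R0 / TVCL at each subject's covariate value
  spec <- cohort_spec(n_subjects = 3000, cmax_fraction = 0,
                      samples_per_subject = 1, ss_window = c(400, 500))
  covs <- draw_covariates(spec, seed = 93)
  des <- build_design(spec, covs, seed = 94)
  d <- simulate_observations(des, final_model(), seed = 95)
  obs <- unlist(lapply(d$subjects, `[[`, "dv"))
  gm_free <- exp(mean(log(free_concentration(obs))))
  # oracle by lognormal geometric-mean algebra: the eta factor cancels
  # (mean 0), the covariate factor contributes GM(CLCR), and the
  # proportional noise contributes exp(E[log(1 + eps)]) (numeric integral)
  gm_tvcl <- 12.0 * exp(mean(log(covs$CLCR))) / 99.24
  e_log1p <- integrate(function(x) log1p(x) * dnorm(x, 0, sqrt(0.14)),
                       -0.999, 6)$value
  expect_equal(gm_free, 0.70 * 500 / gm_tvcl * exp(e_log1p),
               tolerance = 0.02)
})
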