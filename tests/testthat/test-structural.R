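test_that("pk_parameters enforces invariants and derives rate constants", {
  p <- table2_params()
  expect_equal(p$k10, 12.0 / 20.7)
  expect_equal(p$k12, 4.77 / 20.7)
  expect_equal(p$k21, 4.77 / 62.4)
  expect_equal(total_vd(p), 83.1)
  expect_error(pk_parameters(-1, 20, 60, 5), "strictly positive")
  expect_error(pk_parameters(12, 0, 60, 5), "strictly positive")

  # alpha > beta > 0 and A + B = 1 over random admissible parameters
  set.seed(42)
  for (i in 1:50) {
    q <- pk_parameters(runif(1, 1, 30), runif(1, 5, 50),
                       runif(1, 10, 200), runif(1, 0.5, 20))
    hc <- hybrid_constants(q)
    expect_gt(hc$beta, 0)
    expect_gt(hc$alpha, hc$beta)
    expect_equal(hc$A + hc$B, 1)
  }
})

test_that("typical_clearance matches the proportional covariate equation", {
  rel <- covariate_relation("CLCR", "proportional", reference = 99.24)
  expect_equal(typical_clearance(rel, 12.0, 99.24), 12.0)
  expect_equal(typical_clearance(rel, 12.0, 198.48), 24.0)
  expect_equal(typical_clearance(rel, 12.0, 49.62), 6.0)
  expect_error(typical_clearance(rel, 12.0, 0), "positive")
  expect_error(typical_clearance(rel, 12.0, -5), "positive")

  # exactly homogeneous of degree 1 in clcr
  set.seed(7)
  clcr <- runif(20, 60, 200)
  c_scale <- runif(20, 0.5, 2)
  expect_equal(typical_clearance(rel, 12, clcr * c_scale),
               typical_clearance(rel, 12, clcr) * c_scale)

  # linear form can predict a non-positive clearance -> domain error
  lin <- covariate_relation("CLCR", "linear", reference = 99.24, beta = -0.5)
  expect_error(typical_clearance(lin, 12, 150), "non-positive")
})

test_that("individualize acts on clearance only, exponentially", {
  p <- table2_params()
  expect_equal(individualize(p, 0), p)
  p2 <- individualize(p, log(2))
  expect_equal(p2$CL, 24.0)
  expect_equal(p2$Vc, p$Vc)
  expect_equal(p2$Vp, p$Vp)
  expect_equal(p2$CLD, p$CLD)

  # median of CL_i over lognormal draws is the typical value
  set.seed(11)
  cls <- vapply(rnorm(4000, 0, sqrt(0.190)),
                function(e) individualize(p, e)$CL, numeric(1))
  expect_equal(median(cls), 12.0, tolerance = 0.03)
})

test_that("closed-form infusion solution: pre-dose, steady state, linearity", {
  p <- table2_params()
  reg <- ci_regimen(12)
  expect_identical(predict_concentration(p, reg, 0), 0)

  # steady-state limit Css = R0/CL: 7 terminal half-lives leave ~2^-7 of
  # the accumulation (about 1%); 0.1% needs ten
  hc <- hybrid_constants(p)
  reg0 <- ci_regimen(12, loading_dose_g = 0)
  css7 <- predict_concentration(p, reg0, 7 * log(2) / hc$beta)
  expect_equal(css7, 500 / 12.0, tolerance = 1e-2)
  css10 <- predict_concentration(p, reg0, 10 * log(2) / hc$beta)
  expect_equal(css10, 500 / 12.0, tolerance = 1e-3)

  # superposition: scaling all rates by c scales every concentration by c
  tt <- c(0.25, 0.5, 1, 4, 12, 30)
  reg3 <- dosing_regimen(reg$rate * 3, reg$start, reg$duration)
  expect_equal(predict_concentration(p, reg3, tt),
               3 * predict_concentration(p, reg, tt))

  # overlapping events are additive
  both <- predict_concentration(p, reg, tt)
  ld_only <- predict_concentration(p, ci_regimen(0, loading_dose_g = 4), tt)
  ci_only <- predict_concentration(p, ci_regimen(12, loading_dose_g = 0), tt)
  expect_equal(both, ld_only + ci_only)

  expect_error(predict_concentration(p, reg, c(3, 1)), "sorted")
  expect_error(predict_concentration(p, reg, c(-1, 2)), "non-negative")
})

test_that("closed form agrees with the ODE oracle to 1e-6 relative", {
  p <- table2_params()
  reg <- ci_regimen(12)
  tt <- sort(c(seq(0.1, 2, by = 0.1), seq(3, 72, by = 3)))
  cf <- predict_concentration(p, reg, tt)
  od <- ode_concentration(p, elimination_spec("first_order"), reg, tt,
                          rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(cf - od) / cf), 1e-6)

  # second parameter set + a finite-duration regimen with a gap
  p2 <- pk_parameters(5, 30, 40, 10)
  reg2 <- dosing_regimen(rate = c(2000, 400), start = c(0, 2),
                         duration = c(1, 20))
  tt2 <- seq(0.2, 30, by = 0.4)
  cf2 <- predict_concentration(p2, reg2, tt2)
  od2 <- ode_concentration(p2, elimination_spec("first_order"), reg2, tt2,
                           rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(cf2 - od2) / cf2), 1e-6)
})

test_that("Michaelis-Menten solution converges to first order as Km grows", {
  p <- table2_params()
  reg <- ci_regimen(12)
  tt <- c(0.5, 1, 6, 24, 48)
  cf <- predict_concentration(p, reg, tt)
  # Vmax/Km = CL with Km far above all concentrations
  mm <- predict_concentration(p, reg, tt,
                              elim = elimination_spec("michaelis_menten",
                                                      Vmax = 12 * 1e4,
                                                      Km = 1e4))
  expect_equal(mm, cf, tolerance = 2e-2)
  expect_error(elimination_spec("michaelis_menten"), "Vmax")
  # genuinely saturable elimination gives higher concentrations
  sat <- predict_concentration(p, reg, tt,
                               elim = elimination_spec("michaelis_menten",
                                                       Vmax = 800, Km = 30))
  expect_true(all(sat > cf))
})

test_that("free_concentration applies the unbound fraction", {
  expect_equal(free_concentration(100, 0.70), 70)
  expect_equal(free_concentration(0, 0.70), 0)
  expect_equal(free_concentration(500 / 12, 0.70), 29.17, tolerance = 1e-3)
  expect_error(free_concentration(10, 0), "fu")
  expect_error(free_concentration(10, 1.2), "fu")
  expect_error(free_concentration(-1), "non-negative")
})

test_that("regimens encode the loading-dose + CI convention", {
  reg <- ci_regimen(12)
  expect_equal(reg$rate, c(8000, 500))      # 4 g / 0.5 h, 500 mg/h
  expect_equal(reg$duration[1], 0.5)
  expect_equal(ci_regimen(24)$rate[2], 1000)
  expect_error(dosing_regimen(-1, 0, 1), "non-negative")

  cfg <- read_regimen_config(text = c("daily_dose_g: 8", "loading_dose_g: 4",
                                      "loading_minutes: 30  # comment"))
  expect_equal(cfg$rate, c(8000, 8000 / 24))
  expect_error(read_regimen_config(text = "no separator here"), "malformed")
})
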