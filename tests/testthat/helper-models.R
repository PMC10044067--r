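# Shared fixtures and independent oracles, all built in code.

table2 <- list(CL = 12.0, Vc = 20.7, Vp = 62.4, CLD = 4.77,
               omega2 = 0.190, sigma2 = 0.140, clcr_ref = 99.24)

table2_params <- function() {
  pk_parameters(table2$CL, table2$Vc, table2$Vp, table2$CLD)
}

# perturbed start values for refits (roughly 0.5-0.8 x truth)
start_far <- function() {
  final_model(CL = 10, Vc = 15, Vp = 40, CLD = 3,
              omega2_CL = 0.1, sigma2 = 0.1)
}

# a linear-in-eta Gaussian toy: y_ij = mu + eta_i + eps_ij, additive error.
# FOCEI must be exact on it.
linear_toy_model <- function(mu = 5, omega2 = 2, sigma2 = 1.5) {
  pop_model(
    structural_custom("MU", function(phi, subject, times) {
      rep(phi[["MU"]], length(times))
    }),
    theta = c(MU = mu),
    bpv = list(MU = list(omega2 = omega2, transform = "additive")),
    residual = residual_spec("additive", sigma2_add = sigma2)
  )
}

linear_toy_data <- function(n = 8, mu = 5, omega2 = 2, sigma2 = 1.5,
                            seed = 3) {
  set.seed(seed)
  pk_data(lapply(seq_len(n), function(i) {
    ni <- sample(1:4, 1)
    eta <- rnorm(1, 0, sqrt(omega2))
    pk_subject(i, list(), dosing_regimen(numeric(0), numeric(0), numeric(0)),
               times = seq_len(ni),
               dv = mu + eta + rnorm(ni, 0, sqrt(sigma2)))
  }))
}

# exact marginal -2LL for the linear toy (closed form)
linear_toy_m2ll <- function(data, mu, omega2, sigma2) {
  sum(vapply(data$subjects, function(s) {
    ni <- length(s$dv)
    V <- matrix(omega2, ni, ni) + diag(sigma2, ni)
    r <- s$dv - mu
    as.numeric(determinant(V)$modulus) + drop(r %*% solve(V) %*% r) +
      ni * log(2 * pi)
  }, numeric(1)))
}

# Independent marginal -2LL oracle: (non-adaptive) Gauss-Hermite quadrature
# over the single random effect, using only predict via the public API.
gh_m2ll <- function(model, data, nq = 61) {
  i <- seq_len(nq - 1)
  a <- sqrt(i / 2)
  J <- matrix(0, nq, nq)
  J[cbind(i, i + 1)] <- a
  J[cbind(i + 1, i)] <- a
  ev <- eigen(J, symmetric = TRUE)
  x <- ev$values
  w <- ev$vectors[1, ]^2  # weights / sqrt(pi)
  stopifnot(length(model$bpv) == 1)
  p_eta <- names(model$bpv)
  omega2 <- model$bpv[[1]]$omega2
  res <- model$residual
  sum(vapply(data$subjects, function(s) {
    lik <- sum(vapply(seq_len(nq), function(j) {
      eta <- stats::setNames(sqrt(2 * omega2) * x[j], p_eta)
      f <- cippk:::predict_subject(model, s, eta)
      g2 <- cippk:::resid_var(res, f)
      w[j] * exp(sum(stats::dnorm(s$dv, f, sqrt(g2), log = TRUE)))
    }, numeric(1)))
    -2 * log(lik)
  }, numeric(1)))
}

# small cheap steady-state toy for calibration studies: one-compartment CI,
# every subject observed twice at (near) steady state; fits in ~0.2 s.
ss_toy_cohort <- function(n = 24, theta_cl = 12, omega2 = 0.19,
                          sigma2 = 0.14, covariate = NULL, beta = 0,
                          seed = 1) {
  set.seed(seed)
  reg <- ci_regimen(12, loading_dose_g = 0)
  xval <- rnorm(n)
  pk_data(lapply(seq_len(n), function(i) {
    cl <- theta_cl * exp(beta * xval[i]) * exp(rnorm(1, 0, sqrt(omega2)))
    tt <- c(150, 200)
    f <- 500 / cl * (1 - exp(-cl / 25 * tt))
    dv <- f * (1 + rnorm(2, 0, sqrt(sigma2)))
    covs <- list(X = xval[i])
    pk_subject(i, covs, reg, tt[dv > 0], dv[dv > 0])
  }))
}

ss_toy_model <- function(theta_cl = 10, omega2 = 0.1, sigma2 = 0.1) {
  m <- pop_model(structural_pk(1),
                 theta = c(CL = theta_cl, Vc = 25),
                 bpv = list(CL = list(omega2 = omega2)),
                 residual = residual_spec("proportional",
                                          sigma2_prop = sigma2),
                 fixed = "Vc")
  m
}

fast_ctrl <- list(rel.tol = 1e-7, iter.max = 200, eval.max = 800)
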