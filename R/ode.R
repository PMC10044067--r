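# Adaptive Dormand-Prince RK45 integrator.
#
# No ODE-solver package ships with this environment, so the numerical route
# (saturable elimination, and the independent oracle for the closed forms)
# uses this small embedded Runge-Kutta pair with step-size control. The
# piecewise-constant infusion input is handled by integrating segment by
# segment between event breakpoints, so the right-hand side is smooth within
# every integration interval.

.dp_A <- matrix(c(
  0, 0, 0, 0, 0, 0,
  1/5, 0, 0, 0, 0, 0,
  3/40, 9/40, 0, 0, 0, 0,
  44/45, -56/15, 32/9, 0, 0, 0,
  19372/6561, -25360/2187, 64448/6561, -212/729, 0, 0,
  9017/3168, -355/33, 46732/5247, 49/176, -5103/18656, 0
), nrow = 6, byrow = TRUE)
.dp_c <- c(0, 1/5, 3/10, 4/5, 8/9, 1)
.dp_b5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
.dp_b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)

# Integrate dy/dt = f(t, y) from t0 to t1 (f smooth on [t0, t1]).
rk45_segment <- function(f, y0, t0, t1, rtol, atol, out_times = numeric(0)) {
  y <- y0
  t <- t0
  h <- min(t1 - t0, 0.1)
  out <- matrix(NA_real_, length(out_times), length(y0))
  oi <- 1L
  k <- matrix(0, 7, length(y0))
  while (t < t1 - 1e-14) {
    h <- min(h, t1 - t)
    k[1, ] <- f(t, y)
    for (s in 2:6) {
      k[s, ] <- f(t + .dp_c[s] * h,
                  y + h * drop(.dp_A[s, 1:(s - 1), drop = FALSE] %*%
                                 k[1:(s - 1), , drop = FALSE]))
    }
    y5 <- y + h * drop(.dp_b5[1:6] %*% k[1:6, , drop = FALSE])
    k[7, ] <- f(t + h, y5)
    y4 <- y + h * drop(.dp_b4 %*% k)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (err <= 1) {
      # dense output: cubic Hermite on the accepted step
      while (oi <= length(out_times) && out_times[oi] <= t + h + 1e-14) {
        th <- (out_times[oi] - t) / h
        f0 <- k[1, ]; f1 <- k[7, ]
        h00 <- (1 + 2 * th) * (1 - th)^2
        h10 <- th * (1 - th)^2
        h01 <- th^2 * (3 - 2 * th)
        h11 <- th^2 * (th - 1)
        out[oi, ] <- h00 * y + h10 * h * f0 + h01 * y5 + h11 * h * f1
        oi <- oi + 1L
      }
      t <- t + h
      y <- y5
    }
    h <- h * min(5, max(0.2, 0.9 * (1 / max(err, 1e-10))^(1/5)))
    if (h < 1e-12) stop("ODE step size underflow")
  }
  while (oi <= length(out_times)) { out[oi, ] <- y; oi <- oi + 1L }
  list(y = y, out = out)
}

# Right-hand side of the compartmental system in amounts (mg).
# y = (A_central, A_peripheral); input rate in mg/h.
pk_rhs <- function(params, elim, rate_fn) {
  Vc <- params$Vc; k12 <- params$k12; k21 <- params$k21
  k10 <- params$k10
  kind <- elim$kind
  Vmax <- elim$Vmax; Km <- elim$Km
  function(t, y) {
    C <- y[1] / Vc
    elim_rate <- switch(kind,
      first_order = k10 * y[1],
      michaelis_menten = Vmax * C / (Km + C),
      parallel_fo_mm = k10 * y[1] + Vmax * C / (Km + C))
    c(rate_fn(t) - elim_rate - k12 * y[1] + k21 * y[2],
      k12 * y[1] - k21 * y[2])
  }
}

#' Numerical (ODE) solution of the compartmental model
#'
#' Integrates the two-compartment amounts with adaptive RK45 and returns the
#' central concentration. Serves as the independent oracle for the closed
#' forms and as the solver for saturable elimination.
#'
#' @inheritParams predict_concentration
#' @param rtol,atol relative and absolute integration tolerances.
#' @return concentrations, mg/L, at `times`.
#' @export
ode_concentration <- function(params, elim, regimen, times,
                              rtol = 1e-8, atol = 1e-10) {
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times)) stop("times must be sorted increasingly")
  tmax <- max(times)
  brk <- sort(unique(c(0, regimen$start, regimen$start + regimen$duration,
                       tmax)))
  brk <- brk[is.finite(brk) & brk <= tmax]
  if (max(brk) < tmax) brk <- c(brk, tmax)
  rate_fn <- function(t) {
    sum(regimen$rate[regimen$start <= t & t < regimen$start + regimen$duration])
  }
  y <- c(0, 0)
  conc <- numeric(length(times))
  conc[times == 0] <- 0
  for (s in seq_len(length(brk) - 1)) {
    t0 <- brk[s]; t1 <- brk[s + 1]
    # rate is constant on (t0, t1); evaluate at the midpoint
    r <- rate_fn((t0 + t1) / 2)
    f_seg <- pk_rhs(params, elim, function(t) r)
    sel <- times > t0 + 1e-14 & times <= t1 + 1e-14
    res <- rk45_segment(f_seg, y, t0, t1, rtol, atol,
                        out_times = times[sel])
    y <- res$y
    if (any(sel)) conc[sel] <- res$out[, 1] / params$Vc
  }
  pmax(conc, 0)
}
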