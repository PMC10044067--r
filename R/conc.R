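# Closed-form solutions for zero-order infusion input.
#
# All closed forms are built from the unit impulse response of the central
# compartment and the superposition principle, so overlapping infusion events
# simply add. The two-compartment during/post-infusion branches collapse into
# one expression: with tau = t - start, te = min(tau, duration),
#   C(t) = (R0/Vc) * sum_l (C_l/lambda_l) (1 - e^{-lambda_l te}) e^{-lambda_l max(tau-dur,0)}
# over the hybrid constants lambda_l in {alpha, beta} with coefficients A, B.

# Vectorized two-compartment concentration. CL, Vc, Vp, CLD are vectors the
# same length as `times` (or scalars); `events` is a dosing_regimen.
conc2_first_order <- function(CL, Vc, Vp, CLD, times, events) {
  k10 <- CL / Vc; k12 <- CLD / Vc; k21 <- CLD / Vp
  s <- k10 + k12 + k21
  disc <- sqrt(pmax(s * s - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  A <- (alpha - k21) / (alpha - beta)
  B <- (k21 - beta) / (alpha - beta)
  conc <- numeric(length(times))
  for (i in seq_len(nrow(events))) {
    tau <- times - events$start[i]
    on <- tau > 0
    if (!any(on)) next
    tau <- tau[on]
    te <- pmin(tau, events$duration[i])
    tpost <- pmax(tau - events$duration[i], 0)
    al <- if (length(alpha) > 1) alpha[on] else alpha
    be <- if (length(beta) > 1) beta[on] else beta
    Ao <- if (length(A) > 1) A[on] else A
    Bo <- if (length(B) > 1) B[on] else B
    Vco <- if (length(Vc) > 1) Vc[on] else Vc
    conc[on] <- conc[on] + events$rate[i] / Vco *
      (Ao / al * (1 - exp(-al * te)) * exp(-al * tpost) +
       Bo / be * (1 - exp(-be * te)) * exp(-be * tpost))
  }
  conc
}

# One-compartment analogue (used for nested-model comparisons).
conc1_first_order <- function(CL, Vc, times, events) {
  k <- CL / Vc
  conc <- numeric(length(times))
  for (i in seq_len(nrow(events))) {
    tau <- times - events$start[i]
    on <- tau > 0
    if (!any(on)) next
    tau <- tau[on]
    te <- pmin(tau, events$duration[i])
    tpost <- pmax(tau - events$duration[i], 0)
    ko <- if (length(k) > 1) k[on] else k
    CLo <- if (length(CL) > 1) CL[on] else CL
    conc[on] <- conc[on] + events$rate[i] / CLo *
      (1 - exp(-ko * te)) * exp(-ko * tpost)
  }
  conc
}

#' Predict total plasma concentration under a dosing regimen
#'
#' Evaluates the disposition model at the requested times. First-order
#' elimination uses the closed-form biexponential solution per zero-order
#' infusion event, summed by superposition; saturable (Michaelis-Menten)
#' variants integrate the compartmental ODEs with an adaptive Runge-Kutta
#' scheme.
#'
#' @param params a [pk_parameters()] object.
#' @param regimen a [dosing_regimen()].
#' @param times sorted non-negative times, h.
#' @param elim an [elimination_spec()]; default first-order.
#' @param ode_control list of `rtol`, `atol` for the ODE path.
#' @return total plasma concentrations, mg/L (non-negative).
#' @examples
#' p <- pk_parameters(CL = 12, Vc = 20.7, Vp = 62.4, CLD = 4.77)
#' predict_concentration(p, ci_regimen(12), times = c(0, 0.5, 6, 24, 72))
#' @export
predict_concentration <- function(params, regimen, times,
                                  elim = elimination_spec("first_order"),
                                  ode_control = list(rtol = 1e-8, atol = 1e-10)) {
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times)) stop("times must be sorted increasingly")
  if (elim$kind == "first_order") {
    conc2_first_order(params$CL, params$Vc, params$Vp, params$CLD,
                      times, regimen)
  } else {
    ode_concentration(params, elim, regimen, times,
                      rtol = ode_control$rtol, atol = ode_control$atol)
  }
}

#' Convert total to free (unbound) concentration
#'
#' Piperacillin protein binding is about 30%, so the default unbound
#' fraction is `fu = 0.70`; the free concentration is simply `fu * C`.
#'
#' @param total total concentration(s), mg/L (non-negative).
#' @param fu unbound fraction in (0, 1].
#' @return free concentration(s), mg/L.
#' @export
free_concentration <- function(total, fu = 0.70) {
  if (any(total < 0)) stop("total concentration must be non-negative")
  if (fu <= 0 || fu > 1) stop("fu must lie in (0, 1]")
  fu * total
}
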