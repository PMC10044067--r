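#' Disposition parameters for the two-compartment model
#'
#' Container for individual or typical piperacillin disposition parameters:
#' plasma clearance `CL` (L/h), central volume `Vc` (L), peripheral volume
#' `Vp` (L) and distributional (intercompartmental) clearance `CLD` (L/h).
#' All four must be strictly positive; the derived micro rate constants
#' (`k10 = CL/Vc`, `k12 = CLD/Vc`, `k21 = CLD/Vp`) and hybrid constants
#' (`alpha > beta > 0`) then exist automatically.
#'
#' @param CL plasma clearance, L/h.
#' @param Vc central compartment distribution volume, L.
#' @param Vp peripheral compartment distribution volume, L.
#' @param CLD distributional clearance, L/h.
#' @return An object of class `pk_parameters`: a named list with the four
#'   parameters plus derived micro constants `k10`, `k12`, `k21`.
#' @examples
#' p <- pk_parameters(CL = 12.0, Vc = 20.7, Vp = 62.4, CLD = 4.77)
#' total_vd(p)  # 83.1 L
#' @seealso [hybrid_constants()], [individualize()]
#' @export
pk_parameters <- function(CL, Vc, Vp, CLD) {
  vals <- c(CL = CL, Vc = Vc, Vp = Vp, CLD = CLD)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all PK parameters (CL, Vc, Vp, CLD) must be strictly positive")
  }
  structure(
    list(CL = CL, Vc = Vc, Vp = Vp, CLD = CLD,
         k10 = CL / Vc, k12 = CLD / Vc, k21 = CLD / Vp),
    class = "pk_parameters"
  )
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("Two-compartment PK parameters:\n")
  cat(sprintf("  CL  = %.4g L/h\n  Vc  = %.4g L\n  Vp  = %.4g L\n  CLD = %.4g L/h\n",
              x$CL, x$Vc, x$Vp, x$CLD))
  hc <- hybrid_constants(x)
  cat(sprintf("  alpha = %.4g 1/h, beta = %.4g 1/h (t1/2,beta = %.3g h)\n",
              hc$alpha, hc$beta, log(2) / hc$beta))
  invisible(x)
}

#' Hybrid (macro) rate constants of the two-compartment model
#'
#' Computes the fast (`alpha`) and slow (`beta`) disposition rate constants
#' and the corresponding central-compartment coefficients `A`, `B`
#' (normalised so `A + B = 1`) from the micro constants. `alpha > beta > 0`
#' always holds for valid parameters.
#'
#' @param params a [pk_parameters()] object.
#' @return list with `alpha`, `beta`, `A`, `B`.
#' @export
hybrid_constants <- function(params) {
  s <- params$k10 + params$k12 + params$k21
  p <- params$k10 * params$k21
  disc <- sqrt(pmax(s^2 - 4 * p, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  A <- (alpha - params$k21) / (alpha - beta)
  B <- (params$k21 - beta) / (alpha - beta)
  list(alpha = alpha, beta = beta, A = A, B = B)
}

#' Total (steady-state) volume of distribution
#'
#' @param params a [pk_parameters()] object.
#' @return `Vc + Vp` in litres.
#' @export
total_vd <- function(params) params$Vc + params$Vp

#' Apply a between-patient random effect to clearance
#'
#' Between-patient variability enters exponentially on plasma clearance only
#' (`CL_i = TVCL * exp(eta)`); the volumes and distributional clearance stay
#' at their typical values.
#'
#' @param typical a [pk_parameters()] object holding typical values.
#' @param eta_CL dimensionless random effect on log clearance.
#' @return a new [pk_parameters()] object with individualized `CL`.
#' @export
individualize <- function(typical, eta_CL) {
  stopifnot(is.finite(eta_CL))
  pk_parameters(CL = typical$CL * exp(eta_CL),
                Vc = typical$Vc, Vp = typical$Vp, CLD = typical$CLD)
}

#' Reduction in a between-patient variance between two nested models
#'
#' Standard pharmacometric summary of how much of the between-patient
#' variance a covariate explains: `100 * (omega2_base - omega2_final) /
#' omega2_base` (percent).
#'
#' @param omega2_base variance in the model without the covariate.
#' @param omega2_final variance in the model with the covariate.
#' @return percent reduction (negative if the variance grew).
#' @export
bpv_reduction <- function(omega2_base, omega2_final) {
  stopifnot(omega2_base > 0, omega2_final >= 0)
  100 * (omega2_base - omega2_final) / omega2_base
}
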