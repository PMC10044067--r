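#' Renal function panel
#'
#' The covariates needed by the creatinine-clearance equations.
#'
#' @param age years (>= 18).
#' @param sex `"male"` or `"female"`.
#' @param weight kg.
#' @param scr serum creatinine, mg/dL.
#' @param height cm (optional; only used for body surface area).
#' @param black logical race flag for the equations that carry a race
#'   coefficient (the study cohort was 96% Caucasian).
#' @return object of class `renal_panel`.
#' @export
renal_panel <- function(age, sex = c("male", "female"), weight, scr,
                        height = NA_real_, black = FALSE) {
  sex <- match.arg(sex)
  if (age < 18) stop("adult equations only: age must be >= 18")
  if (scr <= 0) stop("serum creatinine must be positive")
  if (weight <= 0) stop("weight must be positive")
  structure(list(age = age, sex = sex, weight = weight, scr = scr,
                 height = height, black = isTRUE(black)),
            class = "renal_panel")
}

#' Estimated creatinine clearance / glomerular filtration rate
#'
#' Implements the three published equations compared in the analysis:
#' \describe{
#'   \item{CKD-EPI}{the 2009 creatinine equation,
#'     `141 * min(Scr/kappa, 1)^a * max(Scr/kappa, 1)^-1.209 * 0.993^age`
#'     with female (1.018) and, optionally, black-race (1.159) factors;
#'     mL/min/1.73 m2.}
#'   \item{CG}{Cockcroft-Gault, `(140 - age) * weight / (72 * Scr)` with the
#'     0.85 female factor; raw mL/min, no body-surface-area indexing.}
#'   \item{MDRD-4}{4-variable MDRD (IDMS-traceable, 175 coefficient),
#'     `175 * Scr^-1.154 * age^-0.203` with female (0.742) and black (1.212)
#'     factors; mL/min/1.73 m2.}
#' }
#'
#' @param panel a [renal_panel()].
#' @param formula one of `"CKD-EPI"`, `"CG"`, `"MDRD-4"`.
#' @param race_coefficient apply the race coefficient of the original
#'   equations (default `TRUE`; set `FALSE` for the race-free variant).
#' @return estimated clearance; mL/min for CG, mL/min/1.73 m2 otherwise.
#' @export
renal_function <- function(panel, formula = c("CKD-EPI", "CG", "MDRD-4"),
                           race_coefficient = TRUE) {
  formula <- match.arg(formula)
  female <- panel$sex == "female"
  black <- panel$black && race_coefficient
  switch(formula,
    "CKD-EPI" = {
      kappa <- if (female) 0.7 else 0.9
      a <- if (female) -0.329 else -0.411
      r <- panel$scr / kappa
      141 * pmin(r, 1)^a * pmax(r, 1)^(-1.209) * 0.993^panel$age *
        (if (female) 1.018 else 1) * (if (black) 1.159 else 1)
    },
    "CG" = {
      (140 - panel$age) * panel$weight / (72 * panel$scr) *
        (if (female) 0.85 else 1)
    },
    "MDRD-4" = {
      175 * panel$scr^(-1.154) * panel$age^(-0.203) *
        (if (female) 0.742 else 1) * (if (black) 1.212 else 1)
    })
}

#' Augmented renal clearance flag
#'
#' ARC is defined as a CKD-EPI creatinine clearance of at least 130
#' mL/min/1.73 m2.
#'
#' @param clcr_ckdepi CKD-EPI value(s), mL/min/1.73 m2.
#' @return logical vector.
#' @export
is_arc <- function(clcr_ckdepi) clcr_ckdepi >= 130

# Invert CKD-EPI for a target clearance: the serum creatinine that a subject
# with these demographics would need. Keeps generated covariate panels
# round-trip consistent with the formula. The equation is piecewise power in
# Scr and strictly decreasing, so the inverse is closed-form (vectorized).
scr_from_ckdepi <- function(target, age, sex, black = FALSE) {
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  a <- ifelse(female, -0.329, -0.411)
  const <- 141 * 0.993^age * ifelse(female, 1.018, 1) *
    ifelse(black, 1.159, 1)
  r <- ifelse(target >= const,
              (target / const)^(1 / a),
              (target / const)^(-1 / 1.209))
  kappa * r
}
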