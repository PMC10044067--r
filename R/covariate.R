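#' Covariate relation on a PK parameter
#'
#' Describes how a typical parameter value depends on a covariate. Supported
#' forms, with `x` the covariate, `ref` the centering value and `beta` the
#' coefficient (ignored by `proportional`):
#' \describe{
#'   \item{proportional}{`theta * x / ref` — linear through the origin, the
#'     renal-function relation of the final model (reference 99.24
#'     mL/min/1.73 m2 for creatinine clearance).}
#'   \item{linear}{`theta * (1 + beta * (x - ref))`.}
#'   \item{power}{`theta * (x / ref)^beta` (allometric when `beta` is fixed
#'     at 0.75 on body weight).}
#'   \item{exponential}{`theta * exp(beta * (x - ref))`.}
#'   \item{binary}{`theta * (1 + beta * x)` for a 0/1 flag.}
#' }
#'
#' @param covariate name of the covariate column.
#' @param form one of `"proportional"`, `"linear"`, `"power"`,
#'   `"exponential"`, `"binary"`.
#' @param reference centering value (median of the covariate; unused for
#'   `binary`).
#' @param beta coefficient; `NA` marks it as to-be-estimated, and
#'   `proportional` has none.
#' @param fixed_beta logical; if `TRUE` the coefficient is not estimated
#'   (e.g. allometric exponent fixed at 0.75).
#' @return an object of class `covariate_relation`.
#' @export
covariate_relation <- function(covariate, form = c("proportional", "linear",
                                                   "power", "exponential",
                                                   "binary"),
                               reference = NA_real_, beta = NA_real_,
                               fixed_beta = FALSE) {
  form <- match.arg(form)
  if (form != "binary" && !is.finite(reference)) {
    stop("continuous covariate forms need a finite reference value")
  }
  structure(list(covariate = covariate, form = form, reference = reference,
                 beta = beta, fixed_beta = isTRUE(fixed_beta)),
            class = "covariate_relation")
}

#' Multiplicative covariate factor
#'
#' The factor by which a covariate relation scales the typical parameter
#' value; [typical_clearance()] is `theta * cov_factor(...)`.
#'
#' @param relation a [covariate_relation()].
#' @param x covariate value(s).
#' @param beta coefficient to use (overrides the one stored in `relation`).
#' @return numeric vector of factors; a domain error is raised if any factor
#'   is non-positive (a linear form with an extreme slope can do this).
#' @export
cov_factor <- function(relation, x, beta = relation$beta) {
  f <- switch(relation$form,
    proportional = x / relation$reference,
    linear = 1 + beta * (x - relation$reference),
    power = (x / relation$reference)^beta,
    exponential = exp(beta * (x - relation$reference)),
    binary = 1 + beta * x
  )
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("covariate relation predicts a non-positive parameter value")
  }
  f
}

#' Typical clearance at a given creatinine clearance
#'
#' Evaluates the covariate model for typical plasma clearance. For the final
#' model's proportional form this is `theta * clcr / reference`, so the
#' typical patient (`clcr == reference`) has clearance exactly `theta`.
#'
#' @param relation a [covariate_relation()] on clearance (continuous form).
#' @param theta typical clearance at the reference covariate value, L/h.
#' @param clcr creatinine clearance value(s), mL/min/1.73 m2; must be > 0.
#' @return typical clearance(s), L/h.
#' @examples
#' rel <- covariate_relation("CLCR", "proportional", reference = 99.24)
#' typical_clearance(rel, theta = 12.0, clcr = 99.24)   # 12.0
#' typical_clearance(rel, theta = 12.0, clcr = 198.48)  # 24.0
#' @export
typical_clearance <- function(relation, theta, clcr) {
  if (any(!is.finite(clcr)) || any(clcr <= 0)) {
    stop("clcr must be strictly positive")
  }
  stopifnot(theta > 0)
  theta * cov_factor(relation, clcr)
}
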