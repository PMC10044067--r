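#' Residual-error specification
#'
#' @param model `"proportional"` (`var = sigma2_prop * f^2`), `"additive"`
#'   (`var = sigma2_add`) or `"combined"` (sum of both).
#' @param sigma2_prop proportional-error variance (dimensionless).
#' @param sigma2_add additive-error variance, (mg/L)^2.
#' @return object of class `residual_spec`.
#' @export
residual_spec <- function(model = c("proportional", "additive", "combined"),
                          sigma2_prop = NA_real_, sigma2_add = NA_real_) {
  model <- match.arg(model)
  if (model %in% c("proportional", "combined") &&
      (!is.finite(sigma2_prop) || sigma2_prop <= 0)) {
    stop("sigma2_prop must be positive for this residual model")
  }
  if (model %in% c("additive", "combined") &&
      (!is.finite(sigma2_add) || sigma2_add <= 0)) {
    stop("sigma2_add must be positive for this residual model")
  }
  structure(list(model = model, sigma2_prop = sigma2_prop,
                 sigma2_add = sigma2_add),
            class = "residual_spec")
}

# residual variance given predictions (interaction: f is the conditional
# prediction under FOCEI). Floored to keep log() finite at f = 0.
resid_var <- function(residual, f) {
  v <- switch(residual$model,
    proportional = residual$sigma2_prop * f * f,
    additive = rep_len(residual$sigma2_add, length(f)),
    combined = residual$sigma2_add + residual$sigma2_prop * f * f)
  pmax(v, 1e-10)
}

#' Nonlinear mixed-effects population model
#'
#' Bundles the structural model, fixed effects, covariate relations,
#' between-patient variability (BPV) and residual-error model. The built-in
#' structural model is the compartmental infusion model (`structural_pk()`);
#' a custom prediction function can be supplied for toy or diagnostic
#' models.
#'
#' @param structural a [structural_pk()] description (or
#'   [structural_custom()]).
#' @param theta named numeric vector of fixed effects on the natural scale;
#'   must contain every structural parameter, plus any covariate
#'   coefficients named `beta_<param>_<covariate>`.
#' @param covariates named list: parameter name -> list of
#'   [covariate_relation()]s applied multiplicatively.
#' @param bpv named list: parameter name -> `list(omega2 =, transform =)`
#'   where `transform` is `"exp"` (lognormal, the default) or `"additive"`.
#' @param residual a [residual_spec()].
#' @param fixed character vector of estimate names excluded from estimation
#'   (e.g. `"Vp"`, `"beta_CL_WT"` for an allometric exponent fixed at 0.75).
#' @return object of class `pop_model`.
#' @seealso [final_model()], [base_model()] for the piperacillin models.
#' @export
pop_model <- function(structural, theta, covariates = list(),
                      bpv = list(), residual, fixed = character()) {
  stopifnot(inherits(residual, "residual_spec"))
  missing_pars <- setdiff(structural$pars, names(theta))
  if (length(missing_pars)) {
    stop("theta lacks structural parameter(s): ",
         paste(missing_pars, collapse = ", "))
  }
  if (any(theta[structural$pars] <= 0)) {
    stop("structural parameters must be strictly positive")
  }
  for (p in names(bpv)) {
    b <- bpv[[p]]
    if (is.null(b$transform)) bpv[[p]]$transform <- "exp"
    if (!is.finite(b$omega2) || b$omega2 < 0) stop("omega2 must be >= 0")
    if (!p %in% structural$pars) stop("BPV on unknown parameter ", p)
  }
  for (p in names(covariates)) {
    rels <- covariates[[p]]
    if (inherits(rels, "covariate_relation")) {
      covariates[[p]] <- list(rels); rels <- covariates[[p]]
    }
    for (rel in rels) {
      bn <- beta_name(p, rel$covariate)
      if (rel$form != "proportional" && !bn %in% names(theta)) {
        theta[bn] <- if (is.finite(rel$beta)) rel$beta else 0
      }
      if (rel$form != "proportional" && rel$fixed_beta) {
        fixed <- union(fixed, bn)
      }
    }
  }
  structure(list(structural = structural, theta = theta,
                 covariates = covariates, bpv = bpv, residual = residual,
                 fixed = fixed),
            class = "pop_model")
}

beta_name <- function(param, covariate) paste0("beta_", param, "_", covariate)

#' Built-in compartmental structural model
#'
#' @param n_compartments 1 or 2.
#' @param elim an [elimination_spec()]; saturable kinds add `Vmax`, `Km` to
#'   the structural parameters and are solved by ODE integration.
#' @return structural description used by [pop_model()].
#' @export
structural_pk <- function(n_compartments = 2,
                          elim = elimination_spec("first_order")) {
  stopifnot(n_compartments %in% c(1, 2))
  pars <- if (n_compartments == 2) c("CL", "Vc", "Vp", "CLD") else c("CL", "Vc")
  if (elim$kind == "michaelis_menten") pars <- setdiff(pars, "CL")
  if (elim$kind != "first_order") pars <- c(pars, "Vmax", "Km")
  list(kind = "pk", n_compartments = n_compartments, elim = elim, pars = pars)
}

#' Custom structural model (arbitrary prediction function)
#'
#' Mostly used to embed analytically tractable toy models (e.g. models
#' linear in the random effect) into the same estimation machinery for
#' validation purposes.
#'
#' @param pars character vector of structural parameter names.
#' @param predict `function(phi, subject, times)` returning predictions;
#'   `phi` is the named vector of individualized parameters.
#' @export
structural_custom <- function(pars, predict) {
  list(kind = "custom", pars = pars, predict = predict)
}

# typical value of parameter p for every subject (vectorized over a
# covariate table with one row per subject).
typical_values <- function(model, p, covtab) {
  tv <- rep_len(model$theta[[p]], nrow(covtab))
  for (rel in model$covariates[[p]]) {
    x <- covtab[[rel$covariate]]
    if (is.null(x)) stop("missing covariate ", rel$covariate)
    beta <- if (rel$form == "proportional") NA_real_ else
      model$theta[[beta_name(p, rel$covariate)]]
    tv <- tv * cov_factor(rel, x, beta)
  }
  tv
}

# individualized parameter set (named vector) for one subject
individual_phi <- function(model, subject, eta = NULL) {
  covtab <- if (length(subject$covariates)) as.data.frame(subject$covariates)
            else data.frame(row.names = 1)
  phi <- vapply(model$structural$pars, function(p) {
    tv <- typical_values(model, p, covtab)
    if (!is.null(eta) && p %in% names(eta)) {
      tr <- model$bpv[[p]]$transform %||% "exp"
      tv <- if (tr == "exp") tv * exp(eta[[p]]) else tv + eta[[p]]
    }
    tv
  }, numeric(1))
  names(phi) <- model$structural$pars
  phi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# structural prediction for one subject
predict_subject <- function(model, subject, eta = NULL) {
  st <- model$structural
  if (st$kind == "custom") {
    phi <- individual_phi(model, subject, eta)
    return(st$predict(phi, subject, subject$times))
  }
  phi <- individual_phi(model, subject, eta)
  if (st$elim$kind == "first_order") {
    if (st$n_compartments == 2) {
      conc2_first_order(phi[["CL"]], phi[["Vc"]], phi[["Vp"]], phi[["CLD"]],
                        subject$times, subject$events)
    } else {
      conc1_first_order(phi[["CL"]], phi[["Vc"]], subject$times,
                        subject$events)
    }
  } else {
    elim <- elimination_spec(st$elim$kind, Vmax = phi[["Vmax"]],
                             Km = phi[["Km"]])
    Vc <- phi[["Vc"]]
    CL <- if ("CL" %in% names(phi)) phi[["CL"]] else 1e-12
    Vp <- if (st$n_compartments == 2) phi[["Vp"]] else 1e6
    CLD <- if (st$n_compartments == 2) phi[["CLD"]] else 1e-12
    pars <- list(CL = CL, Vc = Vc, Vp = Vp, CLD = CLD,
                 k10 = CL / Vc, k12 = CLD / Vc, k21 = CLD / Vp)
    ode_concentration(pars, elim, subject$events, subject$times,
                      rtol = 1e-7, atol = 1e-9)
  }
}

#' Final piperacillin population model
#'
#' Two-compartment model with first-order elimination, proportional
#' creatinine-clearance (CKD-EPI) effect on clearance centered at 99.24
#' mL/min/1.73 m2, exponential between-patient variability on clearance and
#' proportional residual error. Defaults are the published final estimates
#' (CL 12.0 L/h, Vc 20.7 L, Vp 62.4 L, CLD 4.77 L/h, omega2_CL 0.190,
#' sigma2 0.140).
#'
#' @param CL,Vc,Vp,CLD fixed effects (typical values at the reference).
#' @param omega2_CL variance of the exponential random effect on CL.
#' @param sigma2 proportional residual variance.
#' @param clcr_reference centering value for creatinine clearance.
#' @param clcr_covariate covariate column name (default `"CLCR"`).
#' @return a [pop_model()].
#' @export
final_model <- function(CL = 12.0, Vc = 20.7, Vp = 62.4, CLD = 4.77,
                        omega2_CL = 0.190, sigma2 = 0.140,
                        clcr_reference = 99.24, clcr_covariate = "CLCR") {
  pop_model(
    structural = structural_pk(2),
    theta = c(CL = CL, Vc = Vc, Vp = Vp, CLD = CLD),
    covariates = list(CL = covariate_relation(clcr_covariate, "proportional",
                                              reference = clcr_reference)),
    bpv = list(CL = list(omega2 = omega2_CL, transform = "exp")),
    residual = residual_spec("proportional", sigma2_prop = sigma2)
  )
}

#' Base (no-covariate) piperacillin population model
#'
#' Same structure as [final_model()] but without the renal-function
#' covariate; defaults are the published base-model estimates.
#'
#' @inheritParams final_model
#' @export
base_model <- function(CL = 11.9, Vc = 20.4, Vp = 65.3, CLD = 5.6,
                       omega2_CL = 0.253, sigma2 = 0.148) {
  pop_model(
    structural = structural_pk(2),
    theta = c(CL = CL, Vc = Vc, Vp = Vp, CLD = CLD),
    bpv = list(CL = list(omega2 = omega2_CL, transform = "exp")),
    residual = residual_spec("proportional", sigma2_prop = sigma2)
  )
}

#' Add a covariate relation to a model
#'
#' Convenience for stepwise covariate selection: returns a copy of the model
#' with one more covariate relation on a parameter (coefficient initialised
#' at 0 unless given).
#'
#' @param model a [pop_model()].
#' @param param parameter receiving the covariate.
#' @param relation a [covariate_relation()].
#' @export
add_covariate <- function(model, param, relation) {
  covs <- model$covariates
  covs[[param]] <- c(covs[[param]], list(relation))
  pop_model(model$structural, model$theta, covs, model$bpv, model$residual,
            model$fixed)
}
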