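#' Likelihood-ratio test between nested FOCEI fits
#'
#' `delta_ofv = OFV_nested - OFV_full` is referenced against a chi-squared
#' quantile expressed in OFV units. The study conventions: 7.879 (p < 0.005,
#' 1 df) for base-model development, 3.841 (p < 0.05) for forward covariate
#' inclusion and 10.8 (p < 0.001) for backward elimination.
#'
#' @param nested_fit,full_fit [fit_model()] results (or any objects with an
#'   `ofv` element); `full_fit` must have `df` more estimated parameters.
#' @param df degrees-of-freedom difference (informational; the threshold is
#'   given directly in OFV units).
#' @param threshold OFV-difference threshold (default 7.879).
#' @return list with `delta_ofv`, `significant`, `threshold`, `df`.
#' @export
lrt <- function(nested_fit, full_fit, df = 1, threshold = 7.879) {
  d <- nested_fit$ofv - full_fit$ofv
  if (d < -0.05) {
    warning("full model has higher OFV than nested model (delta = ",
            format(d, digits = 3), "); possible optimizer failure")
  }
  list(delta_ofv = d, significant = d > threshold, threshold = threshold,
       df = df)
}

#' Akaike information criterion of a fit
#'
#' `OFV + 2 * (number of estimated parameters)`; used to compare
#' non-hierarchical models (e.g. first-order versus Michaelis-Menten
#' elimination).
#'
#' @param fit a [fit_model()] result.
#' @return numeric AIC.
#' @export
aic <- function(fit) fit$ofv + 2 * fit$n_par

# remove one covariate relation (and its coefficient) from a model
drop_covariate <- function(model, param, covariate) {
  rels <- model$covariates[[param]]
  keep <- vapply(rels, function(r) r$covariate != covariate, TRUE)
  model$covariates[[param]] <- rels[keep]
  if (!length(model$covariates[[param]])) model$covariates[[param]] <- NULL
  bn <- beta_name(param, covariate)
  model$theta <- model$theta[setdiff(names(model$theta), bn)]
  model$fixed <- setdiff(model$fixed, bn)
  pop_model(model$structural, model$theta, model$covariates, model$bpv,
            model$residual, model$fixed)
}

#' Stepwise covariate selection (forward inclusion / backward elimination)
#'
#' Cumulative forward inclusion at `delta OFV > forward_threshold` (default
#' 3.841, p < 0.05) followed by backward elimination at `delta OFV >
#' backward_threshold` (default 10.8, p < 0.001). At each forward step every
#' remaining candidate is fitted on top of the current model; the candidate
#' with the largest significant OFV drop is added (ties broken by larger
#' reduction of the between-patient variance, then input order).
#' Non-converging candidate fits are recorded and skipped.
#'
#' @param base_model a [pop_model()] without the candidate covariates.
#' @param data a [pk_data()].
#' @param candidates list of candidates, each
#'   `list(param = "CL", relation = covariate_relation(...))`.
#' @param forward_threshold,backward_threshold OFV-difference thresholds.
#' @param control outer-optimizer control passed to [fit_model()].
#' @return list with `final_fit`, `selected` (list of retained candidates),
#'   and `trace` (data.frame logging every step: phase, candidate, delta
#'   OFV, BPV reduction, action).
#' @export
covariate_scan <- function(base_model, data, candidates,
                           forward_threshold = 3.841,
                           backward_threshold = 10.8,
                           control = list()) {
  cand_label <- function(cd) paste0(cd$param, "~", cd$relation$covariate,
                                    " (", cd$relation$form, ")")
  bpv_of <- function(f) {
    if (length(f$model$bpv)) f$model$bpv[[1]]$omega2 else NA_real_
  }
  current_model <- base_model
  current_fit <- fit_model(current_model, data, hessian = FALSE,
                           control = control)
  trace <- data.frame(step = integer(0), phase = character(0),
                      candidate = character(0), delta_ofv = numeric(0),
                      bpv_reduction = numeric(0), action = character(0))
  log_step <- function(step, phase, cand, dofv, bpvred, action) {
    rbind(trace, data.frame(step = step, phase = phase, candidate = cand,
                            delta_ofv = dofv, bpv_reduction = bpvred,
                            action = action))
  }
  remaining <- candidates
  included <- list()
  step <- 0L
  # forward inclusion
  repeat {
    if (!length(remaining)) break
    step <- step + 1L
    results <- vector("list", length(remaining))
    for (j in seq_along(remaining)) {
      cd <- remaining[[j]]
      m <- add_covariate(current_model, cd$param, cd$relation)
      f <- tryCatch(fit_model(m, data,
                              start = current_fit$estimates[
                                intersect(names(current_fit$estimates),
                                          names(model_estimates(m)))],
                              hessian = FALSE, control = control),
                    error = function(e) NULL)
      if (is.null(f)) {
        trace <- log_step(step, "forward", cand_label(cd), NA, NA,
                          "fit failed; skipped")
        next
      }
      dofv <- current_fit$ofv - f$ofv
      bpvred <- bpv_reduction(max(bpv_of(current_fit), 1e-12), bpv_of(f))
      results[[j]] <- list(cd = cd, fit = f, dofv = dofv, bpvred = bpvred)
      trace <- log_step(step, "forward", cand_label(cd), dofv, bpvred,
                        "evaluated")
    }
    ok <- Filter(Negate(is.null), results)
    if (!length(ok)) break
    dofvs <- vapply(ok, `[[`, numeric(1), "dofv")
    bpvs <- vapply(ok, `[[`, numeric(1), "bpvred")
    best <- order(-dofvs, -bpvs)[1]
    if (dofvs[best] <= forward_threshold) break
    chosen <- ok[[best]]
    included <- c(included, list(chosen$cd))
    remaining <- Filter(function(cd) cand_label(cd) != cand_label(chosen$cd),
                        remaining)
    current_model <- chosen$fit$model
    current_fit <- chosen$fit
    trace <- log_step(step, "forward", cand_label(chosen$cd), chosen$dofv,
                      chosen$bpvred, "added")
  }
  # backward elimination
  repeat {
    if (!length(included)) break
    step <- step + 1L
    worst <- NULL
    for (j in seq_along(included)) {
      cd <- included[[j]]
      m <- drop_covariate(current_model, cd$param, cd$relation$covariate)
      f <- tryCatch(fit_model(m, data, hessian = FALSE, control = control),
                    error = function(e) NULL)
      if (is.null(f)) next
      dofv <- f$ofv - current_fit$ofv  # OFV increase on removal
      trace <- log_step(step, "backward", cand_label(cd), dofv, NA,
                        "removal evaluated")
      if (is.null(worst) || dofv < worst$dofv) {
        worst <- list(j = j, cd = cd, fit = f, dofv = dofv)
      }
    }
    if (is.null(worst) || worst$dofv > backward_threshold) break
    trace <- log_step(step, "backward", cand_label(worst$cd), worst$dofv, NA,
                      "removed")
    included <- included[-worst$j]
    current_model <- worst$fit$model
    current_fit <- worst$fit
  }
  if (is.null(current_fit$cov)) {
    current_fit <- fit_model(current_fit$model, data, control = control)
  }
  list(final_fit = current_fit, selected = included, trace = trace)
}
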