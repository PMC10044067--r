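#' Residual diagnostics tables
#'
#' Per-observation diagnostics of a converged fit: population prediction
#' `PRED` (random effects at zero), individual prediction `IPRED` (at the
#' conditional mode), individual weighted residual `IWRES = (DV - IPRED) /
#' sd(IPRED)`, and conditional weighted residual `CWRES` — the FOCE-
#' linearized marginal residual whitened by the full per-subject covariance
#' (`V^{-1/2} (y - f + G eta-hat)` with the interaction variance).
#'
#' @param fit a [fit_model()] result.
#' @param data a [pk_data()] (defaults to the fitted data).
#' @return data.frame with columns `ID`, `TIME`, `DV`, `PRED`, `IPRED`,
#'   `IWRES`, `CWRES`, `flag_zero_ipred`.
#' @export
residual_tables <- function(fit, data = fit$data) {
  model <- fit$model
  eta_names <- names(model$bpv)
  k <- length(eta_names)
  omega2 <- if (k) vapply(model$bpv, `[[`, numeric(1), "omega2") else numeric(0)
  Omega <- diag(omega2, k)
  rows <- lapply(seq_along(data$subjects), function(i) {
    s <- data$subjects[[i]]
    ni <- length(s$dv)
    if (ni == 0) return(NULL)
    etahat <- if (k) stats::setNames(fit$eta[i, ], eta_names) else NULL
    pred <- predict_subject(model, s,
                            if (k) stats::setNames(numeric(k), eta_names)
                            else NULL)
    ipred <- predict_subject(model, s, etahat)
    gv <- resid_var(model$residual, ipred)
    iwres <- (s$dv - ipred) / sqrt(gv)
    if (k) {
      h <- 1e-4
      G <- matrix(0, ni, k)
      for (j in seq_len(k)) {
        ep <- etahat; em <- etahat
        ep[j] <- ep[j] + h; em[j] <- em[j] - h
        G[, j] <- (predict_subject(model, s, ep) -
                     predict_subject(model, s, em)) / (2 * h)
      }
      V <- G %*% Omega %*% t(G) + diag(gv, ni)
      r <- s$dv - ipred + drop(G %*% etahat)
    } else {
      V <- diag(gv, ni)
      r <- s$dv - ipred
    }
    cwres <- backsolve(chol(V), r, transpose = TRUE)
    data.frame(ID = s$id, TIME = s$times, DV = s$dv, PRED = pred,
               IPRED = ipred, IWRES = iwres, CWRES = cwres,
               flag_zero_ipred = model$residual$model == "proportional" &
                 ipred <= 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Eta- and epsilon-shrinkage
#'
#' `eta-shrinkage = 100 * (1 - SD(eta-hat) / omega)` per random effect and
#' `eps-shrinkage = 100 * (1 - SD(IWRES))`. Both collapse towards 100% as
#' the individual data become uninformative.
#'
#' @param fit a [fit_model()] result (>= 2 subjects).
#' @param data a [pk_data()] (defaults to the fitted data).
#' @return list with `eta_shrinkage` (named, %) and `eps_shrinkage` (%).
#' @export
shrinkage <- function(fit, data = fit$data) {
  if (fit$n_subjects < 2) stop("shrinkage needs at least 2 subjects")
  eta_names <- names(fit$model$bpv)
  eta_shr <- vapply(seq_along(eta_names), function(j) {
    om2 <- fit$model$bpv[[j]]$omega2
    if (om2 <= 0) return(NA_real_)
    100 * (1 - stats::sd(fit$eta[, j]) / sqrt(om2))
  }, numeric(1))
  names(eta_shr) <- eta_names
  rt <- residual_tables(fit, data)
  list(eta_shrinkage = eta_shr,
       eps_shrinkage = 100 * (1 - stats::sd(rt$IWRES)))
}

#' Condition number of the estimation
#'
#' Square root of the ratio of the largest to the smallest eigenvalue of
#' the correlation matrix of the parameter estimates. `Inf` when the matrix
#' is numerically singular.
#'
#' @param fit a [fit_model()] result with a successful covariance step, or a
#'   correlation/covariance matrix.
#' @return dimensionless condition number.
#' @export
condition_number <- function(fit) {
  cm <- if (inherits(fit, "pk_fit")) {
    if (is.null(fit$cov)) stop("covariance step did not succeed")
    fit$cov
  } else fit
  cr <- stats::cov2cor(cm)
  ev <- eigen(cr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= .Machine$double.eps * max(ev)) return(Inf)
  sqrt(max(ev) / min(ev))
}
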