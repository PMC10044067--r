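# FOCEI estimation engine.
#
# Each subject's marginal likelihood is approximated at the conditional mode
# (empirical Bayes estimate) eta-hat of the penalized conditional objective,
# with the residual variance evaluated at the conditional prediction (the
# "interaction" part of FOCEI):
#
#   q_i(eta) = sum_j [(y_ij - f_ij(eta))^2 / g_ij^2(eta) + log g_ij^2(eta)]
#              + eta' Omega^-1 eta
#   eta-hat_i = argmin q_i
#   OFV_i = q_i(eta-hat) + log det Omega + log det(H_i / 2) + n_i log 2*pi
#
# where H_i is the Hessian of q_i at the mode (Laplace approximation; the
# Gauss-Newton H_i = 2 (G' D^-1 G + Omega^-1) is the fallback when the
# numerical Hessian is not positive definite). On models linear in eta with
# additive error the Hessian is exact and the value equals the exact -2 log
# likelihood. A vectorized path (all subjects advanced in lockstep) covers
# the common case of a single exponential random effect on the built-in
# first-order compartmental model; everything else goes through a generic
# per-subject path.

INNER_GTOL <- 1e-8  # inner gradient tolerance (per design)

# ---- parameter bookkeeping -------------------------------------------------

param_map <- function(model) {
  nm <- names(model$theta)
  kind <- ifelse(startsWith(nm, "beta_"), "beta", "theta")
  map <- data.frame(name = nm, kind = kind,
                    trans = ifelse(kind == "beta", "identity", "log"),
                    stringsAsFactors = FALSE)
  for (p in names(model$bpv)) {
    map <- rbind(map, data.frame(name = paste0("omega2_", p), kind = "omega2",
                                 trans = "log"))
  }
  res <- model$residual
  if (res$model %in% c("proportional", "combined")) {
    map <- rbind(map, data.frame(name = "sigma2_prop", kind = "sigma2",
                                 trans = "log"))
  }
  if (res$model %in% c("additive", "combined")) {
    map <- rbind(map, data.frame(name = "sigma2_add", kind = "sigma2",
                                 trans = "log"))
  }
  map$estimated <- !map$name %in% model$fixed
  map
}

#' Current estimate vector of a model
#'
#' Named vector of all fixed effects, variance components and residual
#' variances of a [pop_model()] on the natural scale.
#'
#' @param model a [pop_model()].
#' @return named numeric vector.
#' @export
model_estimates <- function(model) {
  est <- model$theta
  for (p in names(model$bpv)) est[paste0("omega2_", p)] <- model$bpv[[p]]$omega2
  res <- model$residual
  if (res$model %in% c("proportional", "combined")) {
    est["sigma2_prop"] <- res$sigma2_prop
  }
  if (res$model %in% c("additive", "combined")) {
    est["sigma2_add"] <- res$sigma2_add
  }
  est
}

update_model <- function(model, est) {
  th <- names(model$theta)
  model$theta[th] <- est[th]
  for (p in names(model$bpv)) {
    model$bpv[[p]]$omega2 <- unname(est[paste0("omega2_", p)])
  }
  if ("sigma2_prop" %in% names(est)) {
    model$residual$sigma2_prop <- unname(est["sigma2_prop"])
  }
  if ("sigma2_add" %in% names(est)) {
    model$residual$sigma2_add <- unname(est["sigma2_add"])
  }
  model
}

# ---- stacked data for the vectorized path ----------------------------------

can_fast_path <- function(model) {
  st <- model$structural
  st$kind == "pk" && st$elim$kind == "first_order" &&
    length(model$bpv) == 1 &&
    (model$bpv[[1]]$transform %||% "exp") == "exp"
}

stack_data <- function(data) {
  subs <- data$subjects
  n <- length(subs)
  nper <- vapply(subs, function(s) length(s$dv), 1L)
  sid <- rep.int(seq_len(n), nper)
  y <- unlist(lapply(subs, `[[`, "dv"), use.names = FALSE)
  t <- unlist(lapply(subs, `[[`, "times"), use.names = FALSE)
  if (is.null(y)) { y <- numeric(0); t <- numeric(0) }
  N <- length(y)
  # observation x dose-event pairs with precomputed time pieces
  pobs <- integer(0); psid <- integer(0)
  prate <- numeric(0); pte <- numeric(0); ptpost <- numeric(0)
  off <- 0L
  for (i in seq_len(n)) {
    ev <- subs[[i]]$events
    ti <- subs[[i]]$times
    if (length(ti) && nrow(ev)) {
      for (k in seq_len(nrow(ev))) {
        tau <- ti - ev$start[k]
        on <- which(tau > 0)
        if (!length(on)) next
        pobs <- c(pobs, off + on)
        psid <- c(psid, rep.int(i, length(on)))
        prate <- c(prate, rep.int(ev$rate[k], length(on)))
        pte <- c(pte, pmin(tau[on], ev$duration[k]))
        ptpost <- c(ptpost, pmax(tau[on] - ev$duration[k], 0))
      }
    }
    off <- off + length(ti)
  }
  o <- order(pobs)
  covnames <- unique(unlist(lapply(subs, function(s) names(s$covariates))))
  covtab <- as.data.frame(lapply(stats::setNames(covnames, covnames),
                                 function(cn) {
    vapply(subs, function(s) {
      v <- s$covariates[[cn]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }), optional = TRUE)
  list(n = n, N = N, sid = sid, y = y, t = t, nper = nper,
       us = sort(unique(sid)),
       pobs = pobs[o], psid = psid[o], prate = prate[o], pte = pte[o],
       ptpost = ptpost[o], uobs = unique(pobs[o]), covtab = covtab,
       ids = vapply(subs, function(s) as.character(s$id), ""))
}

fast_conc <- function(S, ncmp, CL, Vc, Vp = NULL, CLD = NULL) {
  i <- S$psid
  if (ncmp == 2) {
    k10 <- CL / Vc; k12 <- CLD / Vc; k21 <- CLD / Vp
    s <- k10 + k12 + k21
    disc <- sqrt(pmax(s * s - 4 * k10 * k21, 0))
    al <- (s + disc) / 2; be <- (s - disc) / 2
    A <- (al - k21) / (al - be); B <- (k21 - be) / (al - be)
    ali <- al[i]; bei <- be[i]
    contrib <- S$prate / Vc[i] *
      (A[i] / ali * (1 - exp(-ali * S$pte)) * exp(-ali * S$ptpost) +
       B[i] / bei * (1 - exp(-bei * S$pte)) * exp(-bei * S$ptpost))
  } else {
    k <- CL / Vc
    ki <- k[i]
    contrib <- S$prate / CL[i] * (1 - exp(-ki * S$pte)) * exp(-ki * S$ptpost)
  }
  yp <- numeric(S$N)
  yp[S$uobs] <- rowsum(contrib, S$pobs, reorder = FALSE)
  yp
}

# per-subject typical-value vectors for the structural parameters
fast_tv <- function(model, S) {
  lapply(stats::setNames(model$structural$pars, model$structural$pars),
         function(p) typical_values(model, p, S$covtab))
}

fast_pred <- function(model, S, tv, eta) {
  p_eta <- names(model$bpv)
  pars <- tv
  pars[[p_eta]] <- tv[[p_eta]] * exp(eta)
  if (model$structural$n_compartments == 2) {
    fast_conc(S, 2, pars$CL, pars$Vc, pars$Vp, pars$CLD)
  } else {
    fast_conc(S, 1, pars$CL, pars$Vc)
  }
}

per_subject_sum <- function(S, x) {
  out <- numeric(S$n)
  if (length(x)) out[S$us] <- rowsum(x, S$sid, reorder = FALSE)
  out
}

# per-subject penalized conditional objective, vectorized over subjects
fast_q <- function(model, S, tv, eta, omega2) {
  f <- fast_pred(model, S, tv, eta)
  g2 <- resid_var(model$residual, f)
  per_subject_sum(S, (S$y - f)^2 / g2 + log(g2)) + eta^2 / omega2
}

# vectorized inner problem: all subjects' 1-d conditional modes by a
# safeguarded Newton iteration in lockstep
inner_fast <- function(model, S, tv, eta0 = NULL) {
  omega2 <- model$bpv[[1]]$omega2
  if (omega2 < 1e-12) return(numeric(S$n))
  qfun <- function(eta) fast_q(model, S, tv, eta, omega2)
  eta <- if (is.null(eta0)) numeric(S$n) else eta0
  h <- 1e-4
  q0 <- qfun(eta)
  for (it in 1:40) {
    qp <- qfun(eta + h)
    qm <- qfun(eta - h)
    g <- (qp - qm) / (2 * h)
    H <- (qp + qm - 2 * q0) / h^2
    conv <- abs(g) < INNER_GTOL * (1 + abs(q0))
    if (all(conv)) break
    step <- ifelse(H > 1e-8, -g / H, -sign(g) * 0.2)
    step <- pmax(pmin(step, 1), -1)
    step[conv] <- 0
    eta_new <- eta + step
    q1 <- qfun(eta_new)
    for (half in 1:25) {
      bad <- q1 > q0 + 1e-12
      if (!any(bad)) break
      step[bad] <- step[bad] / 2
      eta_new <- eta + step
      q1 <- qfun(eta_new)
    }
    eta <- eta_new
    q0 <- q1
  }
  eta
}

ofv_fast <- function(model, S, env = NULL) {
  tv <- fast_tv(model, S)
  omega2 <- model$bpv[[1]]$omega2
  f0_of <- function(eta) fast_pred(model, S, tv, eta)
  if (omega2 < 1e-12) {
    # degenerate prior: fixed-effects weighted least squares
    f0 <- f0_of(numeric(S$n))
    d <- resid_var(model$residual, f0)
    ofv_i <- per_subject_sum(S, (S$y - f0)^2 / d + log(d)) +
      S$nper * log(2 * pi)
    if (!is.null(env)) env$eta <- numeric(S$n)
    return(structure(sum(ofv_i), by_subject = ofv_i, eta = numeric(S$n)))
  }
  eta0 <- if (!is.null(env)) env$eta else NULL
  if (!is.null(eta0) && length(eta0) != S$n) eta0 <- NULL
  eta <- inner_fast(model, S, tv, eta0)
  if (!is.null(env)) env$eta <- eta
  # Laplace: curvature of q at the mode by central differences
  h <- 1e-3
  q0 <- fast_q(model, S, tv, eta, omega2)
  qp <- fast_q(model, S, tv, eta + h, omega2)
  qm <- fast_q(model, S, tv, eta - h, omega2)
  qpp <- (qp + qm - 2 * q0) / h^2
  # Gauss-Newton fallback where the numerical curvature is unusable
  bad <- !is.finite(qpp) | qpp <= 1e-8
  if (any(bad)) {
    f0 <- f0_of(eta)
    G <- (f0_of(eta + h) - f0_of(eta - h)) / (2 * h)
    d <- resid_var(model$residual, f0)
    S1 <- per_subject_sum(S, G * G / d)
    qpp[bad] <- 2 * (S1[bad] + 1 / omega2)
  }
  ofv_i <- q0 + log(omega2) + log(qpp / 2) + S$nper * log(2 * pi)
  if (any(!is.finite(ofv_i))) {
    stop("non-finite OFV contribution for subject id ",
         S$ids[which(!is.finite(ofv_i))[1]])
  }
  structure(sum(ofv_i), by_subject = ofv_i, eta = eta)
}

# ---- generic per-subject path ----------------------------------------------

inner_objective <- function(model, subject, Omega_inv, eta_names) {
  function(eta) {
    names(eta) <- eta_names
    f <- predict_subject(model, subject, eta)
    g2 <- resid_var(model$residual, f)
    sum((subject$dv - f)^2 / g2 + log(g2)) +
      drop(eta %*% Omega_inv %*% eta)
  }
}

#' Empirical Bayes estimate (conditional mode) for one subject
#'
#' Minimizes the subject's penalized conditional objective (residual term
#' under the error model plus the `eta' Omega^-1 eta` prior penalty). With
#' no observations the prior mode 0 is returned.
#'
#' @param model a [pop_model()] with at least one BPV term.
#' @param subject a [pk_subject()].
#' @param eta0 optional start values.
#' @return named vector of eta-hat values (one per BPV parameter).
#' @export
inner_map <- function(model, subject, eta0 = NULL) {
  eta_names <- names(model$bpv)
  omega2 <- vapply(model$bpv, `[[`, numeric(1), "omega2")
  if (length(subject$dv) == 0 || all(omega2 < 1e-12)) {
    return(stats::setNames(numeric(length(eta_names)), eta_names))
  }
  Omega_inv <- diag(1 / omega2, length(omega2))
  obj <- inner_objective(model, subject, Omega_inv, eta_names)
  start <- if (is.null(eta0)) numeric(length(eta_names)) else eta0
  opt <- stats::nlminb(start, obj,
                       control = list(abs.tol = 0, rel.tol = 1e-12,
                                      x.tol = 1e-12))
  stats::setNames(opt$par, eta_names)
}

ofv_generic <- function(model, data, env = NULL) {
  eta_names <- names(model$bpv)
  k <- length(eta_names)
  omega2 <- if (k) vapply(model$bpv, `[[`, numeric(1), "omega2") else numeric(0)
  Omega <- diag(omega2, k)
  total <- 0
  by_subject <- numeric(length(data$subjects))
  etas <- matrix(0, length(data$subjects), k,
                 dimnames = list(NULL, eta_names))
  for (i in seq_along(data$subjects)) {
    s <- data$subjects[[i]]
    ni <- length(s$dv)
    if (ni == 0) next
    eta0 <- if (!is.null(env) && !is.null(env$etas) &&
                nrow(env$etas) == length(data$subjects)) env$etas[i, ] else NULL
    etahat <- if (k) inner_map(model, s, eta0) else
      stats::setNames(numeric(0), character(0))
    if (k) etas[i, ] <- etahat
    f0 <- predict_subject(model, s, etahat)
    d <- resid_var(model$residual, f0)
    if (k && any(diag(Omega) >= 1e-12)) {
      Omega_inv <- diag(1 / pmax(diag(Omega), 1e-12), k)
      qf <- inner_objective(model, s, Omega_inv, eta_names)
      H <- fd_hessian(qf, etahat, rel_h = 1e-3, abs_h = 1e-3)
      ch <- tryCatch(chol(H / 2), error = function(e) NULL)
      if (is.null(ch)) {
        # Gauss-Newton curvature fallback
        G <- matrix(0, ni, k)
        h <- 1e-3
        for (j in seq_len(k)) {
          ep <- etahat; em <- etahat
          ep[j] <- ep[j] + h; em[j] <- em[j] - h
          G[, j] <- (predict_subject(model, s, ep) -
                       predict_subject(model, s, em)) / (2 * h)
        }
        ch <- chol(crossprod(G / sqrt(d)) + Omega_inv)
      }
      ofv_i <- qf(etahat) + sum(log(diag(Omega))) +
        2 * sum(log(diag(ch))) + ni * log(2 * pi)
    } else {
      ofv_i <- sum((s$dv - f0)^2 / d + log(d)) + ni * log(2 * pi)
    }
    if (!is.finite(ofv_i)) {
      stop("non-finite OFV contribution for subject id ", s$id)
    }
    by_subject[i] <- ofv_i
    total <- total + ofv_i
  }
  if (!is.null(env)) env$etas <- etas
  structure(total, by_subject = by_subject, eta = etas)
}

#' FOCEI objective function value (-2 approximate log-likelihood)
#'
#' Sums the per-subject FOCEI contributions evaluated at each subject's
#' conditional mode, with the residual variance evaluated at the conditional
#' prediction (interaction). Includes the `n log 2*pi` constant, so on
#' models linear in the random effect with additive error the value equals
#' the exact -2 log-likelihood.
#'
#' @param model a [pop_model()].
#' @param data a [pk_data()].
#' @return numeric OFV with attribute `by_subject`.
#' @export
ofv <- function(model, data) {
  if (can_fast_path(model)) {
    S <- stack_data(data)
    out <- ofv_fast(model, S)
  } else {
    out <- ofv_generic(model, data)
  }
  out
}

# ---- maximum likelihood fit ------------------------------------------------

#' Fit a population model by FOCEI
#'
#' Outer quasi-Newton optimization (on log scale for positive parameters,
#' identity scale for covariate coefficients) of the FOCEI objective, with
#' standard errors from a central finite-difference Hessian of the
#' objective (`cov = 2 H^-1`).
#'
#' @param model a [pop_model()]; its current parameter values are the start
#'   values unless `start` overrides them.
#' @param data a [pk_data()].
#' @param start optional named vector overriding start values.
#' @param hessian compute the covariance step (default `TRUE`); skip it in
#'   replicate studies where only point estimates are needed.
#' @param control passed to [stats::nlminb()] (outer iteration limits and
#'   tolerances; default `rel.tol 1e-8`).
#' @return object of class `pk_fit` with elements `model` (updated),
#'   `estimates`, `ofv`, `se`, `rse`, `cov`, `eta` (per-subject conditional
#'   modes), `status`, `n_par`, `n_obs`, `n_subjects`, `data`.
#' @export
fit_model <- function(model, data, start = NULL, hessian = TRUE,
                      control = list()) {
  map <- param_map(model)
  est <- model_estimates(model)
  if (!is.null(start)) {
    bad <- setdiff(names(start), names(est))
    if (length(bad)) stop("unknown start value(s): ", paste(bad, collapse = ", "))
    est[names(start)] <- start
  }
  if (any(est[map$name[map$trans == "log"]] <= 0)) {
    stop("start values for positive-constrained parameters must be > 0")
  }
  model <- update_model(model, est)
  fast <- can_fast_path(model)
  S <- if (fast) stack_data(data) else NULL
  env <- new.env(parent = emptyenv())
  emap <- map[map$estimated, , drop = FALSE]
  is_log <- emap$trans == "log"
  to_trans <- function(v) {
    v[is_log] <- log(v[is_log])
    v
  }
  from_trans <- function(p) {
    p[is_log] <- exp(p[is_log])
    p
  }
  cur <- est
  ofv_at <- function(vals) {
    cur[emap$name] <- vals
    m <- update_model(model, cur)
    tryCatch(
      as.numeric(if (fast) ofv_fast(m, S, env) else ofv_generic(m, data, env)),
      error = function(e) 1e10)
  }
  objective <- function(p) ofv_at(from_trans(p))
  ctrl <- utils::modifyList(list(iter.max = 400, eval.max = 1600,
                                 rel.tol = 1e-8), control)
  opt <- stats::nlminb(to_trans(est[emap$name]), objective, control = ctrl)
  est[emap$name] <- from_trans(opt$par)
  model <- update_model(model, est)
  final <- if (fast) ofv_fast(model, S, env) else ofv_generic(model, data, env)
  eta_mat <- if (fast) {
    matrix(attr(final, "eta"), ncol = 1,
           dimnames = list(NULL, names(model$bpv)))
  } else attr(final, "eta")
  status <- if (opt$convergence == 0) "converged" else
    paste0("not converged (", opt$message, ")")
  se <- rse <- stats::setNames(rep(NA_real_, nrow(emap)), emap$name)
  covmat <- NULL
  if (hessian && nrow(emap) > 0) {
    H <- fd_hessian(ofv_at, est[emap$name])
    covmat <- tryCatch({
      cm <- 2 * solve(H)
      if (any(diag(cm) <= 0)) NULL else cm
    }, error = function(e) NULL)
    if (is.null(covmat)) {
      status <- paste0(status, "; covariance step failed")
    } else {
      dimnames(covmat) <- list(emap$name, emap$name)
      se <- sqrt(diag(covmat))
      rse <- 100 * se / abs(est[emap$name])
    }
  }
  structure(list(model = model, estimates = est, ofv = as.numeric(final),
                 se = se, rse = rse, cov = covmat, eta = eta_mat,
                 status = status, n_par = nrow(emap), n_obs = n_obs(data),
                 n_subjects = length(data$subjects), data = data,
                 opt = opt),
            class = "pk_fit")
}

fd_hessian <- function(f, x, rel_h = 1e-4, abs_h = 1e-7) {
  k <- length(x)
  h <- pmax(abs(x) * rel_h, abs_h)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    fpp <- f(x + ei); fmm <- f(x - ei)
    H[i, i] <- (fpp + fmm - 2 * f0) / h[i]^2
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        ej <- replace(numeric(k), j, h[j])
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
             f(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  (H + t(H)) / 2
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("FOCEI fit: %d subjects, %d observations, OFV = %.3f (%s)\n",
              x$n_subjects, x$n_obs, x$ofv, x$status))
  tab <- data.frame(estimate = x$estimates,
                    row.names = names(x$estimates))
  tab$rse_pct <- NA_real_
  tab[names(x$rse), "rse_pct"] <- x$rse
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.pk_fit <- function(object, ...) object$estimates

#' @export
logLik.pk_fit <- function(object, ...) {
  structure(-object$ofv / 2, df = object$n_par, class = "logLik")
}
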