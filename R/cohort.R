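#' Specification of a synthetic critically-ill cohort
#'
#' Encodes the sparse two-window sampling design of the study: every subject
#' receives the loading dose + continuous infusion regimen and one
#' steady-state sample (uniform in the 6-24 h window); a fraction
#' additionally contributes one post-loading-dose peak sample (uniform in
#' the 0.5-1 h window) and/or a second steady-state sample, so that the
#' expected total is about 2.1 samples per subject (218 for 106 subjects).
#' Covariates are drawn from lognormal marginals matching the reported
#' medians and interquartile ranges, with creatinine clearance truncated to
#' the preserved-renal-function inclusion range.
#'
#' @param n_subjects number of subjects (default 106).
#' @param daily_dose_g continuous-infusion daily dose, g (default 12).
#' @param loading_fraction fraction receiving the 4 g / 30 min loading dose
#'   (default 1; the study's small already-on-treatment subgroup skipped it).
#' @param cmax_fraction fraction contributing a peak sample (default 0.50).
#' @param samples_per_subject target average samples per subject (default
#'   218/106 ~ 2.06); sets the second steady-state-sample fraction as
#'   `samples_per_subject - 1 - cmax_fraction`.
#' @param cmax_window,ss_window sampling windows, h (peak window measured
#'   from the loading-dose start).
#' @param ss2_window window for the second steady-state sample, h; the
#'   default places it on the next monitoring occasion (day 2), matching
#'   routine daily therapeutic drug monitoring.
#' @param covariates list of covariate generator settings; see defaults.
#' @param lloq lower limit of quantification applied to simulated
#'   observations, mg/L.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 106, daily_dose_g = 12,
                        loading_fraction = 1, cmax_fraction = 0.50,
                        samples_per_subject = 218 / 106,
                        cmax_window = c(0.5, 1.0), ss_window = c(6, 24),
                        ss2_window = c(24, 48),
                        covariates = default_covariate_generators(),
                        lloq = 0.54) {
  second_ss_fraction <- samples_per_subject - 1 - cmax_fraction
  if (cmax_fraction < 0 || cmax_fraction > 1 ||
      second_ss_fraction < 0 || second_ss_fraction > 1 ||
      loading_fraction < 0 || loading_fraction > 1) {
    stop("design fractions must lie in [0, 1]")
  }
  structure(list(n_subjects = n_subjects, daily_dose_g = daily_dose_g,
                 loading_fraction = loading_fraction,
                 cmax_fraction = cmax_fraction,
                 second_ss_fraction = second_ss_fraction,
                 cmax_window = cmax_window, ss_window = ss_window,
                 ss2_window = ss2_window,
                 covariates = covariates, lloq = lloq),
            class = "cohort_spec")
}

#' Default covariate generators (study population marginals)
#'
#' Continuous covariates are lognormal with the reported median and IQR
#' (creatinine clearance 97.1 (86-114) mL/min/1.73 m2 truncated to
#' [60, 200]; age 65 (50-72) y truncated to [18, 90]; weight 72 (65-84) kg;
#' albumin 29 (26-33) g/L); binary covariates use the reported proportions
#' (male 66.98%, neurocritical 33.96%, drainage 34.91%, ventilated 59.43%,
#' vasoactive drugs 42.45%).
#'
#' @return named list of generator settings consumed by
#'   [draw_covariates()].
#' @export
default_covariate_generators <- function() {
  list(
    CLCR = list(type = "lognormal", median = 97.1, iqr = c(86, 114),
                trunc = c(60, 200)),
    AGE = list(type = "lognormal", median = 65, iqr = c(50, 72),
               trunc = c(18, 90)),
    WT = list(type = "lognormal", median = 72, iqr = c(65, 84),
              trunc = c(35, 200)),
    ALB = list(type = "lognormal", median = 29, iqr = c(26, 33),
               trunc = c(10, 60)),
    MALE = list(type = "binary", p = 0.6698),
    NEURO = list(type = "binary", p = 0.3396),
    DRAIN = list(type = "binary", p = 0.3491),
    VENT = list(type = "binary", p = 0.5943),
    VASO = list(type = "binary", p = 0.4245)
  )
}

# lognormal parameterized by median and IQR; truncation by rejection
rlnorm_med_iqr <- function(n, median, iqr, trunc = c(-Inf, Inf)) {
  if (median <= trunc[1] || median >= trunc[2]) {
    stop("infeasible truncation: median outside the truncation bounds")
  }
  meanlog <- log(median)
  sdlog <- log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * (n - length(out)) + 10, meanlog, sdlog)
    out <- c(out, x[x >= trunc[1] & x <= trunc[2]])
  }
  out[seq_len(n)]
}

#' Draw a covariate table for a synthetic cohort
#'
#' Marginals per [default_covariate_generators()] (independent across
#' covariates, as no correlation structure is reported). Serum creatinine is
#' back-solved from the generated CKD-EPI clearance given age and sex, and
#' the Cockcroft-Gault and MDRD-4 clearances are then computed from that
#' creatinine, so the three renal covariates are formula-consistent.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional RNG seed.
#' @return data.frame with one row per subject: `ID`, the generated
#'   covariates, plus `SCR`, `CLCR_CG`, `CLCR_MDRD4`.
#' @export
draw_covariates <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects
  out <- data.frame(ID = seq_len(n))
  for (nm in names(spec$covariates)) {
    g <- spec$covariates[[nm]]
    out[[nm]] <- switch(g$type,
      lognormal = rlnorm_med_iqr(n, g$median, g$iqr,
                                 g$trunc %||% c(-Inf, Inf)),
      binary = as.numeric(stats::runif(n) < g$p),
      stop("unknown generator type ", g$type))
  }
  if (all(c("CLCR", "AGE", "MALE", "WT") %in% names(out))) {
    sex <- ifelse(out$MALE == 1, "male", "female")
    female <- out$MALE != 1
    out$SCR <- scr_from_ckdepi(out$CLCR, out$AGE, sex)
    out$CLCR_CG <- (140 - out$AGE) * out$WT / (72 * out$SCR) *
      ifelse(female, 0.85, 1)
    out$CLCR_MDRD4 <- 175 * out$SCR^(-1.154) * out$AGE^(-0.203) *
      ifelse(female, 0.742, 1)
  }
  out
}

#' Build the dosing/sampling design for a cohort
#'
#' Assigns each subject the loading-dose + continuous-infusion regimen and
#' draws sample times: one steady-state sample for everyone, a peak sample
#' for the `cmax_fraction` subset and a second steady-state sample (on the
#' next monitoring occasion) for the `second_ss_fraction` subset.
#'
#' @param spec a [cohort_spec()].
#' @param covariates covariate table from [draw_covariates()].
#' @param seed optional RNG seed.
#' @return object of class `cohort_design`: list with `spec`, `covariates`,
#'   `regimens` and `sample_times` (lists indexed by subject).
#' @export
build_design <- function(spec, covariates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(covariates)
  has_ld <- stats::runif(n) < spec$loading_fraction
  has_cmax <- stats::runif(n) < spec$cmax_fraction
  has_ss2 <- stats::runif(n) < spec$second_ss_fraction
  regimens <- lapply(seq_len(n), function(i) {
    ci_regimen(spec$daily_dose_g,
               loading_dose_g = if (has_ld[i]) 4 else 0)
  })
  sample_times <- lapply(seq_len(n), function(i) {
    tt <- stats::runif(1, spec$ss_window[1], spec$ss_window[2])
    if (has_cmax[i] && has_ld[i]) {
      tt <- c(tt, stats::runif(1, spec$cmax_window[1], spec$cmax_window[2]))
    }
    if (has_ss2[i]) {
      tt <- c(tt, stats::runif(1, spec$ss2_window[1], spec$ss2_window[2]))
    }
    sort(tt)
  })
  structure(list(spec = spec, covariates = covariates, regimens = regimens,
                 sample_times = sample_times),
            class = "cohort_design")
}

#' Simulate observations for a designed cohort
#'
#' Per subject: draw the random effect(s) from `N(0, omega2)`,
#' individualize the parameters through the model's covariate relations and
#' random effects, evaluate the structural model at the design's sample
#' times, apply proportional residual noise and discard observations below
#' the limit of quantification.
#'
#' @param design a [build_design()] result.
#' @param model a [pop_model()] (generative truth).
#' @param seed optional RNG seed.
#' @return a [pk_data()]; attribute `truth` holds a data.frame of true etas
#'   and individual clearances, attribute `n_blq` the number of discarded
#'   below-LLOQ observations.
#' @export
simulate_observations <- function(design, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(design$covariates)
  eta_names <- names(model$bpv)
  omega2 <- vapply(model$bpv, `[[`, numeric(1), "omega2")
  res <- model$residual
  sd_prop <- if (res$model %in% c("proportional", "combined"))
    sqrt(res$sigma2_prop) else 0
  sd_add <- if (res$model %in% c("additive", "combined"))
    sqrt(res$sigma2_add) else 0
  etas <- matrix(stats::rnorm(n * length(eta_names), 0,
                              rep(sqrt(omega2), each = n)),
                 n, length(eta_names), dimnames = list(NULL, eta_names))
  truth <- data.frame(ID = design$covariates$ID)
  for (j in seq_along(eta_names)) {
    truth[[paste0("eta_", eta_names[j])]] <- etas[, j]
  }
  subjects <- vector("list", n)
  true_cl <- numeric(n)
  for (i in seq_len(n)) {
    covs <- as.list(design$covariates[i, setdiff(names(design$covariates),
                                                 "ID"), drop = FALSE])
    subj <- pk_subject(design$covariates$ID[i], covs, design$regimens[[i]])
    subj$times <- design$sample_times[[i]]
    eta <- stats::setNames(etas[i, ], eta_names)
    phi <- individual_phi(model, subj, eta)
    true_cl[i] <- if ("CL" %in% names(phi)) phi[["CL"]] else NA_real_
    f <- predict_subject(model, subj, eta)
    dv <- f * (1 + stats::rnorm(length(f), 0, sd_prop)) +
      stats::rnorm(length(f), 0, sd_add)
    keep <- dv > 0
    subjects[[i]] <- pk_subject(subj$id, covs, design$regimens[[i]],
                                subj$times[keep], dv[keep])
  }
  truth$CL_i <- true_cl
  out <- suppressMessages(apply_lloq(pk_data(subjects),
                                     lloq = design$spec$lloq))
  attr(out, "truth") <- truth
  out
}

#' One-call synthetic cohort
#'
#' Convenience wrapper: [draw_covariates()] + [build_design()] +
#' [simulate_observations()] under a single seed.
#'
#' @param spec a [cohort_spec()].
#' @param model generative [pop_model()] (default [final_model()]).
#' @param seed RNG seed.
#' @return a [pk_data()] with `truth` attribute.
#' @export
simulate_cohort <- function(spec = cohort_spec(), model = final_model(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  covs <- draw_covariates(spec)
  design <- build_design(spec, covs)
  simulate_observations(design, model)
}
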