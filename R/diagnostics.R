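#' Non-parametric bootstrap of a population model fit
#'
#' Resamples subjects with replacement at the original cohort size, refits
#' each resample (warm-started at the original estimates to cut runtime)
#' and summarizes the re-estimates: median, 2.5/97.5 percentiles and the
#' relative bias of the bootstrap median against the original estimate.
#' Non-converged replicates are dropped and counted; more than 20%
#' non-convergence flags a warning status.
#'
#' @param model a [pop_model()] holding the original (point) estimates.
#' @param data the original [pk_data()].
#' @param n_resamples number of resamples (study convention: 200).
#' @param seed optional RNG seed.
#' @param control outer-optimizer control for the refits.
#' @return object of class `bootstrap_result`: list with `estimates`
#'   (matrix of re-estimates), `summary` (data.frame with original, median,
#'   lo, hi, bias percent), `n_failed`, `status`, and `indices` (the
#'   resampled subject indices, one row per resample).
#' @export
bootstrap <- function(model, data, n_resamples = 200, seed = NULL,
                      control = list()) {
  if (!is.null(seed)) set.seed(seed)
  orig <- model_estimates(model)
  map <- param_map(model)
  enames <- map$name[map$estimated]
  n <- length(data$subjects)
  reps <- matrix(NA_real_, n_resamples, length(enames),
                 dimnames = list(NULL, enames))
  indices <- matrix(NA_integer_, n_resamples, n)
  n_failed <- 0L
  for (b in seq_len(n_resamples)) {
    idx <- sample.int(n, n, replace = TRUE)
    indices[b, ] <- idx
    subs <- lapply(seq_along(idx), function(j) {
      s <- data$subjects[[idx[j]]]
      s$id <- j  # relabel so resampled clones stay distinct
      s
    })
    f <- tryCatch(fit_model(model, pk_data(subs), hessian = FALSE,
                            control = control),
                  error = function(e) NULL)
    if (is.null(f) || !startsWith(f$status, "converged")) {
      n_failed <- n_failed + 1L
      next
    }
    reps[b, ] <- f$estimates[enames]
  }
  ok <- stats::complete.cases(reps)
  est <- reps[ok, , drop = FALSE]
  med <- apply(est, 2, stats::median)
  qs <- apply(est, 2, stats::quantile, probs = c(0.025, 0.975), type = 7)
  summary <- data.frame(parameter = enames, original = unname(orig[enames]),
                        median = unname(med), lo = unname(qs[1, ]),
                        hi = unname(qs[2, ]),
                        bias_pct = unname(100 * (med - orig[enames]) /
                                            orig[enames]))
  status <- if (n_failed > 0.2 * n_resamples) "warning: >20% non-convergence"
            else "ok"
  structure(list(estimates = est, summary = summary, n_failed = n_failed,
                 n_resamples = n_resamples, status = status,
                 indices = indices),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap: %d resamples, %d failed (%s)\n",
              x$n_resamples, x$n_failed, x$status))
  print(x$summary, digits = 4)
  invisible(x)
}

# default binning: the post-loading-dose window is its own bin; the
# steady-state window is split at observed-time quantiles
auto_bins <- function(times, n_ss_bins = 3) {
  early <- times <= 1.5
  edges <- c(0, if (any(early)) 1.5 else numeric(0))
  tss <- times[!early]
  if (length(tss)) {
    qs <- unique(stats::quantile(tss, probs = seq(0, 1, length.out =
                                                    n_ss_bins + 1)[-c(1, n_ss_bins + 1)],
                                 type = 7))
    edges <- c(edges, qs, max(times) + 1e-9)
  }
  unique(edges)
}

#' Prediction-corrected visual predictive check
#'
#' Observations and model-simulated replicates are rescaled by the ratio of
#' the bin-median population prediction to each observation's own
#' population prediction (`pcY_ij = Y_ij * median(PRED_bin) / PRED_ij`),
#' then the observed 2.5/50/97.5 percentiles per time bin are compared with
#' 95% confidence bands formed from the replicate-wise percentiles.
#'
#' @param model a [pop_model()] used for simulation (usually the fitted
#'   final model).
#' @param fit a [fit_model()] result (supplies population predictions); may
#'   be a model-only surrogate created by [as_fit()] when evaluating a
#'   known model.
#' @param data a [pk_data()].
#' @param n_replicates number of simulated datasets (study convention:
#'   1000).
#' @param bins numeric vector of bin edges, or `NULL` for automatic binning
#'   (peak window + steady-state quantile bins). Empty bins are merged with
#'   their left neighbour.
#' @param seed optional RNG seed.
#' @return object of class `vpc_result`: data.frame `table` with one row
#'   per bin x percentile (`bin_lo`, `bin_hi`, `percentile`, `observed`,
#'   `lo`, `hi`, `n_obs`), plus `n_replicates`; attribute `degenerate` set
#'   when `n_replicates < 2` (zero-width bands).
#' @export
pcvpc <- function(model, fit, data, n_replicates = 1000, bins = NULL,
                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eta_names <- names(model$bpv)
  k <- length(eta_names)
  zero_eta <- if (k) stats::setNames(numeric(k), eta_names) else NULL
  subs <- data$subjects
  pred <- unlist(lapply(subs, function(s) {
    predict_subject(fit$model, s, zero_eta)
  }), use.names = FALSE)
  times <- unlist(lapply(subs, `[[`, "times"), use.names = FALSE)
  y <- unlist(lapply(subs, `[[`, "dv"), use.names = FALSE)
  if (is.null(bins)) bins <- auto_bins(times)
  binid <- findInterval(times, bins, rightmost.closed = TRUE,
                        all.inside = TRUE)
  # merge empty bins leftwards
  counts <- tabulate(binid, nbins = length(bins) - 1)
  if (any(counts == 0)) {
    keep <- which(counts > 0)
    message("merging ", sum(counts == 0), " empty time bin(s)")
    bins <- c(bins[1], bins[keep + 1])
    binid <- findInterval(times, bins, rightmost.closed = TRUE,
                          all.inside = TRUE)
  }
  pc_factor <- stats::ave(pred, binid, FUN = stats::median) / pred
  pc_obs <- y * pc_factor
  probs <- c(0.025, 0.5, 0.975)
  obs_pct <- vapply(split(pc_obs, binid), stats::quantile, numeric(3),
                    probs = probs, type = 7)
  # simulate replicates on the same design
  omega2 <- vapply(model$bpv, `[[`, numeric(1), "omega2")
  res <- model$residual
  sd_prop <- if (res$model %in% c("proportional", "combined"))
    sqrt(res$sigma2_prop) else 0
  sd_add <- if (res$model %in% c("additive", "combined"))
    sqrt(res$sigma2_add) else 0
  nbin <- length(unique(binid))
  sim_pct <- array(NA_real_, c(n_replicates, 3, nbin))
  for (r in seq_len(n_replicates)) {
    ysim <- unlist(lapply(subs, function(s) {
      eta <- stats::setNames(stats::rnorm(k, 0, sqrt(omega2)), eta_names)
      f <- predict_subject(model, s, eta)
      f * (1 + stats::rnorm(length(f), 0, sd_prop)) +
        stats::rnorm(length(f), 0, sd_add)
    }), use.names = FALSE)
    pc_sim <- ysim * pc_factor
    sim_pct[r, , ] <- vapply(split(pc_sim, binid), stats::quantile,
                             numeric(3), probs = probs, type = 7)
  }
  ubin <- sort(unique(binid))
  tab <- do.call(rbind, lapply(seq_along(ubin), function(bi) {
    data.frame(bin_lo = bins[ubin[bi]], bin_hi = bins[ubin[bi] + 1],
               percentile = probs * 100,
               observed = obs_pct[, bi],
               lo = apply(sim_pct[, , bi, drop = FALSE], 2, stats::quantile,
                          probs = 0.025, type = 7),
               hi = apply(sim_pct[, , bi, drop = FALSE], 2, stats::quantile,
                          probs = 0.975, type = 7),
               n_obs = sum(binid == ubin[bi]))
  }))
  rownames(tab) <- NULL
  out <- structure(list(table = tab, n_replicates = n_replicates,
                        bins = bins),
                   class = "vpc_result")
  if (n_replicates < 2) {
    attr(out, "degenerate") <- TRUE
    warning("n_replicates < 2: confidence bands are degenerate (zero width)")
  }
  out
}

#' Wrap a known model as a fit surrogate
#'
#' Several diagnostics take a fitted object only to read its model and
#' conditional modes. When evaluating a model with known (e.g. generative)
#' parameters, this builds the minimal `pk_fit`-shaped object.
#'
#' @param model a [pop_model()].
#' @param data a [pk_data()].
#' @return a `pk_fit` object with estimates equal to the model's values and
#'   conditional modes computed from the data.
#' @export
as_fit <- function(model, data) {
  out <- if (can_fast_path(model)) {
    ofv_fast(model, stack_data(data))
  } else {
    ofv_generic(model, data)
  }
  eta_mat <- attr(out, "eta")
  if (is.null(dim(eta_mat))) {
    eta_mat <- matrix(eta_mat, ncol = max(1, length(names(model$bpv))),
                      dimnames = list(NULL, names(model$bpv)))
  }
  map <- param_map(model)
  structure(list(model = model, estimates = model_estimates(model),
                 ofv = as.numeric(out), se = NULL, rse = NULL, cov = NULL,
                 eta = eta_mat, status = "fixed (not estimated)",
                 n_par = sum(map$estimated), n_obs = n_obs(data),
                 n_subjects = length(data$subjects), data = data),
            class = "pk_fit")
}
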