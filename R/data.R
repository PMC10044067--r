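#' Subject record
#'
#' One subject's covariates, dosing history and timed concentration
#' observations — the estimation unit of the mixed-effects analysis.
#'
#' @param id subject identifier.
#' @param covariates named list of baseline covariate values.
#' @param events a [dosing_regimen()].
#' @param times observation times, h.
#' @param dv observed total concentrations, mg/L (must be positive; below
#'   the limit of quantification observations are removed beforehand).
#' @return object of class `pk_subject`.
#' @export
pk_subject <- function(id, covariates = list(), events = dosing_regimen(
                         numeric(0), numeric(0), numeric(0)),
                       times = numeric(0), dv = numeric(0)) {
  stopifnot(length(times) == length(dv))
  if (length(dv) && any(dv <= 0)) stop("observed concentrations must be > 0")
  if (length(times) && any(times < 0)) stop("observation times must be >= 0")
  o <- order(times)
  structure(list(id = id, covariates = covariates, events = events,
                 times = times[o], dv = dv[o]),
            class = "pk_subject")
}

#' Collection of subject records
#'
#' @param subjects list of [pk_subject()] objects.
#' @return object of class `pk_data`.
#' @export
pk_data <- function(subjects) {
  stopifnot(all(vapply(subjects, inherits, TRUE, "pk_subject")))
  structure(list(subjects = subjects), class = "pk_data")
}

#' @export
print.pk_data <- function(x, ...) {
  nobs <- sum(vapply(x$subjects, function(s) length(s$dv), 1L))
  cat(sprintf("pk_data: %d subjects, %d observations (%.2f per subject)\n",
              length(x$subjects), nobs, nobs / length(x$subjects)))
  invisible(x)
}

n_obs <- function(data) sum(vapply(data$subjects, function(s) length(s$dv), 1L))

#' Convert a NONMEM-style data frame to subject records
#'
#' Expects the conventional longitudinal event layout: columns `ID`, `TIME`,
#' `AMT`, `RATE`, `DV`, `EVID`, `MDV`; every additional column is treated as
#' a baseline covariate (first value per subject). Dose records (`EVID ==
#' 1`) carry `AMT` (mg) and `RATE` (mg/h), giving a zero-order infusion of
#' duration `AMT/RATE`; `AMT == 0` with `RATE > 0` encodes an open-ended
#' infusion. Observation records are `EVID == 0 & MDV == 0`.
#'
#' @param df data.frame in NONMEM layout.
#' @return a [pk_data()].
#' @export
as_pk_data <- function(df) {
  need <- c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "MDV")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  covcols <- setdiff(names(df), need)
  subjects <- lapply(split(df, factor(df$ID, levels = unique(df$ID))),
                     function(d) {
    dose <- d[d$EVID == 1, , drop = FALSE]
    if (any(dose$RATE <= 0)) stop("dose records need RATE > 0 (zero-order)")
    dur <- ifelse(dose$AMT > 0, dose$AMT / dose$RATE, Inf)
    obs <- d[d$EVID == 0 & d$MDV == 0, , drop = FALSE]
    if (nrow(obs) && nrow(dose) && any(obs$TIME < min(dose$TIME))) {
      stop("subject ", d$ID[1],
           ": observation times outside the dosing history span ",
           "(observation before the first dose)")
    }
    pk_subject(id = d$ID[1],
               covariates = as.list(d[1, covcols, drop = FALSE]),
               events = dosing_regimen(dose$RATE, dose$TIME, dur),
               times = obs$TIME, dv = obs$DV)
  })
  pk_data(unname(subjects))
}

#' Flatten subject records back to a NONMEM-style data frame
#'
#' Inverse of [as_pk_data()] (round-trips through [write_nonmem()] /
#' [read_nonmem()]).
#'
#' @param data a [pk_data()].
#' @return data.frame with the standard event columns plus covariates.
#' @export
as_nonmem_df <- function(data) {
  rows <- lapply(data$subjects, function(s) {
    ev <- s$events
    amt <- ifelse(is.finite(ev$duration), ev$rate * ev$duration, 0)
    dose <- data.frame(ID = s$id, TIME = ev$start, AMT = amt, RATE = ev$rate,
                       DV = 0, EVID = 1, MDV = 1)
    obs <- data.frame(ID = s$id, TIME = s$times, AMT = 0, RATE = 0,
                      DV = s$dv, EVID = 0, MDV = 0)
    out <- rbind(dose, obs)
    out <- out[order(out$TIME, -out$EVID), , drop = FALSE]
    for (cn in names(s$covariates)) {
      v <- s$covariates[[cn]]
      out[[cn]] <- if (is.logical(v)) as.integer(v) else v
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname as_nonmem_df
#' @param path CSV file path.
#' @export
write_nonmem <- function(data, path) {
  utils::write.csv(as_nonmem_df(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname as_nonmem_df
#' @export
read_nonmem <- function(path) {
  as_pk_data(utils::read.csv(path))
}

#' Remove below-quantification observations (M1 handling)
#'
#' Observations under the assay's lower limit of quantification (0.54 mg/L
#' for the piperacillin UHPLC-MS/MS method) are discarded; the number
#' removed is reported via a message.
#'
#' @param data a [pk_data()].
#' @param lloq lower limit of quantification, mg/L.
#' @return filtered [pk_data()] with attribute `n_blq`.
#' @export
apply_lloq <- function(data, lloq = 0.54) {
  n_removed <- 0L
  subjects <- lapply(data$subjects, function(s) {
    keep <- s$dv >= lloq
    n_removed <<- n_removed + sum(!keep)
    pk_subject(s$id, s$covariates, s$events, s$times[keep], s$dv[keep])
  })
  if (n_removed > 0) message(n_removed, " observation(s) below LLOQ removed")
  out <- pk_data(subjects)
  attr(out, "n_blq") <- n_removed
  out
}
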