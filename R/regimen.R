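#' Dosing regimen of zero-order infusion events
#'
#' A regimen is an ordered table of zero-order infusion events
#' (rate in mg/h, start in h, duration in h). Overlapping events are legal
#' and additive (superposition), which is how the 30-min loading dose rides
#' on top of the continuous infusion during the first half hour.
#'
#' @param rate infusion rate(s), mg/h (non-negative).
#' @param start start time(s), h (non-negative).
#' @param duration duration(s), h (non-negative; `Inf` allowed for an
#'   open-ended continuous infusion).
#' @return object of class `dosing_regimen`: a data.frame with columns
#'   `rate`, `start`, `duration`.
#' @seealso [ci_regimen()] for the loading-dose + continuous-infusion
#'   convention used throughout.
#' @export
dosing_regimen <- function(rate, start, duration) {
  stopifnot(length(rate) == length(start), length(start) == length(duration))
  if (any(rate < 0) || any(start < 0) || any(duration < 0)) {
    stop("rates, starts and durations must be non-negative")
  }
  ev <- data.frame(rate = as.numeric(rate), start = as.numeric(start),
                   duration = as.numeric(duration))
  ev <- ev[order(ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("dosing_regimen", "data.frame"))
}

#' Loading dose + continuous infusion regimen
#'
#' The study convention: a loading dose (default 4 g over 30 min) started at
#' time zero, with the continuous infusion (daily dose / 24 as a constant
#' rate) running from time zero as well; the two overlap during the loading
#' infusion and their rates add.
#'
#' @param daily_dose_g total daily piperacillin dose given as CI, grams.
#' @param loading_dose_g loading dose, grams (0 suppresses it).
#' @param loading_minutes duration of the loading infusion, minutes.
#' @param ci_hours duration of the continuous infusion, h (default `Inf`,
#'   i.e. maintained to steady state).
#' @return a [dosing_regimen()].
#' @examples
#' ci_regimen(12)  # 4 g / 30 min loading dose + 500 mg/h CI
#' @export
ci_regimen <- function(daily_dose_g = 12, loading_dose_g = 4,
                       loading_minutes = 30, ci_hours = Inf) {
  stopifnot(daily_dose_g >= 0, loading_dose_g >= 0, loading_minutes > 0)
  rate <- numeric(0); start <- numeric(0); dur <- numeric(0)
  if (loading_dose_g > 0) {
    rate <- c(rate, loading_dose_g * 1000 / (loading_minutes / 60))
    start <- c(start, 0); dur <- c(dur, loading_minutes / 60)
  }
  if (daily_dose_g > 0) {
    rate <- c(rate, daily_dose_g * 1000 / 24)
    start <- c(start, 0); dur <- c(dur, ci_hours)
  }
  dosing_regimen(rate, start, dur)
}

#' Read a flat `key: value` regimen configuration block
#'
#' Accepts the minimal configuration format
#' ```
#' daily_dose_g: 12
#' infusion_hours: 24
#' loading_dose_g: 4
#' loading_minutes: 30
#' ```
#' (comments after `#` ignored) and returns the corresponding regimen.
#'
#' @param path file containing the block, or a character vector of lines via
#'   `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return a [dosing_regimen()].
#' @export
read_regimen_config <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- stats::setNames(as.numeric(trimws(vapply(kv, `[`, "", 2))),
                          trimws(vapply(kv, `[`, "", 1)))
  get_or <- function(key, default) if (key %in% names(vals)) vals[[key]] else default
  ci_regimen(daily_dose_g = get_or("daily_dose_g", 12),
             loading_dose_g = get_or("loading_dose_g", 4),
             loading_minutes = get_or("loading_minutes", 30),
             ci_hours = get_or("infusion_hours", Inf))
}

#' Elimination specification
#'
#' @param kind `"first_order"` (clearance-driven), `"michaelis_menten"`
#'   (saturable, capacity `Vmax` mg/h and affinity `Km` mg/L), or
#'   `"parallel_fo_mm"` (both pathways in parallel).
#' @param Vmax maximum elimination rate, mg/h (saturable kinds only).
#' @param Km concentration of half-maximal elimination, mg/L.
#' @return object of class `elimination_spec`.
#' @export
elimination_spec <- function(kind = c("first_order", "michaelis_menten",
                                      "parallel_fo_mm"),
                             Vmax = NULL, Km = NULL) {
  kind <- match.arg(kind)
  if (kind != "first_order") {
    if (is.null(Vmax) || is.null(Km) || Vmax <= 0 || Km <= 0) {
      stop("saturable elimination requires Vmax > 0 and Km > 0")
    }
  }
  structure(list(kind = kind, Vmax = Vmax, Km = Km),
            class = "elimination_spec")
}
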