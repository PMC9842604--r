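#' Tidy a cohort report
#'
#' @param x an `fsgs_report`.
#' @param ... unused.
#' @return the subgroup detection-rate tibble.
#' @method tidy fsgs_report
#' @export
tidy.fsgs_report <- function(x, ...) {
  x$rates
}

#' One-row summary of a cohort report
#'
#' @param x an `fsgs_report`.
#' @param ... unused.
#' @return one-row tibble: patients, solved, overall rate, VUS carriers,
#'   median ages.
#' @method glance fsgs_report
#' @export
glance.fsgs_report <- function(x, ...) {
  overall <- x$rates[x$rates$subgroup == "overall", ]
  tibble(
    n_patients = x$n_patients,
    n_solved = overall$n_solved,
    detection_rate = overall$rate,
    detection_rate_pct = overall$rate_pct,
    n_vus_carriers = x$n_vus_carriers,
    median_onset_all = x$medians$median_onset_all,
    median_onset_solved = x$medians$median_onset_solved,
    median_esrd_solved = x$medians$median_esrd_solved
  )
}

#' Tidy a pipeline run into per-patient verdicts
#'
#' @param x an `fsgs_run`.
#' @param ... unused.
#' @return the per-patient cohort tibble (metadata + verdict).
#' @method tidy fsgs_run
#' @export
tidy.fsgs_run <- function(x, ...) {
  x$cohort
}

#' @rdname glance.fsgs_report
#' @method glance fsgs_run
#' @export
glance.fsgs_run <- function(x, ...) {
  glance(x$report)
}

#' Tidy a cascade into its filtering funnel
#'
#' @param x an `fsgs_cascade`.
#' @param ... unused.
#' @return the per-patient, per-criterion trace tibble.
#' @method tidy fsgs_cascade
#' @export
tidy.fsgs_cascade <- function(x, ...) {
  x$trace
}
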