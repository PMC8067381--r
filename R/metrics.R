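#' Interval reproductive performance measures
#'
#' These summaries use the herd mating start date as day 0 and half-open
#' windows: "within N days" means the event day is strictly less than N,
#' so the 21/42/84-day windows correspond to 1, 2 and 4 complete 21-day
#' cycles.
#'
#' `interval_in_calf_rate` is the proportion of cows conceiving before the
#' window closes; `submission_rate` the proportion with at least one AI
#' service in the window; `conception_rate_first_service` the proportion of
#' AI-served cows conceiving at their first service;
#' `services_per_conception` the ratio of all AI services to AI conceptions
#' (bull conceptions carry no service record and are excluded);
#' `barren_proportion` is one minus the product-limit cumulative pregnancy
#' at 84 days on the group's shifted time scale.
#'
#' @param records Cow-record tibble for one group.
#' @param window_days Window length in days (> 0).
#' @return A proportion (or ratio for `services_per_conception`); `NA` with
#'   a warning when the denominator is empty.
#' @name repro_rates
NULL

#' @rdname repro_rates
#' @export
interval_in_calf_rate <- function(records, window_days) {
  stopifnot(window_days > 0)
  if (nrow(records) == 0) {
    warning("no cows: in-calf rate undefined")
    return(NA_real_)
  }
  mean(!is.na(records$conception_day) & records$conception_day < window_days)
}

#' @rdname repro_rates
#' @export
submission_rate <- function(records, window_days = 21) {
  stopifnot(window_days > 0)
  if (nrow(records) == 0) {
    warning("no cows: submission rate undefined")
    return(NA_real_)
  }
  served <- vapply(records$service_days,
                   function(s) length(s) > 0 && min(s) < window_days,
                   logical(1))
  mean(served)
}

#' @rdname repro_rates
#' @export
conception_rate_first_service <- function(records) {
  served <- vapply(records$service_days, function(s) length(s) > 0,
                   logical(1))
  if (!any(served)) {
    warning("no served cows: first-service conception rate undefined")
    return(NA_real_)
  }
  first_sv <- vapply(records$service_days[served], min, numeric(1))
  conc <- records$conception_day[served]
  mean(!is.na(conc) & abs(conc - first_sv) < 1e-9)
}

#' @rdname repro_rates
#' @export
services_per_conception <- function(records) {
  n_services <- sum(lengths(records$service_days))
  ai_conc <- mapply(function(cd, sv) {
    !is.na(cd) && length(sv) > 0 && any(abs(sv - cd) < 1e-9)
  }, records$conception_day, records$service_days)
  n_conc <- sum(ai_conc)
  if (n_conc == 0) {
    warning("no AI conceptions: services per conception undefined")
    return(NA_real_)
  }
  n_services / n_conc
}

#' @rdname repro_rates
#' @export
barren_proportion <- function(records) {
  curve <- group_survival_curve(records)
  1 - time_point_estimate(curve, 84)$cumulative_pregnancy
}

#' Summarize the reproductive performance of one treatment group
#'
#' Bundles the interval measures, the first-service conception rate,
#' services per conception, the survival-based barren proportion and the
#' calving-interval means into a one-row tibble.
#'
#' @param records Cow-record tibble for one group.
#' @return One-row tibble with columns `n`, `submission_rate_21`,
#'   `in_calf_21`, `in_calf_42`, `in_calf_84`,
#'   `conception_rate_first_service`, `services_per_conception`,
#'   `barren_proportion`, `mean_calving_first_service`,
#'   `mean_calving_conception`, `median_msd_conception`.
#' @export
summarize_group <- function(records) {
  served <- vapply(records$service_days, function(s) length(s) > 0,
                   logical(1))
  first_sv <- rep(NA_real_, nrow(records))
  first_sv[served] <- vapply(records$service_days[served], min, numeric(1))
  conceived <- !is.na(records$conception_day)
  tibble::tibble(
    n = nrow(records),
    submission_rate_21 = submission_rate(records, 21),
    in_calf_21 = interval_in_calf_rate(records, 21),
    in_calf_42 = interval_in_calf_rate(records, 42),
    in_calf_84 = interval_in_calf_rate(records, 84),
    conception_rate_first_service = conception_rate_first_service(records),
    services_per_conception = services_per_conception(records),
    barren_proportion = barren_proportion(records),
    mean_calving_first_service =
      mean(records$cbsi_days[served] + first_sv[served]),
    mean_calving_conception =
      mean(records$cbsi_days[conceived] +
             records$conception_day[conceived]),
    median_msd_conception =
      stats::median(records$conception_day[conceived])
  )
}
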