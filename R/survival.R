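#' Treatment-group time origin for survival analysis
#'
#' Because fixed-time AI and estrus-based AI start at different days, the
#' conception-time clock is started separately per treatment group at the
#' group's first insemination: the minimum recorded service day.
#'
#' @param records Cow-record tibble for one treatment group.
#' @return The origin day offset (day of the group's first service).
#' @export
group_time_origin <- function(records) {
  days <- unlist(records$service_days)
  if (length(days) == 0) {
    stop("no services recorded in this group; time origin undefined",
         call. = FALSE)
  }
  min(days)
}

#' Product-limit (Kaplan-Meier) survival estimate with Greenwood errors
#'
#' First-principles product-limit estimator
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i/n_i)} over the distinct event
#' times, with Greenwood variance
#' \eqn{S(t)^2 \sum d_i / (n_i (n_i - d_i))}. Events and censorings tied at
#' the same time are resolved by the usual convention: cows censored at an
#' event time remain at risk for that time's events.
#'
#' @param event_times Days of conception or censoring (absolute day
#'   offsets, `>= origin`).
#' @param event_flags Logical; `TRUE` for conception, `FALSE` for censoring.
#' @param origin Day offset used as time zero; durations are
#'   `event_times - origin`, floored at 0.
#' @return An object of class `survival_curve`: list with `origin_day`,
#'   `times` (distinct event times on the shifted scale), `n_at_risk`,
#'   `n_events`, `survival`, `se`, `censor_times`, `n`.
#' @export
#' @examples
#' # 4 cows: conceptions at days 5, 10, 20; one censored at 12
#' km <- kaplan_meier(c(5, 10, 12, 20), c(TRUE, TRUE, FALSE, TRUE))
#' km$survival  # 0.75 0.50 0.00
kaplan_meier <- function(event_times, event_flags, origin = 0) {
  if (length(event_times) == 0) {
    stop("empty input: no observations", call. = FALSE)
  }
  if (length(event_times) != length(event_flags)) {
    stop("`event_times` and `event_flags` must have equal length",
         call. = FALSE)
  }
  if (any(event_times < origin)) {
    stop("negative durations: some times precede the origin", call. = FALSE)
  }
  time <- pmax(event_times - origin, 0)
  event <- as.logical(event_flags)
  ut <- sort(unique(time[event]))
  n <- length(time)
  if (length(ut) == 0) {
    return(structure(
      list(origin_day = origin, times = numeric(0), n_at_risk = integer(0),
           n_events = integer(0), survival = numeric(0), se = numeric(0),
           censor_times = sort(time[!event]), n = n),
      class = "survival_curve"
    ))
  }
  n_at_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_events <- vapply(ut, function(t) sum(time == t & event), numeric(1))
  surv <- cumprod(1 - n_events / n_at_risk)
  gw_terms <- ifelse(n_at_risk > n_events,
                     n_events / (n_at_risk * (n_at_risk - n_events)), 0)
  gw <- cumsum(gw_terms)
  se <- surv * sqrt(gw)  # 0 where S = 0 (variance undefined there)
  structure(
    list(origin_day = origin, times = ut, n_at_risk = as.integer(n_at_risk),
         n_events = as.integer(n_events), survival = surv, se = se,
         censor_times = sort(time[!event]), n = n),
    class = "survival_curve"
  )
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Product-limit survival curve (origin day ", x$origin_day, ", n = ",
      x$n, ")\n", sep = "")
  print(tibble::tibble(time = x$times, n_at_risk = x$n_at_risk,
                       n_events = x$n_events, survival = x$survival,
                       se = x$se))
  invisible(x)
}

#' Build the per-group survival curve from cow records
#'
#' Convenience wrapper: derives the group origin, turns each record into a
#' (time, event) pair — conception day for pregnant cows, censor day
#' otherwise (cows never served stay in the risk set until censoring) —
#' and calls [kaplan_meier()].
#'
#' @param records Cow-record tibble for one group.
#' @param origin Time origin; defaults to [group_time_origin()] of the
#'   group.
#' @return A `survival_curve`.
#' @export
group_survival_curve <- function(records, origin = NULL) {
  if (is.null(origin)) origin <- group_time_origin(records)
  event <- !is.na(records$conception_day)
  time <- ifelse(event, records$conception_day, records$censor_day)
  time <- pmax(time, origin)  # events before the group origin count at 0
  kaplan_meier(time, event, origin = origin)
}

#' Cumulative pregnancy at a time point
#'
#' Returns `1 - S(t)` and the Greenwood standard error from the last event
#' time at or before `t`. Evaluation beyond the last follow-up time returns
#' the final estimate with `beyond_followup = TRUE`.
#'
#' @param curve A `survival_curve`.
#' @param t Time point (days on the curve's shifted scale).
#' @return List with `cumulative_pregnancy`, `se`, `survival`,
#'   `beyond_followup`.
#' @export
time_point_estimate <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"), t >= 0)
  last_follow_up <- max(c(curve$times, curve$censor_times, 0))
  idx <- which(curve$times <= t)
  if (length(idx) == 0) {
    return(list(cumulative_pregnancy = 0, se = 0, survival = 1,
                beyond_followup = t > last_follow_up))
  }
  i <- max(idx)
  list(cumulative_pregnancy = 1 - curve$survival[i], se = curve$se[i],
       survival = curve$survival[i],
       beyond_followup = t > last_follow_up)
}

#' Median survival time
#'
#' Smallest event time at which the survival estimate drops to 0.5 or
#' below; `NA` when the curve never reaches 0.5.
#'
#' @param curve A `survival_curve`.
#' @return Days, or `NA_real_`.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  idx <- which(curve$survival <= 0.5 + 1e-12)
  if (length(idx) == 0) return(NA_real_)
  curve$times[min(idx)]
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank test computed from first principles: at
#' each distinct event time the expected events in group A are
#' \eqn{e_A = n_A d / n} and the variance is the hypergeometric
#' \eqn{n_A n_B d (n - d) / (n^2 (n - 1))};
#' \eqn{\chi^2 = (\sum (o_A - e_A))^2 / \sum V} on 1 df. The statistic is
#' symmetric under swapping the groups.
#'
#' @param time_a,time_b Event/censor times per group (durations from each
#'   group's own origin).
#' @param event_a,event_b Logical event indicators.
#' @return List with `chisq`, `p_value`, `observed`, `expected` (length-2
#'   vectors for groups A and B).
#' @export
log_rank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0 || length(time_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  time <- c(time_a, time_b)
  event <- as.logical(c(event_a, event_b))
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  if (!any(event)) stop("zero events in total; log-rank undefined",
                        call. = FALSE)
  ut <- sort(unique(time[event]))
  o_a <- e_a <- v <- numeric(length(ut))
  for (i in seq_along(ut)) {
    t <- ut[i]
    at_risk <- time >= t
    n <- as.double(sum(at_risk))
    n_a <- as.double(sum(at_risk & grp == "A"))
    d <- as.double(sum(time == t & event))
    d_a <- as.double(sum(time == t & event & grp == "A"))
    o_a[i] <- d_a
    e_a[i] <- n_a * d / n
    v[i] <- if (n > 1) n_a * (n - n_a) * d * (n - d) / (n^2 * (n - 1)) else 0
  }
  vsum <- sum(v)
  chisq <- if (vsum > 0) (sum(o_a) - sum(e_a))^2 / vsum else 0
  list(
    chisq = chisq,
    p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
    observed = c(A = sum(o_a), B = sum(event) - sum(o_a)),
    expected = c(A = sum(e_a), B = sum(event) - sum(e_a))
  )
}

#' Schoenfeld sample size for a two-group log-rank comparison
#'
#' Required events \eqn{D = 4 (z_{1-\alpha/2} + z_{power})^2 / (\ln HR)^2},
#' converted to animals per group by dividing over two groups at the given
#' event probability and rounding up.
#'
#' @param hazard_ratio Assumed hazard ratio (not 1).
#' @param alpha_two_sided Two-sided type-1 error.
#' @param power Desired power.
#' @param event_probability Probability an enrolled animal experiences the
#'   event during follow-up.
#' @return List with `n_per_group` and `n_events` (required total events).
#' @export
#' @examples
#' schoenfeld_sample_size(1.5, 0.05, 0.8, 1)$n_per_group  # 96
schoenfeld_sample_size <- function(hazard_ratio, alpha_two_sided = 0.05,
                                   power = 0.8, event_probability = 1) {
  if (hazard_ratio <= 0) stop("`hazard_ratio` must be > 0", call. = FALSE)
  if (hazard_ratio == 1) {
    stop("`hazard_ratio` of 1 implies no effect: required n is infinite",
         call. = FALSE)
  }
  if (alpha_two_sided <= 0 || alpha_two_sided >= 1 || power <= 0 ||
      power >= 1 || event_probability <= 0 || event_probability > 1) {
    stop("alpha and power must lie in (0, 1), event probability in (0, 1]",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha_two_sided / 2) + stats::qnorm(power)
  d <- 4 * z^2 / log(hazard_ratio)^2
  list(n_per_group = ceiling(d / (2 * event_probability)), n_events = d)
}
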