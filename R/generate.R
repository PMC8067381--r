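#' Allocate a cow to a treatment group by freeze-brand parity
#'
#' Even freeze-brand numbers receive the single prostaglandin treatment
#' (PGOD); odd numbers receive the modified Ovsynch protocol (MOFT). The
#' rule is deterministic, so the allocation is reproducible from the herd
#' records alone.
#'
#' @param freeze_brand Vector of positive whole numbers.
#' @return Character vector, `"PGOD"` or `"MOFT"`.
#' @export
#' @examples
#' allocate_treatment(c(1, 2, 1000001))
allocate_treatment <- function(freeze_brand) {
  if (length(freeze_brand) == 0L) return(character(0))
  if (!is.numeric(freeze_brand) || any(is.na(freeze_brand)) ||
      any(freeze_brand < 1) || any(freeze_brand != floor(freeze_brand))) {
    stop("`freeze_brand` must contain positive whole numbers", call. = FALSE)
  }
  ifelse(freeze_brand %% 2 == 0, "PGOD", "MOFT")
}

#' Apply trial eligibility filters to cow records
#'
#' Excludes cows with a calving interval above `max_calving_interval_days`,
#' systemically ill cows, cows with abnormal vaginal discharge, and
#' nulliparous animals. Enrollment flags are recorded at examination and are
#' supplied separately from the breeding records.
#'
#' @param records Cow-record tibble (see [generate_herd()]).
#' @param flags Data frame with columns `cow_id`, `calving_interval_days`,
#'   `systemically_ill`, `abnormal_discharge`, `nulliparous`; one row per
#'   cow in `records`.
#' @param max_calving_interval_days Exclusion threshold (strictly greater
#'   is excluded).
#' @param quiet Suppress the retained/excluded count message.
#' @return The retained records, original order preserved, with an
#'   `n_excluded` attribute.
#' @export
apply_eligibility_filters <- function(records, flags,
                                      max_calving_interval_days = 365,
                                      quiet = FALSE) {
  needed <- c("cow_id", "calving_interval_days", "systemically_ill",
              "abnormal_discharge", "nulliparous")
  missing_cols <- setdiff(needed, names(flags))
  if (length(missing_cols) > 0) {
    stop("`flags` is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(records$cow_id, flags$cow_id)
  if (anyNA(idx)) {
    stop("no eligibility flags supplied for cow(s): ",
         paste(records$cow_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  f <- flags[idx, , drop = FALSE]
  if (anyNA(f[needed])) {
    bad <- records$cow_id[rowSums(is.na(f[needed])) > 0]
    stop("incomplete eligibility flags for cow(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  keep <- f$calving_interval_days <= max_calving_interval_days &
    !f$systemically_ill & !f$abnormal_discharge & !f$nulliparous
  out <- records[keep, , drop = FALSE]
  if (!quiet) {
    message(sum(keep), " of ", nrow(records), " cows retained (",
            sum(!keep), " excluded)")
  }
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Generate a synthetic breeding-season cohort
#'
#' Creates one record per cow (farm, treatment by freeze-brand parity,
#' parity class, body-condition class, CBSI) and simulates the full
#' breeding season for each cow under the supplied dynamics: AI services,
#' conception or right-censoring at the end of follow-up, and natural
#' (bull) service on farms that switch away from AI. Identical
#' `(config, dynamics, seed)` yield a bit-identical cohort.
#'
#' @param config A [herd_config()].
#' @param dynamics A [breeding_dynamics()].
#' @param seed Integer seed for the cohort.
#' @return A tibble with columns `cow_id`, `freeze_brand`, `farm`,
#'   `treatment`, `parity_class`, `bcs_class`, `cbsi_days`,
#'   `service_days` (list column of ascending day offsets from mating start
#'   date), `conception_day`, `censor_day`. `censor_day` is set (to the
#'   follow-up length) exactly when `conception_day` is absent.
#' @export
#' @examples
#' herd <- generate_herd(herd_config(n_per_farm = c(10, 5)), seed = 1)
#' nrow(herd)
generate_herd <- function(config = herd_config(),
                          dynamics = breeding_dynamics(),
                          seed = 1L) {
  stopifnot(inherits(config, "herd_config"),
            inherits(dynamics, "breeding_dynamics"))
  set.seed(as.integer(seed))
  n <- sum(config$n_per_farm)
  if (n == 0L) {
    return(tibble::tibble(
      cow_id = character(0), freeze_brand = integer(0), farm = integer(0),
      treatment = character(0), parity_class = character(0),
      bcs_class = character(0), cbsi_days = integer(0),
      service_days = list(), conception_day = numeric(0),
      censor_day = numeric(0)
    ))
  }
  farm <- rep(seq_along(config$n_per_farm), config$n_per_farm)
  if (is.null(config$group_sizes_override)) {
    freeze_brand <- seq_len(n)
    treatment <- allocate_treatment(freeze_brand)
  } else {
    sizes <- config$group_sizes_override
    treatment <- sample(rep(c("PGOD", "MOFT"),
                            c(sizes[["PGOD"]], sizes[["MOFT"]])))
    freeze_brand <- integer(n)
    # even brands for PGOD, odd for MOFT, issued in cow order
    freeze_brand[treatment == "PGOD"] <- 2L * seq_len(sum(treatment == "PGOD"))
    freeze_brand[treatment == "MOFT"] <- 2L * seq_len(sum(treatment == "MOFT")) - 1L
  }
  parity_class <- sample(c("1", "2", "3plus"), n, replace = TRUE,
                         prob = config$parity_fractions)
  bcs_class <- ifelse(stats::runif(n) < config$bcs_low_fraction,
                      "le2.5", "ge2.75")
  cbsi_days <- as.integer(rtrunc_norm_round(n, config$cbsi_mean_days,
                                            config$cbsi_sd_days,
                                            config$cbsi_min_days))
  records <- tibble::tibble(
    cow_id = sprintf("F%d-%04d", farm, seq_len(n)),
    freeze_brand = as.integer(freeze_brand),
    farm = farm,
    treatment = treatment,
    parity_class = parity_class,
    bcs_class = bcs_class,
    cbsi_days = cbsi_days,
    service_days = vector("list", n),
    conception_day = NA_real_,
    censor_day = NA_real_
  )
  ns_by_farm <- config$natural_service_start_day
  for (i in seq_len(n)) {
    sim <- sim_cow_events(treatment[i], dynamics, config$follow_up_days,
                          ns_by_farm[farm[i]])
    records$service_days[[i]] <- sim$services
    records$conception_day[i] <- sim$conception
    records$censor_day[i] <- sim$censor
  }
  records
}

#' Simulate the breeding events of a single cow
#'
#' Fills the service list and conception/censor outcome of one cow record
#' with an empty service list, using the current R random-number stream
#' (set a seed first, or pass one).
#'
#' @param record One-row cow-record tibble with an empty `service_days`
#'   entry.
#' @param dynamics A [breeding_dynamics()].
#' @param follow_up_days Breeding-season length (days).
#' @param natural_service_start_day Day the cow's farm switches to natural
#'   service, or `NA` for AI throughout.
#' @param seed Optional seed; if `NULL` the RNG must already be initialized.
#' @return The record with `service_days`, `conception_day` and
#'   `censor_day` completed.
#' @export
simulate_breeding_events <- function(record, dynamics,
                                     follow_up_days = 84,
                                     natural_service_start_day = NA,
                                     seed = NULL) {
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
  } else if (!exists(".Random.seed", envir = globalenv())) {
    stop("random-number state absent: call set.seed() or pass `seed`",
         call. = FALSE)
  }
  if (length(record$service_days[[1]]) != 0) {
    stop("`record` must have an empty service list", call. = FALSE)
  }
  sim <- sim_cow_events(record$treatment, dynamics, follow_up_days,
                        natural_service_start_day)
  record$service_days[[1]] <- sim$services
  record$conception_day <- sim$conception
  record$censor_day <- sim$censor
  record
}

# one cow's breeding season; consumes the global RNG stream
sim_cow_events <- function(treatment, dyn, follow_up, ns_day) {
  draw_cycle <- function() {
    rtrunc_norm_round2(1, dyn$cycle_length_mean, dyn$cycle_length_sd,
                       dyn$cycle_length_bounds[1], dyn$cycle_length_bounds[2])
  }
  ai_allowed <- function(d) {
    d <= follow_up && (is.na(ns_day) || d < ns_day)
  }
  services <- numeric(0)
  conception <- NA_real_
  never <- stats::runif(1) < dyn$p_never_served[[treatment]]
  if (never) {
    day <- NA_real_
  } else if (treatment == "PGOD") {
    if (stats::runif(1) < dyn$p_first_response) {
      w <- dyn$pgod_response_window
      day <- sample(seq(w[1], w[2]), 1)
    } else {
      w <- dyn$first_estrus_window
      e <- sample(seq(w[1], w[2]), 1)
      while (e <= follow_up && stats::runif(1) >= dyn$p_detect_return) {
        e <- e + draw_cycle()
      }
      day <- if (e <= follow_up) e else NA_real_
    }
  } else {
    if (stats::runif(1) < dyn$p_early_estrus) {
      w <- dyn$moft_early_window
      day <- sample(seq(w[1], w[2]), 1)
    } else {
      day <- dyn$moft_ftai_day
    }
  }
  k <- 1L
  while (!is.na(day) && ai_allowed(day)) {
    services <- c(services, day)
    p <- if (k == 1L) dyn$conception_prob_first[[treatment]] else
      dyn$conception_prob_repeat
    if (stats::runif(1) < p) {
      conception <- day
      break
    }
    e <- round(day) + draw_cycle()
    while (e <= follow_up && stats::runif(1) >= dyn$p_detect_return) {
      e <- e + draw_cycle()
    }
    day <- if (e <= follow_up) e else NA_real_
    k <- k + 1L
  }
  if (is.na(conception) && !is.na(ns_day) && ns_day <= follow_up) {
    cd <- ns_day + stats::rgeom(1, dyn$bull_daily_conception_hazard)
    if (cd <= follow_up) conception <- cd
  }
  list(
    services = services,
    conception = conception,
    censor = if (is.na(conception)) follow_up else NA_real_
  )
}

#' Validate the structural invariants of cow records
#'
#' Checks that service days are strictly ascending within follow-up, that
#' a conception day coincides with a service day (or falls in the natural
#' service period with no later services), and that exactly one of
#' `conception_day` / `censor_day` is present.
#'
#' @param records Cow-record tibble.
#' @param follow_up_days Breeding-season length.
#' @param natural_service_start_day Either a single day, a vector indexed
#'   by farm, or `NA` when no farm runs a bull.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_cow_records <- function(records, follow_up_days = 84,
                                 natural_service_start_day = NA) {
  ns <- natural_service_start_day
  for (i in seq_len(nrow(records))) {
    id <- records$cow_id[i]
    sv <- records$service_days[[i]]
    cd <- records$conception_day[i]
    xd <- records$censor_day[i]
    ns_i <- if (length(ns) > 1) ns[records$farm[i]] else ns
    if (length(sv) > 0 && (any(diff(sv) <= 0) || any(sv < 0) ||
                           any(sv > follow_up_days))) {
      stop("cow ", id, ": service days must be strictly ascending within [0, ",
           follow_up_days, "]", call. = FALSE)
    }
    if (is.na(cd) == is.na(xd)) {
      stop("cow ", id, ": exactly one of conception_day/censor_day required",
           call. = FALSE)
    }
    if (!is.na(cd)) {
      on_service <- length(sv) > 0 && any(abs(sv - cd) < 1e-9)
      bull_ok <- !is.na(ns_i) && cd >= ns_i &&
        (length(sv) == 0 || max(sv) <= cd)
      if (!on_service && !bull_ok) {
        stop("cow ", id, ": conception day ", cd,
             " matches no service day and is outside the natural-service ",
             "period", call. = FALSE)
      }
      if (on_service && length(sv) > 0 && max(sv) > cd + 1e-9) {
        stop("cow ", id, ": services recorded after conception", call. = FALSE)
      }
    }
    if (!is.na(records$cbsi_days[i]) && records$cbsi_days[i] < 0) {
      stop("cow ", id, ": negative cbsi_days", call. = FALSE)
    }
  }
  invisible(TRUE)
}
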