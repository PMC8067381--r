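# Independent oracles used by the tests. These re-derive expected values by
# direct probability convolution / closed forms, sharing no code with the
# package's simulator or estimators.

# discrete cycle-length pmf implied by a rounded, doubly truncated normal
oracle_cycle_pmf <- function(mean, sd, lo, hi) {
  z <- stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)
  ls <- lo:hi
  p <- numeric(length(ls))
  for (i in seq_along(ls)) {
    a <- max(ls[i] - 0.5, lo)
    b <- min(ls[i] + 0.5, hi)
    p[i] <- (stats::pnorm(b, mean, sd) - stats::pnorm(a, mean, sd)) / z
  }
  names(p) <- ls
  p
}

# Exact conception-time distribution for one treatment group on one farm,
# by day-grid convolution over response, estrus-detection and return-cycle
# outcomes (quarter-day grid to carry the fractional fixed-time AI day).
# Returns P(first AI service at day d), P(conception <= t) on the grid.
oracle_group_model <- function(dyn, treatment, follow_up = 84,
                               ns_day = NA) {
  step <- 0.25
  grid <- seq(0, follow_up, by = step)
  ix <- function(d) round(d / step) + 1L
  n_grid <- length(grid)
  cyc <- oracle_cycle_pmf(dyn$cycle_length_mean, dyn$cycle_length_sd,
                          dyn$cycle_length_bounds[1],
                          dyn$cycle_length_bounds[2])
  cyc_l <- as.integer(names(cyc))
  ai_ok <- function(d) d <= follow_up && (is.na(ns_day) || d < ns_day)
  never <- dyn$p_never_served[[treatment]]
  det <- dyn$p_detect_return

  # distribution of the first *potential* service day (before the AI-window
  # cap), built from the protocol rules and missed-detection chains
  fs <- numeric(n_grid)
  if (treatment == "PGOD") {
    w <- dyn$pgod_response_window
    days <- w[1]:w[2]
    fs[ix(days)] <- fs[ix(days)] +
      (1 - never) * dyn$p_first_response / length(days)
    # non-responders: spontaneous estrus chain with per-estrus detection
    ew <- dyn$first_estrus_window
    e_days <- ew[1]:ew[2]
    pend <- numeric(n_grid)  # mass in estrus, not yet served
    pend[ix(e_days)] <- (1 - never) * (1 - dyn$p_first_response) /
      length(e_days)
    repeat {
      if (sum(pend) < 1e-15) break
      fs <- fs + det * pend
      nxt <- numeric(n_grid)
      for (i in which(pend > 0)) {
        for (k in seq_along(cyc_l)) {
          d2 <- grid[i] + cyc_l[k]
          if (d2 <= follow_up) {
            nxt[ix(d2)] <- nxt[ix(d2)] + (1 - det) * pend[i] * cyc[k]
          }
        }
      }
      pend <- nxt
    }
  } else {
    w <- dyn$moft_early_window
    days <- w[1]:w[2]
    fs[ix(days)] <- fs[ix(days)] +
      (1 - never) * dyn$p_early_estrus / length(days)
    fs[ix(dyn$moft_ftai_day)] <- fs[ix(dyn$moft_ftai_day)] +
      (1 - never) * (1 - dyn$p_early_estrus)
  }
  served <- vapply(grid, ai_ok, logical(1))
  fs_ai <- ifelse(served, fs, 0)  # services realized inside the AI window

  # conception mass by repeated service rounds
  p1 <- dyn$conception_prob_first[[treatment]]
  pr <- dyn$conception_prob_repeat
  conc <- numeric(n_grid)
  fail <- numeric(n_grid)
  conc <- conc + p1 * fs_ai
  fail <- fail + (1 - p1) * fs_ai
  for (round_i in 1:12) {
    if (sum(fail) < 1e-15) break
    # failed service at d -> detected return chain -> next service day
    pend <- numeric(n_grid)
    for (i in which(fail > 0)) {
      base <- round(grid[i])
      for (k in seq_along(cyc_l)) {
        d2 <- base + cyc_l[k]
        if (d2 <= follow_up) pend[ix(d2)] <- pend[ix(d2)] + fail[i] * cyc[k]
      }
    }
    nxt_service <- numeric(n_grid)
    repeat {
      if (sum(pend) < 1e-15) break
      nxt_service <- nxt_service + det * pend
      nxt <- numeric(n_grid)
      for (i in which(pend > 0)) {
        for (k in seq_along(cyc_l)) {
          d2 <- grid[i] + cyc_l[k]
          if (d2 <= follow_up) {
            nxt[ix(d2)] <- nxt[ix(d2)] + (1 - det) * pend[i] * cyc[k]
          }
        }
      }
      pend <- nxt
    }
    nxt_service <- ifelse(served, nxt_service, 0)
    conc <- conc + pr * nxt_service
    fail <- (1 - pr) * nxt_service
  }
  ai_cdf <- cumsum(conc)

  cdf <- function(t) {
    t <- min(t, follow_up)
    p <- ai_cdf[ix(floor(t / step) * step)]
    if (!is.na(ns_day) && t >= ns_day) {
      bull_pool <- 1 - ai_cdf[n_grid]
      h <- dyn$bull_daily_conception_hazard
      p <- p + bull_pool * (1 - (1 - h)^(floor(t - ns_day) + 1))
    }
    p
  }
  in_calf <- function(window) cdf(window - step)  # conception day < window
  submission <- function(window) sum(fs_ai[grid < window])
  list(cdf = cdf, in_calf = in_calf, submission = submission,
       first_service = fs_ai)
}

# analytic triangular CDF (minimum a, mode m, maximum b)
oracle_triangular_cdf <- function(q, a, m, b) {
  ifelse(q <= a, 0,
         ifelse(q < m, (q - a)^2 / ((b - a) * (m - a)),
                ifelse(q < b, 1 - (b - q)^2 / ((b - a) * (b - m)), 1)))
}

# random small right-censored dataset with integer times (plenty of ties)
random_survival_data <- function(n, max_time = 10, p_event = 0.7) {
  time <- sample(0:max_time, n, replace = TRUE)
  event <- stats::runif(n) < p_event
  event[1] <- TRUE  # at least one event so the estimate is non-trivial
  list(time = time, event = event)
}

# cow-record tibble built directly (bypasses the generator)
make_records <- function(service_days, conception_day, farm = 1,
                         cbsi = 70, treatment = "PGOD",
                         follow_up = 84) {
  n <- length(service_days)
  tibble::tibble(
    cow_id = sprintf("T-%03d", seq_len(n)),
    freeze_brand = seq_len(n),
    farm = rep_len(farm, n),
    treatment = rep_len(treatment, n),
    parity_class = rep_len("1", n),
    bcs_class = rep_len("ge2.75", n),
    cbsi_days = rep_len(cbsi, n),
    service_days = service_days,
    conception_day = conception_day,
    censor_day = ifelse(is.na(conception_day), follow_up, NA_real_)
  )
}
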