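test_that("group time origin is the minimum service day", {
  rec <- make_records(list(c(8, 30), c(12), c(9.25)),
                      c(NA, 12, NA), treatment = "MOFT")
  expect_equal(group_time_origin(rec), 8)
  single <- make_records(list(0), NA_real_)
  expect_equal(group_time_origin(single), 0)
  none <- make_records(list(numeric(0)), NA_real_)
  expect_error(group_time_origin(none), "no services")
})

test_that("product-limit estimate matches the hand-worked 4-cow example", {
  km <- kaplan_meier(c(5, 10, 12, 20), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(km$times, c(5, 10, 20))
  expect_equal(km$n_at_risk, c(4L, 3L, 1L))
  expect_equal(km$survival, c(3 / 4, 1 / 2, 0))  # 3/4 * 2/3 * 0/1
  expect_equal(km$censor_times, 12)
  # step-function lookup between event times
  expect_equal(time_point_estimate(km, 15)$cumulative_pregnancy, 0.5)
  expect_equal(median_survival(km), 10)
})

test_that("degenerate curves behave: all censored, no censoring", {
  all_cens <- kaplan_meier(c(3, 6, 9), c(FALSE, FALSE, FALSE))
  expect_equal(length(all_cens$times), 0L)
  expect_equal(time_point_estimate(all_cens, 5)$cumulative_pregnancy, 0)
  expect_true(is.na(median_survival(all_cens)))

  set.seed(10)
  t <- sample(1:15, 40, replace = TRUE)
  no_cens <- kaplan_meier(t, rep(TRUE, 40))
  for (q in c(2, 7, 12, 15)) {
    expect_equal(1 - time_point_estimate(no_cens, q)$survival,
                 mean(t <= q))  # 1 - S is the empirical CDF
  }
  expect_error(kaplan_meier(numeric(0), logical(0)), "empty")
  expect_error(kaplan_meier(c(3, 5), c(TRUE, TRUE), origin = 4),
               "negative durations")
})

test_that("survival, errors and median match the survival package", {
  skip_if_not_installed("survival")
  set.seed(99)
  for (i in 1:30) {
    d <- random_survival_data(n = sample(5:30, 1))
    km <- kaplan_meier(d$time, d$event)
    fit <- summary(survival::survfit(
      survival::Surv(d$time, d$event) ~ 1, conf.type = "none"
    ))
    expect_equal(km$times, fit$time, tolerance = 1e-12)
    expect_equal(km$survival, fit$surv, tolerance = 1e-10)
    expect_equal(km$n_at_risk, as.integer(fit$n.risk))
    expect_equal(km$n_events, as.integer(fit$n.event))
    pos <- km$survival > 0
    expect_equal(km$se[pos], fit$std.err[pos], tolerance = 1e-10)
    lib_median <- if (any(fit$surv <= 0.5 + 1e-12)) {
      fit$time[min(which(fit$surv <= 0.5 + 1e-12))]
    } else NA_real_
    expect_equal(median_survival(km), lib_median)
  }
})

test_that("time points beyond follow-up flag and reuse the last estimate", {
  km <- kaplan_meier(c(5, 10, 12), c(TRUE, TRUE, FALSE))
  est <- time_point_estimate(km, 50)
  expect_true(est$beyond_followup)
  expect_equal(est$survival, km$survival[2])
  expect_false(time_point_estimate(km, 11)$beyond_followup)
})

test_that("log-rank matches a hand hypergeometric tally and is symmetric", {
  # A events {1,2}, B events {3,4}, no censoring
  # t=1: n=4, nA=2, d=1 -> eA=0.5, v=4*1*3/(16*3)=0.25
  # t=2: n=3, nA=1, d=1 -> eA=1/3, v=1*2*1*2/(9*2)=2/9
  # t=3: n=2, nA=0, d=1 -> eA=0,   v=0
  # t=4: n=1 -> v=0;  O-E = 2 - 5/6 = 7/6; V = 0.25 + 2/9
  lr <- log_rank_test(c(1, 2), c(TRUE, TRUE), c(3, 4), c(TRUE, TRUE))
  expect_equal(lr$chisq, (7 / 6)^2 / (1 / 4 + 2 / 9), tolerance = 1e-12)
  swapped <- log_rank_test(c(3, 4), c(TRUE, TRUE), c(1, 2), c(TRUE, TRUE))
  expect_equal(lr$chisq, swapped$chisq, tolerance = 1e-12)

  ident <- log_rank_test(c(1, 2, 5), c(TRUE, TRUE, FALSE),
                         c(1, 2, 5), c(TRUE, TRUE, FALSE))
  expect_equal(ident$chisq, 0)
  expect_equal(ident$p_value, 1)

  expect_error(log_rank_test(c(1, 2), c(FALSE, FALSE), c(3), FALSE),
               "zero events")
  expect_error(log_rank_test(numeric(0), logical(0), c(1), TRUE),
               "non-empty")
})

test_that("log-rank agrees with survdiff on random tied datasets", {
  skip_if_not_installed("survival")
  set.seed(7)
  for (i in 1:25) {
    a <- random_survival_data(sample(4:20, 1))
    b <- random_survival_data(sample(4:20, 1))
    lr <- log_rank_test(a$time, a$event, b$time, b$event)
    sd_fit <- survival::survdiff(
      survival::Surv(c(a$time, b$time), c(a$event, b$event)) ~
        rep(1:2, c(length(a$time), length(b$time)))
    )
    expect_equal(lr$chisq, unname(sd_fit$chisq), tolerance = 1e-10)
  }
})

test_that("interval rates, CR1 and services per conception count correctly", {
  # 2 cows: services {2} and {3, 24}; conceptions at 2 and 24
  rec <- make_records(list(2, c(3, 24)), c(2, 24))
  expect_equal(services_per_conception(rec), 1.5)  # 3 services, 2 conceptions
  expect_equal(conception_rate_first_service(rec), 0.5)
  expect_equal(interval_in_calf_rate(rec, 21), 0.5)
  expect_equal(interval_in_calf_rate(rec, 42), 1.0)
  expect_equal(submission_rate(rec, 21), 1.0)

  # every cow conceives to its single first service
  rec1 <- make_records(list(2, 5, 9), c(2, 5, 9))
  expect_equal(services_per_conception(rec1), 1.0)
  expect_equal(conception_rate_first_service(rec1), 1.0)

  # half-open windows: a conception on day 21 is outside the 21-day window
  edge <- make_records(list(21), 21)
  expect_equal(interval_in_calf_rate(edge, 21), 0)
  expect_equal(submission_rate(edge, 21), 0)

  none <- make_records(list(numeric(0)), NA_real_)
  expect_warning(v <- conception_rate_first_service(none), "undefined")
  expect_true(is.na(v))
  expect_warning(v2 <- services_per_conception(none), "undefined")
  expect_true(is.na(v2))
})

test_that("in-calf rates are monotone in the window and barren consistent", {
  herd <- generate_herd(herd_config(), seed = 11)
  for (g in c("PGOD", "MOFT")) {
    gr <- herd[herd$treatment == g, ]
    s <- summarize_group(gr)
    expect_lte(s$in_calf_21, s$in_calf_42)
    expect_lte(s$in_calf_42, s$in_calf_84)
    curve <- group_survival_curve(gr)
    expect_equal(s$barren_proportion,
                 1 - time_point_estimate(curve, 84)$cumulative_pregnancy)
    expect_gte(s$services_per_conception, 1)
    expect_true(all(diff(curve$survival) <= 1e-12))
  }
  # with no censoring before 84 and no bull, barren = simple non-pregnant
  # fraction: only censored-at-84 cows are non-events and the KM estimate
  # at the last event time equals the empirical fraction
  cfg <- herd_config(n_per_farm = 300, natural_service_start_day = NA)
  herd2 <- generate_herd(cfg, seed = 12)
  gr <- herd2[herd2$treatment == "PGOD", ]
  expect_equal(barren_proportion(gr),
               mean(is.na(gr$conception_day)))
})

test_that("Schoenfeld sample size matches the closed form", {
  res <- schoenfeld_sample_size(1.5, 0.05, 0.8, 1)
  expect_equal(res$n_per_group, 96)
  # halving the event probability scales the pre-rounding answer by two
  expect_equal(schoenfeld_sample_size(1.5, 0.05, 0.8, 0.5)$n_per_group,
               ceiling(res$n_events))
  # direct closed-form evaluation at HR 2
  z2 <- (stats::qnorm(0.975) + stats::qnorm(0.8))^2
  expect_equal(schoenfeld_sample_size(2, 0.05, 0.8, 1)$n_per_group,
               ceiling(4 * z2 / log(2)^2 / 2))
  expect_error(schoenfeld_sample_size(1), "infinite")
  expect_error(schoenfeld_sample_size(-2), "> 0")
})
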