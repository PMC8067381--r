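fixed_yes <- budget_scenario("fixed", "yes")
fixed_no <- budget_scenario("fixed", "no")
var_yes <- budget_scenario("variable", "yes")
var_no <- budget_scenario("variable", "no")

random_inputs <- function() {
  economic_inputs(
    days_gain = stats::runif(1, 0, 10),
    daily_yield_l = stats::runif(1, 10, 40),
    milk_price_gbp_per_l = stats::runif(1, 0.1, 0.5),
    feed_cost_gbp_per_l = stats::runif(1, 0, 0.2),
    barren_reduction = stats::runif(1, 0, 0.2),
    heifer_cost_gbp = stats::runif(1, 800, 2500),
    cull_value_gbp = stats::runif(1, 300, 900),
    treatment_extra_cost_gbp = stats::runif(1, 0, 40),
    ai_cost_gbp = stats::runif(1, 5, 40),
    services_per_conception_pgod = stats::runif(1, 1, 3),
    services_per_conception_moft = stats::runif(1, 1, 3),
    conc_first42_pgod = stats::runif(1, 0.3, 0.8),
    conc_first42_moft = stats::runif(1, 0.3, 0.8),
    conc_second42_pgod = stats::runif(1, 0, 0.15),
    conc_second42_moft = stats::runif(1, 0, 0.15),
    calf_value_dairy_male = stats::runif(1, 20, 150),
    calf_value_dairy_female = stats::runif(1, 50, 300),
    calf_value_beefx_male = stats::runif(1, 100, 300),
    calf_value_beefx_female = stats::runif(1, 80, 250),
    male_fraction = stats::runif(1, 0.4, 0.6)
  )
}

test_that("milk income is realized only under a fixed dry-off date", {
  inp <- economic_inputs()
  expect_equal(milk_income(inp, fixed_yes), 4 * 24 * 0.28)  # 26.88
  expect_equal(milk_income(inp, var_yes), 0)
  expect_equal(milk_income(economic_inputs(days_gain = 0), fixed_yes), 0)
})

test_that("calf income values the breed-mix difference", {
  # identical mixes are worth nothing under either normalization
  eq <- economic_inputs(conc_first42_moft = 0.70, conc_second42_moft = 0.10)
  expect_equal(calf_income_difference(eq, fixed_yes), 0)
  expect_equal(calf_income_difference(eq, fixed_yes, "raw"), 0)

  # per-treated ("raw") difference with sex-flattened calf values
  flat <- economic_inputs(
    calf_value_dairy_male = 110, calf_value_dairy_female = 110,
    calf_value_beefx_male = 165, calf_value_beefx_female = 165
  )
  expect_equal(calf_income_difference(flat, fixed_yes, "raw"),
               (0.77 * 110 + 0.09 * 165) - (0.70 * 110 + 0.10 * 165))

  # share normalization: sign follows (beef - dairy) value times the
  # beef-share difference, identical across barren settings
  inp <- economic_inputs()
  expect_equal(calf_income_difference(inp, fixed_yes),
               calf_income_difference(inp, fixed_no))
  share_diff <- 0.09 / 0.86 - 0.10 / 0.80
  v_dairy <- 0.52 * 45 + 0.48 * 143
  v_beef <- 0.52 * 200 + 0.48 * 163
  expect_equal(calf_income_difference(inp, fixed_yes),
               share_diff * (v_beef - v_dairy))

  # a MOFT mix shifted entirely to beef at equal totals gains iff
  # beef calves outvalue dairy calves
  all_beef <- economic_inputs(conc_first42_moft = 0,
                              conc_second42_moft = 0.80)
  expect_gt(calf_income_difference(all_beef, fixed_no, "raw"), 0)
  cheap_beef <- economic_inputs(
    conc_first42_moft = 0, conc_second42_moft = 0.80,
    calf_value_beefx_male = 10, calf_value_beefx_female = 10
  )
  expect_lt(calf_income_difference(cheap_beef, fixed_no, "raw"), 0)

  # explicit share override wins over the windows
  shifted <- economic_inputs(beef_share_shift = -0.03)
  expect_equal(calf_income_difference(shifted, var_no),
               -0.03 * (v_beef - v_dairy))
})

test_that("saving and cost components are simple products", {
  inp20 <- economic_inputs(ai_cost_gbp = 20)
  expect_equal(insemination_cost_saving(inp20), 0.07 * 20)  # 1.40
  eq_spc <- economic_inputs(services_per_conception_moft = 1.72)
  expect_equal(insemination_cost_saving(eq_spc), 0)
  expect_equal(insemination_cost_saving(economic_inputs(ai_cost_gbp = 0)), 0)

  inp <- economic_inputs()
  expect_equal(replacement_cost_saving(inp, fixed_yes),
               0.06 * (1495 - 631))  # 51.84
  expect_equal(replacement_cost_saving(inp, fixed_no), 0)
  expect_equal(
    replacement_cost_saving(economic_inputs(barren_reduction = 0),
                            fixed_yes), 0)

  feed9 <- economic_inputs(feed_cost_gbp_per_l = 0.09)
  expect_equal(extra_feed_cost(feed9), 4 * 24 * 0.09)  # 8.64
  expect_equal(extra_feed_cost(economic_inputs(days_gain = 0)), 0)

  expect_equal(extra_treatment_cost(inp), 18)
  expect_equal(
    extra_treatment_cost(economic_inputs(treatment_extra_cost_gbp = 24)),
    24)
})

test_that("the ledger identity holds for arbitrary inputs", {
  set.seed(21)
  for (i in 1:40) {
    inp <- random_inputs()
    for (sc in standard_scenarios()) {
      b <- net_benefit(inp, sc)
      expect_equal(
        b$net_benefit,
        b$milk_income + b$calf_income + b$ai_saving +
          b$replacement_saving - b$treatment_cost - b$feed_cost -
          b$returns_foregone,
        tolerance = 1e-9
      )
      expect_equal(b$returns_foregone, 0)
    }
  }
})

test_that("fixed-minus-variable difference is exactly the gross milk term", {
  set.seed(22)
  for (i in 1:25) {
    inp <- random_inputs()
    for (b in c("yes", "no")) {
      d <- net_benefit(inp, budget_scenario("fixed", b))$net_benefit -
        net_benefit(inp, budget_scenario("variable", b))$net_benefit
      expect_equal(d, inp$days_gain * inp$daily_yield_l *
                     inp$milk_price_gbp_per_l, tolerance = 1e-9)
    }
  }
  expect_equal(
    net_benefit(economic_inputs(), fixed_yes)$net_benefit -
      net_benefit(economic_inputs(), var_yes)$net_benefit,
    26.88, tolerance = 1e-9)
})

test_that("reference inputs reproduce the scenario net benefits", {
  expect_equal(round(net_benefit(economic_inputs(),
                                 fixed_yes)$net_benefit, 2), 53.42)
  expect_equal(round(net_benefit(economic_inputs(),
                                 var_yes)$net_benefit, 2), 26.54)
  # stripped-down budget: only the treatment cost survives
  zero <- economic_inputs(
    days_gain = 0, barren_reduction = 0,
    services_per_conception_moft = 1.72,
    conc_first42_moft = 0.70, conc_second42_moft = 0.10,
    treatment_extra_cost_gbp = 18
  )
  expect_equal(net_benefit(zero, fixed_yes)$net_benefit, -18)
})

test_that("net benefit is affine in each input and monotone where expected", {
  base <- economic_inputs()
  fields <- c("days_gain", "daily_yield_l", "milk_price_gbp_per_l",
              "feed_cost_gbp_per_l", "barren_reduction", "heifer_cost_gbp",
              "cull_value_gbp", "treatment_extra_cost_gbp", "ai_cost_gbp")
  for (f in fields) {
    x <- unlist(base[f]) * c(0.5, 1, 1.5)
    nb <- vapply(x, function(v) {
      inp <- base
      inp[[f]] <- v
      net_benefit(inp, fixed_yes)$net_benefit
    }, numeric(1))
    # three-point collinearity
    expect_equal(nb[2] - nb[1], nb[3] - nb[2], tolerance = 1e-9)
  }
  nb_heifer <- vapply(c(1000, 1495, 2000), function(v) {
    net_benefit(economic_inputs(heifer_cost_gbp = v),
                fixed_yes)$net_benefit
  }, numeric(1))
  expect_true(all(diff(nb_heifer) > 0))
  nb_treat <- vapply(c(12, 18, 24), function(v) {
    net_benefit(economic_inputs(treatment_extra_cost_gbp = v),
                fixed_yes)$net_benefit
  }, numeric(1))
  expect_true(all(diff(nb_treat) < 0))
})

test_that("input validation rejects impossible economics", {
  expect_error(economic_inputs(milk_price_gbp_per_l = -1), ">= 0")
  expect_error(economic_inputs(barren_reduction = 1.4), "\\[0, 1\\]")
  expect_error(economic_inputs(conc_first42_moft = 0.95,
                               conc_second42_moft = 0.10), "at most 1")
  expect_error(economic_inputs(services_per_conception_moft = 0.8),
               ">= 1")
  expect_error(budget_scenario("sometimes"), "arg")
})
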