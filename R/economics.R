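#' Economic inputs of the partial budget
#'
#' All monetary and biological parameters needed to value a switch from the
#' single-prostaglandin treatment (PGOD) to the modified Ovsynch protocol
#' (MOFT), per cow treated, over one breeding season. Monetary values are
#' pounds sterling at 2020 price levels.
#'
#' The default trade values that are not herd measurements (AI cost per
#' insemination, feed cost per liter, the four calf values) are a synthetic
#' reconstruction: realistic UK market figures calibrated so that the
#' expected-value budget is internally consistent with the package's
#' reference scenario results (see the methods vignette for the
#' derivation). Override them with farm-specific figures for real use.
#'
#' @param days_gain Difference in mean calving-conception interval between
#'   the groups (days; extra lactating days under a fixed dry-off date).
#' @param daily_yield_l Mean daily milk yield (liters/day).
#' @param milk_price_gbp_per_l Milk price (GBP/liter).
#' @param feed_cost_gbp_per_l Feed cost per liter of milk produced
#'   (GBP/liter).
#' @param barren_reduction Reduction in barren rate attributable to MOFT
#'   (proportion of cows).
#' @param heifer_cost_gbp Cost of rearing a replacement heifer (GBP).
#' @param cull_value_gbp Market value of a cull cow (GBP).
#' @param treatment_extra_cost_gbp Extra cost of the MOFT protocol over the
#'   prostaglandin protocol (GBP/cow treated).
#' @param ai_cost_gbp Cost per insemination (GBP).
#' @param services_per_conception_pgod,services_per_conception_moft Mean
#'   inseminations per conception.
#' @param conc_first42_pgod,conc_first42_moft Proportion conceiving in the
#'   first 42 days (dairy-sired conceptions).
#' @param conc_second42_pgod,conc_second42_moft Proportion conceiving in
#'   the second 42 days (beef-sired conceptions).
#' @param calf_value_dairy_male,calf_value_dairy_female GBP value of
#'   dairy-sired calves under three weeks.
#' @param calf_value_beefx_male,calf_value_beefx_female GBP value of
#'   beef-cross calves under three weeks.
#' @param male_fraction Proportion of calves born male.
#' @param beef_share_shift Optional override of the beef-calf share
#'   difference (MOFT minus PGOD, per calving); `NA` derives it from the
#'   conception-window proportions. Used by the sensitivity and Monte-Carlo
#'   layers, where this share difference is an uncertain input in its own
#'   right.
#' @return An object of class `economic_inputs`.
#' @export
economic_inputs <- function(days_gain = 4,
                            daily_yield_l = 24,
                            milk_price_gbp_per_l = 0.28,
                            feed_cost_gbp_per_l = 0.07,
                            barren_reduction = 0.06,
                            heifer_cost_gbp = 1495,
                            cull_value_gbp = 631,
                            treatment_extra_cost_gbp = 18,
                            ai_cost_gbp = 18,
                            services_per_conception_pgod = 1.72,
                            services_per_conception_moft = 1.65,
                            conc_first42_pgod = 0.70,
                            conc_first42_moft = 0.77,
                            conc_second42_pgod = 0.10,
                            conc_second42_moft = 0.09,
                            calf_value_dairy_male = 45,
                            calf_value_dairy_female = 143,
                            calf_value_beefx_male = 200,
                            calf_value_beefx_female = 163,
                            male_fraction = 0.52,
                            beef_share_shift = NA_real_) {
  x <- list(
    days_gain = days_gain, daily_yield_l = daily_yield_l,
    milk_price_gbp_per_l = milk_price_gbp_per_l,
    feed_cost_gbp_per_l = feed_cost_gbp_per_l,
    barren_reduction = barren_reduction,
    heifer_cost_gbp = heifer_cost_gbp, cull_value_gbp = cull_value_gbp,
    treatment_extra_cost_gbp = treatment_extra_cost_gbp,
    ai_cost_gbp = ai_cost_gbp,
    services_per_conception_pgod = services_per_conception_pgod,
    services_per_conception_moft = services_per_conception_moft,
    conc_first42_pgod = conc_first42_pgod,
    conc_first42_moft = conc_first42_moft,
    conc_second42_pgod = conc_second42_pgod,
    conc_second42_moft = conc_second42_moft,
    calf_value_dairy_male = calf_value_dairy_male,
    calf_value_dairy_female = calf_value_dairy_female,
    calf_value_beefx_male = calf_value_beefx_male,
    calf_value_beefx_female = calf_value_beefx_female,
    male_fraction = male_fraction,
    beef_share_shift = beef_share_shift
  )
  monetary <- c("daily_yield_l", "milk_price_gbp_per_l",
                "feed_cost_gbp_per_l", "heifer_cost_gbp", "cull_value_gbp",
                "treatment_extra_cost_gbp", "ai_cost_gbp",
                "calf_value_dairy_male", "calf_value_dairy_female",
                "calf_value_beefx_male", "calf_value_beefx_female")
  for (nm in monetary) {
    if (any(x[[nm]] < 0)) stop("`", nm, "` must be >= 0", call. = FALSE)
  }
  props <- c("barren_reduction", "conc_first42_pgod", "conc_first42_moft",
             "conc_second42_pgod", "conc_second42_moft", "male_fraction")
  for (nm in props) {
    if (any(x[[nm]] < 0 | x[[nm]] > 1)) {
      stop("`", nm, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (any(x$conc_first42_pgod + x$conc_second42_pgod > 1 + 1e-9) ||
      any(x$conc_first42_moft + x$conc_second42_moft > 1 + 1e-9)) {
    stop("conception-window proportions must sum to at most 1 per group",
         call. = FALSE)
  }
  if (any(x$services_per_conception_pgod < 1) ||
      any(x$services_per_conception_moft < 1)) {
    stop("services per conception must be >= 1", call. = FALSE)
  }
  structure(x, class = "economic_inputs")
}

#' Dry-off by barren-rate scenario
#'
#' The four management scenarios of the budget: herd dry-off policy
#' (`fixed` calendar date vs `variable`, tied to the next calving) crossed
#' with whether MOFT is credited with a barren-rate improvement.
#'
#' @param dry_off `"fixed"` or `"variable"`.
#' @param barren_improvement `"yes"` or `"no"`.
#' @return An object of class `budget_scenario`.
#' @export
#' @examples
#' budget_scenario("fixed", "yes")
budget_scenario <- function(dry_off = c("fixed", "variable"),
                            barren_improvement = c("yes", "no")) {
  dry_off <- match.arg(dry_off)
  barren_improvement <- match.arg(barren_improvement)
  structure(list(dry_off = dry_off,
                 barren_improvement = barren_improvement),
            class = "budget_scenario")
}

#' The four standard budget scenarios
#'
#' Letters follow the panel convention: (a) fixed dry-off, reduced barren
#' rate; (b) fixed dry-off, no barren improvement; (c) variable dry-off,
#' reduced barren rate; (d) variable dry-off, no barren improvement.
#'
#' @return Named list of [budget_scenario()] objects `a`-`d`.
#' @export
standard_scenarios <- function() {
  list(
    a = budget_scenario("fixed", "yes"),
    b = budget_scenario("fixed", "no"),
    c = budget_scenario("variable", "yes"),
    d = budget_scenario("variable", "no")
  )
}

sex_weighted_calf_values <- function(inputs) {
  m <- inputs$male_fraction
  list(
    dairy = m * inputs$calf_value_dairy_male +
      (1 - m) * inputs$calf_value_dairy_female,
    beef = m * inputs$calf_value_beefx_male +
      (1 - m) * inputs$calf_value_beefx_female
  )
}

#' Partial-budget components
#'
#' Each component values one element of the MOFT-vs-PGOD comparison, per
#' cow treated:
#' * `milk_income`: extra milk from `days_gain` additional lactating days;
#'   only herds drying off on a fixed calendar date realize it — under a
#'   variable dry-off date the lactation shifts rather than lengthens, so
#'   the term is zero.
#' * `calf_income_difference`: value of the difference in the calf crop.
#'   With the default `normalization = "share"` each group is normalized to
#'   100 cows calving, so only the dairy/beef breed mix (early vs late
#'   conceptions, sex-weighted calf values) is monetized and the term is
#'   the same under both barren settings. `normalization = "raw"` values
#'   the unnormalized per-100-treated difference instead (and, under
#'   `barren_improvement = "no"`, rescales the MOFT totals to the PGOD
#'   total while keeping the MOFT breed mix).
#' * `insemination_cost_saving`: fewer services per conception times the
#'   cost per insemination.
#' * `replacement_cost_saving`: barren-rate reduction times the rearing
#'   cost of a replacement heifer net of cull value; omitted when no barren
#'   improvement is credited.
#' * `extra_feed_cost`: feed for the additional lactating days, charged
#'   under both dry-off policies (the earlier-calving cow is fed a
#'   lactating ration for longer either way).
#' * `extra_treatment_cost`: protocol cost difference.
#'
#' @param inputs An [economic_inputs()].
#' @param scenario A [budget_scenario()].
#' @param normalization Calf-crop normalization, `"share"` (per cow
#'   calving) or `"raw"` (per cow treated).
#' @return GBP per cow treated (vectorized over vector-valued fields).
#' @name budget_components
NULL

#' @rdname budget_components
#' @export
milk_income <- function(inputs, scenario) {
  if (scenario$dry_off != "fixed") {
    return(0 * inputs$days_gain)
  }
  inputs$days_gain * inputs$daily_yield_l * inputs$milk_price_gbp_per_l
}

#' @rdname budget_components
#' @export
calf_income_difference <- function(inputs, scenario,
                                   normalization = c("share", "raw")) {
  normalization <- match.arg(normalization)
  v <- sex_weighted_calf_values(inputs)
  cf_p <- inputs$conc_first42_pgod
  cs_p <- inputs$conc_second42_pgod
  cf_m <- inputs$conc_first42_moft
  cs_m <- inputs$conc_second42_moft
  if (normalization == "share") {
    share_diff <- ifelse(is.na(inputs$beef_share_shift),
                         cs_m / (cf_m + cs_m) - cs_p / (cf_p + cs_p),
                         inputs$beef_share_shift)
    return(share_diff * (v$beef - v$dairy))
  }
  if (scenario$barren_improvement == "no") {
    scale <- (cf_p + cs_p) / (cf_m + cs_m)
    cf_m <- cf_m * scale
    cs_m <- cs_m * scale
  }
  if (any(c(cf_p, cs_p, cf_m, cs_m) < 0)) {
    stop("implied calf counts are negative", call. = FALSE)
  }
  (cf_m * v$dairy + cs_m * v$beef) - (cf_p * v$dairy + cs_p * v$beef)
}

#' @rdname budget_components
#' @export
insemination_cost_saving <- function(inputs) {
  (inputs$services_per_conception_pgod -
     inputs$services_per_conception_moft) * inputs$ai_cost_gbp
}

#' @rdname budget_components
#' @export
replacement_cost_saving <- function(inputs, scenario) {
  if (scenario$barren_improvement != "yes") {
    return(0 * inputs$barren_reduction)
  }
  inputs$barren_reduction * (inputs$heifer_cost_gbp - inputs$cull_value_gbp)
}

#' @rdname budget_components
#' @export
extra_feed_cost <- function(inputs) {
  inputs$days_gain * inputs$daily_yield_l * inputs$feed_cost_gbp_per_l
}

#' @rdname budget_components
#' @export
extra_treatment_cost <- function(inputs) {
  inputs$treatment_extra_cost_gbp
}

#' Net benefit of the MOFT protocol over PGOD
#'
#' Assembles the partial budget (additional income + reduced costs −
#' returns foregone − extra costs) for one scenario. No returns foregone
#' are considered in this model.
#'
#' @inheritParams budget_components
#' @return An object of class `budget_result`: list of the component
#'   ledger (`milk_income`, `calf_income`, `ai_saving`,
#'   `replacement_saving`, `treatment_cost`, `feed_cost`,
#'   `returns_foregone`) and `net_benefit`, all GBP per cow treated.
#' @export
#' @examples
#' net_benefit(economic_inputs(), budget_scenario("fixed", "yes"))
net_benefit <- function(inputs, scenario,
                        normalization = c("share", "raw")) {
  normalization <- match.arg(normalization)
  comp <- list(
    milk_income = milk_income(inputs, scenario),
    calf_income = calf_income_difference(inputs, scenario, normalization),
    ai_saving = insemination_cost_saving(inputs),
    replacement_saving = replacement_cost_saving(inputs, scenario),
    treatment_cost = extra_treatment_cost(inputs),
    feed_cost = extra_feed_cost(inputs),
    returns_foregone = 0
  )
  comp$net_benefit <- comp$milk_income + comp$calf_income + comp$ai_saving +
    comp$replacement_saving - comp$treatment_cost - comp$feed_cost -
    comp$returns_foregone
  comp$scenario <- scenario
  structure(comp, class = "budget_result")
}

#' @export
print.budget_result <- function(x, ...) {
  cat("Partial budget, MOFT vs PGOD (", x$scenario$dry_off, " dry-off, ",
      "barren improvement: ", x$scenario$barren_improvement, ")\n",
      sep = "")
  rows <- c("milk_income", "calf_income", "ai_saving", "replacement_saving",
            "treatment_cost", "feed_cost", "returns_foregone")
  sign <- c(1, 1, 1, 1, -1, -1, -1)
  for (i in seq_along(rows)) {
    cat(sprintf("  %-20s %10s\n", rows[i],
                format_gbp(sign[i] * x[[rows[i]]][1])))
  }
  cat(sprintf("  %-20s %10s per cow treated\n", "net benefit",
              format_gbp(x$net_benefit[1])))
  invisible(x)
}

#' Format pounds sterling with bracketed negatives
#'
#' Two-decimal display; negative amounts are wrapped in brackets, the axis
#' convention used on tornado charts.
#'
#' @param x Numeric GBP values.
#' @return Character vector.
#' @export
#' @examples
#' format_gbp(c(53.424, -24.8))
format_gbp <- function(x) {
  x[x == 0] <- 0  # normalize negative zero
  ifelse(x < 0, sprintf("(%.2f)", -x), sprintf("%.2f", x))
}
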