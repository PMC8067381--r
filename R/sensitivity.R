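#' One-way parameter ranges
#'
#' A low/expected/high triple for a single economic input, the unit of the
#' tornado sensitivity analysis.
#'
#' @param name Field name of an [economic_inputs()] component.
#' @param low,expected,high Values in the field's own units,
#'   `low <= expected <= high`.
#' @return A one-row tibble of class `param_range`.
#' @export
param_range <- function(name, low, expected, high) {
  if (!(low <= expected && expected <= high)) {
    stop("`", name, "`: need low <= expected <= high", call. = FALSE)
  }
  check_input_field(name)
  structure(tibble::tibble(name = name, low = low, expected = expected,
                           high = high),
            class = c("param_range", "tbl_df", "tbl", "data.frame"))
}

check_input_field <- function(name) {
  valid <- names(economic_inputs())
  bad <- setdiff(name, valid)
  if (length(bad) > 0) {
    stop("unknown economic input field(s): ", paste(bad, collapse = ", "),
         "\nvalid names: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

set_input_field <- function(inputs, name, value) {
  check_input_field(name)
  inputs[[name]] <- value
  inputs
}

#' Default uncertainty ranges for the economic inputs
#'
#' Low/expected/high triples for the key inputs: measured herd quantities
#' carry trial-scale confidence ranges, market prices a symmetric spread,
#' and the reconstructed trade inputs (lactation-length gain, feed cost)
#' carry the calibrated asymmetric ranges discussed in the methods
#' vignette. The same triples serve as min/mode/max triangular
#' distributions in the Monte-Carlo layer.
#'
#' @return Tibble with columns `name`, `low`, `expected`, `high`.
#' @export
default_economic_ranges <- function() {
  tibble::tibble(
    name = c("barren_reduction", "heifer_cost_gbp", "daily_yield_l",
             "beef_share_shift", "milk_price_gbp_per_l", "cull_value_gbp",
             "treatment_extra_cost_gbp", "days_gain",
             "feed_cost_gbp_per_l"),
    low = c(0.02, 1136, 15, -0.09, 0.20, 534, 12, 2, 0.0222),
    expected = c(0.06, 1495, 24, -0.03, 0.28, 631, 18, 4, 0.07),
    high = c(0.10, 1854, 33, 0.03, 0.36, 728, 24, 7.8, 0.07)
  )
}

#' Parameter set applicable to a scenario
#'
#' Scenarios without a barren-rate improvement drop the barren-linked
#' inputs (reduction, heifer cost, cull value); variable dry-off scenarios
#' drop the milk-revenue inputs (lactation-length gain, daily yield, milk
#' price) whose income term is absent there.
#'
#' @param scenario A [budget_scenario()].
#' @param ranges Full range table, default [default_economic_ranges()].
#' @return The filtered range tibble.
#' @export
scenario_ranges <- function(scenario, ranges = default_economic_ranges()) {
  drop <- character(0)
  if (scenario$barren_improvement == "no") {
    drop <- c(drop, "barren_reduction", "heifer_cost_gbp", "cull_value_gbp")
  }
  if (scenario$dry_off == "variable") {
    drop <- c(drop, "days_gain", "daily_yield_l", "milk_price_gbp_per_l")
  }
  ranges[!ranges$name %in% drop, , drop = FALSE]
}

#' One-way (tornado) sensitivity sweep
#'
#' Evaluates the net benefit with each input at its low and high value in
#' turn, all other inputs held at their expected values, and ranks the
#' inputs by swing (absolute output range).
#'
#' @param ranges Range tibble (`name`, `low`, `expected`, `high`); e.g.
#'   [scenario_ranges()].
#' @param inputs Base [economic_inputs()] holding the expected values.
#' @param scenario A [budget_scenario()].
#' @param nb_fun Optional replacement output function taking an
#'   `economic_inputs` and returning a number; defaults to the scenario's
#'   [net_benefit()]. Useful for testing the sweep machinery against toy
#'   models.
#' @param normalization Passed to [net_benefit()].
#' @return Tibble of class `tornado_entries`, one row per input, sorted by
#'   descending swing: `name`, `low`, `expected`, `high`, `nb_low`,
#'   `nb_expected`, `nb_high`, `swing`, plus `contribution_pct` from
#'   [contribution_to_variation()].
#' @export
one_way_sweep <- function(ranges, inputs = economic_inputs(),
                          scenario = budget_scenario(), nb_fun = NULL,
                          normalization = "share") {
  check_input_field(ranges$name)
  if (is.null(nb_fun)) {
    nb_fun <- function(x) net_benefit(x, scenario, normalization)$net_benefit
  }
  nb_expected <- nb_fun(inputs)
  nb_low <- nb_high <- numeric(nrow(ranges))
  for (i in seq_len(nrow(ranges))) {
    nb_low[i] <- nb_fun(set_input_field(inputs, ranges$name[i],
                                        ranges$low[i]))
    nb_high[i] <- nb_fun(set_input_field(inputs, ranges$name[i],
                                         ranges$high[i]))
  }
  out <- tibble::tibble(
    name = ranges$name, low = ranges$low, expected = ranges$expected,
    high = ranges$high, nb_low = nb_low, nb_expected = nb_expected,
    nb_high = nb_high, swing = abs(nb_high - nb_low)
  )
  out <- out[order(-out$swing), , drop = FALSE]
  out <- contribution_to_variation(out)
  class(out) <- c("tornado_entries", class(out))
  out
}

#' Share of total output variation per input
#'
#' Attributes to each input a percentage of the total variation, by
#' default the squared-swing share
#' \eqn{100 \, s_i^2 / \sum_j s_j^2} (the convention of spreadsheet
#' tornado add-ins); `method = "absolute"` uses plain swing shares.
#' All-zero swings yield zero contributions with a warning.
#'
#' @param entries Tornado entry tibble with a `swing` column.
#' @param method `"squared"` or `"absolute"`.
#' @return `entries` with a `contribution_pct` column.
#' @export
contribution_to_variation <- function(entries,
                                      method = c("squared", "absolute")) {
  method <- match.arg(method)
  if (nrow(entries) == 0) {
    entries$contribution_pct <- numeric(0)
    return(entries)
  }
  w <- if (method == "squared") entries$swing^2 else entries$swing
  total <- sum(w)
  if (total == 0) {
    warning("all swings are zero; contributions undefined, set to 0")
    entries$contribution_pct <- rep(0, nrow(entries))
  } else {
    entries$contribution_pct <- 100 * w / total
  }
  entries
}

#' Tornado table for reporting
#'
#' Orders the entries by swing and adds display columns in the bar-interval
#' format of a tornado chart (net benefit at low/expected/high), with
#' negative amounts bracketed.
#'
#' @param entries A `tornado_entries` tibble from [one_way_sweep()].
#' @param scenario Optional [budget_scenario()] recorded as an attribute.
#' @return Tibble ordered by descending swing with `label_low`,
#'   `label_expected`, `label_high` display columns.
#' @export
tornado_report <- function(entries, scenario = NULL) {
  out <- entries[order(-entries$swing), , drop = FALSE]
  out$label_low <- format_gbp(out$nb_low)
  out$label_expected <- format_gbp(out$nb_expected)
  out$label_high <- format_gbp(out$nb_high)
  if (!is.null(scenario)) attr(out, "scenario") <- scenario
  out
}
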