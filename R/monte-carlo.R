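#' Triangular sampling parameter
#'
#' Minimum/mode/maximum specification of a triangular probability density
#' for one uncertain economic input.
#'
#' @param name Field name of an [economic_inputs()] component.
#' @param minimum,mode,maximum Distribution parameters,
#'   `minimum <= mode <= maximum`.
#' @return A one-row tibble of class `triangular_param`.
#' @export
triangular_param <- function(name, minimum, mode, maximum) {
  if (!(minimum <= mode && mode <= maximum)) {
    stop("`", name, "`: need minimum <= mode <= maximum", call. = FALSE)
  }
  check_input_field(name)
  structure(tibble::tibble(name = name, minimum = minimum, mode = mode,
                           maximum = maximum),
            class = c("triangular_param", "tbl_df", "tbl", "data.frame"))
}

#' Convert a range table to triangular parameters
#'
#' Reads the low/expected/high triples as minimum/mode/maximum, the
#' convention under which the sensitivity ranges double as Monte-Carlo
#' distributions.
#'
#' @param ranges Tibble with `name`, `low`, `expected`, `high`.
#' @return Tibble with `name`, `minimum`, `mode`, `maximum`.
#' @export
ranges_to_triangular <- function(ranges) {
  tibble::tibble(name = ranges$name, minimum = ranges$low,
                 mode = ranges$expected, maximum = ranges$high)
}

#' Inverse-CDF sampling from a triangular distribution
#'
#' Maps uniform variates through the analytic inverse CDF: for
#' \eqn{u \le (m-a)/(b-a)}, \eqn{a + \sqrt{u (b-a)(m-a)}}; otherwise
#' \eqn{b - \sqrt{(1-u)(b-a)(b-m)}} (minimum \eqn{a}, mode \eqn{m},
#' maximum \eqn{b}). A degenerate parameter (`minimum == maximum`) returns
#' the constant.
#'
#' @param param A [triangular_param()] (or any list with `minimum`,
#'   `mode`, `maximum`).
#' @param u Uniform variates in `[0, 1]`.
#' @return Sampled values, same length as `u`.
#' @export
#' @examples
#' sample_triangular(triangular_param("days_gain", 0, 0, 1), 0.5)
sample_triangular <- function(param, u) {
  if (any(u < 0 | u > 1)) {
    stop("`u` must lie in [0, 1]", call. = FALSE)
  }
  a <- param$minimum
  m <- param$mode
  b <- param$maximum
  if (b == a) return(rep(a, length(u)))
  f <- (m - a) / (b - a)
  ifelse(u <= f,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

#' Summarize Monte-Carlo draws
#'
#' Mean, sample standard deviation (n − 1 denominator), quartiles by
#' linear interpolation of order statistics, and range.
#'
#' @param draws Numeric vector of net-benefit draws (GBP).
#' @return An object of class `mc_summary`: list with `n_iter`, `mean`,
#'   `sd`, `q1`, `median`, `q3`, `minimum`, `maximum`.
#' @export
#' @examples
#' summarize_draws(c(1, 2, 3, 4))  # q1 1.75, q3 3.25
summarize_draws <- function(draws) {
  if (length(draws) == 0) stop("empty draw vector", call. = FALSE)
  qs <- stats::quantile(draws, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(
    list(n_iter = length(draws), mean = mean(draws),
         sd = if (length(draws) > 1) stats::sd(draws) else 0,
         q1 = qs[1], median = qs[2], q3 = qs[3],
         minimum = min(draws), maximum = max(draws)),
    class = "mc_summary"
  )
}

#' @export
print.mc_summary <- function(x, ...) {
  cat("Monte-Carlo net benefit (", x$n_iter, " iterations)\n", sep = "")
  cat(sprintf("  mean %s  sd %s  q1 %s  median %s  q3 %s  range [%s, %s]\n",
              format_gbp(x$mean), format_gbp(x$sd), format_gbp(x$q1),
              format_gbp(x$median), format_gbp(x$q3),
              format_gbp(x$minimum), format_gbp(x$maximum)))
  invisible(x)
}

#' Monte-Carlo propagation of input uncertainty through the budget
#'
#' Per iteration, draws every listed parameter independently from its
#' triangular distribution, overwrites the base inputs, and evaluates the
#' scenario's net benefit. Draws are consumed in the declared parameter
#' order from a single seeded stream, so identical
#' `(params, scenario, n_iter, seed)` give bit-identical results.
#'
#' @param params Triangular parameter tibble (`name`, `minimum`, `mode`,
#'   `maximum`), e.g. `ranges_to_triangular(scenario_ranges(scenario))`.
#' @param base_inputs Base [economic_inputs()]; fields not listed in
#'   `params` stay at their base values.
#' @param scenario A [budget_scenario()].
#' @param n_iter Number of iterations (default 10,000).
#' @param seed Integer seed.
#' @param normalization Passed to [net_benefit()].
#' @param keep_draws Attach the raw draw vector to the summary.
#' @return An `mc_summary`; with `keep_draws = TRUE` the net-benefit draws
#'   are included as `$draws` and the sampled input matrix as
#'   `$input_draws`.
#' @export
run_monte_carlo <- function(params, base_inputs = economic_inputs(),
                            scenario = budget_scenario(), n_iter = 10000,
                            seed = 1L, normalization = "share",
                            keep_draws = FALSE) {
  if (n_iter < 1) stop("`n_iter` must be >= 1", call. = FALSE)
  check_input_field(params$name)
  set.seed(as.integer(seed))
  k <- nrow(params)
  u <- matrix(stats::runif(n_iter * k), nrow = n_iter, ncol = k,
              byrow = TRUE)  # row = iteration, column order = param order
  inputs <- base_inputs
  draw_mat <- matrix(NA_real_, nrow = n_iter, ncol = k,
                     dimnames = list(NULL, params$name))
  for (j in seq_len(k)) {
    draw_mat[, j] <- sample_triangular(params[j, , drop = FALSE], u[, j])
    inputs[[params$name[j]]] <- draw_mat[, j]
  }
  nb <- net_benefit(inputs, scenario, normalization)$net_benefit
  nb <- rep_len(nb, n_iter)  # guard: all-degenerate params give length 1
  out <- summarize_draws(nb)
  out$scenario <- scenario
  if (keep_draws) {
    out$draws <- nb
    out$input_draws <- draw_mat
  }
  out
}

#' Histogram export of Monte-Carlo draws
#'
#' Bin edges and counts for plotting the net-benefit distribution.
#'
#' @param draws Numeric draw vector (e.g. `$draws` of a `run_monte_carlo`
#'   call with `keep_draws = TRUE`).
#' @param breaks Passed to [graphics::hist()] breaks argument.
#' @return Tibble with `bin_left`, `bin_right`, `count`.
#' @export
mc_histogram <- function(draws, breaks = 30) {
  h <- graphics::hist(draws, breaks = breaks, plot = FALSE)
  tibble::tibble(bin_left = utils::head(h$breaks, -1),
                 bin_right = utils::tail(h$breaks, -1),
                 count = h$counts)
}
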