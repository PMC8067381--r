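COW_CSV_COLUMNS <- c("cow_id", "freeze_brand", "farm", "treatment",
                     "parity_class", "bcs_class", "cbsi_days",
                     "service_days", "conception_day", "censor_day")

#' Write cow records to CSV
#'
#' One row per cow; `service_days` are joined with semicolons; missing
#' values are written as the empty string; UTF-8 with header.
#'
#' @param records Cow-record tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cow_csv <- function(records, path) {
  flat <- data.frame(
    cow_id = records$cow_id,
    freeze_brand = records$freeze_brand,
    farm = records$farm,
    treatment = records$treatment,
    parity_class = records$parity_class,
    bcs_class = records$bcs_class,
    cbsi_days = records$cbsi_days,
    service_days = vapply(records$service_days, paste,
                          character(1), collapse = ";"),
    conception_day = ifelse(is.na(records$conception_day), "",
                            as.character(records$conception_day)),
    censor_day = ifelse(is.na(records$censor_day), "",
                        as.character(records$censor_day)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(flat, path, row.names = FALSE, fileEncoding = "UTF-8",
                   na = "")
  invisible(path)
}

#' Read cow records from CSV
#'
#' Reads the dialect written by [write_cow_csv()], parses the
#' semicolon-separated service lists, and validates every row (ascending
#' services, conception/censor consistency); malformed rows are reported
#' with their file line number.
#'
#' @param path CSV file path.
#' @param follow_up_days Breeding-season length used for validation.
#' @param natural_service_start_day Optional per-farm bull start days for
#'   validating conceptions without a matching service day.
#' @return Cow-record tibble.
#' @export
read_cow_csv <- function(path, follow_up_days = 84,
                         natural_service_start_day = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8", na.strings = NULL)
  missing_cols <- setdiff(COW_CSV_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("cow CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_or_na <- function(s) {
    out <- suppressWarnings(as.numeric(s))
    out[s == ""] <- NA_real_
    out
  }
  n <- nrow(raw)
  records <- tibble::tibble(
    cow_id = raw$cow_id,
    freeze_brand = as.integer(raw$freeze_brand),
    farm = as.integer(raw$farm),
    treatment = raw$treatment,
    parity_class = raw$parity_class,
    bcs_class = raw$bcs_class,
    cbsi_days = as.integer(raw$cbsi_days),
    service_days = lapply(seq_len(n), function(i) {
      s <- raw$service_days[i]
      if (s == "") return(numeric(0))
      v <- suppressWarnings(as.numeric(strsplit(s, ";", fixed = TRUE)[[1]]))
      if (anyNA(v)) {
        stop("line ", i + 1, ": unparseable service_days \"", s, "\"",
             call. = FALSE)
      }
      v
    }),
    conception_day = num_or_na(raw$conception_day),
    censor_day = num_or_na(raw$censor_day)
  )
  for (i in seq_len(n)) {
    res <- tryCatch(
      validate_cow_records(records[i, , drop = FALSE], follow_up_days,
                           natural_service_start_day),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      stop("line ", i + 1, ": ", conditionMessage(res), call. = FALSE)
    }
  }
  records
}

#' Write a survival curve to CSV
#'
#' Columns `time`, `n_at_risk`, `n_events`, `survival`, `se`.
#'
#' @param curve A `survival_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(curve, path) {
  utils::write.csv(
    data.frame(time = curve$times, n_at_risk = curve$n_at_risk,
               n_events = curve$n_events, survival = curve$survival,
               se = curve$se),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Load an economic configuration file
#'
#' Reads a YAML (or JSON-compatible YAML) file whose top-level keys mirror
#' the [economic_inputs()] field names. Each entry is either a single
#' expected value or a `{low, expected, high}` block; blocks feed the
#' sensitivity ranges and (as min/mode/max) the Monte-Carlo triangulars.
#' Fields absent from the file fall back to the package defaults — with a
#' warning for the documented placeholder trade values, or an error in
#' strict mode.
#'
#' @param path Config file path.
#' @param strict Error (instead of warn) when a mandatory trade field
#'   (`ai_cost_gbp`, `feed_cost_gbp_per_l`, the four calf values) is
#'   absent.
#' @return List with `inputs` (an `economic_inputs` at expected values),
#'   `ranges` (tibble of the fields given as blocks) and `triangular`
#'   (the same as min/mode/max).
#' @export
load_economic_config <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  valid <- names(economic_inputs())
  bad <- setdiff(names(cfg), valid)
  if (length(bad) > 0) {
    stop("unknown economic input field(s) in config: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mandatory <- c("ai_cost_gbp", "feed_cost_gbp_per_l",
                 "calf_value_dairy_male", "calf_value_dairy_female",
                 "calf_value_beefx_male", "calf_value_beefx_female")
  absent <- setdiff(mandatory, names(cfg))
  if (length(absent) > 0) {
    msg <- paste("placeholder defaults used for:",
                 paste(absent, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  expected <- list()
  rng <- list(name = character(0), low = numeric(0), expected = numeric(0),
              high = numeric(0))
  for (nm in names(cfg)) {
    entry <- cfg[[nm]]
    if (is.list(entry)) {
      need <- c("low", "expected", "high")
      if (!all(need %in% names(entry))) {
        stop("field `", nm, "` must give low, expected and high",
             call. = FALSE)
      }
      if (!(entry$low <= entry$expected && entry$expected <= entry$high)) {
        stop("field `", nm, "`: need low <= expected <= high",
             call. = FALSE)
      }
      # beef_share_shift ranges feed the uncertainty layers only; the
      # deterministic budget derives the share from the conception windows
      if (nm != "beef_share_shift") expected[[nm]] <- entry$expected
      rng$name <- c(rng$name, nm)
      rng$low <- c(rng$low, entry$low)
      rng$expected <- c(rng$expected, entry$expected)
      rng$high <- c(rng$high, entry$high)
    } else {
      expected[[nm]] <- entry
    }
  }
  inputs <- do.call(economic_inputs, expected)
  ranges <- tibble::as_tibble(rng)
  list(inputs = inputs, ranges = ranges,
       triangular = ranges_to_triangular(ranges))
}

derive_budget_inputs <- function(summaries, curves, base_inputs) {
  tp <- function(curve, t) time_point_estimate(curve, t)$cumulative_pregnancy
  p42_p <- tp(curves$PGOD, 42); p84_p <- tp(curves$PGOD, 84)
  p42_m <- tp(curves$MOFT, 42); p84_m <- tp(curves$MOFT, 84)
  inputs <- base_inputs
  inputs$days_gain <- summaries$PGOD$mean_calving_conception -
    summaries$MOFT$mean_calving_conception
  inputs$barren_reduction <- summaries$PGOD$barren_proportion -
    summaries$MOFT$barren_proportion
  inputs$conc_first42_pgod <- p42_p
  inputs$conc_second42_pgod <- p84_p - p42_p
  inputs$conc_first42_moft <- p42_m
  inputs$conc_second42_moft <- p84_m - p42_m
  inputs$services_per_conception_pgod <- summaries$PGOD$services_per_conception
  inputs$services_per_conception_moft <- summaries$MOFT$services_per_conception
  inputs
}

#' End-to-end analysis pipeline
#'
#' Simulates a cohort, computes the per-group survival curves and
#' fertility summaries, derives the herd-measured budget inputs from them
#' (lactation gain, barren-rate reduction, conception-window proportions,
#' services per conception), and runs the deterministic budget, tornado
#' sensitivity and Monte-Carlo simulation for the requested scenarios.
#' Optionally writes all outputs plus a manifest sufficient to re-run the
#' analysis.
#'
#' @param config A [herd_config()].
#' @param dynamics A [breeding_dynamics()].
#' @param econ Economic configuration: an [economic_inputs()] object, a
#'   config file path for [load_economic_config()], or `NULL` for package
#'   defaults.
#' @param ranges Uncertainty ranges; defaults to
#'   [default_economic_ranges()] (or the config file's blocks).
#' @param scenarios Character subset of `c("a", "b", "c", "d")`.
#' @param n_iter Monte-Carlo iterations per scenario.
#' @param seed Master seed: herd generation uses `seed`, the Monte-Carlo
#'   of scenarios a-d uses `seed + 1 ... seed + 4`.
#' @param out_dir Optional output directory for CSVs and the manifest.
#' @return List with `herd`, `summaries`, `curves`, `log_rank`,
#'   `derived_inputs`, `budget`, `tornado`, `monte_carlo` (per scenario),
#'   and `manifest`.
#' @export
run_pipeline <- function(config = herd_config(),
                         dynamics = breeding_dynamics(),
                         econ = NULL,
                         ranges = NULL,
                         scenarios = c("a", "b", "c", "d"),
                         n_iter = 10000,
                         seed = 1L,
                         out_dir = NULL) {
  scenarios <- match.arg(scenarios, c("a", "b", "c", "d"),
                         several.ok = TRUE)
  stage <- "economic configuration"
  res <- tryCatch({
    if (is.null(econ)) {
      base_inputs <- economic_inputs()
    } else if (is.character(econ)) {
      loaded <- load_economic_config(econ)
      base_inputs <- loaded$inputs
      if (is.null(ranges) && nrow(loaded$ranges) > 0) {
        ranges <- loaded$ranges
      }
    } else {
      base_inputs <- econ
    }
    if (is.null(ranges)) ranges <- default_economic_ranges()

    stage <- "herd simulation"
    herd <- generate_herd(config, dynamics, seed = seed)
    groups <- split(herd, herd$treatment)

    stage <- "reproductive metrics"
    summaries <- lapply(groups, summarize_group)
    curves <- lapply(groups, group_survival_curve)
    origin <- lapply(groups, group_time_origin)
    lr_time <- lapply(groups, function(g) {
      ev <- !is.na(g$conception_day)
      o <- group_time_origin(g)
      pmax(ifelse(ev, g$conception_day, g$censor_day) - o, 0)
    })
    lr_event <- lapply(groups, function(g) !is.na(g$conception_day))
    lr <- log_rank_test(lr_time$PGOD, lr_event$PGOD,
                        lr_time$MOFT, lr_event$MOFT)

    stage <- "budget-input derivation"
    inputs <- derive_budget_inputs(summaries, curves, base_inputs)

    stage <- "partial budget / sensitivity / Monte Carlo"
    scen <- standard_scenarios()[scenarios]
    budget <- lapply(scen, function(s) net_benefit(inputs, s))
    tornado <- lapply(scen, function(s) {
      tornado_report(one_way_sweep(scenario_ranges(s, ranges), inputs, s), s)
    })
    mc <- lapply(seq_along(scen), function(i) {
      run_monte_carlo(
        ranges_to_triangular(scenario_ranges(scen[[i]], ranges)),
        inputs, scen[[i]], n_iter = n_iter,
        seed = seed + match(names(scen)[i], c("a", "b", "c", "d"))
      )
    })
    names(mc) <- names(scen)
    list(herd = herd, summaries = summaries, curves = curves,
         origins = origin, log_rank = lr, derived_inputs = inputs,
         budget = budget, tornado = tornado, monte_carlo = mc,
         ranges = ranges)
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })

  res$manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("herdsync")),
    seed = as.integer(seed),
    n_iter = n_iter,
    scenarios = scenarios,
    herd_config = unclass(config),
    dynamics = unclass(dynamics),
    economic_inputs = unclass(res$derived_inputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(out_dir, ...)
    write_cow_csv(res$herd, p("herd.csv"))
    utils::write.csv(cbind(group = names(res$summaries),
                           do.call(rbind, res$summaries)),
                     p("group_summaries.csv"), row.names = FALSE)
    for (g in names(res$curves)) {
      write_survival_csv(res$curves[[g]],
                         p(paste0("survival_", tolower(g), ".csv")))
    }
    ledger <- do.call(rbind, lapply(names(res$budget), function(s) {
      b <- res$budget[[s]]
      data.frame(scenario = s,
                 component = c("milk_income", "calf_income", "ai_saving",
                               "replacement_saving", "treatment_cost",
                               "feed_cost", "returns_foregone",
                               "net_benefit"),
                 value_gbp = c(b$milk_income, b$calf_income, b$ai_saving,
                               b$replacement_saving, b$treatment_cost,
                               b$feed_cost, b$returns_foregone,
                               b$net_benefit))
    }))
    utils::write.csv(ledger, p("budget_ledger.csv"), row.names = FALSE)
    for (s in names(res$tornado)) {
      utils::write.csv(as.data.frame(res$tornado[[s]]),
                       p(paste0("tornado_", s, ".csv")), row.names = FALSE)
    }
    mc_tab <- do.call(rbind, lapply(names(res$monte_carlo), function(s) {
      m <- res$monte_carlo[[s]]
      data.frame(scenario = s, n_iter = m$n_iter, mean = m$mean, sd = m$sd,
                 q1 = m$q1, median = m$median, q3 = m$q3,
                 minimum = m$minimum, maximum = m$maximum)
    }))
    utils::write.csv(mc_tab, p("monte_carlo.csv"), row.names = FALSE)
    res$manifest$outputs <- list.files(out_dir)
    yaml::write_yaml(res$manifest, p("manifest.yaml"))
  }
  res
}
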