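# Annual burden reports, period summaries, scenario batches.

#' Tally an annual burden report
#'
#' Computes one report row from an agent population: adult population,
#' MASLD/MASH counts and prevalence (denominator: alive agents aged 18+),
#' MASH share, fibrosis-stage distribution among prevalent MASLD,
#' prevalent DC, and the cycle's incident HCC/LT and deaths taken from the
#' cycle log. All counts are agent tallies times `person_weight`.
#'
#' @param pop Agent data frame.
#' @param log One-row cycle log from [step_cycle()], or `NULL` at model
#'   start (incident columns are then zero).
#' @param person_weight Persons per agent.
#' @param year Calendar year of the report.
#' @return One-row data frame.
#' @export
tally <- function(pop, log = NULL, person_weight = 100, year = NA) {
  tally_state(pop_to_state(pop), person_weight, year,
              log$inc_hcc %||% 0L, log$inc_lt %||% 0L,
              log$liver_deaths %||% 0L, log$adult_deaths %||% 0L)
}

#' Summarize a period of annual reports
#'
#' Mean annual and cumulative incident HCC and LT over an inclusive year
#' range of a report table.
#'
#' @param reports Annual report data frame (e.g. `summary` of a
#'   `masld_sim`, or a `masld_sim` itself).
#' @param start,end First and last calendar year, inclusive.
#' @return A `masld_period` one-row data frame: period, mean annual HCC
#'   and LT, cumulative HCC and LT.
#' @export
summarize_period <- function(reports, start, end) {
  if (inherits(reports, "masld_sim")) reports <- reports$summary
  years <- start:end
  miss <- setdiff(years, reports$year)
  if (length(miss))
    stop("missing year(s) in reports: ", paste(miss, collapse = ", "))
  r <- reports[reports$year %in% years, ]
  structure(data.frame(
    period = paste0(start, "-", end),
    mean_annual_hcc = mean(r$hcc_incident),
    mean_annual_lt = mean(r$lt_incident),
    cumulative_hcc = sum(r$hcc_incident),
    cumulative_lt = sum(r$lt_incident)),
    class = c("masld_period", "data.frame"))
}

#' Run a batch of scenarios
#'
#' Runs each scenario (over its seeds) and builds a comparison table of
#' headline outputs in the final common year: MASLD and MASH prevalence
#' and counts, incident HCC and LT.
#'
#' @param specs List of `masld_scenario` objects (e.g. from
#'   [ci_sweep_specs()]), or a single scenario.
#' @param params,inputs Shared model inputs.
#' @param ... Passed to [masld_simulate()].
#' @return A `masld_scenarios` list: `$sims` (named by scenario label) and
#'   `$comparison`.
#' @export
run_scenarios <- function(specs, params = masld_parameters(),
                          inputs = masld_inputs(), ...) {
  if (inherits(specs, "masld_scenario")) specs <- list(specs)
  sims <- lapply(specs, masld_simulate, params = params, inputs = inputs,
                 ...)
  names(sims) <- vapply(specs, `[[`, "", "label")
  year <- min(vapply(specs, `[[`, 0, "end_year"))
  comparison <- do.call(rbind, lapply(names(sims), function(nm) {
    s <- sims[[nm]]$summary
    r <- s[s$year == year, ]
    data.frame(scenario = nm, year = year,
               masld_prev = r$masld_prev, masld_count = r$masld_count,
               mash_prev = r$mash_prev, mash_count = r$mash_count,
               dc_count = r$dc_count, hcc_incident = r$hcc_incident,
               lt_incident = r$lt_incident)
  }))
  structure(list(sims = sims, comparison = comparison),
            class = "masld_scenarios")
}

#' @export
print.masld_scenarios <- function(x, ...) {
  cat("Scenario comparison (final common year):\n")
  print(x$comparison, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Extract a target statistic from annual reports
#'
#' Maps a calibration/validation target name to the corresponding model
#' statistic over an inclusive year range (point targets use `y0 == y1`):
#' prevalences and shares are period means, `cumulative_*` are sums.
#'
#' @param reports Annual report data frame.
#' @param name Statistic name: one of `masld_prevalence`,
#'   `mash_prevalence`, `mash_share`, `f0_share` ... `f4_share`,
#'   `dc_count`, `mean_annual_hcc`, `mean_annual_lt`, `cumulative_hcc`,
#'   `cumulative_lt`, `total_population`.
#' @param y0,y1 First and last calendar year of the period.
#' @return The statistic as a single number.
#' @export
extract_target_stat <- function(reports, name, y0, y1 = y0) {
  years <- y0:y1
  miss <- setdiff(years, reports$year)
  if (length(miss))
    stop("target '", name, "': year(s) not in reports: ",
         paste(miss, collapse = ", "))
  r <- reports[reports$year %in% years, ]
  switch(name,
    masld_prevalence = mean(r$masld_prev),
    mash_prevalence = mean(r$mash_prev),
    mash_share = mean(r$mash_share),
    f0_share = mean(r$f0_pct), f1_share = mean(r$f1_pct),
    f2_share = mean(r$f2_pct), f3_share = mean(r$f3_pct),
    f4_share = mean(r$f4_pct),
    dc_count = mean(r$dc_count),
    mean_annual_hcc = mean(r$hcc_incident),
    mean_annual_lt = mean(r$lt_incident),
    cumulative_hcc = sum(r$hcc_incident),
    cumulative_lt = sum(r$lt_incident),
    total_population = mean(r$total_pop),
    stop("unknown target name: ", name))
}

#' Load a calibration/validation target file
#'
#' Reads a CSV of targets (`name`, `year_start`, `year_end`, `value`,
#' `weight`, `tolerance`); the bundled default contains the published
#' anchors: adult MASLD prevalence 2020 and 2030, the 2018 MASH share,
#' and mean annual HCC and LT counts 2020--2025.
#'
#' @param path Target file; default the bundled one.
#' @return Data frame of targets.
#' @export
load_calibration_targets <- function(path = extdata("calibration_targets.csv")) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "year_start", "year_end", "value", "weight", "tolerance")
  miss <- setdiff(need, names(t))
  if (length(miss)) stop("target file lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(t$weight <= 0) || any(!is.finite(t$value)))
    stop("targets must have positive weight and finite value")
  t
}
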