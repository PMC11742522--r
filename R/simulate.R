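# User-facing simulation front end and result methods.

#' Define a simulation scenario
#'
#' A scenario bundles everything that distinguishes one model run from
#' another: the incidence assumption, parameter overrides, the agent
#' count and person weight, the RNG seeds, and the calendar horizon.
#'
#' @param incidence_scenario `"base"` (incidence rises until 2030, then
#'   constant), `"best_case"` (constant after 2014) or `"worst_case"`
#'   (keeps rising through 2050).
#' @param n_agents Number of simulated agents at model start.
#' @param seeds Integer vector of RNG seeds; one full run per seed.
#' @param person_weight Persons represented by one agent; defaults to the
#'   2000 start population divided by `n_agents` (100 at the full
#'   2 821 624-agent size).
#' @param start_year,end_year Calendar horizon.
#' @param overrides Named parameter overrides (see [apply_overrides()]).
#' @param label Optional scenario label used in comparison tables.
#' @return A `masld_scenario` object.
#' @export
masld_scenario <- function(incidence_scenario = "base",
                           n_agents = 250000, seeds = 1:3,
                           person_weight = NULL,
                           start_year = 2000, end_year = 2050,
                           overrides = NULL, label = NULL) {
  incidence_scenario <- match.arg(incidence_scenario,
                                  c("base", "best_case", "worst_case"))
  if (n_agents < 1) stop("n_agents must be >= 1")
  if (is.null(person_weight)) person_weight <- POP2000 / n_agents
  if (person_weight <= 0) stop("person_weight must be > 0")
  if (!(start_year < end_year)) stop("start_year must precede end_year")
  structure(list(incidence_scenario = incidence_scenario,
                 n_agents = as.integer(n_agents),
                 seeds = as.integer(seeds),
                 person_weight = person_weight,
                 start_year = start_year, end_year = end_year,
                 overrides = overrides,
                 label = label %||% incidence_scenario),
            class = "masld_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the microsimulation
#'
#' Simulates the scenario once per seed: synthesizes the initial
#' population, assigns the 2000 disease distribution, then advances the
#' annual cycle to the horizon, tallying an annual burden report per year.
#' Fully reproducible: the same scenario and seeds give bit-identical
#' results.
#'
#' @param scenario A `masld_scenario`.
#' @param params A `masld_params`; the scenario's overrides are applied on
#'   top.
#' @param schedule A `masld_schedule`, or `NULL` to build the default
#'   calibrated schedule for the scenario's incidence assumption.
#' @param init A `masld_init`, `NULL` for the default calibrated 2000
#'   state, or `NA` to start disease-free.
#' @param inputs A `masld_inputs` object.
#' @param keep_population Keep the final agent table of each seed.
#' @return A `masld_sim` object: per-seed annual reports, their across-seed
#'   mean (`$summary`), per-cycle logs, and the run configuration.
#' @export
#' @examples
#' \donttest{
#' sim <- masld_simulate(masld_scenario(n_agents = 20000, seeds = 1))
#' sim
#' }
masld_simulate <- function(scenario = masld_scenario(),
                           params = masld_parameters(),
                           schedule = NULL, init = NULL,
                           inputs = masld_inputs(),
                           keep_population = FALSE) {
  stopifnot(inherits(scenario, "masld_scenario"))
  if (!is.null(scenario$overrides))
    params <- apply_overrides(params, scenario$overrides)
  if (is.null(schedule))
    schedule <- build_incidence_schedule(scenario$incidence_scenario)
  d <- masld_defaults()
  if (is.null(init))
    init <- masld_initial_state(d$p0, d$mash_share0, params,
                                prev_shape = d$prev_shape, rho = d$rho)
  else if (!inherits(init, "masld_init")) init <- NULL  # NA: disease-free
  runs <- lapply(scenario$seeds, function(s)
    run_microsim(scenario, params, schedule, init, inputs, s,
                 keep_population))
  reports <- do.call(rbind, lapply(seq_along(runs), function(i)
    cbind(seed = scenario$seeds[i], runs[[i]]$reports)))
  num <- setdiff(names(runs[[1]]$reports), "year")
  summary <- runs[[1]]$reports["year"]
  for (nm in num)
    summary[[nm]] <- rowMeans(sapply(runs, function(r) r$reports[[nm]]))
  structure(list(summary = summary, reports = reports,
                 logs = lapply(runs, `[[`, "logs"),
                 populations = if (keep_population)
                   lapply(runs, `[[`, "population"),
                 scenario = scenario, params = params,
                 schedule = schedule, init = init),
            class = "masld_sim")
}

#' @export
print.masld_sim <- function(x, ...) {
  s <- x$summary
  cat(sprintf("MASLD microsimulation: scenario '%s', %d agents, %d seed(s), %d-%d\n",
              x$scenario$label, x$scenario$n_agents,
              length(x$scenario$seeds), x$scenario$start_year,
              x$scenario$end_year))
  yrs <- intersect(c(2020, 2030, 2050), s$year)
  for (y in yrs) {
    sel <- s[s$year == y, ]
    win <- s[s$year %in% (y - 4):y, ]  # 5-year mean smooths event counts
    cat(sprintf("  %d: MASLD %.1f%% of adults (%.1fM), MASH %.1f%%, DC %s, HCC %s/y, LT %s/y\n",
                y, sel$masld_prev, sel$masld_count / 1e6, sel$mash_prev,
                fmt_count(sel$dc_count), fmt_count(mean(win$hcc_incident)),
                fmt_count(mean(win$lt_incident))))
  }
  invisible(x)
}

# human-readable counts, rounded to the nearest hundred persons
fmt_count <- function(x) formatC(round(x / 100) * 100, format = "d",
                                 big.mark = " ")

#' @export
summary.masld_sim <- function(object, ...) {
  object$summary
}

#' @export
as.data.frame.masld_sim <- function(x, ...) x$reports

#' @export
plot.masld_sim <- function(x, what = c("prevalence", "events"), ...) {
  what <- match.arg(what)
  s <- x$summary
  if (what == "prevalence") {
    graphics::matplot(s$year, cbind(s$masld_prev, s$mash_prev), type = "l",
                      lty = 1, lwd = 2, col = c("steelblue", "firebrick"),
                      xlab = "year", ylab = "% of US adults", ...)
    graphics::legend("topleft", c("MASLD", "MASH"), lwd = 2,
                     col = c("steelblue", "firebrick"), bty = "n")
  } else {
    graphics::matplot(s$year, cbind(s$hcc_incident, s$lt_incident),
                      type = "l", lty = 1, lwd = 2,
                      col = c("darkorange", "forestgreen"),
                      xlab = "year", ylab = "incident persons per year", ...)
    graphics::legend("topleft", c("HCC", "LT"), lwd = 2,
                     col = c("darkorange", "forestgreen"), bty = "n")
  }
  invisible(x)
}
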