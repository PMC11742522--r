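# The microsimulation engine. One annual cycle has a fixed event ordering:
# (1) mortality, (2) a single categorical transition draw per survivor,
# (3) age/duration increments, (4) entrants appended. The ordering makes
# the conservation identity alive(t+1) + deaths(t) = alive(t) + entrants(t)
# exact and forbids multi-step jumps within a cycle.

# Internal agent store: a list of parallel vectors (faster than a
# data.frame in the inner loop).
pop_to_state <- function(pop) {
  list(age = as.integer(pop$age), sex = as.integer(pop$sex),
       state = as.integer(pop$state), fib = as.integer(pop$fib),
       mash = as.logical(pop$mash),
       ys_hcc = as.integer(pop$ys_hcc), ys_lt = as.integer(pop$ys_lt),
       age_lt = as.integer(pop$age_lt))
}

state_to_pop <- function(st) {
  as.data.frame(st, stringsAsFactors = FALSE)
}

# One annual cycle on the vector store. Uses the ambient RNG stream.
step_core <- function(st, year, params, schedule, inputs, person_weight,
                      entrants = TRUE) {
  v <- params$values
  r <- stage_rate_matrices(params)
  alive0 <- which(st$state <= S_LT)
  n0 <- length(alive0)

  ## (1) mortality
  age0 <- st$age[alive0]
  qx <- inputs$life_table[cbind(pmin(age0, 100L) + 1L, st$sex[alive0])]
  s0 <- st$state[alive0]
  pbg <- ifelse(s0 == S_NONE, qx, pmin(1, qx * v[["hr_masld"]]))
  pliv <- numeric(n0)
  i_dc <- s0 == S_DC
  pliv[i_dc] <- v[["dc_mortality"]]
  i_hcc <- s0 == S_HCC
  if (any(i_hcc))
    pliv[i_hcc] <- inputs$hcc_survival[pmin(st$ys_hcc[alive0[i_hcc]], 10L) + 1L]
  i_lt <- s0 == S_LT
  if (any(i_lt))
    pliv[i_lt] <- inputs$lt_survival[cbind(
      lt_band_index(st$age_lt[alive0[i_lt]]),
      pmin(st$ys_lt[alive0[i_lt]], 10L) + 1L)]
  liver_fire <- stats::runif(n0) < pliv
  bg_fire <- stats::runif(n0) < pbg
  died <- liver_fire | bg_fire
  st$state[alive0[liver_fire]] <- S_DEAD_LIVER
  st$state[alive0[died & !liver_fire]] <- S_DEAD_OTHER
  log <- list(year = year, alive_start = n0,
              deaths = sum(died), liver_deaths = sum(liver_fire),
              other_deaths = sum(died & !liver_fire),
              adult_deaths = sum(died & age0 >= 18L))

  ## (2) transitions, single categorical draw per survivor
  surv <- alive0[!died]
  state1 <- st$state  # pre-transition snapshot of survivors' states
  u <- stats::runif(length(surv))
  names(u) <- NULL
  inc_masld <- inc_mash <- inc_dc <- inc_hcc <- inc_lt <- 0L

  is_none <- which(state1[surv] == S_NONE)
  if (length(is_none)) {
    idx <- surv[is_none]
    p_inc <- incidence_at(schedule, st$age[idx], year)
    hit <- is_none[u[is_none] < p_inc]
    if (length(hit)) {
      idx <- surv[hit]
      st$state[idx] <- S_MASLD
      st$fib[idx] <- 0L
      st$mash[idx] <- FALSE
      inc_masld <- length(hit)
    }
  }

  is_m <- which(state1[surv] == S_MASLD)
  if (length(is_m)) {
    idx <- surv[is_m]
    fib <- st$fib[idx]
    mash <- st$mash[idx]
    mi <- cbind(mash + 1L, fib + 1L)
    p_up <- r$up[mi]
    p_down <- r$down[mi]
    f0m <- fib == 0L & !mash
    if (any(f0m))
      p_down[f0m] <- 0.5 * incidence_at(schedule, st$age[idx[f0m]], year)
    p_sw <- ifelse(fib <= 2L, ifelse(mash, v[["mash_resolution"]],
                                     v[["mash_onset"]]), 0)
    p_dc <- ifelse(fib == 4L, v[["f4_to_dc"]], 0)
    p_hcc <- ifelse(fib == 3L, v[["f3_to_hcc"]],
                    ifelse(fib == 4L, v[["f4_to_hcc"]], 0))
    t1 <- p_down; t2 <- t1 + p_up; t3 <- t2 + p_sw
    t4 <- t3 + p_dc; t5 <- t4 + p_hcc
    if (any(t5 > 1)) stop("exit probabilities exceed 1 in a MASLD state")
    um <- u[is_m]
    down <- um < t1
    up <- !down & um < t2
    sw <- um >= t2 & um < t3
    dc <- um >= t3 & um < t4
    hcc <- um >= t4 & um < t5
    # regression out of MASL F0 leaves the disease entirely
    to_none <- down & fib == 0L
    st$state[idx[to_none]] <- S_NONE
    st$fib[idx[to_none]] <- NA_integer_
    st$mash[idx[to_none]] <- FALSE
    dn <- down & fib > 0L
    st$fib[idx[dn]] <- fib[dn] - 1L
    st$fib[idx[up]] <- fib[up] + 1L
    st$mash[idx[sw]] <- !mash[sw]
    inc_mash <- sum(sw & !mash)
    st$state[idx[dc]] <- S_DC
    st$fib[idx[dc]] <- NA_integer_
    st$mash[idx[dc]] <- FALSE
    st$state[idx[hcc]] <- S_HCC
    st$fib[idx[hcc]] <- NA_integer_
    st$mash[idx[hcc]] <- FALSE
    st$ys_hcc[idx[hcc]] <- 0L
    inc_dc <- sum(dc)
    inc_hcc <- sum(hcc)
  }

  is_dc <- which(state1[surv] == S_DC)
  if (length(is_dc)) {
    ud <- u[is_dc]
    to_hcc <- ud < v[["dc_to_hcc"]]
    to_lt <- !to_hcc & ud < v[["dc_to_hcc"]] + v[["lt_rate"]]
    idx <- surv[is_dc[to_hcc]]
    st$state[idx] <- S_HCC
    st$ys_hcc[idx] <- 0L
    idx <- surv[is_dc[to_lt]]
    st$state[idx] <- S_LT
    st$ys_lt[idx] <- 0L
    st$age_lt[idx] <- st$age[idx]
    inc_hcc <- inc_hcc + sum(to_hcc)
    inc_lt <- inc_lt + sum(to_lt)
  }

  is_h <- which(state1[surv] == S_HCC)
  if (length(is_h)) {
    to_lt <- u[is_h] < v[["lt_rate"]]
    idx <- surv[is_h[to_lt]]
    st$state[idx] <- S_LT
    st$ys_lt[idx] <- 0L
    st$age_lt[idx] <- st$age[idx]
    inc_lt <- inc_lt + sum(to_lt)
  }

  ## (3) increments: survivors age one year; durations advance for agents
  ## who began the cycle in the duration-tracked state
  st$age[surv] <- st$age[surv] + 1L
  cont_hcc <- surv[state1[surv] == S_HCC & st$state[surv] == S_HCC]
  st$ys_hcc[cont_hcc] <- st$ys_hcc[cont_hcc] + 1L
  cont_lt <- surv[state1[surv] == S_LT]
  st$ys_lt[cont_lt] <- st$ys_lt[cont_lt] + 1L

  ## (4) entrants
  n_new <- 0L
  if (entrants) {
    batch <- annual_entrants(inputs$series, year, person_weight,
                             inputs$migrant_ages)
    n_new <- nrow(batch)
    if (n_new > 0)
      for (nm in names(st)) st[[nm]] <- c(st[[nm]], batch[[nm]])
  }
  log$entrants <- n_new
  log$alive_end <- sum(st$state <= S_LT)
  log <- c(log, list(inc_masld = inc_masld, inc_mash = inc_mash,
                     inc_dc = inc_dc, inc_hcc = inc_hcc, inc_lt = inc_lt))
  list(state = st, log = as.data.frame(log))
}

#' Advance a population one annual cycle
#'
#' Applies one cycle of the model to an agent data frame: mortality first,
#' then a single categorical transition draw per survivor, then age and
#' duration increments, then the year's entrant batch. Dead agents remain
#' in the table in an absorbing death state. Uses the ambient RNG stream;
#' seed at the caller for reproducibility.
#'
#' @param pop Agent data frame (see [synthesize_initial_population()]).
#' @param year Calendar year of the cycle's end.
#' @param params A `masld_params` object.
#' @param schedule A `masld_schedule`.
#' @param inputs A `masld_inputs` object.
#' @param person_weight Persons per agent (entrant scaling).
#' @param entrants Whether to append the year's entrant batch (disable for
#'   closed-cohort experiments).
#' @return List with the updated `pop` and a one-row `log` data frame of
#'   cycle tallies (deaths by cause, incident MASLD/MASH/DC/HCC/LT,
#'   entrants, and the conservation bookkeeping).
#' @export
step_cycle <- function(pop, year, params, schedule, inputs,
                       person_weight = 100, entrants = TRUE) {
  res <- step_core(pop_to_state(pop), year, params, schedule, inputs,
                   person_weight, entrants)
  list(pop = state_to_pop(res$state), log = res$log)
}

# Full run for one seed; returns per-year reports, cycle logs, and
# (optionally) the final population.
run_microsim <- function(scenario, params, schedule, init, inputs, seed,
                         keep_population = FALSE) {
  pw <- scenario$person_weight
  pop <- synthesize_initial_population(scenario$n_agents, seed,
                                       inputs$pyramid)
  st <- pop_to_state(pop)
  if (!is.null(init)) st <- pop_to_state(
    assign_initial_disease(state_to_pop(st), init))
  reports <- tally_state(st, pw, scenario$start_year, 0L, 0L, 0L, 0L)
  logs <- NULL
  for (year in (scenario$start_year + 1):scenario$end_year) {
    res <- step_core(st, year, params, schedule, inputs, pw)
    st <- res$state
    logs <- rbind(logs, res$log)
    reports <- rbind(reports, tally_state(
      st, pw, year, res$log$inc_hcc, res$log$inc_lt,
      res$log$liver_deaths, res$log$adult_deaths))
  }
  list(reports = reports, logs = logs,
       population = if (keep_population) state_to_pop(st))
}

# Burden tallies on the vector store; counts scaled to persons.
tally_state <- function(st, person_weight, year, inc_hcc, inc_lt,
                        liver_deaths, adult_deaths) {
  alive <- st$state <= S_LT
  adult <- alive & st$age >= 18L
  n_adult <- sum(adult)
  if (n_adult == 0) stop("zero adult denominator in year ", year)
  m <- adult & st$state == S_MASLD
  n_masld <- sum(m)
  n_mash <- sum(m & st$mash)
  stg <- tabulate(st$fib[m] + 1L, 5L)
  data.frame(
    year = year,
    total_pop = sum(alive) * person_weight,
    adult_pop = n_adult * person_weight,
    masld_count = n_masld * person_weight,
    masld_prev = 100 * n_masld / n_adult,
    mash_count = n_mash * person_weight,
    mash_prev = 100 * n_mash / n_adult,
    mash_share = if (n_masld > 0) 100 * n_mash / n_masld else 0,
    f0_pct = pct(stg[1], n_masld), f1_pct = pct(stg[2], n_masld),
    f2_pct = pct(stg[3], n_masld), f3_pct = pct(stg[4], n_masld),
    f4_pct = pct(stg[5], n_masld),
    dc_count = sum(alive & st$state == S_DC) * person_weight,
    hcc_incident = inc_hcc * person_weight,
    lt_incident = inc_lt * person_weight,
    liver_deaths = liver_deaths * person_weight,
    allcause_deaths = adult_deaths * person_weight)
}
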