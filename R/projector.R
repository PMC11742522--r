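# Deterministic age-structured expectation projection of the open
# population: the exact expectation of the agent engine (same kernel, same
# cycle ordering), used for fast baseline calibration and as an
# independent check on the microsimulation.

# Patch the incidence-dependent entries of a base (incidence = 0) survivor
# transition matrix. Only the no-steatosis row and the MASL F0
# steatosis-regression term depend on incidence.
patch_incidence <- function(T0, inc) {
  T0[O_NONE, O_NONE] <- 1 - inc
  T0[O_NONE, o_masl(0)] <- inc
  reg <- 0.5 * inc
  T0[o_masl(0), O_NONE] <- reg
  T0[o_masl(0), o_masl(0)] <- T0[o_masl(0), o_masl(0)] - reg
  T0
}

#' Deterministic expectation projection of the population model
#'
#' Projects the expected person counts by single year of age, sex and
#' expanded health state through the annual cycle (mortality, transitions,
#' ageing, entrants — the engine's ordering), with no Monte Carlo error.
#' With `init = NULL` and `schedule = NULL` this is a pure demographic
#' projection (no disease), the source of the bundled population targets.
#'
#' @param params A `masld_params` object.
#' @param schedule A `masld_schedule`, or `NULL` for zero incidence.
#' @param init A `masld_init`, or `NULL` for a disease-free start.
#' @param inputs A `masld_inputs` object.
#' @param start_year,end_year Calendar horizon (reports one row per year,
#'   the first being the initial state).
#' @param pop0 Persons represented at model start.
#' @return Data frame with one row per year: population totals, adult
#'   MASLD/MASH prevalence (%), MASH share (%), fibrosis-stage shares
#'   among MASLD (%), prevalent DC persons, incident HCC/LT persons, and
#'   liver/all-cause deaths among adults (persons).
#' @export
project_expectation <- function(params = masld_parameters(),
                                schedule = NULL, init = NULL,
                                inputs = masld_inputs(),
                                start_year = 2000, end_year = 2050,
                                pop0 = POP2000) {
  stopifnot(start_year < end_year)
  v <- params$values
  ages <- 0:100
  gi <- age_group_index(ages)
  w <- inputs$pyramid$weight

  A <- array(0, c(101, 2, N_ALIVE))
  A[, 1, O_NONE] <- pop0 * w * 0.491
  A[, 2, O_NONE] <- pop0 * w * 0.509
  if (!is.null(init)) {
    for (i in which(!is.na(gi))) {
      p <- init$prev_by_group[[gi[i]]]
      for (s in 1:2) {
        tot <- A[i, s, O_NONE]
        A[i, s, 2:11] <- tot * p * init$joint
        A[i, s, O_NONE] <- tot * (1 - p)
      }
    }
  }

  # liver-cause death probabilities by age row x state (LT band depends on
  # age at transplant = current age - duration bin)
  PL <- matrix(0, 101, N_ALIVE)
  PL[, O_DC] <- v[["dc_mortality"]]
  PL[, o_hcc(0:10)] <- matrix(inputs$hcc_survival, 101, 11, byrow = TRUE)
  for (k in 0:10)
    PL[, o_lt(k)] <- inputs$lt_survival[cbind(lt_band_index(ages - k), k + 1)]

  T0 <- survivor_transition_matrix(params, 0)
  Tchild <- survivor_transition_matrix(params, 0, adult = FALSE)
  grp_rows <- lapply(1:3, function(g) which(!is.na(gi) & gi == g))
  child_rows <- which(is.na(gi))
  mig_w <- migrant_age_weights(inputs$migrant_ages)

  tally1 <- function(A, year, hcc_in, lt_in, liv_d, all_d) {
    adult <- 19:101
    adult_pop <- sum(A[adult, , ])
    if (adult_pop <= 0) stop("zero adult population")
    masld <- sum(A[adult, , 2:11])
    mash <- sum(A[adult, , 7:11])
    stg <- vapply(0:4, function(f)
      sum(A[adult, , c(o_masl(f), o_mash(f))]), numeric(1))
    data.frame(
      year = year, total_pop = sum(A), adult_pop = adult_pop,
      masld_count = masld, masld_prev = 100 * masld / adult_pop,
      mash_count = mash, mash_prev = 100 * mash / adult_pop,
      mash_share = if (masld > 0) 100 * mash / masld else 0,
      f0_pct = pct(stg[1], masld), f1_pct = pct(stg[2], masld),
      f2_pct = pct(stg[3], masld), f3_pct = pct(stg[4], masld),
      f4_pct = pct(stg[5], masld),
      dc_count = sum(A[, , O_DC]),
      hcc_incident = hcc_in, lt_incident = lt_in,
      liver_deaths = liv_d, allcause_deaths = all_d)
  }

  out <- tally1(A, start_year, 0, 0, 0, 0)
  for (year in (start_year + 1):end_year) {
    hcc_in <- lt_in <- liv_d <- all_d <- 0
    for (s in 1:2) {
      qx <- inputs$life_table[, s]
      PB <- matrix(pmin(1, qx * v[["hr_masld"]]), 101, N_ALIVE)
      PB[, O_NONE] <- qx
      M <- A[, s, ]
      liv <- M * PL
      oth <- M * PB * (1 - PL)
      liv_d <- liv_d + sum(liv[19:101, ])
      all_d <- all_d + sum(liv[19:101, ]) + sum(oth[19:101, ])
      M <- M - liv - oth
      # survivor transitions, by incidence group
      M[child_rows, ] <- M[child_rows, ] %*% Tchild
      for (g in 1:3) {
        inc <- if (is.null(schedule)) 0 else
          schedule$mat[g, match(year, schedule$years)]
        M[grp_rows[[g]], ] <- M[grp_rows[[g]], ] %*% patch_incidence(T0, inc)
      }
      hcc_in <- hcc_in + sum(M[, o_hcc(0)])
      lt_in <- lt_in + sum(M[, o_lt(0)])
      # ageing: age 100 has qx = 1, so its row is already empty
      M <- rbind(0, M[1:100, ])
      A[, s, ] <- M
    }
    i <- match(year, inputs$series$year)
    if (is.na(i)) stop("year ", year, " outside the demography series")
    A[1, 1, O_NONE] <- A[1, 1, O_NONE] + inputs$series$births[i] * 0.512
    A[1, 2, O_NONE] <- A[1, 2, O_NONE] + inputs$series$births[i] * 0.488
    A[, 1, O_NONE] <- A[, 1, O_NONE] + inputs$series$net_migrants[i] * 0.5 * mig_w
    A[, 2, O_NONE] <- A[, 2, O_NONE] + inputs$series$net_migrants[i] * 0.5 * mig_w
    out <- rbind(out, tally1(A, year, hcc_in, lt_in, liv_d, all_d))
  }
  rownames(out) <- NULL
  out
}

pct <- function(x, denom) if (denom > 0) 100 * x / denom else 0

# single-year-of-age weights of the migrant age-band distribution
migrant_age_weights <- function(migrant_ages) {
  w <- numeric(101)
  for (i in seq_len(nrow(migrant_ages))) {
    a <- migrant_ages$age_lo[i]:migrant_ages$age_hi[i]
    w[a + 1] <- w[a + 1] + migrant_ages$weight[i] / length(a)
  }
  w / sum(w)
}
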