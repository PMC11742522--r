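# Transition kernel over the model state space. One construction code path
# serves the agent engine, the closed-cohort oracle matrix, and the
# deterministic population projector.

# Agent-level state codes
S_NONE <- 1L; S_MASLD <- 2L; S_DC <- 3L; S_HCC <- 4L; S_LT <- 5L
S_DEAD_LIVER <- 6L; S_DEAD_OTHER <- 7L

# Expanded (oracle/projector) state space: HCC and LT carry 11 duration
# bins (0-10+) so that duration-dependent mortality stays Markov.
N_ALIVE <- 34L
O_NONE <- 1L
o_masl <- function(f) 2L + f          # f = 0..4
o_mash <- function(f) 7L + f
O_DC <- 12L
o_hcc <- function(k) 13L + k          # k = 0..10
o_lt  <- function(k) 24L + k
O_DEAD_LIVER <- 35L; O_DEAD_OTHER <- 36L

ALIVE_STATE_NAMES <- c(
  "none", paste0("masl_f", 0:4), paste0("mash_f", 0:4), "dc",
  paste0("hcc_", 0:10), paste0("lt_", 0:10))
STATE_NAMES <- c(ALIVE_STATE_NAMES, "liver_death", "other_death")

# Per-track stage-progression (up) and stage-regression (down) rates as
# 2 x 5 matrices indexed [mash + 1, fib + 1]. The "down" rate at F0 for
# MASL is the steatosis-regression term, half the incidence, supplied
# separately because it is age- and year-specific.
stage_rate_matrices <- function(params) {
  v <- params$values
  up <- rbind(
    masl = c(v[["masl_f0_to_f1"]], v[["masl_f1_to_f2"]], v[["masl_f2_to_f3"]],
             v[["masl_f3_to_f4"]], 0),
    mash = c(v[["mash_f0_to_f1"]], v[["mash_f1_to_f2"]], v[["mash_f2_to_f3"]],
             v[["mash_f3_to_f4"]], 0))
  down <- rbind(
    masl = c(0, v[["masl_f1_to_f0"]], v[["masl_f2_to_f1"]], v[["masl_f3_to_f2"]],
             v[["masl_f4_to_f3"]]),
    mash = c(0, v[["mash_f1_to_f0"]], v[["mash_f2_to_f1"]], v[["mash_f3_to_f2"]],
             v[["mash_f4_to_f3"]]))
  list(up = up, down = down)
}

#' Destination distribution of a single health state
#'
#' Returns the categorical distribution over destination states (plus
#' `stay`) for one source state, conditional on surviving the cycle:
#' the row of the transition kernel the microsimulation draws from.
#' Mortality is handled separately and first (see the cycle ordering in
#' [masld_simulate()]).
#'
#' @param state One of `"none"`, `"masld"`, `"dc"`, `"hcc"`, `"lt"`.
#' @param params A `masld_params` object.
#' @param fib Fibrosis stage 0--4 (MASLD states only).
#' @param mash Logical MASH flag (MASLD states only).
#' @param age Agent age in years (incidence applies only at ages >= 18).
#' @param incidence Annual MASLD incidence probability for the agent's age
#'   group and calendar year.
#' @return Named numeric vector of probabilities summing to 1.
#' @export
#' @examples
#' destination_distribution("masld", masld_parameters(), fib = 3, mash = TRUE)
destination_distribution <- function(state, params, fib = NULL, mash = FALSE,
                                     age = 40, incidence = 0) {
  v <- params$values
  row <- switch(state,
    none = if (age >= 18) c(masl_f0 = incidence) else c(),
    masld = {
      r <- stage_rate_matrices(params)
      m <- mash + 1L
      trk <- if (mash) "mash" else "masl"
      oth <- if (mash) "masl" else "mash"
      out <- c()
      if (fib == 0 && !mash) out <- c(out, none = 0.5 * incidence)
      if (fib > 0)
        out <- c(out, stats::setNames(r$down[m, fib + 1],
                                      paste0(trk, "_f", fib - 1)))
      if (fib < 4)
        out <- c(out, stats::setNames(r$up[m, fib + 1],
                                      paste0(trk, "_f", fib + 1)))
      if (fib <= 2) {
        sw <- if (mash) v[["mash_resolution"]] else v[["mash_onset"]]
        out <- c(out, stats::setNames(sw, paste0(oth, "_f", fib)))
      }
      if (fib == 3) out <- c(out, hcc = v[["f3_to_hcc"]])
      if (fib == 4) out <- c(out, dc = v[["f4_to_dc"]], hcc = v[["f4_to_hcc"]])
      out
    },
    dc = c(hcc = v[["dc_to_hcc"]], lt = v[["lt_rate"]]),
    hcc = c(lt = v[["lt_rate"]]),
    lt = c(),
    stop("unknown state: ", state)
  )
  stay <- 1 - sum(row)
  if (stay < 0) stop("exit probabilities exceed 1 for state ", state)
  c(row, stay = stay)
}

# 34 x 34 transition matrix over alive states, conditional on survival,
# for a given incidence probability. Staying in HCC/LT advances the
# duration bin; entering starts at bin 0; bin 10 is 10+.
survivor_transition_matrix <- function(params, incidence = 0, adult = TRUE) {
  v <- params$values
  r <- stage_rate_matrices(params)
  M <- matrix(0, N_ALIVE, N_ALIVE, dimnames = list(ALIVE_STATE_NAMES,
                                                   ALIVE_STATE_NAMES))
  inc <- if (adult) incidence else 0
  M[O_NONE, o_masl(0)] <- inc
  M[O_NONE, O_NONE] <- 1 - inc
  for (mash in c(FALSE, TRUE)) {
    m <- mash + 1L
    idx <- function(f) if (mash) o_mash(f) else o_masl(f)
    oidx <- function(f) if (mash) o_masl(f) else o_mash(f)
    for (f in 0:4) {
      i <- idx(f)
      if (f == 0 && !mash) M[i, O_NONE] <- 0.5 * inc
      if (f > 0) M[i, idx(f - 1)] <- r$down[m, f + 1]
      if (f < 4) M[i, idx(f + 1)] <- r$up[m, f + 1]
      if (f <= 2)
        M[i, oidx(f)] <- if (mash) v[["mash_resolution"]] else v[["mash_onset"]]
      if (f == 3) M[i, o_hcc(0)] <- v[["f3_to_hcc"]]
      if (f == 4) {
        M[i, O_DC] <- v[["f4_to_dc"]]
        M[i, o_hcc(0)] <- v[["f4_to_hcc"]]
      }
      M[i, i] <- 1 - sum(M[i, -i])
    }
  }
  M[O_DC, o_hcc(0)] <- v[["dc_to_hcc"]]
  M[O_DC, o_lt(0)] <- v[["lt_rate"]]
  M[O_DC, O_DC] <- 1 - v[["dc_to_hcc"]] - v[["lt_rate"]]
  for (k in 0:10) {
    i <- o_hcc(k)
    M[i, o_lt(0)] <- v[["lt_rate"]]
    M[i, o_hcc(min(k + 1, 10))] <- 1 - v[["lt_rate"]]
    M[o_lt(k), o_lt(min(k + 1, 10))] <- 1
  }
  if (any(M < 0)) stop("negative transition probability; exit sums exceed 1")
  M
}

# Annual death probabilities over the 34 alive states for one background
# mortality level qx. Background mortality is multiplied by the MASLD
# hazard ratio in every disease state; in DC/HCC/LT it is composed with
# the liver-specific probability as independent competing causes, and a
# death is attributed to the liver whenever the liver cause fires.
# `lt_age_at_transplant` resolves the LT fixture band; it may be a vector
# of length 11 (one age per duration bin).
state_death_probs <- function(qx, params, hcc_fix, lt_fix,
                              lt_age_at_transplant = 60) {
  v <- params$values
  p_bg <- rep(pmin(1, qx * v[["hr_masld"]]), N_ALIVE)
  p_bg[O_NONE] <- qx
  p_liv <- numeric(N_ALIVE)
  p_liv[O_DC] <- v[["dc_mortality"]]
  p_liv[o_hcc(0:10)] <- hcc_fix
  band <- lt_band_index(rep_len(lt_age_at_transplant, 11))
  p_liv[o_lt(0:10)] <- lt_fix[cbind(band, 1:11)]
  list(liver = p_liv,
       other = p_bg * (1 - p_liv),
       total = 1 - (1 - p_bg) * (1 - p_liv))
}
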