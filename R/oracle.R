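# Deterministic expectation twin of the agent engine: a closed-cohort
# transition matrix over the duration-expanded state space, an expectation
# iterator, and stage-distribution utilities used by the initializer.

#' Closed-cohort one-cycle transition matrix
#'
#' Builds the full row-stochastic matrix over the expanded state space (34
#' alive states — HCC and LT expanded into 11 duration bins each — plus
#' liver and other death), composing mortality first and movement second,
#' exactly as the engine orders them within a cycle. Used as the
#' brute-force expectation oracle for engine tests and for fast closed-
#' cohort projections.
#'
#' @param params A `masld_params` object.
#' @param incidence Annual MASLD incidence probability applied to the
#'   no-steatosis state (a closed-cohort constant).
#' @param qx Background annual death probability (age-free constant).
#' @param fixtures Survival fixtures as from [make_survival_fixtures()].
#' @param lt_age_at_transplant Age used to resolve the LT fixture band.
#' @param adult Whether incidence applies (FALSE for a pediatric cohort).
#' @return A 36 x 36 row-stochastic matrix; death states absorbing.
#' @export
build_transition_matrix <- function(params, incidence = 0, qx = 0,
                                    fixtures = make_survival_fixtures(),
                                    lt_age_at_transplant = 60,
                                    adult = TRUE) {
  Tm <- survivor_transition_matrix(params, incidence, adult)
  d <- state_death_probs(qx, params, fixtures$hcc, fixtures$lt,
                         lt_age_at_transplant)
  n <- N_ALIVE + 2L
  M <- matrix(0, n, n, dimnames = list(STATE_NAMES, STATE_NAMES))
  M[1:N_ALIVE, 1:N_ALIVE] <- (1 - d$total) * Tm
  M[1:N_ALIVE, O_DEAD_LIVER] <- d$liver
  M[1:N_ALIVE, O_DEAD_OTHER] <- d$other
  M[O_DEAD_LIVER, O_DEAD_LIVER] <- 1
  M[O_DEAD_OTHER, O_DEAD_OTHER] <- 1
  if (max(abs(rowSums(M) - 1)) > 1e-12 * n)
    stop("transition matrix rows do not sum to 1")
  M
}

#' Expected state occupancy over k cycles
#'
#' Iterates the expectation of the chain: repeated vector-matrix products
#' of an initial distribution with one transition matrix (or a list of
#' per-cycle matrices, e.g. for a year-varying incidence).
#'
#' @param init Initial distribution over the 36 expanded states (or over
#'   the 34 alive states, padded with zeros); must sum to 1.
#' @param matrix A 36 x 36 matrix from [build_transition_matrix()], or a
#'   list of `k` such matrices.
#' @param k Number of cycles (>= 0).
#' @return A `(k + 1) x 36` occupancy matrix; row `i` is the distribution
#'   after `i - 1` cycles.
#' @export
run_expectation <- function(init, matrix, k) {
  if (k < 0) stop("k must be >= 0")
  if (length(init) == N_ALIVE) init <- c(init, 0, 0)
  stopifnot(length(init) == N_ALIVE + 2L,
            abs(sum(init) - 1) < 1e-8)
  mats <- if (is.list(matrix)) matrix else rep(list(matrix), k)
  if (length(mats) < k) stop("need one matrix per cycle")
  occ <- base::matrix(0, k + 1, N_ALIVE + 2L,
                      dimnames = list(0:k, STATE_NAMES))
  occ[1, ] <- init
  v <- init
  for (i in seq_len(k)) {
    v <- as.numeric(v %*% mats[[i]])
    occ[i + 1, ] <- v
  }
  occ
}

# Fibrosis sub-chain of one track (5 x 5, sub-stochastic: exits to DC/HCC
# and the MASH switch leak out).
fibrosis_subchain <- function(params, track = c("masl", "mash")) {
  track <- match.arg(track)
  Tm <- survivor_transition_matrix(params, incidence = 0)
  idx <- if (track == "masl") o_masl(0:4) else o_mash(0:4)
  # sub-stochastic: the diagonal already excludes mass leaking to the
  # other track, DC and HCC
  Tm[idx, idx]
}

#' Quasi-stationary fibrosis-stage distribution
#'
#' Normalized leading left eigenvector of the fibrosis sub-chain of one
#' track (F0--F4 with exits to the other track, DC and HCC treated as
#' absorbing leakage): the long-run stage mix conditional on remaining in
#' the track.
#'
#' @param params A `masld_params` object.
#' @param track `"masl"` or `"mash"`.
#' @return Named length-5 probability vector over F0--F4.
#' @export
quasi_stationary_stage_distribution <- function(params, track = "masl") {
  P <- fibrosis_subchain(params, track)
  r <- stage_rate_matrices(params)
  m <- (track == "mash") + 1L
  if (any(r$up[m, 1:4] <= 0) || any(r$down[m, 2:5] <= 0))
    stop("fibrosis sub-chain is reducible over F0-F4")
  ev <- eigen(t(P))
  i <- which.max(Re(ev$values))
  v <- Re(ev$vectors[, i])
  v <- abs(v) / sum(abs(v))
  stats::setNames(v, paste0("f", 0:4))
}

#' Duration-weighted initial stage distribution
#'
#' Expected joint (track, stage) distribution of prevalent cases at the
#' simulation start, modeling the prevalent pool as a mixture of cases
#' over disease duration `d` with geometric weights `(1 - rho)^d` and
#' within-duration occupancy `e_F0 P^d` of the joint MASL/MASH sub-chain
#' (all cases incident at MASL F0). `rho` is the annual removal rate of
#' the pre-baseline prevalent pool (mortality plus historical relative
#' incidence growth); the default 0.045 is the package's a-priori choice,
#' discussed in the methods vignette. Unlike the quasi-stationary
#' distribution this reproduces the mild stage mix of a prevalent
#' population still far from the chain's long-run state.
#'
#' @param params A `masld_params` object.
#' @param rho Annual removal rate of the historical prevalent pool.
#' @param max_duration Longest disease duration considered, years.
#' @return Named length-10 probability vector over MASL F0--F4, MASH
#'   F0--F4.
#' @export
duration_weighted_stage_distribution <- function(params, rho = 0.045,
                                                 max_duration = 60) {
  Tm <- survivor_transition_matrix(params, incidence = 0)
  idx <- c(o_masl(0:4), o_mash(0:4))
  P <- Tm[idx, idx]
  occ <- c(1, numeric(9))
  acc <- occ
  w <- 1
  for (d in seq_len(max_duration)) {
    occ <- as.numeric(occ %*% P)
    w <- w * (1 - rho)
    acc <- acc + w * occ
  }
  stats::setNames(acc / sum(acc), ALIVE_STATE_NAMES[idx])
}
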