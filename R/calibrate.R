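# Calibration: deterministic baseline solves (incidence trend, initial
# 2000 state) against published prevalence anchors, and a stochastic
# derivative-free calibrator for free transition parameters.

#' Back-calculate the initial 2000 disease state
#'
#' One-dimensional bisection on the overall 2000 adult prevalence scalar
#' (applied to the age-shape template) so that the forward projection
#' reproduces a late-period MASLD prevalence anchor; and, if a MASH-share
#' anchor is present, a second bisection on the 2000 MASH share so the
#' projection reproduces it. The solves use the deterministic expectation
#' projector ([project_expectation()]), which shares the engine's kernel,
#' so the calibrated point transfers to the microsimulation up to Monte
#' Carlo error. The stage mix of prevalent cases is the duration-weighted
#' default of [masld_initial_state()].
#'
#' @param anchors Target data frame (see [load_calibration_targets()]);
#'   must contain a `masld_prevalence` row.
#' @param schedule The incidence schedule to project under.
#' @param params A `masld_params`.
#' @param inputs A `masld_inputs`.
#' @param mash_share0 Starting MASH share used when no share anchor is
#'   given.
#' @return A `masld_init` with an `anchors_achieved` attribute.
#' @export
back_calculate_initial_state <- function(anchors, schedule,
                                         params = masld_parameters(),
                                         inputs = masld_inputs(),
                                         mash_share0 = masld_defaults()$mash_share0) {
  prow <- anchors[anchors$name == "masld_prevalence", ]
  if (nrow(prow) == 0) stop("anchors must include a masld_prevalence row")
  prow <- prow[which.max(prow$year_start), ]  # latest prevalence anchor
  srow <- anchors[anchors$name == "mash_share", ]
  horizon <- max(prow$year_end, if (nrow(srow)) srow$year_end)
  proj_stat <- function(p0, s0, name, y) {
    init <- masld_initial_state(p0, s0, params)
    r <- project_expectation(params, schedule, init, inputs,
                             end_year = horizon)
    extract_target_stat(r, name, y)
  }
  s0 <- mash_share0
  if (nrow(srow)) srow <- srow[1, ]
  for (round in 1:2) {
    p0 <- stats::uniroot(function(p)
      proj_stat(p, s0, "masld_prevalence", prow$year_start) - prow$value,
      c(0.02, 0.6), tol = 1e-5)$root
    if (nrow(srow))
      s0 <- stats::uniroot(function(s)
        proj_stat(p0, s, "mash_share", srow$year_start) - srow$value,
        c(0.005, 0.45), tol = 1e-5)$root
    else break
  }
  init <- masld_initial_state(p0, s0, params)
  ach <- c(masld_prevalence = proj_stat(p0, s0, "masld_prevalence",
                                        prow$year_start))
  if (nrow(srow))
    ach <- c(ach, mash_share = proj_stat(p0, s0, "mash_share",
                                         srow$year_start))
  attr(init, "anchors_achieved") <- ach
  init
}

#' Calibrate the baseline model to the bundled anchors
#'
#' Jointly determines the free baseline scalars — the overall 2000 adult
#' prevalence, the 2000 incidence level, the annual incidence slope, and
#' the 2000 MASH share — so that the deterministic projection reproduces
#' the anchor suite (by default: adult MASLD prevalence 28.0% in 2001,
#' 33.7% in 2020 and 36.8% in 2030, and a MASH share of 17.2% in 2018).
#' The early, middle and late prevalence anchors identify the initial
#' prevalence, the incidence level and the incidence slope respectively;
#' the solve is coordinate-wise bisection iterated to joint convergence,
#' deterministic and fast. With only two prevalence anchors the level
#' stays fixed and only (prevalence, slope) are solved. The rounded
#' result is frozen as [masld_defaults()].
#'
#' @param anchors Target data frame; needs at least two
#'   `masld_prevalence` rows and optionally a `mash_share` row.
#' @param params A `masld_params`.
#' @param inputs A `masld_inputs`.
#' @param level Starting (or, with two anchors, fixed) overall 2000
#'   incidence level.
#' @param rounds Coordinate iterations.
#' @return A `masld_baseline` list: `level`, `slope`, `p0`,
#'   `mash_share0`, the calibrated base-case `schedule` and `init`, and
#'   an anchor convergence table.
#' @export
calibrate_baseline <- function(anchors = load_calibration_targets(),
                               params = masld_parameters(),
                               inputs = masld_inputs(),
                               level = masld_defaults()$level,
                               rounds = 4) {
  prow <- anchors[anchors$name == "masld_prevalence", ]
  if (nrow(prow) < 2)
    stop("need at least two masld_prevalence anchors")
  prow <- prow[order(prow$year_start), ]
  n <- nrow(prow)
  fit_level <- n >= 3
  y_e <- prow$year_start[1]; v_e <- prow$value[1]
  y_m <- prow$year_start[max(1, n - 1)]; v_m <- prow$value[max(1, n - 1)]
  y_l <- prow$year_start[n]; v_l <- prow$value[n]
  srow <- anchors[anchors$name == "mash_share", ]
  d <- masld_defaults()
  slope <- d$slope; p0 <- d$p0; s0 <- d$mash_share0
  stat <- function(level, slope, p0, s0, name, year) {
    sched <- build_incidence_schedule("base", level = level, slope = slope)
    init <- masld_initial_state(p0, s0, params)
    extract_target_stat(
      project_expectation(params, sched, init, inputs, end_year = year),
      name, year)
  }
  for (it in seq_len(rounds)) {
    p0 <- stats::uniroot(function(p)
      stat(level, slope, p, s0, "masld_prevalence", y_e) - v_e,
      c(0.02, 0.6), tol = 1e-5)$root
    if (fit_level)
      level <- stats::uniroot(function(L)
        stat(L, slope, p0, s0, "masld_prevalence", y_m) - v_m,
        c(5e-4, 0.05), tol = 1e-7)$root
    slope <- stats::uniroot(function(sl)
      stat(level, sl, p0, s0, "masld_prevalence", y_l) - v_l,
      c(-level / 60, 2e-3), tol = 1e-7)$root
    if (nrow(srow))
      s0 <- stats::uniroot(function(s)
        stat(level, slope, p0, s, "mash_share", srow$year_start[1]) -
          srow$value[1],
        c(0.005, 0.45), tol = 1e-5)$root
  }
  schedule <- build_incidence_schedule("base", level = level, slope = slope)
  init <- masld_initial_state(p0, s0, params)
  r <- project_expectation(params, schedule, init, inputs,
                           end_year = max(prow$year_start, if (nrow(srow))
                             srow$year_start[1]))
  tab <- data.frame(
    name = c(rep("masld_prevalence", n), if (nrow(srow)) "mash_share"),
    year = c(prow$year_start, if (nrow(srow)) srow$year_start[1]),
    target = c(prow$value, if (nrow(srow)) srow$value[1]))
  tab$achieved <- mapply(function(nm, y) extract_target_stat(r, nm, y),
                         tab$name, tab$year)
  structure(list(level = level, slope = slope, p0 = p0, mash_share0 = s0,
                 schedule = schedule, init = init, anchors = tab,
                 converged = all(abs(tab$achieved - tab$target) < 0.05)),
            class = "masld_baseline")
}

#' @export
print.masld_baseline <- function(x, ...) {
  cat(sprintf("Baseline calibration: level %.4f, slope %.3e, 2000 prevalence %.4f, 2000 MASH share %.4f\n",
              x$level, x$slope, x$p0, x$mash_share0))
  print(x$anchors, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Calibrate free parameters against targets by simulation
#'
#' Derivative-free calibration of named transition parameters: minimizes
#' the weighted sum of squared relative deviations between simulated and
#' target statistics, using common random numbers (the same seeds for
#' every loss evaluation, so the loss is deterministic in the parameters)
#' and a Nelder--Mead simplex with random restarts. Values outside the
#' declared bounds are rejected with a penalized loss.
#'
#' @param free Character vector of parameter names to fit.
#' @param bounds 2 x length(free) matrix (rows `lo`, `hi`) or named list
#'   of `c(lo, hi)`.
#' @param targets Target data frame (see [load_calibration_targets()]).
#' @param scenario `masld_scenario` used for the loss evaluations
#'   (typically a reduced agent count).
#' @param params Base `masld_params`.
#' @param inputs A `masld_inputs`.
#' @param schedule,init Passed to [masld_simulate()].
#' @param restarts Random restarts after the first start at the bound
#'   midpoint.
#' @param reltol Relative convergence tolerance on the loss.
#' @param maxit Maximum simplex iterations per start.
#' @param seed Seed for the restart draws (not the simulation seeds,
#'   which come from `scenario$seeds`).
#' @return A `masld_calibration`: fitted values, loss, per-target table,
#'   convergence flag.
#' @export
calibrate_model <- function(free, bounds, targets,
                            scenario = masld_scenario(n_agents = 200000,
                                                      seeds = 1),
                            params = masld_parameters(),
                            inputs = masld_inputs(),
                            schedule = NULL, init = NULL,
                            restarts = 3, reltol = 1e-3, maxit = 200,
                            seed = 1) {
  if (is.list(bounds)) bounds <- sapply(bounds[free], identity)
  bounds <- matrix(as.numeric(bounds), 2, length(free),
                   dimnames = list(c("lo", "hi"), free))
  stopifnot(all(is.finite(bounds)), nrow(targets) >= 1)
  unknown <- setdiff(free, PARAM_NAMES)
  if (length(unknown)) stop("unknown free parameter(s): ",
                            paste(unknown, collapse = ", "))
  model_stats <- function(theta) {
    ps <- apply_overrides(params, stats::setNames(theta, free))
    sim <- masld_simulate(scenario, ps, schedule = schedule, init = init,
                          inputs = inputs)
    vapply(seq_len(nrow(targets)), function(i)
      extract_target_stat(sim$summary, targets$name[i],
                          targets$year_start[i], targets$year_end[i]),
      numeric(1))
  }
  loss_of <- function(stats_vec)
    sum(targets$weight * ((stats_vec - targets$value) / targets$value)^2)
  penalized <- function(theta) {
    viol <- pmax(bounds["lo", ] - theta, theta - bounds["hi", ], 0)
    if (any(viol > 0)) return(1e6 * (1 + sum(viol / (bounds["hi", ] -
                                                       bounds["lo", ]))))
    loss_of(model_stats(theta))
  }
  if (length(free) == 0) {
    st <- model_stats(numeric(0))
    return(structure(list(par = numeric(0), loss = loss_of(st),
                          table = cbind(targets, model = st),
                          converged = TRUE, iterations = 0),
                     class = "masld_calibration"))
  }
  set.seed(as.integer(seed))
  # Brent's method is deterministic over the whole interval, so restarts
  # only matter for the multi-parameter simplex.
  if (length(free) == 1) restarts <- 0
  starts <- rbind(colMeans(bounds),
                  if (restarts > 0)
                    sapply(seq_len(length(free)), function(j)
                      stats::runif(restarts, bounds["lo", j],
                                   bounds["hi", j])))
  starts <- matrix(starts, ncol = length(free))
  best <- NULL
  iters <- 0L
  conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- if (length(free) == 1)
      stats::optim(starts[i, ], penalized, method = "Brent",
                   lower = bounds["lo", 1], upper = bounds["hi", 1],
                   control = list(maxit = maxit))
    else
      stats::optim(starts[i, ], penalized, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = maxit))
    iters <- iters + fit$counts[1]
    conv <- conv || fit$convergence == 0
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  start_loss <- penalized(starts[1, ])
  st <- model_stats(best$par)
  structure(list(par = stats::setNames(best$par, free),
                 loss = best$value, start_loss = start_loss,
                 table = cbind(targets, model = st),
                 converged = conv, iterations = as.integer(iters)),
            class = "masld_calibration")
}

#' @export
print.masld_calibration <- function(x, ...) {
  cat("Model calibration (Nelder-Mead, common random numbers)\n")
  if (length(x$par))
    cat(sprintf("  %s = %.5g\n", names(x$par), x$par))
  cat(sprintf("  loss %.5g, converged: %s\n", x$loss, x$converged))
  print(x$table[, c("name", "year_start", "year_end", "value", "model")],
        row.names = FALSE, digits = 5)
  invisible(x)
}
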