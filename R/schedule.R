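# Age- and year-specific MASLD incidence schedule and the initial 2000
# disease distribution.

POP2000 <- 282162400   # persons represented at model start (2 821 624 x 100)
AGE_GROUPS <- c("18-39", "40-59", "60+")

#' Package default trend and initialization constants
#'
#' The free quantities of the baseline model: the year-2000 incidence
#' level and its age-group shape, the annual incidence slope, the overall
#' 2000 adult prevalence and its age-group shape, the 2000 MASH share
#' among prevalent cases, and the removal rate of the duration-weighted
#' initializer. `level`, `slope`, `p0` and `mash_share0` are calibrated
#' stand-ins: re-derivable from the bundled anchors with
#' [calibrate_baseline()], whose rounded output they are. The remaining
#' constants are fixed a-priori choices discussed in the methods
#' vignette.
#'
#' @return Named list of constants.
#' @export
masld_defaults <- function() {
  list(
    level = 0.01376,                # overall incidence in 2000, per year
    slope = 3.509e-4,               # annual increase in incidence
    inc_shape = c(0.8, 1.2, 1.1),   # age-group multipliers 18-39/40-59/60+
    prev_shape = c(0.8, 1.15, 1.1), # same, for the 2000 prevalence
    p0 = 0.28127,                   # overall adult MASLD prevalence, 2000
    mash_share0 = 0.28393,          # MASH share among prevalent cases, 2000
    rho = 0.045                     # initializer pool-removal rate
  )
}

#' Build an incidence schedule
#'
#' Annual probability of developing MASLD by age group (18--39, 40--59,
#' 60+) and calendar year: linear in year with a scenario-specific plateau
#' rule. In the base case incidence rises until 2030 and is constant
#' thereafter; in the best case it is constant after 2014; in the worst
#' case it keeps rising through 2050.
#'
#' @param scenario `"base"`, `"best_case"` or `"worst_case"`.
#' @param level Overall incidence level in 2000.
#' @param slope Annual additive increase of the overall level.
#' @param shape Length-3 age-group multipliers.
#' @param years Calendar years covered.
#' @return A `masld_schedule`: list with the 3 x length(years) probability
#'   matrix `mat` and the generating parameters.
#' @export
build_incidence_schedule <- function(scenario = c("base", "best_case",
                                                  "worst_case"),
                                     level = masld_defaults()$level,
                                     slope = masld_defaults()$slope,
                                     shape = masld_defaults()$inc_shape,
                                     years = 2000:2050) {
  scenario <- match.arg(scenario)
  stopifnot(length(shape) == 3, all(is.finite(c(level, slope, shape))))
  plateau <- switch(scenario, base = 2030, best_case = 2014,
                    worst_case = Inf)
  eff <- pmin(years, plateau) - 2000
  mat <- outer(shape, level + slope * eff)
  dimnames(mat) <- list(AGE_GROUPS, years)
  if (any(mat < 0) || any(mat > 1))
    stop("incidence escapes [0, 1] on the horizon")
  structure(list(mat = mat, years = years, scenario = scenario,
                 level = level, slope = slope, shape = shape,
                 plateau = plateau),
            class = "masld_schedule")
}

# Vectorized lookup: 0 below age 18 or outside the schedule's years.
incidence_at <- function(schedule, ages, year) {
  j <- match(year, schedule$years)
  if (is.na(j)) stop("year ", year, " outside the incidence schedule")
  g <- age_group_index(ages)
  out <- numeric(length(ages))
  adult <- !is.na(g)
  out[adult] <- schedule$mat[g[adult], j]
  out
}

age_group_index <- function(ages) {
  g <- 1L + (ages >= 40) + (ages >= 60)
  g[ages < 18] <- NA_integer_
  g
}

#' Construct an initial disease distribution
#'
#' The year-2000 disease state: age-group-specific MASLD prevalence
#' (overall scalar times an age shape) and the joint track/stage
#' distribution of prevalent cases, rescaled to a given MASH share.
#'
#' @param p0 Overall adult MASLD prevalence in 2000.
#' @param mash_share MASH proportion among prevalent cases in 2000.
#' @param params A `masld_params` object (stage mix comes from its
#'   fibrosis chain via [duration_weighted_stage_distribution()]).
#' @param prev_shape Length-3 age-group multipliers of `p0`.
#' @param joint Optional length-10 joint (track, stage) distribution to
#'   use instead of the duration-weighted default.
#' @param rho Removal rate passed to the duration-weighted initializer.
#' @return A `masld_init` object.
#' @export
masld_initial_state <- function(p0, mash_share,
                                params = masld_parameters(),
                                prev_shape = masld_defaults()$prev_shape,
                                joint = NULL,
                                rho = masld_defaults()$rho) {
  stopifnot(p0 >= 0, p0 <= 1, mash_share >= 0, mash_share <= 1,
            length(prev_shape) == 3)
  if (is.null(joint))
    joint <- duration_weighted_stage_distribution(params, rho = rho)
  stopifnot(length(joint) == 10, abs(sum(joint) - 1) < 1e-8)
  masl <- joint[1:5]; mash <- joint[6:10]
  joint <- c(masl * (1 - mash_share) / sum(masl),
             mash * mash_share / sum(mash))
  prev <- pmin(1, p0 * prev_shape)
  structure(list(prev_by_group = stats::setNames(prev, AGE_GROUPS),
                 joint = joint, p0 = p0, mash_share = mash_share),
            class = "masld_init")
}

# Assign initial disease states to adult agents in place (ambient RNG).
assign_initial_disease <- function(pop, init) {
  g <- age_group_index(pop$age)
  adult <- which(!is.na(g) & pop$state == S_NONE)
  p <- init$prev_by_group[g[adult]]
  sick <- adult[stats::runif(length(adult)) < p]
  if (length(sick)) {
    cls <- sample.int(10L, length(sick), replace = TRUE, prob = init$joint)
    pop$state[sick] <- S_MASLD
    pop$mash[sick] <- cls > 5L
    pop$fib[sick] <- as.integer((cls - 1L) %% 5L)
  }
  pop
}
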