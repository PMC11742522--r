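# Demographic machinery: bundled fixtures, life table, initial population,
# annual entrants. All counts in fixture files are persons; the engine
# divides by the scenario's person weight.

extdata <- function(file) {
  system.file("extdata", file, package = "masldsim", mustWork = TRUE)
}

#' Parametric sex-specific life table
#'
#' Builds an annual-probability life table with a Gompertz--Makeham shape,
#' `qx = A + B exp(c * age)`, plus an infant-mortality increment at age 0.
#' The bundled default constants are calibrated so that period life
#' expectancy at birth is about 75.7 years for males and 79.8 for females
#' (pooled about 77), matching the US around 2000. `qx` is clamped at 1
#' (with a warning if that happens before age 100) and forced to 1 at age
#' 100, the model's terminal age.
#'
#' @param makeham Named list per sex (`male`, `female`) of constants
#'   `A`, `B`, `c`, `q0`.
#' @return A `masld_lifetable`: 101 x 2 matrix of death probabilities,
#'   rows ages 0--100, columns `male`, `female`.
#' @export
make_life_table <- function(makeham = list(
  male   = c(A = 9e-4, B = 3.2e-5, c = 0.094, q0 = 0.0075),
  female = c(A = 4e-4, B = 1.75e-5, c = 0.099, q0 = 0.0061))) {
  ages <- 0:100
  qx <- sapply(makeham, function(p) {
    q <- p[["A"]] + p[["B"]] * exp(p[["c"]] * ages)
    q[1] <- q[1] + p[["q0"]]
    q
  })
  if (any(qx[1:100, ] > 1))
    warning("life-table parameters give qx > 1 before age 100; clamped")
  qx <- pmin(qx, 1)
  qx[101, ] <- 1
  colnames(qx) <- c("male", "female")
  rownames(qx) <- ages
  structure(qx, class = c("masld_lifetable", "matrix", "array"))
}

#' Period life expectancy at birth from a life table
#'
#' Standard life-table recursion with deaths spread mid-year.
#'
#' @param lt A `masld_lifetable`.
#' @param sex `"male"`, `"female"`, or `"both"` (unweighted mean).
#' @return Life expectancy at birth in years.
#' @export
life_expectancy <- function(lt, sex = "both") {
  e1 <- function(qx) {
    lx <- cumprod(c(1, 1 - qx[1:100]))
    sum(lx * (1 - qx) + 0.5 * lx * qx)
  }
  if (sex == "both") mean(c(e1(lt[, "male"]), e1(lt[, "female"])))
  else e1(lt[, sex])
}

#' Bundled model inputs
#'
#' Loads all bundled demographic fixtures: the 2000 age pyramid, the
#' births/net-migration/target-population series 2000--2050, the migrant age
#' distribution, the duration-dependent HCC and LT survival fixtures, and
#' the parametric life table. The fixtures are coarse published-shape
#' approximations stored as CSV so they can be swapped for registry extracts
#' without code changes.
#'
#' @param life_table Optionally a replacement `masld_lifetable`.
#' @return A `masld_inputs` list with elements `pyramid`, `series`,
#'   `migrant_ages`, `hcc_survival`, `lt_survival`, `life_table`.
#' @export
masld_inputs <- function(life_table = make_life_table()) {
  pyramid <- utils::read.csv(extdata("age_pyramid_2000.csv"))
  series <- utils::read.csv(extdata("demography_series.csv"))
  mig <- utils::read.csv(extdata("migrant_age_distribution.csv"))
  hcc <- utils::read.csv(extdata("hcc_survival.csv"))
  ltt <- utils::read.csv(extdata("lt_survival.csv"))
  structure(list(
    pyramid = pyramid,
    series = series,
    migrant_ages = mig,
    hcc_survival = hcc$annual_death_prob[order(hcc$years_since_dx)],
    lt_survival = lt_survival_matrix(ltt),
    life_table = life_table
  ), class = "masld_inputs")
}

# 3 x 11 matrix: rows age bands at transplant (18-49, 50-64, 65+),
# columns years since transplant 0-10+.
lt_survival_matrix <- function(df) {
  bands <- c("18-49", "50-64", "65+")
  m <- matrix(NA_real_, 3, 11, dimnames = list(bands, 0:10))
  for (i in seq_len(nrow(df)))
    m[df$age_band[i], as.character(df$years_since_lt[i])] <- df$annual_death_prob[i]
  if (anyNA(m)) stop("incomplete LT survival fixture")
  m
}

lt_band_index <- function(age_at_lt) {
  1L + (age_at_lt >= 50) + (age_at_lt >= 65)
}

#' Survival fixtures for HCC and liver transplant
#'
#' Returns the bundled duration-dependent annual death probabilities:
#' for HCC a vector over years since diagnosis (0--10+, first year about
#' 0.55 declining to 0.05 by year 10, a SEER-like conditional-survival
#' shape); for LT a matrix over age band at transplant (18--49, 50--64,
#' 65+) by years since transplant (elevated first-year mortality, then a
#' low plateau, higher in older bands). Durations beyond 10 years use the
#' 10+ value.
#'
#' @return List with elements `hcc` (length-11 vector) and `lt`
#'   (3 x 11 matrix).
#' @export
make_survival_fixtures <- function() {
  inp <- masld_inputs()
  list(hcc = inp$hcc_survival, lt = inp$lt_survival)
}

# Empty agent table with the canonical columns.
empty_population <- function(n = 0) {
  data.frame(
    age = integer(n), sex = integer(n), state = integer(n),
    fib = integer(n), mash = logical(n),
    ys_hcc = rep(NA_integer_, n), ys_lt = rep(NA_integer_, n),
    age_lt = rep(NA_integer_, n)
  )
}

#' Synthesize the initial population
#'
#' Draws `n` agents with ages sampled from the bundled US-2000-like age
#' pyramid and sex male with probability 0.491. All agents start in the
#' no-steatosis state; disease is assigned separately from an initial
#' disease distribution (see [back_calculate_initial_state()]).
#'
#' @param n Number of agents (>= 1).
#' @param seed RNG seed; the draw is seed-deterministic.
#' @param pyramid Age-weight data frame (columns `age`, `weight`);
#'   defaults to the bundled pyramid.
#' @return Agent data frame with columns `age`, `sex` (1 male, 2 female),
#'   `state`, `fib`, `mash`, `ys_hcc`, `ys_lt`, `age_lt`.
#' @export
synthesize_initial_population <- function(n, seed = 1L, pyramid = NULL) {
  if (length(n) != 1 || !is.finite(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  if (is.null(pyramid)) pyramid <- masld_inputs()$pyramid
  set.seed(as.integer(seed))
  pop <- empty_population(n)
  pop$age <- sample(pyramid$age, n, replace = TRUE, prob = pyramid$weight)
  pop$sex <- ifelse(stats::runif(n) < 0.491, 1L, 2L)
  pop$state <- rep(S_NONE, n)
  pop$fib <- rep(NA_integer_, n)
  pop
}

# Stochastic rounding: floor(x) plus a Bernoulli on the fractional part,
# so expected counts are unbiased at small agent counts.
stoch_round <- function(x) {
  f <- floor(x)
  as.integer(f + (stats::runif(length(x)) < (x - f)))
}

#' Annual entrant batch (births and net migrants)
#'
#' Builds the agent batch entering the population at the end of a model
#' year: newborns at age 0 and migrants with ages drawn from the bundled
#' migrant age distribution, both disease-free. Person counts from the
#' demography series are scaled by `1 / person_weight` and rounded
#' stochastically so expected agent counts are unbiased. Newborn sex is
#' male with probability 0.512 (sex ratio at birth), migrant sex 0.5.
#' Uses the ambient RNG stream; seed at the caller.
#'
#' @param series Demography series data frame (`year`, `births`,
#'   `net_migrants`, ...).
#' @param year Calendar year, must be within the series.
#' @param person_weight Persons represented by one agent.
#' @param migrant_ages Migrant age-band distribution data frame.
#' @return Agent data frame (possibly empty).
#' @export
annual_entrants <- function(series, year, person_weight,
                            migrant_ages = masld_inputs()$migrant_ages) {
  i <- match(year, series$year)
  if (is.na(i)) stop("year ", year, " outside the demography series")
  nb <- stoch_round(series$births[i] / person_weight)
  nm <- stoch_round(series$net_migrants[i] / person_weight)
  out <- empty_population(nb + nm)
  if (nb + nm == 0) return(out)
  out$state <- rep(S_NONE, nb + nm)
  out$fib <- rep(NA_integer_, nb + nm)
  out$age <- c(rep(0L, nb), sample_migrant_ages(nm, migrant_ages))
  out$sex <- ifelse(stats::runif(nb + nm) <
                      c(rep(0.512, nb), rep(0.5, nm)), 1L, 2L)
  out
}

sample_migrant_ages <- function(n, migrant_ages) {
  if (n == 0) return(integer(0))
  band <- sample.int(nrow(migrant_ages), n, replace = TRUE,
                     prob = migrant_ages$weight)
  lo <- migrant_ages$age_lo[band]
  hi <- migrant_ages$age_hi[band]
  as.integer(lo + floor(stats::runif(n) * (hi - lo + 1)))
}
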