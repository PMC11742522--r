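# Shared fixtures, all built in code.

params_t1 <- masld_parameters()
inputs_std <- masld_inputs()

# Inputs with a constant background death probability at every age
# (closed-cohort experiments; the terminal-age rule is irrelevant there).
const_qx_inputs <- function(qx) {
  inp <- masld_inputs()
  inp$life_table[, ] <- qx
  inp
}

# Flat incidence schedule: the same annual probability for every adult
# age group and year.
const_schedule <- function(p) {
  build_incidence_schedule("base", level = p, slope = 0, shape = c(1, 1, 1))
}
zero_schedule <- const_schedule(0)

# Homogeneous cohort population.
cohort_pop <- function(n, state = "masld", fib = 0L, mash = FALSE,
                       age = 40L, ys_hcc = 0L, ys_lt = 0L) {
  code <- switch(state, none = 1L, masld = 2L, dc = 3L, hcc = 4L, lt = 5L)
  data.frame(
    age = rep(as.integer(age), n), sex = rep(1:2, length.out = n),
    state = rep(code, n),
    fib = if (code == 2L) rep(as.integer(fib), n) else rep(NA_integer_, n),
    mash = if (code == 2L) rep(mash, n) else rep(FALSE, n),
    ys_hcc = if (code == 4L) rep(as.integer(ys_hcc), n) else
      rep(NA_integer_, n),
    ys_lt = if (code == 5L) rep(as.integer(ys_lt), n) else
      rep(NA_integer_, n),
    age_lt = if (code == 5L) rep(as.integer(age), n) else
      rep(NA_integer_, n))
}

# Occupancy of the expanded 36-state space as fractions of the table.
pop_occupancy <- function(pop) {
  idx <- integer(nrow(pop))
  st <- pop$state
  idx[st == 1L] <- 1L
  m <- st == 2L
  idx[m] <- ifelse(pop$mash[m], 7L, 2L) + pop$fib[m]
  idx[st == 3L] <- 12L
  h <- st == 4L
  idx[h] <- 13L + pmin(pop$ys_hcc[h], 10L)
  l <- st == 5L
  idx[l] <- 24L + pmin(pop$ys_lt[l], 10L)
  idx[st == 6L] <- 35L
  idx[st == 7L] <- 36L
  tabulate(idx, 36L) / nrow(pop)
}

# Closed-cohort engine run (no entrants), returning per-cycle occupancy.
run_closed <- function(pop, k, qx = 0, incidence = 0, seed = 1,
                       params = params_t1) {
  inp <- const_qx_inputs(qx)
  sched <- const_schedule(incidence)
  set.seed(seed)
  occ <- matrix(NA_real_, k + 1, 36)
  occ[1, ] <- pop_occupancy(pop)
  for (i in seq_len(k)) {
    res <- step_cycle(pop, 2000 + i, params, sched, inp, entrants = FALSE)
    pop <- res$pop
    occ[i + 1, ] <- pop_occupancy(pop)
  }
  list(occ = occ, pop = pop)
}

# Mixed-state cohort covering every region of the state space, plus its
# exact initial occupancy vector.
mixed_cohort <- function(n, age = 20L) {
  frac <- c(none = 0.40, masl0 = 0.10, masl1 = 0.08, masl2 = 0.06,
            masl3 = 0.04, masl4 = 0.04, mash0 = 0.06, mash1 = 0.05,
            mash2 = 0.04, mash3 = 0.03, mash4 = 0.02, dc = 0.05,
            hcc = 0.03)
  counts <- round(n * frac)
  counts["none"] <- n - sum(counts[-1])
  pieces <- list(
    cohort_pop(counts["none"], "none", age = age),
    cohort_pop(counts["masl0"], "masld", 0, FALSE, age),
    cohort_pop(counts["masl1"], "masld", 1, FALSE, age),
    cohort_pop(counts["masl2"], "masld", 2, FALSE, age),
    cohort_pop(counts["masl3"], "masld", 3, FALSE, age),
    cohort_pop(counts["masl4"], "masld", 4, FALSE, age),
    cohort_pop(counts["mash0"], "masld", 0, TRUE, age),
    cohort_pop(counts["mash1"], "masld", 1, TRUE, age),
    cohort_pop(counts["mash2"], "masld", 2, TRUE, age),
    cohort_pop(counts["mash3"], "masld", 3, TRUE, age),
    cohort_pop(counts["mash4"], "masld", 4, TRUE, age),
    cohort_pop(counts["dc"], "dc", age = age),
    cohort_pop(counts["hcc"], "hcc", age = age))
  pop <- do.call(rbind, pieces)
  list(pop = pop, init = pop_occupancy(pop))
}
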