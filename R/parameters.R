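# Canonical parameter names. Order matters only for printing.
PARAM_NAMES <- c(
  "masl_f0_to_f1", "masl_f1_to_f0", "masl_f1_to_f2", "masl_f2_to_f1",
  "masl_f2_to_f3", "masl_f3_to_f2", "masl_f3_to_f4", "masl_f4_to_f3",
  "mash_f0_to_f1", "mash_f1_to_f0", "mash_f1_to_f2", "mash_f2_to_f1",
  "mash_f2_to_f3", "mash_f3_to_f2", "mash_f3_to_f4", "mash_f4_to_f3",
  "mash_onset", "mash_resolution",
  "f4_to_dc", "f3_to_hcc", "f4_to_hcc", "dc_to_hcc",
  "lt_rate", "dc_mortality", "hr_masld"
)

#' Default annual transition probabilities
#'
#' Loads the bundled parameter file: the annual per-person transition
#' probabilities between the model's liver health states (parallel MASL and
#' MASH fibrosis tracks F0--F4, decompensated cirrhosis, hepatocellular
#' carcinoma, liver transplant), the MASLD all-cause mortality hazard ratio,
#' and, where published, the uncertainty range of each probability.
#' Calibrated quantities (MASH onset and resolution, the transplant rate,
#' the hazard ratio) carry no range and are excluded from one-way sweeps.
#'
#' @return A `masld_params` object: list with named numeric vectors
#'   `values`, `lo` and `hi` (the latter two `NA` where no range is
#'   published).
#' @seealso [load_parameters()], [apply_overrides()], [ci_sweep_specs()]
#' @export
#' @examples
#' p <- masld_parameters()
#' p$values[["mash_f3_to_f4"]]
masld_parameters <- function() {
  load_parameters(system.file("extdata", "parameters.yaml",
                              package = "masldsim", mustWork = TRUE))
}

#' Load and validate a parameter file
#'
#' Reads a YAML (or JSON, which YAML subsumes) parameter file with one entry
#' per transition probability, each a mapping with a `value` and an optional
#' `low`/`high` range, and validates it: every canonical name must be
#' present, probabilities must lie in \[0, 1\], the hazard ratio must be
#' at least 1, ranges must bracket the base value, and the total exit
#' probability out of every health state must not exceed 1.
#'
#' @param path Path to the parameter file.
#' @return A validated `masld_params` object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  missing <- setdiff(PARAM_NAMES, names(raw))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(raw), PARAM_NAMES)
  if (length(extra))
    stop("unknown parameter(s): ", paste(extra, collapse = ", "))
  get1 <- function(nm, fld) {
    v <- raw[[nm]][[fld]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  ps <- structure(list(
    values = vapply(PARAM_NAMES, get1, numeric(1), fld = "value"),
    lo     = vapply(PARAM_NAMES, get1, numeric(1), fld = "low"),
    hi     = vapply(PARAM_NAMES, get1, numeric(1), fld = "high")
  ), class = "masld_params")
  validate_parameters(ps)
  ps
}

#' Write a parameter set back to YAML
#'
#' Inverse of [load_parameters()]; a load/write/load round trip yields an
#' identical parameter set.
#'
#' @param ps A `masld_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(ps, path) {
  stopifnot(inherits(ps, "masld_params"))
  out <- lapply(PARAM_NAMES, function(nm) {
    e <- list(value = unname(ps$values[[nm]]))
    if (!is.na(ps$lo[[nm]])) {
      e$low <- unname(ps$lo[[nm]])
      e$high <- unname(ps$hi[[nm]])
    }
    e
  })
  names(out) <- PARAM_NAMES
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

# Total exit probability per source state, excluding mortality. Incidence
# enters the MASL F0 row as the steatosis-regression term (half the
# incidence); it is bounded by its worst case 0.5 here.
state_exit_sums <- function(v) {
  c(masl_f0 = 0.5 + v[["masl_f0_to_f1"]] + v[["mash_onset"]],
    masl_f1 = v[["masl_f1_to_f0"]] + v[["masl_f1_to_f2"]] + v[["mash_onset"]],
    masl_f2 = v[["masl_f2_to_f1"]] + v[["masl_f2_to_f3"]] + v[["mash_onset"]],
    masl_f3 = v[["masl_f3_to_f2"]] + v[["masl_f3_to_f4"]] + v[["f3_to_hcc"]],
    masl_f4 = v[["masl_f4_to_f3"]] + v[["f4_to_dc"]] + v[["f4_to_hcc"]],
    mash_f0 = v[["mash_f0_to_f1"]] + v[["mash_resolution"]],
    mash_f1 = v[["mash_f1_to_f0"]] + v[["mash_f1_to_f2"]] + v[["mash_resolution"]],
    mash_f2 = v[["mash_f2_to_f1"]] + v[["mash_f2_to_f3"]] + v[["mash_resolution"]],
    mash_f3 = v[["mash_f3_to_f2"]] + v[["mash_f3_to_f4"]] + v[["f3_to_hcc"]],
    mash_f4 = v[["mash_f4_to_f3"]] + v[["f4_to_dc"]] + v[["f4_to_hcc"]],
    dc      = v[["dc_to_hcc"]] + v[["lt_rate"]],
    hcc     = v[["lt_rate"]])
}

# Range bracketing (low <= base <= high) is a property of the published
# table and is enforced at load time only: overrides may legitimately
# step outside a published range in sensitivity explorations.
validate_parameters <- function(ps, check_ranges = TRUE) {
  v <- ps$values
  probs <- v[setdiff(PARAM_NAMES, "hr_masld")]
  bad <- names(probs)[!is.finite(probs) | probs < 0 | probs > 1]
  if (length(bad))
    stop("probability outside [0, 1]: ", paste(bad, collapse = ", "))
  if (!is.finite(v[["hr_masld"]]) || v[["hr_masld"]] < 1)
    stop("hr_masld must be >= 1, got ", v[["hr_masld"]])
  if (check_ranges) {
    has_rng <- !is.na(ps$lo)
    if (any(is.na(ps$hi[has_rng])) || any(!is.na(ps$hi) & is.na(ps$lo)))
      stop("a range must give both low and high")
    bad <- PARAM_NAMES[has_rng & (ps$lo > v | ps$hi < v)]
    if (length(bad))
      stop("base value outside its range: ", paste(bad, collapse = ", "))
  }
  ex <- state_exit_sums(v)
  if (any(ex > 1))
    stop("exit probabilities exceed 1 for state(s): ",
         paste(names(ex)[ex > 1], collapse = ", "))
  invisible(ps)
}

#' Override parameter values
#'
#' Returns a copy of `ps` with the named values replaced and the result
#' revalidated; the original object is unchanged. Used by the one-way
#' sensitivity sweeps and by calibration.
#'
#' @param ps A `masld_params` object.
#' @param overrides Named numeric vector or list of replacement values.
#' @return A new validated `masld_params` object.
#' @export
#' @examples
#' p <- apply_overrides(masld_parameters(), c(f4_to_dc = 0.0286))
apply_overrides <- function(ps, overrides) {
  stopifnot(inherits(ps, "masld_params"))
  overrides <- unlist(overrides)
  if (length(overrides) == 0) return(ps)
  unknown <- setdiff(names(overrides), PARAM_NAMES)
  if (length(unknown))
    stop("unknown parameter(s) in overrides: ", paste(unknown, collapse = ", "))
  ps2 <- ps
  ps2$values[names(overrides)] <- as.numeric(overrides)
  validate_parameters(ps2, check_ranges = FALSE)
  ps2
}

#' One-way sensitivity sweep specifications
#'
#' For every parameter with a published range, produces two scenario
#' specifications — one with the parameter at its low endpoint, one at its
#' high endpoint, everything else at base value. Parameters without a range
#' (the calibrated ones) are skipped.
#'
#' @param ps A `masld_params` object.
#' @param base A `masld_scenario` the endpoint overrides are attached to.
#' @return A list of `masld_scenario` objects, named
#'   `<parameter>_low` / `<parameter>_high`.
#' @export
ci_sweep_specs <- function(ps, base = masld_scenario()) {
  stopifnot(inherits(ps, "masld_params"))
  ranged <- PARAM_NAMES[!is.na(ps$lo)]
  specs <- list()
  for (nm in ranged) {
    for (end in c("low", "high")) {
      val <- if (end == "low") ps$lo[[nm]] else ps$hi[[nm]]
      sp <- base
      sp$overrides <- stats::setNames(val, nm)
      sp$label <- paste0(nm, "_", end)
      specs[[sp$label]] <- sp
    }
  }
  specs
}

#' @export
print.masld_params <- function(x, ...) {
  cat("MASLD annual transition probabilities (per person per year)\n")
  rng <- ifelse(is.na(x$lo), "",
                sprintf("  [%.4f, %.4f]", x$lo, x$hi))
  cat(sprintf("  %-16s %.4f%s", PARAM_NAMES, x$values, rng), sep = "\n")
  invisible(x)
}
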