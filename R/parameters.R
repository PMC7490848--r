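# Model constants, units, time-step scaling and configuration handling.
#
# All rate and normalizing constants are stored in per-day units; the
# time-step length (`step_days`, default 5) is part of the parameter set and
# process code converts explicitly via per_step(). Energies are kJ, masses g
# wet weight, lengths cm, velocities km h^-1. Temperatures are Kelvin inside
# the metabolic equations and degrees Celsius for behavioural thresholds.

#' @keywords internal
.param_units <- c(
  a_AMR = "kJ day-1 g-b_AMR (km h-1)-c_AMR", A_e = "proportion",
  a_f = "eggs cm-b_f", A_r = "dimensionless", a_SMR = "kJ day-1 g-b_SMR",
  a_v = "km h-1 cm-b_v", b_AMR = "dimensionless", b_f = "dimensionless",
  b_SMR = "dimensionless", b_v = "dimensionless", c = "g-1 patch",
  c_AMR = "dimensionless", C_max = "g g-1 day-1", c_v = "dimensionless",
  E_a = "eV", E_flesh = "kJ g-1", E_lipid = "kJ g-1",
  E_max = "proportion of structural mass", E_phyto = "kJ g-1",
  E_sf = "kJ g-1", E_sl = "kJ g-1", h = "g m-2",
  IR_cannibalism = "proportion", k = "day-1", K = "eV K-1", k_1 = "day-1",
  L_1 = "cm", L_inf = "cm", L_hatch = "cm", L_mat = "cm",
  M_a = "day-1", M_e = "day-1", n_b = "batches season-1", SST_lim = "degC",
  t_max = "days",
  # constants not fixed by the core table; configurable with documented
  # defaults (see the methods vignette)
  T_ref = "K", a_w = "g cm-b_w", b_w = "dimensionless", M_0 = "g",
  b_int = "days", t_0 = "days", growth_switch_age = "days",
  step_days = "days", n_cohort = "SIs year-1", max_age_years = "years",
  season_days = "days", spinup_years = "years",
  prey_ratio = "dimensionless", prey_length_max = "cm",
  L_larva = "cm", L_juv = "cm", egg_dev_days = "days",
  F_msy_mult = "dimensionless", F_lim_mult = "dimensionless",
  stop_dist_max = "patches"
)

# per-day rate constants that scale linearly with the step length
.rate_params <- c("C_max", "k", "k_1", "M_a", "M_e")

#' Default model parameters
#'
#' Returns the full set of model constants: the published bioenergetic,
#' movement, mortality and reproduction constants for Northeast Atlantic
#' mackerel, plus the structural constants (reference temperature,
#' length-mass allometry, egg mass, inter-batch interval, time-step length)
#' that are configurable with documented defaults.
#'
#' @return A named list of class `parameter_set`. Each element is a numeric
#'   scalar; the `units` attribute carries a unit tag per field.
#' @export
#' @examples
#' p <- default_parameters()
#' p$h      # half-saturation constant, g m-2
#' p$M_e    # background early mortality, day-1
default_parameters <- function() {
  p <- list(
    a_AMR = 8.86e7, A_e = 0.95, a_f = 8.80, A_r = 4.01, a_SMR = 0.45e8,
    a_v = 0.15, b_AMR = 0.75, b_f = 3.02, b_SMR = 0.75, b_v = 0.62,
    c = 9.71e-11, c_AMR = 1, C_max = 0.69, c_v = 0.35, E_a = 0.5,
    E_flesh = 7.00, E_lipid = 39.3, E_max = 0.78, E_phyto = 6.02,
    E_sf = 3.60, E_sl = 14.7, h = 1.26, IR_cannibalism = 0.064,
    k = 8.6e-4, K = 8.62e-5, k_1 = 0.025, L_1 = 20, L_inf = 42.4,
    L_hatch = 0.3, L_mat = 26.2, M_a = 0.00041, M_e = 0.287, n_b = 5,
    SST_lim = 7, t_max = 55,
    # structural defaults
    T_ref = 283.15,        # reference temperature: 10 degC, mid spawning window
    a_w = 0.0049, b_w = 3.17,  # scombrid length-structural mass allometry
    M_0 = 0.001,           # egg wet mass, g
    b_int = 12,            # inter-batch interval so n_b * b_int = season
    t_0 = NA_real_,        # von Bertalanffy shift; NA = continuity default
    growth_switch_age = 240,
    step_days = 5, n_cohort = 70, max_age_years = 15,
    season_days = 60, spinup_years = 10,
    prey_ratio = 3.5, prey_length_max = 0.33,
    L_larva = 0.61, L_juv = 3, egg_dev_days = 5,
    F_msy_mult = 0.83, F_lim_mult = 1.66,
    stop_dist_max = 10
  )
  # default t_0 makes the adult von Bertalanffy curve continuous with the
  # first-season Gompertz curve at the growth-phase switch age
  L_switch <- p$L_1 * exp(-exp(-p$k_1 * (p$growth_switch_age - p$t_max)))
  p$t_0 <- p$growth_switch_age + log(1 - L_switch / p$L_inf) / p$k
  structure(p, units = .param_units, class = "parameter_set")
}

#' Load and validate a parameter set
#'
#' Builds a `parameter_set` from the defaults with overrides applied.
#' Overrides may be given as a named list, or as a path to a YAML
#' configuration file whose `parameters` section holds the overrides.
#'
#' @param config `NULL` (pure defaults), a named list of overrides, or a
#'   path to a YAML file with a `parameters` section.
#' @return A validated `parameter_set`.
#' @export
#' @examples
#' p <- load_parameters(list(h = 2.0, step_days = 5))
#' per_step(p, "M_a")  # per-time-step background mortality
load_parameters <- function(config = NULL) {
  p <- default_parameters()
  overrides <- list()
  if (is.character(config) && length(config) == 1) {
    doc <- yaml::read_yaml(config)
    overrides <- doc$parameters %||% list()
  } else if (is.list(config)) {
    overrides <- if (!is.null(config$parameters)) config$parameters else config
  } else if (!is.null(config)) {
    stop("`config` must be NULL, a named list, or a YAML file path")
  }
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown)) {
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
    }
    for (nm in names(overrides)) p[[nm]] <- as.numeric(overrides[[nm]])
  }
  validate_parameters(p)
}

#' @keywords internal
validate_parameters <- function(p) {
  stopifnot(is.list(p))
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1, logical(1))
  if (!all(num)) stop("non-scalar parameter value(s): ",
                      paste(names(p)[!num], collapse = ", "))
  if (!(p$A_e > 0 && p$A_e <= 1)) {
    stop("assimilation efficiency A_e must lie in (0, 1], got ", p$A_e)
  }
  if (!(p$IR_cannibalism >= 0 && p$IR_cannibalism < 1)) {
    stop("IR_cannibalism must lie in [0, 1), got ", p$IR_cannibalism)
  }
  if (!(p$E_max > 0)) stop("E_max must be positive")
  rates <- c(.rate_params, "M_a", "M_e", "a_SMR", "a_AMR", "a_v", "a_f",
             "h", "C_max")
  bad <- rates[vapply(rates, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bad)) stop("negative rate constant(s): ", paste(bad, collapse = ", "))
  if (p$step_days <= 0) stop("step_days must be positive")
  if (abs(p$n_b * p$b_int - p$season_days) > 1e-9) {
    stop("n_b * b_int (", p$n_b * p$b_int,
         ") must equal the spawning season length (", p$season_days, " days)")
  }
  structure(p, units = .param_units[names(p)], class = "parameter_set")
}

#' Per-time-step value of a per-day rate constant
#'
#' @param p A `parameter_set`.
#' @param name Parameter name (a per-day rate).
#' @return The rate multiplied by the step length in days.
#' @export
per_step <- function(p, name) {
  p[[name]] * p$step_days
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> ", length(x), " constants; step = ",
      x$step_days, " days\n", sep = "")
  u <- attr(x, "units")
  df <- data.frame(value = unlist(x), unit = u[names(x)], row.names = names(x))
  print(df, ...)
  invisible(x)
}

#' Serialize a parameter set to YAML
#'
#' `write_parameters()` and re-loading through [load_parameters()] round-trip
#' to an identical set.
#'
#' @param p A `parameter_set`.
#' @param path Output file path.
#' @export
write_parameters <- function(p, path) {
  yaml::write_yaml(list(parameters = lapply(unclass(p), identity)), path)
  invisible(path)
}

#' Fishing-mortality scenario multipliers
#'
#' Converts a mean historical fishing mortality-at-age vector into a scenario
#' F-at-age: unchanged (`historical-mean`), zero, the maximum-sustainable-
#' yield rate (`fmsy`, multiplier 0.83) or the upper-limit reference rate
#' (`flim`, multiplier 1.66).
#'
#' @param mean_F_at_age Named numeric vector of annual F (year-1), names
#'   "0".."15" covering ages 0 to 15.
#' @param scenario One of `"historical-mean"`, `"zero"`, `"fmsy"`, `"flim"`.
#' @param p A `parameter_set` (supplies the two multipliers).
#' @return Per-age annual F vector, same names as the input.
#' @export
#' @examples
#' f <- stats::setNames(rep(0.277, 16), 0:15)
#' scenario_F(f, "fmsy")["5"]   # ~0.23 year-1
scenario_F <- function(mean_F_at_age,
                       scenario = c("historical-mean", "zero", "fmsy", "flim"),
                       p = default_parameters()) {
  scenario <- match.arg(scenario)
  need <- as.character(0:15)
  if (is.null(names(mean_F_at_age)) ||
      length(miss <- setdiff(need, names(mean_F_at_age)))) {
    stop("mean_F_at_age must be named by age 0..15; missing: ",
         paste(if (is.null(names(mean_F_at_age))) need else miss,
               collapse = ", "))
  }
  f <- mean_F_at_age[need]
  switch(scenario,
    "historical-mean" = f,
    zero = f * 0,
    fmsy = f * p$F_msy_mult,
    flim = f * p$F_lim_mult
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
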