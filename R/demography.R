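# Mortality channels (background, starvation, predation, fishing),
# fishing-rate scheduling and recruitment.

#' Background mortality rate
#'
#' Eggs, yolk-sac larvae and larvae die at the constant early rate `M_e`;
#' juveniles at `M_a (L_mat / L)` (susceptibility declines with length,
#' reaching the adult rate at the maturity threshold); adults at the
#' constant `M_a`.
#'
#' @param pop Population data.frame.
#' @param p A `parameter_set`.
#' @return Per-day mortality rate vector.
#' @export
background_mortality <- function(pop, p) {
  ifelse(pop$stage <= STAGE_LARVA, p$M_e,
         ifelse(pop$stage == STAGE_JUVENILE, p$M_a * p$L_mat / pop$L, p$M_a))
}

#' Apply mortality rates to SI abundances
#'
#' Abundance is scaled by `exp(-(M_back + F) dt)`, i.e. the fraction
#' `1 - exp(-(M_back + F) dt)` dies. SIs whose abundance falls below one
#' are removed from the model.
#'
#' @param pop Population data.frame.
#' @param M_back Background rate per day (vector).
#' @param F_rate Fishing rate per day (vector).
#' @param step_days Step length, days.
#' @return The population with abundances updated and sub-unit SIs dropped.
#' @export
apply_mortality <- function(pop, M_back, F_rate, step_days) {
  pop$abundance <- pop$abundance * exp(-(M_back + F_rate) * step_days)
  pop[pop$abundance >= 1, , drop = FALSE]
}

#' Predation (cannibalism) mortality on a prey SI
#'
#' The number of prey individuals eaten is the predator SI's total
#' mackerel-prey intake (its per-capita ingestion times the cannibalism
#' share, summed over the predator's abundance) divided by prey body mass.
#' Removal is capped at the prey's abundance.
#'
#' @param prey_abundance Prey SI abundance.
#' @param prey_mass Prey individual body mass, g.
#' @param predator_abundance Predator SI abundance.
#' @param predator_IR Predator per-capita ingestion, g per step.
#' @param p A `parameter_set`.
#' @return The prey abundance after predation.
#' @export
predation_mortality <- function(prey_abundance, prey_mass,
                                predator_abundance, predator_IR, p) {
  eaten <- predator_abundance * predator_IR * p$IR_cannibalism / prey_mass
  pmax(prey_abundance - eaten, 0)
}

#' Remove starved SIs
#'
#' An SI whose total mass has fallen to its structural mass (reserves and
#' gonads exhausted after an unmet energy demand) is removed. Larvae are
#' exempt until they have fed successfully once (they prioritise growth and
#' carry no reserves).
#'
#' @param pop Population data.frame.
#' @return The population without starved SIs.
#' @export
starvation_check <- function(pop) {
  starved <- pop$starving & pop$reserve <= 0 & pop$M_gon <= 0 &
    (pop$stage >= STAGE_JUVENILE | (pop$stage == STAGE_LARVA & pop$has_fed))
  pop[!starved, , drop = FALSE]
}

#' Build a fishing schedule
#'
#' Holds annual F-at-age (year-1) per simulated year and the monthly catch
#' fractions used to apportion each year's F within the year. The per-day F
#' in month m is `F_annual(age) frac(m) / days_in_month(m)`.
#'
#' @param F_at_age Matrix (years x 16 ages, 0..15) of annual F, or a single
#'   named vector recycled over years.
#' @param month_frac 12 non-negative fractions summing to 1.
#' @param years Number of simulated years the schedule must cover.
#' @return An object of class `fishing_schedule`.
#' @export
make_fishing_schedule <- function(F_at_age, month_frac, years) {
  if (is.null(dim(F_at_age))) {
    F_at_age <- matrix(rep(F_at_age, years), nrow = years, byrow = TRUE)
  }
  if (ncol(F_at_age) != 16) stop("F_at_age must cover ages 0..15")
  if (nrow(F_at_age) < years) stop("fishing schedule covers ",
                                   nrow(F_at_age), " < ", years, " years")
  if (length(month_frac) != 12 || any(month_frac < 0)) {
    stop("month_frac must be 12 non-negative values")
  }
  if (abs(sum(month_frac) - 1) > 1e-8) {
    stop("month_frac must sum to 1 (got ", sum(month_frac), ")")
  }
  structure(list(F_at_age = F_at_age, month_frac = month_frac),
            class = "fishing_schedule")
}

#' Per-day fishing mortality for each SI
#'
#' @param schedule A `fishing_schedule`.
#' @param year_index Simulated year (1-based).
#' @param month Calendar month (1..12).
#' @param age_years Integer ages of the SIs.
#' @return Per-day F vector.
#' @export
fishing_rate <- function(schedule, year_index, month, age_years) {
  fa <- schedule$F_at_age[year_index, pmin(age_years, 15L) + 1L]
  fa * schedule$month_frac[month] / days_in_month(month)
}

#' Create the year's emergent-recruitment egg SIs for one batch event
#'
#' The season's egg production is divided equally among `n_cohort` new SIs;
#' the share entering at this batch event is spread over `n_new` SIs placed
#' at spawners' locations.
#'
#' @param total_eggs Eggs produced at this batch event (individuals).
#' @param n_new Number of SIs to create for the event.
#' @param positions Two-column matrix of spawner positions to sample from
#'   (weighted by `weights`).
#' @param weights Egg contribution of each spawner position.
#' @param p A `parameter_set`.
#' @param next_id First SI id to assign.
#' @return Population data.frame of new egg SIs (possibly zero rows when
#'   egg production is zero).
#' @export
recruit_emergent <- function(total_eggs, n_new, positions, weights, p,
                             next_id = 1L) {
  if (total_eggs <= 0 || n_new < 1) return(empty_population(0))
  newp <- empty_population(n_new)
  newp$id <- seq.int(next_id, length.out = n_new)
  newp$abundance <- total_eggs / n_new
  newp$stage <- STAGE_EGG
  newp$gender <- rep_len(c(1L, 2L), n_new)
  newp$L <- 0.1
  newp$M_struct <- p$M_0
  newp$age_years <- 0L
  wsum <- sum(weights)
  pr <- if (wsum > 0) weights / wsum else rep(1 / nrow(positions), nrow(positions))
  pick <- sample.int(nrow(positions), n_new, replace = TRUE, prob = pr)
  newp$x <- positions[pick, 1]
  newp$y <- positions[pick, 2]
  newp$mig_mode <- MIG_NONE
  newp
}

#' Ricker stock-recruitment with an SST covariate
#'
#' `R = alpha SSB exp(-beta SSB + gamma SST_mean)`, the conventional
#' temperature-covariate Ricker curve. Coefficients are user-supplied (the
#' fitted values are not part of this package).
#'
#' @param SSB Spawning-stock biomass.
#' @param mean_SST Mean SST over the designated Ricker spawning area, degC.
#' @param coefficients Named list or vector with `alpha`, `beta`, `gamma`.
#' @return Number of recruits.
#' @export
recruit_ricker <- function(SSB, mean_SST, coefficients) {
  co <- as.list(coefficients)
  if (!all(c("alpha", "beta", "gamma") %in% names(co))) {
    stop("Ricker coefficients must supply alpha, beta and gamma")
  }
  co$alpha * SSB * exp(-co$beta * SSB + co$gamma * mean_SST)
}

#' Read an F-at-age CSV (year x age matrix)
#'
#' @param path CSV with a `year` column and columns `age0`..`age15`.
#' @export
read_F_at_age <- function(path) {
  df <- utils::read.csv(path)
  cols <- paste0("age", 0:15)
  stopifnot(all(cols %in% names(df)))
  as.matrix(df[, cols])
}

#' Read monthly catch fractions
#' @param path CSV with columns `month`, `fraction`.
#' @export
read_month_fractions <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("month", "fraction") %in% names(df)))
  df$fraction[order(df$month)]
}
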