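# Simulation calendar: a fixed 365-day year (leap days ignored so the 5-day
# step cadence is stable; 73 steps per year). Dates are (year index, day of
# year); events bind to the step that contains their date.

.month_days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
.month_start <- cumsum(c(1, .month_days[-12]))

#' @keywords internal
month_of_doy <- function(doy) {
  findInterval(doy, .month_start)
}

#' @keywords internal
days_in_month <- function(m) .month_days[m]

# day-of-year for fixed calendar events
.event_doy <- list(
  spawning_migration = 32,   # Feb 1: maturation census + departure
  maturation = 32,
  ogive_census = 41,         # Feb 10
  spawning_start = 60,       # Mar 1: potential fecundity, season opens
  q1_juvenile_census = 75,   # Mar 16
  feeding_migration = 121,   # May 1: departure + spawning SSB census
  spawning_ssb = 121,
  egg_production_census = 152, # Jun 1
  summer_ssb = 213,          # Aug 1: summer SSB, age structure, weight-at-age
  overwinter_migration = 274, # Oct 1
  fast_onset = 305,          # Nov 1
  q4_juvenile_census = 327,  # Nov 23
  recruitment_census = 365   # Dec 31: recruitment, ageing, cohort turnover
)

#' Build the run calendar
#'
#' @param start_year First simulated calendar year.
#' @param years Number of years to simulate.
#' @param step_days Step length in days (must divide 365).
#' @return A list with the step table (`step`, `year`, `doy_start`,
#'   `doy_end`, `abs_day_start`) and the event day-of-year table.
#' @export
make_calendar <- function(start_year, years, step_days = 5) {
  if (365 %% step_days != 0) stop("step_days must divide the 365-day year")
  steps_per_year <- 365 %/% step_days
  n <- steps_per_year * years
  step <- seq_len(n)
  doy_start <- ((step - 1) %% steps_per_year) * step_days + 1
  list(
    start_year = start_year,
    years = years,
    step_days = step_days,
    steps_per_year = steps_per_year,
    n_steps = n,
    step_year = (step - 1) %/% steps_per_year + 1,
    doy_start = doy_start,
    doy_end = doy_start + step_days - 1,
    events = .event_doy
  )
}

# does the step [doy_start, doy_end] contain day-of-year `doy`?
#' @keywords internal
step_contains <- function(doy_start, doy_end, doy) {
  doy >= doy_start & doy <= doy_end
}

# first step of a month: the step containing the month's first day
#' @keywords internal
month_starting <- function(doy_start, doy_end) {
  m <- .month_start
  m[m >= doy_start & m <= doy_end]
}
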