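# Synthetic test worlds and pseudo-observations with known ground truth:
# every input the simulator needs, generated reproducibly from a seed.

#' A complete small runnable world
#'
#' Assembles a configuration for a small synthetic world: a 40 x 40 grid
#' with a shelf-edge corridor, five years of seeded forcing, a flat fishing
#' table and exponentially declining numbers-at-age — everything
#' [run_simulation()] needs, in seconds. With `test_scale = TRUE` (the
#' default here) the SI count is reduced below the production 1050-multiple
#' rule, which stays strict outside of test scale.
#'
#' @param seed Master seed.
#' @param nx,ny Grid dimensions.
#' @param n_SI Number of SIs (multiple of 15; production rule requires a
#'   multiple of 1050 unless `test_scale`).
#' @param spinup_years,years Spin-up and main-phase lengths.
#' @param test_scale Relax the SI-count rule.
#' @param dir If non-NULL, also write the inputs (numbers-at-age, F table,
#'   month fractions, bathymetry) as CSV files there.
#' @param ... Further entries merged into the configuration (e.g.
#'   `scenario`, `params`, `options`).
#' @return A configuration list for [run_simulation()].
#' @export
make_world_small <- function(seed = 1, nx = 40, ny = 40, n_SI = 105,
                             spinup_years = 2, years = 3,
                             test_scale = TRUE, dir = NULL, ...) {
  mean_F <- stats::setNames(
    c(0, 0.05, 0.15, 0.2, rep(0.277, 5), rep(0.2, 7)), 0:15)
  month_frac <- rep(1 / 12, 12)
  naa <- data.frame(age = 0:14, abundance = 4e9 * exp(-0.35 * (0:14)))
  config <- list(
    seed = seed,
    grid = list(nx = nx, ny = ny),
    forcing = list(years = spinup_years + years),
    n_SI = n_SI,
    test_scale = test_scale,
    numbers_at_age = naa,
    mean_F_at_age = mean_F,
    month_frac = month_frac,
    spinup_years = spinup_years,
    years = years
  )
  extra <- list(...)
  for (nm in names(extra)) config[[nm]] <- extra[[nm]]
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(naa, file.path(dir, "numbers_at_age.csv"),
                     row.names = FALSE)
    fdf <- data.frame(year = 1, t(mean_F))
    names(fdf) <- c("year", paste0("age", 0:15))
    utils::write.csv(fdf, file.path(dir, "F_at_age.csv"), row.names = FALSE)
    utils::write.csv(data.frame(month = 1:12, fraction = month_frac),
                     file.path(dir, "month_fractions.csv"),
                     row.names = FALSE)
    s <- build_grid(config$grid)
    write_field_csv(s$depth, file.path(dir, "bathymetry.csv"))
  }
  config
}

#' Pseudo-observations from a reference run
#'
#' Perturbs a completed run's spawning-SSB series, weight-at-age series
#' and July/August presence grid with stated noise, producing calibration
#' targets and validation observations with known ground truth.
#'
#' @param run_outputs A `run_outputs` object.
#' @param noise Relative (lognormal-free, multiplicative normal) noise sd
#'   applied to SSB and weight-at-age; 0 returns the reference values.
#' @param flip_rate Probability of flipping each presence/absence label.
#' @param seed RNG seed.
#' @return A list: `ssb` (numeric series), `weight_at_age` (numeric
#'   series), `presence` (logical vector over ocean cells), `density`
#'   (predicted densities on the same cells).
#' @export
make_pseudo_observations <- function(run_outputs, noise = 0.05,
                                     flip_rate = 0, seed = 1) {
  set.seed(seed)
  ssb <- run_outputs$ssb_spawning$value
  ssb_obs <- ssb * (1 + stats::rnorm(length(ssb), 0, noise))
  waa <- run_outputs$weight_at_age_spawning$mean_mass
  waa_obs <- waa * (1 + stats::rnorm(length(waa), 0, noise))
  dens <- as.vector(run_outputs$density_map)
  pres <- dens > 0
  if (flip_rate > 0) {
    flip <- stats::runif(length(pres)) < flip_rate
    pres[flip] <- !pres[flip]
  }
  list(ssb = ssb_obs, weight_at_age = waa_obs,
       presence = pres, density = dens)
}
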