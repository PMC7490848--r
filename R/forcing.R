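# Time-indexed environmental forcing. Phytoplankton and SST are 10-day
# composites; photoperiod and currents are monthly (photoperiod values
# correspond to the 15th of each month); fishing inputs are handled by the
# fishing schedule, not here.

#' Generate synthetic environmental forcing
#'
#' Builds a deterministic (seeded) forcing stack emulating the features of
#' the real Northeast Atlantic fields that drive the model: a meridional SST
#' gradient with a seasonal cycle that opens a northward-progressing
#' 10--14 degC band in spring (so spawning movement is exercised), a
#' phytoplankton bloom that peaks in summer at high latitudes (so the
#' feeding migration is rewarded), latitude-dependent photoperiod, and weak
#' current fields.
#'
#' @param seascape A `seascape` (supplies the grid and cell latitudes).
#' @param spec A list: `years` (default 5); `sst_south` mean southern SST
#'   (degC, 14); `sst_lat_grad` cooling per degree latitude (0.3);
#'   `sst_amp` seasonal amplitude (3.5); `sst_peak_doy` (220);
#'   `bloom_amp` bloom peak amplitude, g m-2 (must be positive, default 8);
#'   `bloom_base` baseline (0.5); `bloom_sigma` bloom width in days (35);
#'   `bloom_peak_south_doy` (120); `bloom_lat_delay` days of bloom delay per
#'   degree latitude (2.5); `current_amp` km h-1 (0.05); `noise_sd`
#'   lognormal spatial noise sd on phytoplankton (0.15).
#' @param seed Integer seed; the same seed reproduces the fields bit for bit.
#' @return An object of class `forcing`.
#' @export
generate_synthetic_forcing <- function(seascape, spec = list(), seed = 1) {
  years <- spec$years %||% 5
  sst_south <- spec$sst_south %||% 14
  sst_lat_grad <- spec$sst_lat_grad %||% 0.3
  sst_amp <- spec$sst_amp %||% 3.5
  sst_peak_doy <- spec$sst_peak_doy %||% 220
  bloom_amp <- spec$bloom_amp %||% 8
  if (bloom_amp <= 0) stop("bloom amplitude must be positive")
  bloom_base <- spec$bloom_base %||% 0.5
  bloom_sigma <- spec$bloom_sigma %||% 35
  bloom_peak_south <- spec$bloom_peak_south_doy %||% 120
  bloom_lat_delay <- spec$bloom_lat_delay %||% 2.5
  current_amp <- spec$current_amp %||% 0.05
  noise_sd <- spec$noise_sd %||% 0.15

  nx <- seascape$nx; ny <- seascape$ny
  lat <- seascape$lat
  n_comp <- ceiling(365 * years / 10)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)

  X <- array(0, c(nx, ny, n_comp))
  SST <- array(0, c(nx, ny, n_comp))
  dlat <- lat - lat[1]
  for (ci in seq_len(n_comp)) {
    mid <- (ci - 1) * 10 + 5
    doy <- ((mid - 1) %% 365) + 1
    sst_row <- sst_south - sst_lat_grad * dlat +
      sst_amp * cos(2 * pi * (doy - sst_peak_doy) / 365)
    peak <- bloom_peak_south + bloom_lat_delay * dlat
    amp_row <- bloom_amp * (0.5 + 0.5 * dlat / max(dlat[length(dlat)], 1))
    x_row <- bloom_base + amp_row * exp(-((doy - peak)^2) / (2 * bloom_sigma^2))
    noise <- matrix(exp(stats::rnorm(nx * ny, 0, noise_sd)), nx, ny)
    X[, , ci] <- noise * rep(x_row, each = nx)
    SST[, , ci] <- rep(sst_row, each = nx)
  }

  p_photo <- array(0, c(nx, ny, 12))
  for (m in 1:12) {
    doy15 <- .month_start[m] + 14
    frac <- geosphere::daylength(lat, doy15) / 24
    p_photo[, , m] <- rep(frac, each = nx)
  }

  U <- array(0, c(nx, ny, 12))
  V <- array(0, c(nx, ny, 12))
  yy <- seq_len(ny)
  for (m in 1:12) {
    U[, , m] <- rep(current_amp * sin(2 * pi * yy / ny), each = nx)
    V[, , m] <- current_amp * 0.5 * sin(2 * pi * seq_len(nx) / nx)
  }

  structure(list(
    years = years, n_comp = n_comp,
    X = X, SST = SST, p_photo = p_photo, U = U, V = V
  ), class = "forcing")
}

# RNG bookkeeping: save/restore the global stream so generators with their
# own seed argument do not perturb callers.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Apply forcing updates due within a time step
#'
#' Refreshes phytoplankton/SST when the step enters a new 10-day composite,
#' and photoperiod/currents when the step contains a month start (monthly
#' photoperiod values correspond to the 15th of the month). The
#' spawning-area mask is recomputed whenever SST changes.
#'
#' @param seascape A `seascape`.
#' @param forcing A `forcing`.
#' @param abs_day Absolute simulation day (1-based) at the start of the step.
#' @param step_days Step length.
#' @return The updated seascape.
#' @export
update_forcing <- function(seascape, forcing, abs_day, step_days = 5) {
  comp <- (abs_day - 1) %/% 10 + 1
  if (comp > forcing$n_comp) {
    stop("forcing exhausted: composite ", comp, " beyond extent ",
         forcing$n_comp)
  }
  if (comp != seascape$loaded_comp) {
    seascape$X <- forcing$X[, , comp]
    seascape$SST <- forcing$SST[, , comp]
    seascape$loaded_comp <- comp
    seascape <- spawning_mask(seascape)
  }
  doy_end <- ((abs_day + step_days - 2) %% 365) + 1
  m <- month_of_doy(doy_end)
  if (m != seascape$loaded_month) {
    seascape$p_photo <- forcing$p_photo[, , m]
    seascape$U <- forcing$U[, , m]
    seascape$V <- forcing$V[, , m]
    seascape$loaded_month <- m
  }
  seascape
}

#' @export
print.forcing <- function(x, ...) {
  cat("<forcing> ", x$years, " years; ", x$n_comp,
      " 10-day composites; monthly photoperiod/currents\n", sep = "")
  invisible(x)
}
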