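# Orchestration: the per-time-step process order, the annual calendar of
# migrations/spawning/censuses, spin-up, and the run lifecycle.
#
# Per-step order (fixed):
#  1. 10-day phytoplankton/SST refresh
#  2. month-start updates (photoperiod, currents, month catch fraction)
#  3. year-start fishing mortality-at-age update
#  4. mortality (fishing, starvation, background)
#  5. movement (departures, migration, foraging, random walks)
#  6. energy budgets excluding reproduction
#  7. stage progression (February 1st maturation)
#  8. March 1st potential fecundity
#  9. spawning module (batch provisioning, spawning, northward movement)
# 10. new egg SIs enter
# 11. ageing
# 12. state recording
# SIs that die in (4) never move in (5); state variables update immediately.

#' Build a simulation world
#'
#' Assembles parameters, seascape, forcing, fishing schedule, calendar and
#' the initial population into a mutable world state consumed by
#' [step_world()] and [run_simulation()].
#'
#' @param config A configuration list (see [run_simulation()]).
#' @return A list of class `world`.
#' @export
build_world <- function(config) {
  p <- load_parameters(config$params)
  seed <- config$seed %||% 1
  spinup <- config$spinup_years %||% p$spinup_years
  years_main <- config$years %||% 2
  years <- spinup + years_main

  seascape <- config$seascape %||% build_grid(config$grid %||% list())
  fspec <- config$forcing %||% list()
  fspec$years <- fspec$years %||% years
  forcing <- if (inherits(config$forcing, "forcing")) config$forcing else
    generate_synthetic_forcing(seascape, fspec, seed = seed + 7919)
  if (forcing$n_comp * 10 < years * 365 - 9) {
    stop("forcing extent (", forcing$n_comp * 10, " days) is shorter than ",
         "the run horizon (", years * 365, " days)")
  }

  scenario <- config$scenario %||% "historical-mean"
  mean_F <- config$mean_F_at_age %||%
    stats::setNames(c(0, 0.05, 0.15, rep(0.277, 6), rep(0.2, 7)), 0:15)
  f_vec <- scenario_F(mean_F, scenario, p)
  month_frac <- config$month_frac %||% rep(1 / 12, 12)
  fishing <- make_fishing_schedule(f_vec, month_frac, years)

  naa <- config$numbers_at_age %||%
    data.frame(age = 0:14, abundance = 4e9 * exp(-0.3 * (0:14)))
  n_SI <- config$n_SI %||% 1050
  test_scale <- isTRUE(config$test_scale)

  set.seed(seed)
  pop <- initialize_population(naa, n_SI, p, seascape, test_scale = test_scale)

  cal <- make_calendar(config$start_year %||% 2005, years, p$step_days)
  opts <- config$options %||% list()

  w <- list(
    p = p, seascape = seascape, forcing = forcing, fishing = fishing,
    pop = pop, cal = cal, step_index = 0L,
    seed = seed,
    spinup_years = spinup, years = years,
    n_cohort = as.integer((n_SI / 15) %||% p$n_cohort),
    ricker = config$ricker, emergent = !isTRUE(config$ricker_mode),
    recruitment_series = config$recruitment_series %||%
      rep(naa$abundance[naa$age == 0][1], spinup),
    opts = opts,
    next_id = max(pop$id) + 1L,
    # accumulators
    year_eggs = 0, event_eggs = 0, batch_events_done = 0L,
    spinup_recruit_lengths = numeric(0),
    ledger_max_resid = 0,
    sum_density = matrix(0, seascape$nx, seascape$ny),
    sum_presence = matrix(0, seascape$nx, seascape$ny),
    n_summer_steps = 0L,
    out = list(
      ssb_summer = data.frame(year = integer(), value = numeric()),
      ssb_spawning = data.frame(year = integer(), value = numeric()),
      egg_production = data.frame(year = integer(), value = numeric()),
      recruitment = data.frame(year = integer(), value = numeric()),
      maturity_ogive = data.frame(year = integer(), age = integer(),
                                  prop_mature = numeric()),
      adult_age_dist = data.frame(year = integer(), age = integer(),
                                  prop = numeric()),
      weight36 = data.frame(year = integer(), month = integer(),
                            mean_mass = numeric()),
      juv_len_q1 = data.frame(year = integer(), bin = numeric(),
                              prop = numeric()),
      juv_len_q4 = data.frame(year = integer(), bin = numeric(),
                              prop = numeric()),
      weight_at_age_summer = data.frame(year = integer(), age = integer(),
                                        mean_mass = numeric()),
      weight_at_age_spawning = data.frame(year = integer(), age = integer(),
                                          mean_mass = numeric()),
      n_SI = data.frame(step = integer(), n = integer())
    )
  )
  # n_cohort: SIs entering per year equals SIs per age class
  w$n_cohort <- as.integer(n_SI / 15)
  class(w) <- "world"
  w
}

#' Advance the world by one time step
#'
#' Executes the twelve scheduled processes for the step in their fixed
#' order. Identical seeds and configurations reproduce trajectories
#' bit for bit.
#'
#' @param w A `world`.
#' @return The updated world.
#' @export
step_world <- function(w) {
  w$step_index <- w$step_index + 1L
  si <- w$step_index
  cal <- w$cal
  if (si > cal$n_steps) stop("run horizon exhausted")
  doy <- cal$doy_start[si]
  doy_end <- cal$doy_end[si]
  year <- cal$step_year[si]
  abs_day <- (year - 1) * 365 + doy
  p <- w$p
  ev <- function(e) step_contains(doy, doy_end, .event_doy[[e]])

  # (1)-(2) forcing refresh (10-day composites, monthly fields)
  w$seascape <- update_forcing(w$seascape, w$forcing, abs_day, p$step_days)
  # (3) year-start F-at-age is indexed directly by `year` below

  pop <- w$pop

  # local mackerel density, g per patch (recomputed each step)
  w$seascape$D <- density_field(pop, w$seascape, p)

  # (4) mortality: fishing + background on abundances, then starvation
  if (nrow(pop)) {
    m_back <- if (!is.null(w$opts$const_M)) {
      rep(w$opts$const_M, nrow(pop))
    } else {
      background_mortality(pop, p)
    }
    f_rate <- fishing_rate(w$fishing, year, month_of_doy(doy), pop$age_years)
    pop$F_rate <- f_rate
    pop <- apply_mortality(pop, m_back, f_rate, p$step_days)
    pop <- starvation_check(pop)
  }

  # (5) movement
  if (!isTRUE(w$opts$disable_movement) && nrow(pop)) {
    pop <- movement_phase(pop, w$seascape, p, doy, doy_end)
  } else if (nrow(pop)) {
    pop$V_real <- 0
  }

  # (6) energy budgets (reproduction excluded)
  if (!isTRUE(w$opts$disable_bioenergetics) && nrow(pop)) {
    eb <- energy_budget_phase(pop, w$seascape, p)
    pop <- eb$pop
    w$ledger_max_resid <- max(w$ledger_max_resid, eb$max_resid)
  }

  # (7) stage progression (Feb 1 maturation census)
  if (nrow(pop)) pop <- transform_stage(pop, doy, p$step_days, p)

  # (8) Mar 1: potential fecundity and spawning onset
  if (ev("spawning_start") && nrow(pop)) {
    ad <- pop$stage == STAGE_ADULT
    pop$f_p[ad] <- potential_fecundity(pop$L[ad], p)
    pop$spawning[ad] <- TRUE
    pop$batches[ad] <- 0L
    pop$eggs_spawned[ad] <- 0
    pop$batch_energy[ad] <- 0
    w$batch_events_done <- 0L
    w$year_eggs <- 0
  }

  # (9)-(10) spawning module and new egg SIs
  if (nrow(pop)) {
    sp <- spawning_phase(w, pop, doy, doy_end)
    w <- sp$world
    pop <- sp$pop
  }

  # (11) ageing
  if (nrow(pop)) pop$age_days <- pop$age_days + p$step_days

  w$pop <- pop

  # (12) state recording + year-end bookkeeping
  w <- record_outputs(w, year, doy, doy_end)
  if (step_contains(doy, doy_end, .event_doy$recruitment_census)) {
    w <- year_end(w, year)
  }
  w
}

#' @keywords internal
density_field <- function(pop, seascape, p) {
  D <- matrix(0, seascape$nx, seascape$ny)
  if (!nrow(pop)) return(D)
  px <- patch_of(pop$x, seascape$nx)
  py <- patch_of(pop$y, seascape$ny)
  idx <- (py - 1L) * seascape$nx + px
  mass <- total_mass(pop, p) * pop$abundance
  agg <- rowsum(mass, idx)
  D[as.integer(rownames(agg))] <- agg[, 1]
  D
}

# movement dispatch: departures, migration steps, GAS foraging, random
# walks. Sets V_real and the active flag used for metabolic costing.
#' @keywords internal
movement_phase <- function(pop, seascape, p, doy, doy_end) {
  ev <- function(e) step_contains(doy, doy_end, .event_doy[[e]])
  ad <- pop$stage == STAGE_ADULT

  if (ev("spawning_migration") && any(ad)) {
    pop$migrating[ad] <- TRUE
    pop$mig_mode[ad] <- MIG_SPAWN
  }
  if (ev("feeding_migration") && any(ad)) {
    pop$migrating[ad] <- TRUE
    pop$mig_mode[ad] <- MIG_FEED
    pop$stop_dist[ad] <- stats::runif(sum(ad), 0, p$stop_dist_max)
    pop$feeding[ad] <- TRUE
    pop$spawning[ad] <- FALSE
  }
  if (ev("overwinter_migration") && any(ad)) {
    pop$migrating[ad] <- TRUE
    pop$mig_mode[ad] <- MIG_OW
  }
  if (ev("fast_onset") && any(ad)) pop$feeding[ad] <- FALSE

  pop$V_real <- 0
  was_migrating <- pop$migrating
  pop <- migration_step(pop, seascape, p)

  # summer foraging: feeding adults, not migrating, between the spawning
  # season and the overwintering departure
  gas_window <- doy >= .event_doy$spawning_start &
    doy < .event_doy$overwinter_migration
  gas <- which(ad & pop$feeding & !pop$migrating & !pop$spawning &
                 !was_migrating & gas_window)
  if (length(gas)) {
    cue <- profitability(seascape, p)
    for (d in seq_len(p$step_days)) {
      pop <- gas_daily_step(pop, gas, seascape, cue, p)
    }
  }

  juv <- which(pop$stage == STAGE_JUVENILE & !pop$migrating)
  pop <- random_walk_in_area(pop, juv, seascape, seascape$NArea, p)
  ow <- which(ad & !pop$migrating & !pop$feeding & !pop$spawning)
  pop <- random_walk_in_area(pop, ow, seascape, seascape$OWArea, p)

  active <- was_migrating | seq_len(nrow(pop)) %in% gas
  pop$V_real[!active] <- 0
  attr(pop, "active") <- active
  pop
}

# the per-SI energy budget for one step (reproduction handled separately)
#' @keywords internal
energy_budget_phase <- function(pop, seascape, p) {
  n <- nrow(pop)
  dt <- p$step_days
  nx <- seascape$nx; ny <- seascape$ny
  px <- patch_of(pop$x, nx); py <- patch_of(pop$y, ny)
  here <- cbind(px, py)
  sst <- seascape$SST[here]
  sst[is.na(sst)] <- p$T_ref - 273.15
  sst_k <- sst + 273.15
  X <- seascape$X[here]
  D <- seascape$D[here]
  M <- total_mass(pop, p)
  active <- attr(pop, "active") %||% rep(FALSE, n)

  stage <- pop$stage
  feeds <- (stage == STAGE_LARVA) | (stage == STAGE_JUVENILE) |
    (stage == STAGE_ADULT & pop$feeding)

  # eggs develop; eggs and yolk-sac larvae grow maximally free of charge
  egg <- stage == STAGE_EGG
  if (any(egg)) pop$development[egg] <- develop_egg(pop$development[egg], dt, p)
  ysl <- stage == STAGE_YSL
  if (any(ysl)) {
    Lnew <- growth_update(pop$L[ysl], pop$age_days[ysl], sst_k[ysl],
                          FALSE, dt, p)
    pop$L[ysl] <- Lnew
    pop$M_struct[ysl] <- struct_mass(Lnew, p)
  }

  live <- which(stage >= STAGE_LARVA)
  if (!length(live)) {
    attr(pop, "active") <- NULL
    return(list(pop = pop, max_resid = 0))
  }

  # ingestion (phytoplankton, plus a cannibalism share where prey co-occur)
  IR_step <- numeric(n)
  fi <- which(feeds)
  if (length(fi)) {
    IR_step[fi] <- ingestion(M[fi], X[fi], D[fi], sst_k[fi], p) * dt
  }
  energy_density <- rep(p$E_phyto, n)

  small <- which(pop$L < p$prey_length_max)
  if (length(small) && p$IR_cannibalism > 0) {
    patch_id <- (py - 1L) * nx + px
    for (i in which(feeds & IR_step > 0)) {
      prey_id <- select_prey(pop$L[i], patch_id[i],
                             pop$L[small], patch_id[small], small, p)
      if (!is.na(prey_id)) {
        pm <- max(M[prey_id], p$M_0)
        lipid_frac <- (pop$reserve[prey_id] / p$E_lipid) / pm
        e_prey <- lipid_frac * p$E_lipid + (1 - lipid_frac) * p$E_flesh
        energy_density[i] <- (1 - p$IR_cannibalism) * p$E_phyto +
          p$IR_cannibalism * e_prey
        pop$abundance[prey_id] <- predation_mortality(
          pop$abundance[prey_id], pm, pop$abundance[i], IR_step[i], p)
      }
    }
  }

  intake <- IR_step * energy_density
  assimilated <- p$A_e * intake
  fed_now <- intake > 0
  pop$has_fed <- pop$has_fed | fed_now

  # maintenance: SMR always accrues; AMR replaces it on active days
  smr_d <- smr(M, sst_k, p)
  maint_d <- smr_d
  act <- active & stage == STAGE_ADULT
  if (any(act)) {
    maint_d[act] <- pmax(smr_d[act], amr(M[act], pop$V_real[act], sst_k[act], p))
  }
  maintenance <- maint_d * dt
  maintenance[stage < STAGE_LARVA] <- 0

  net <- assimilated - maintenance
  net[stage < STAGE_LARVA] <- 0

  # growth from the post-maintenance surplus
  growth_cost <- numeric(n)
  can_grow <- stage >= STAGE_LARVA & feeds
  if (any(can_grow)) {
    g <- which(can_grow)
    L_tgt <- growth_update(pop$L[g], pop$age_days[g], sst_k[g],
                           stage[g] == STAGE_ADULT, dt, p)
    res <- grow(pop$L[g], L_tgt, pmax(net[g], 0), p)
    pop$L[g] <- res$L
    pop$M_struct[g] <- res$M_struct
    growth_cost[g] <- res$cost
  }
  remaining <- net - growth_cost

  # reserves: larvae store nothing (growth priority); juveniles and adults
  # store up to the cap and draw deficits from reserves
  cap_mass <- ifelse(stage >= STAGE_JUVENILE, pop$M_struct, 0)
  ru <- reserves_update(pop$reserve, remaining, cap_mass, p)
  # per-SI closure: assimilated = maintenance + growth + synthesis cost
  #                 + overflow + reserve change - unmet demand
  resid <- assimilated - maintenance - growth_cost -
    ru$synth_cost - ru$overflow -
    (ru$reserve - pop$reserve) + ru$unmet
  resid[stage < STAGE_LARVA] <- 0
  pop$reserve <- ru$reserve
  pop$starving <- ru$unmet > 0 & stage >= STAGE_LARVA
  attr(pop, "active") <- NULL
  list(pop = pop, max_resid = max(abs(resid)))
}

# batch provisioning from reserves, batch spawning on the season's
# inter-batch boundaries, post-spawn northward movement, and creation of
# the new egg SIs
#' @keywords internal
spawning_phase <- function(w, pop, doy, doy_end) {
  p <- w$p
  season_start <- .event_doy$spawning_start
  in_season <- doy_end >= season_start &
    doy <= season_start + p$season_days - 1
  sp <- which(pop$spawning & pop$stage == STAGE_ADULT)
  if (!in_season || !length(sp)) return(list(world = w, pop = pop))

  # provision the current batch from reserves
  b_max <- batch_cost(pop$f_p[sp], p)
  want <- pmin(b_max / p$b_int * p$step_days,
               pmax(b_max - pop$batch_energy[sp], 0))
  drawn <- pmin(want, pop$reserve[sp])
  pop$reserve[sp] <- pop$reserve[sp] - drawn
  pop$batch_energy[sp] <- pop$batch_energy[sp] + drawn
  unit <- p$M_0 * (p$E_flesh + p$E_sf)
  pop$M_gon[sp] <- pop$batch_energy[sp] / unit * p$M_0

  # batch boundaries: season day j * b_int, j = 1..n_b
  batch_doys <- season_start - 1 + seq_len(p$n_b) * p$b_int
  due <- which(batch_doys >= doy & batch_doys <= doy_end)
  for (j in due) {
    spawners <- which(pop$spawning & pop$stage == STAGE_ADULT &
                        pop$batches == (j - 1L))
    if (!length(spawners)) next
    eggs_i <- pop$batch_energy[spawners] / unit
    females <- pop$gender[spawners] == 1L
    event_eggs <- sum(eggs_i[females] * pop$abundance[spawners][females])
    w$year_eggs <- w$year_eggs + event_eggs
    pop$eggs_spawned[spawners] <- pop$eggs_spawned[spawners] + eggs_i
    pop$batch_energy[spawners] <- 0
    pop$M_gon[spawners] <- 0
    pop$batches[spawners] <- pop$batches[spawners] + 1L
    done <- pop$batches[spawners] >= p$n_b
    pop$spawning[spawners[done]] <- FALSE
    pop$feeding[spawners[done]] <- TRUE

    # post-spawn northward movement
    pop <- spawning_move(pop, spawners, w$seascape, p)

    # new egg SIs: the year's n_cohort entries split across batch events
    if (w$emergent && w$cal$step_year[w$step_index] > w$spinup_years &&
        event_eggs > 0) {
      counts <- diff(round(seq(0, w$n_cohort, length.out = p$n_b + 1)))
      n_new <- counts[j]
      posw <- cbind(pop$x[spawners][females], pop$y[spawners][females])
      wts <- (eggs_i * pop$abundance[spawners])[females]
      newp <- recruit_emergent(event_eggs, n_new, posw, wts, p, w$next_id)
      if (nrow(newp)) {
        w$next_id <- w$next_id + nrow(newp)
        pop <- rbind(pop, newp)
      }
    }
    w$batch_events_done <- w$batch_events_done + 1L
  }

  # season close: force spawning off
  if (doy_end >= season_start + p$season_days - 1) {
    still <- pop$spawning & pop$stage == STAGE_ADULT
    pop$spawning[still] <- FALSE
    pop$feeding[still] <- TRUE
  }
  list(world = w, pop = pop)
}

#' @keywords internal
record_outputs <- function(w, year, doy, doy_end) {
  pop <- w$pop
  p <- w$p
  ev <- function(e) step_contains(doy, doy_end, .event_doy[[e]])
  M <- if (nrow(pop)) total_mass(pop, p) else numeric(0)
  ad <- pop$stage == STAGE_ADULT
  ssb <- sum(M[ad] * pop$abundance[ad])
  add <- function(df, row) rbind(df, row)

  if (ev("spawning_ssb")) {
    w$out$ssb_spawning <- add(w$out$ssb_spawning,
                              data.frame(year = year, value = ssb))
    w$out$weight_at_age_spawning <- add(
      w$out$weight_at_age_spawning, weight_at_age(pop, M, year))
  }
  if (ev("summer_ssb")) {
    w$out$ssb_summer <- add(w$out$ssb_summer,
                            data.frame(year = year, value = ssb))
    w$out$weight_at_age_summer <- add(
      w$out$weight_at_age_summer, weight_at_age(pop, M, year))
    if (any(ad)) {
      ab <- rowsum(pop$abundance[ad], pop$age_years[ad])
      w$out$adult_age_dist <- add(w$out$adult_age_dist, data.frame(
        year = year, age = as.integer(rownames(ab)),
        prop = ab[, 1] / sum(ab[, 1])))
    }
  }
  if (ev("egg_production_census")) {
    w$out$egg_production <- add(w$out$egg_production,
                                data.frame(year = year, value = w$year_eggs))
  }
  if (ev("ogive_census") && nrow(pop)) {
    jo <- pop$stage >= STAGE_JUVENILE
    if (any(jo)) {
      tot <- rowsum(pop$abundance[jo], pop$age_years[jo])
      mat <- rowsum(pop$abundance[jo] * (pop$stage[jo] == STAGE_ADULT),
                    pop$age_years[jo])
      w$out$maturity_ogive <- add(w$out$maturity_ogive, data.frame(
        year = year, age = as.integer(rownames(tot)),
        prop_mature = mat[, 1] / tot[, 1]))
    }
  }
  # monthly mean weight of the 36 cm length class (mid-month snapshot)
  mid <- .month_start[month_of_doy(doy)] + 14
  if (step_contains(doy, doy_end, mid) && nrow(pop)) {
    in36 <- pop$L >= 35.5 & pop$L < 36.5
    if (any(in36)) {
      w$out$weight36 <- add(w$out$weight36, data.frame(
        year = year, month = month_of_doy(doy),
        mean_mass = sum(M[in36] * pop$abundance[in36]) /
          sum(pop$abundance[in36])))
    }
  }
  if (ev("q1_juvenile_census")) {
    w$out$juv_len_q1 <- add(w$out$juv_len_q1, juv_length_dist(pop, year))
  }
  if (ev("q4_juvenile_census")) {
    w$out$juv_len_q4 <- add(w$out$juv_len_q4, juv_length_dist(pop, year))
  }
  # July/August presence and density maps
  if (doy >= 182 && doy_end <= 243) {
    w$sum_density <- w$sum_density + w$seascape$D
    w$sum_presence <- w$sum_presence + (w$seascape$D > 0)
    w$n_summer_steps <- w$n_summer_steps + 1L
  }
  w$out$n_SI <- add(w$out$n_SI,
                    data.frame(step = w$step_index, n = nrow(pop)))
  w
}

#' @keywords internal
weight_at_age <- function(pop, M, year) {
  keep <- pop$stage >= STAGE_JUVENILE
  if (!any(keep)) {
    return(data.frame(year = integer(), age = integer(),
                      mean_mass = numeric()))
  }
  wsum <- rowsum((M * pop$abundance)[keep], pop$age_years[keep])
  asum <- rowsum(pop$abundance[keep], pop$age_years[keep])
  data.frame(year = year, age = as.integer(rownames(wsum)),
             mean_mass = wsum[, 1] / asum[, 1])
}

#' @keywords internal
juv_length_dist <- function(pop, year) {
  j <- pop$stage == STAGE_JUVENILE
  if (!any(j)) {
    return(data.frame(year = integer(), bin = numeric(), prop = numeric()))
  }
  bin <- floor(pop$L[j])
  ab <- rowsum(pop$abundance[j], bin)
  data.frame(year = year, bin = as.numeric(rownames(ab)),
             prop = ab[, 1] / sum(ab[, 1]))
}

# Dec 31: recruitment census, ageing in years, cohort turnover, forced
# spin-up recruits (emergent recruitment is suppressed during spin-up) or
# Ricker recruits
#' @keywords internal
year_end <- function(w, year) {
  p <- w$p
  pop <- w$pop
  age0 <- pop$age_years == 0L
  rec <- sum(pop$abundance[age0])
  w$out$recruitment <- rbind(w$out$recruitment,
                             data.frame(year = year, value = rec))
  pop$age_years <- pop$age_years + 1L
  pop <- pop[pop$age_years < p$max_age_years, , drop = FALSE]

  if (year <= w$spinup_years) {
    ab <- w$recruitment_series[min(year, length(w$recruitment_series))]
    newp <- spinup_recruit(ab, p, w$seascape, w$n_cohort)
    newp$id <- seq.int(w$next_id, length.out = nrow(newp))
    w$next_id <- w$next_id + nrow(newp)
    w$spinup_recruit_lengths <- c(w$spinup_recruit_lengths, newp$L)
    pop <- rbind(pop, newp)
  } else if (!w$emergent && !is.null(w$ricker)) {
    ssb_row <- w$out$ssb_spawning[w$out$ssb_spawning$year == year, ]
    mask <- w$seascape$SArea
    msst <- mean(w$seascape$SST[mask], na.rm = TRUE)
    if (!is.finite(msst)) msst <- mean(w$seascape$SST[w$seascape$ocean])
    recn <- recruit_ricker(ssb_row$value[1] %||% 0, msst, w$ricker)
    newp <- spinup_recruit(recn, p, w$seascape, w$n_cohort)
    newp$id <- seq.int(w$next_id, length.out = nrow(newp))
    w$next_id <- w$next_id + nrow(newp)
    pop <- rbind(pop, newp)
  }
  w$year_eggs <- 0
  w$pop <- pop
  w
}

#' Run a full simulation
#'
#' Initializes on January 1st, spins up for `spinup_years` with recruitment
#' forced from the supplied series, then runs the main phase with emergent
#' (or Ricker) recruitment, extracting all population metrics on their
#' census dates.
#'
#' @param config A list (or YAML path) with entries: `params` (parameter
#'   overrides), `grid` (seascape spec or a prebuilt `seascape` under
#'   `seascape`), `forcing` (spec or prebuilt `forcing`), `n_SI`,
#'   `numbers_at_age`, `recruitment_series`, `mean_F_at_age`, `month_frac`,
#'   `scenario`, `spinup_years`, `years` (main-phase years), `start_year`,
#'   `seed`, `test_scale`, `ricker_mode`/`ricker` (coefficients), and
#'   `options` (`disable_movement`, `disable_bioenergetics`, `const_M`).
#' @return An object of class `run_outputs`: the census time series, the
#'   July/August mean presence and density maps, spin-up recruit entry
#'   lengths, the maximum per-SI energy-ledger residual, and the final
#'   population.
#' @export
run_simulation <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  w <- build_world(config)
  for (s in seq_len(w$cal$n_steps)) w <- step_world(w)
  finalize_run(w)
}

#' @keywords internal
finalize_run <- function(w) {
  n <- max(w$n_summer_steps, 1L)
  out <- w$out
  out$presence_map <- w$sum_presence / n
  out$density_map <- w$sum_density / n
  out$spinup_recruit_lengths <- w$spinup_recruit_lengths
  out$ledger_max_resid <- w$ledger_max_resid
  out$final_population <- w$pop
  out$spinup_years <- w$spinup_years
  out$years <- w$years
  class(out) <- "run_outputs"
  out
}

#' @export
print.run_outputs <- function(x, ...) {
  cat("<run_outputs> ", x$years, " simulated years (",
      x$spinup_years, " spin-up)\n", sep = "")
  if (nrow(x$ssb_spawning)) {
    cat("  spawning SSB, final year: ",
        format(utils::tail(x$ssb_spawning$value, 1), digits = 4), " g\n",
        sep = "")
  }
  cat("  final SI count: ", nrow(x$final_population), "\n", sep = "")
  cat("  max energy-ledger residual: ",
      format(x$ledger_max_resid, digits = 3), " kJ\n", sep = "")
  invisible(x)
}

#' Write run outputs as tidy CSV files
#'
#' One CSV per population metric, plus the July/August presence and density
#' maps in long patch format.
#'
#' @param out A `run_outputs` object.
#' @param dir Output directory (created if needed).
#' @export
write_run_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("ssb_summer", "ssb_spawning", "egg_production", "recruitment",
            "maturity_ogive", "adult_age_dist", "weight36",
            "juv_len_q1", "juv_len_q4",
            "weight_at_age_summer", "weight_at_age_spawning", "n_SI")
  for (nm in tabs) {
    utils::write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  write_field_csv(out$presence_map, file.path(dir, "presence_map.csv"))
  write_field_csv(out$density_map, file.path(dir, "density_map.csv"))
  utils::write.csv(
    data.frame(L = out$spinup_recruit_lengths),
    file.path(dir, "spinup_recruit_lengths.csv"), row.names = FALSE)
  invisible(dir)
}
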