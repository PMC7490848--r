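# Super-individual state. The population is a data.frame with one row per
# super-individual (SI); an SI stands for `abundance` identical fish.
# Mortality scales abundance; an SI with abundance < 1 is removed.

# stage codes
STAGE_EGG <- 1L
STAGE_YSL <- 2L     # yolk-sac larva
STAGE_LARVA <- 3L
STAGE_JUVENILE <- 4L
STAGE_ADULT <- 5L

# migration modes
MIG_NONE <- 0L
MIG_SPAWN <- 1L
MIG_FEED <- 2L
MIG_OW <- 3L

#' @keywords internal
empty_population <- function(n = 0) {
  data.frame(
    id = integer(n), abundance = numeric(n), age_days = numeric(n),
    age_years = integer(n), stage = integer(n), gender = integer(n),
    L = numeric(n), M_struct = numeric(n), reserve = numeric(n),
    M_gon = numeric(n), development = numeric(n), has_fed = logical(n),
    x = numeric(n), y = numeric(n),
    migrating = logical(n), mig_mode = integer(n), stop_dist = numeric(n),
    feeding = logical(n), spawning = logical(n),
    batches = integer(n), f_p = numeric(n), eggs_spawned = numeric(n),
    batch_energy = numeric(n),
    A_mat = numeric(n), L_mat_att = numeric(n),
    head_x = numeric(n), head_y = numeric(n), prev_profit = numeric(n),
    V_real = numeric(n), F_rate = numeric(n), starving = logical(n)
  )
}

#' Structural mass from length (allometry)
#' @param L Body length, cm.
#' @param p A `parameter_set`.
#' @return Structural mass, g wet weight.
#' @export
struct_mass <- function(L, p) p$a_w * L^p$b_w

#' Length from structural mass (inverse allometry)
#' @param M_struct Structural mass, g.
#' @param p A `parameter_set`.
#' @export
length_from_struct <- function(M_struct, p) (M_struct / p$a_w)^(1 / p$b_w)

#' Total body mass of SIs
#'
#' Total mass = structural mass + stored lipid mass + gonad mass.
#' @param pop Population data.frame.
#' @param p A `parameter_set`.
#' @export
total_mass <- function(pop, p) {
  pop$M_struct + pop$reserve / p$E_lipid + pop$M_gon
}

#' Maximum energy reserve (kJ)
#'
#' The reserve cap is a lipid mass equal to `E_max` times structural mass,
#' expressed in kJ via the energy density of lipid.
#' @param M_struct Structural mass, g.
#' @param p A `parameter_set`.
#' @export
reserve_cap <- function(M_struct, p) p$E_max * M_struct * p$E_lipid

#' First-season (Gompertz) length-at-age
#' @param t Age, days post-hatch.
#' @param p A `parameter_set`.
#' @export
gompertz_length <- function(t, p) {
  p$L_1 * exp(-exp(-p$k_1 * (t - p$t_max)))
}

#' von Bertalanffy length-at-age
#' @param t Age, days post-hatch.
#' @param p A `parameter_set`.
#' @export
vb_length <- function(t, p) {
  p$L_inf * (1 - exp(-p$k * (t - p$t_0)))
}

#' Initialize the population from numbers-at-age
#'
#' Apportions numbers-at-age into super-individuals: 15 age classes, an
#' equal number of SIs per class, a 1:1 gender ratio, lengths from the von
#' Bertalanffy curve at age, energy reserves at half maximum. Adults are
#' placed at random in the overwintering area and juveniles in the nursery
#' area. Stage is adult iff length has reached the maturity threshold.
#'
#' @param numbers_at_age data.frame with columns `age` (0..14) and
#'   `abundance` (individuals), 15 rows.
#' @param n_SI Total SI count; must be a multiple of 1050 (70 SIs per age
#'   class) unless `test_scale = TRUE`, in which case any multiple of 15 is
#'   accepted.
#' @param p A `parameter_set`.
#' @param seascape A `seascape` (for placement masks).
#' @param test_scale Relax the 1050-multiple rule (testing only).
#' @return Population data.frame.
#' @export
initialize_population <- function(numbers_at_age, n_SI, p, seascape,
                                  test_scale = FALSE) {
  if (!test_scale && n_SI %% 1050 != 0) {
    stop("n_SI must be a multiple of 1050 (70 SIs x 15 age classes); got ",
         n_SI)
  }
  if (n_SI %% 15 != 0) stop("n_SI must be a multiple of 15")
  if (nrow(numbers_at_age) != 15 || any(numbers_at_age$abundance <= 0)) {
    stop("numbers_at_age must give positive abundance for 15 age classes")
  }
  per_class <- n_SI %/% 15L
  ages <- numbers_at_age$age
  pop <- empty_population(n_SI)
  pop$id <- seq_len(n_SI)
  pop$age_years <- rep(as.integer(ages), each = per_class)
  pop$age_days <- pop$age_years * 365
  pop$abundance <- rep(numbers_at_age$abundance / per_class, each = per_class)
  pop$gender <- rep_len(c(1L, 2L), n_SI)
  pop$L <- pmax(vb_length(pop$age_days, p), p$L_hatch)
  pop$M_struct <- struct_mass(pop$L, p)
  pop$reserve <- 0.5 * reserve_cap(pop$M_struct, p)
  pop$stage <- ifelse(pop$L >= p$L_mat, STAGE_ADULT, STAGE_JUVENILE)
  pop$A_mat <- ifelse(pop$stage == STAGE_ADULT, pop$age_years, NA_real_)
  pop$L_mat_att <- ifelse(pop$stage == STAGE_ADULT, pop$L, NA_real_)
  pop$has_fed <- TRUE

  ow <- which(seascape$OWArea, arr.ind = TRUE)
  nu <- which(seascape$NArea, arr.ind = TRUE)
  if (nrow(ow) == 0 || nrow(nu) == 0) {
    stop("seascape lacks overwintering or nursery patches for placement")
  }
  ad <- pop$stage == STAGE_ADULT
  pick <- ow[sample.int(nrow(ow), sum(ad), replace = TRUE), , drop = FALSE]
  pop$x[ad] <- pick[, 1]; pop$y[ad] <- pick[, 2]
  pick <- nu[sample.int(nrow(nu), sum(!ad), replace = TRUE), , drop = FALSE]
  pop$x[!ad] <- pick[, 1]; pop$y[!ad] <- pick[, 2]
  pop$mig_mode <- MIG_NONE
  pop
}

#' Spin-up recruits
#'
#' During the spin-up decade recruits enter at the end of each year with
#' body length set at the maximum end-of-first-season length `L_1` minus
#' three times a standard uniform draw, i.e. lengths in (17, 20] cm.
#'
#' @param year_abundance Total abundance the cohort represents.
#' @param p A `parameter_set`.
#' @param seascape A `seascape` (recruits are placed in the nursery area).
#' @param n_cohort Number of SIs in the cohort (default `p$n_cohort`).
#' @return Population data.frame of the new SIs (age 0, juvenile).
#' @export
spinup_recruit <- function(year_abundance, p, seascape,
                           n_cohort = p$n_cohort) {
  n <- as.integer(n_cohort)
  pop <- empty_population(n)
  eps <- stats::runif(n)
  pop$L <- p$L_1 - 3 * eps
  pop$abundance <- year_abundance / n
  pop$age_years <- 0L
  # end of the first growing season (days post-hatch for a mid-June hatch)
  pop$age_days <- 213
  pop$stage <- STAGE_JUVENILE
  pop$gender <- rep_len(c(1L, 2L), n)
  pop$M_struct <- struct_mass(pop$L, p)
  pop$reserve <- 0.5 * reserve_cap(pop$M_struct, p)
  pop$has_fed <- TRUE
  nu <- which(seascape$NArea, arr.ind = TRUE)
  pick <- nu[sample.int(nrow(nu), n, replace = TRUE), , drop = FALSE]
  pop$x <- pick[, 1]; pop$y <- pick[, 2]
  pop$mig_mode <- MIG_NONE
  pop
}

#' Ontogenetic stage transitions
#'
#' Eggs become yolk-sac larvae at hatching length once their five-day
#' development completes; yolk-sac larvae become larvae at 0.61 cm; larvae
#' become juveniles at 3 cm; juveniles at or above the maturity length all
#' mature together on February 1st, record their age/length at maturity and
#' join the spawning migration. Transitions are irreversible.
#'
#' @param pop Population data.frame.
#' @param doy Day of year at the start of the step.
#' @param step_days Step length (the Feb 1 census binds to the step
#'   containing it).
#' @param p A `parameter_set`.
#' @return The updated population.
#' @export
transform_stage <- function(pop, doy, step_days, p) {
  hatch <- pop$stage == STAGE_EGG & pop$development >= p$egg_dev_days
  if (any(hatch)) {
    pop$stage[hatch] <- STAGE_YSL
    pop$L[hatch] <- p$L_hatch
    pop$M_struct[hatch] <- struct_mass(p$L_hatch, p)
  }
  tolarva <- pop$stage == STAGE_YSL & pop$L >= p$L_larva
  pop$stage[tolarva] <- STAGE_LARVA
  tojuv <- pop$stage == STAGE_LARVA & pop$L >= p$L_juv
  pop$stage[tojuv] <- STAGE_JUVENILE
  doy_end <- doy + step_days - 1
  if (step_contains(doy, doy_end, .event_doy$maturation)) {
    mat <- pop$stage == STAGE_JUVENILE & pop$L >= p$L_mat
    if (any(mat)) {
      pop$stage[mat] <- STAGE_ADULT
      pop$A_mat[mat] <- pop$age_years[mat]
      pop$L_mat_att[mat] <- pop$L[mat]
      pop$migrating[mat] <- TRUE
      pop$mig_mode[mat] <- MIG_SPAWN
    }
  }
  pop
}

#' Write a population snapshot
#'
#' One row per SI, as CSV, for checkpointing and diagnostics.
#' @param pop Population data.frame.
#' @param path Output path.
#' @export
write_population_csv <- function(pop, path) {
  utils::write.csv(pop, path, row.names = FALSE)
  invisible(path)
}

#' Read a numbers-at-age table
#' @param path CSV with columns `age`, `abundance`.
#' @export
read_numbers_at_age <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("age", "abundance") %in% names(df)))
  df
}
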