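# The per-SI energy budget: ingestion (Beddington-DeAngelis), assimilation,
# maintenance (standard/active metabolic rate with Arrhenius temperature
# scaling), growth (Gompertz first season, von Bertalanffy thereafter),
# lipid reserves, fecundity and batch provisioning.
#
# All primitive rates are per day; the orchestrator converts to the 5-day
# step. The metabolic-rate equations use the absolute Arrhenius form
# exp(-E_a/(K T)) while ingestion, the profitability cue and growth use the
# relative form normalised to the reference temperature; both forms are kept
# exactly as published.

#' Relative Arrhenius temperature scaling
#'
#' `exp(-(E_a/K) (1/T - 1/T_ref))`; equals 1 at the reference temperature
#' and increases with temperature.
#'
#' @param SST_K Temperature in Kelvin.
#' @param p A `parameter_set`.
#' @export
#' @examples
#' arrhenius(283.15, default_parameters())  # 1 at T_ref
arrhenius <- function(SST_K, p) {
  exp(-(p$E_a / p$K) * (1 / SST_K - 1 / p$T_ref))
}

# absolute form used by the metabolic-rate equations
#' @rdname arrhenius
#' @export
arrhenius_abs <- function(SST_K, p) {
  exp(-p$E_a / (p$K * SST_K))
}

#' Ingestion rate (Beddington-DeAngelis)
#'
#' `IR = A(SST) C_max X / (X + h + c D) M^(2/3)` in g per day, where X is
#' phytoplankton density (g m-2), D local mackerel density (g per patch,
#' including the focal SI) and M body mass. Non-increasing in D,
#' non-decreasing in X.
#'
#' @param M Body mass, g.
#' @param X Phytoplankton density, g m-2.
#' @param D Local mackerel density, g per patch.
#' @param SST_K Temperature, Kelvin.
#' @param p A `parameter_set`.
#' @return Ingestion rate, g per day.
#' @export
ingestion <- function(M, X, D, SST_K, p) {
  arrhenius(SST_K, p) * p$C_max * X / (X + p$h + p$c * D) * M^(2 / 3)
}

#' Standard metabolic rate
#'
#' `SMR = a_SMR M^b_SMR exp(-E_a/(K T))`, kJ per day.
#' @inheritParams ingestion
#' @export
smr <- function(M, SST_K, p) {
  p$a_SMR * M^p$b_SMR * arrhenius_abs(SST_K, p)
}

#' Active metabolic rate
#'
#' `AMR = a_AMR M^b_AMR V^c_AMR exp(-E_a/(K T))`, kJ per day; linear in
#' swimming speed V (km h-1). Replaces (does not add to) the standard rate
#' while migrating or actively foraging.
#' @param V Swimming speed, km h-1 (non-negative).
#' @inheritParams ingestion
#' @export
amr <- function(M, V, SST_K, p) {
  if (any(V < 0)) stop("swimming speed V must be non-negative")
  p$a_AMR * M^p$b_AMR * V^p$c_AMR * arrhenius_abs(SST_K, p)
}

#' Maximum growth rate in length
#'
#' Before the growth-phase switch age (240 days) growth follows the Gompertz
#' rate `k_1 A(SST) L ln(L_1/L)`; afterwards the von Bertalanffy rate
#' `k A(SST) (L_inf - L)`, with k doubled for adults (which grow only while
#' feeding, i.e. for half the year).
#'
#' @param L Length, cm.
#' @param age_days Age, days post-hatch.
#' @param SST_K Temperature, Kelvin.
#' @param adult Logical; doubles the von Bertalanffy constant.
#' @param p A `parameter_set`.
#' @return Growth rate, cm per day.
#' @export
max_growth <- function(L, age_days, SST_K, adult = FALSE, p) {
  A <- arrhenius(SST_K, p)
  first <- age_days < p$growth_switch_age
  kk <- p$k * ifelse(adult, 2, 1)
  ifelse(first,
         p$k_1 * A * L * pmax(log(p$L_1 / L), 0),
         kk * A * (p$L_inf - L))
}

# Closed-form growth update over dt days at fixed temperature: the exact
# solution of the growth ODEs, so simulated trajectories match the
# analytic length-at-age curves rather than accumulating Euler error.
#' @keywords internal
growth_update <- function(L, age_days, SST_K, adult, dt, p) {
  A <- arrhenius(SST_K, p)
  first <- age_days < p$growth_switch_age
  kk <- p$k * ifelse(adult, 2, 1)
  Lg <- p$L_1 * (pmin(L, p$L_1) / p$L_1)^exp(-p$k_1 * A * dt)
  Lv <- p$L_inf - (p$L_inf - L) * exp(-kk * A * dt)
  out <- ifelse(first, Lg, Lv)
  pmax(out, L)  # growth is irreversible
}

#' Realise growth under an energy constraint
#'
#' Converts a target length increment to a structural-mass increment via the
#' length-mass allometry; the cost is `dM (E_flesh + E_sf)` kJ. If less
#' energy is available than the full cost, the realised mass increment is
#' scaled down proportionally and length recomputed by inverse allometry.
#'
#' @param L Current length, cm.
#' @param L_target Length after unconstrained growth, cm.
#' @param available Energy available for growth, kJ (non-negative).
#' @param p A `parameter_set`.
#' @return A list: `L` (realised length), `M_struct`, `cost` (kJ spent).
#' @export
grow <- function(L, L_target, available, p) {
  m0 <- struct_mass(L, p)
  m1 <- struct_mass(L_target, p)
  dM <- pmax(m1 - m0, 0)
  unit <- p$E_flesh + p$E_sf
  full_cost <- dM * unit
  frac <- ifelse(full_cost > 0, pmin(available / full_cost, 1), 0)
  dM_real <- dM * frac
  m_new <- m0 + dM_real
  list(L = length_from_struct(m_new, p), M_struct = m_new,
       cost = dM_real * unit)
}

#' Update lipid reserves with a surplus or deficit
#'
#' A surplus is charged the lipid-synthesis cost per gram before storage
#' (stored fraction `E_lipid/(E_lipid + E_sl)`), and storage is capped at
#' the maximum reserve; a deficit is drawn from reserves. Energy that can
#' be neither stored (cap) nor met (empty reserves) is reported so the
#' ledger closes exactly.
#'
#' @param reserve Current reserve, kJ.
#' @param delta Energy flow, kJ (positive surplus, negative deficit).
#' @param M_struct Structural mass, g (sets the cap).
#' @param p A `parameter_set`.
#' @return A list: `reserve`, `stored` (kJ added), `synth_cost` (kJ),
#'   `overflow` (surplus discarded at the cap), `unmet` (deficit not
#'   covered by reserves).
#' @export
reserves_update <- function(reserve, delta, M_struct, p) {
  cap <- reserve_cap(M_struct, p)
  surplus <- pmax(delta, 0)
  deficit <- pmax(-delta, 0)
  store_frac <- p$E_lipid / (p$E_lipid + p$E_sl)
  storable <- surplus * store_frac
  room <- pmax(cap - reserve, 0)
  stored <- pmin(storable, room)
  synth_cost <- stored * p$E_sl / p$E_lipid
  overflow <- surplus - stored - synth_cost
  drawn <- pmin(deficit, reserve + stored)
  unmet <- deficit - drawn
  list(reserve = reserve + stored - drawn, stored = stored,
       synth_cost = synth_cost, overflow = overflow, unmet = unmet)
}

#' Potential fecundity
#'
#' `f_p = a_f L^b_f` eggs, evaluated for adult females at the start of the
#' spawning period (March 1st).
#' @param L Length, cm.
#' @param p A `parameter_set`.
#' @export
potential_fecundity <- function(L, p) p$a_f * L^p$b_f

#' Energy cost of a maximum-sized egg batch
#'
#' `b_max = f_p M_0 (E_flesh + E_sf) / n_b` kJ: each of the season's `n_b`
#' batches provisions `f_p/n_b` eggs of mass `M_0` at the flesh energy
#' density plus synthesis cost.
#' @param f_p Potential fecundity, eggs.
#' @param p A `parameter_set`.
#' @export
batch_cost <- function(f_p, p) {
  f_p * p$M_0 * (p$E_flesh + p$E_sf) / p$n_b
}

#' Candidate prey of a focal SI
#'
#' Prey must share the focal SI's patch, be at least `prey_ratio` (3.5)
#' times smaller in length, and be below the absolute prey-length cutoff
#' (0.33 cm as published, which restricts cannibalism to eggs and yolk-sac
#' larvae). One candidate is chosen uniformly at random.
#'
#' @param focal_L Focal SI length, cm.
#' @param focal_patch Integer patch id of the focal SI.
#' @param cand_L,cand_patch,cand_id Candidate lengths, patch ids and ids.
#' @param p A `parameter_set`.
#' @return The chosen prey id, or `NA` if no candidate is eligible.
#' @export
select_prey <- function(focal_L, focal_patch, cand_L, cand_patch, cand_id, p) {
  ok <- cand_patch == focal_patch &
    cand_L * p$prey_ratio <= focal_L &
    cand_L < p$prey_length_max
  ids <- cand_id[ok]
  if (!length(ids)) return(NA_integer_)
  ids[sample.int(length(ids), 1)]
}

#' Advance egg development
#'
#' Embryo duration is a constant five days (temperature dependence of
#' duration and its mortality compensation are deliberately simplified
#' away); hatching itself is handled by the stage-transition operation.
#'
#' @param development Days developed as an egg.
#' @param step_days Step length, days.
#' @param p A `parameter_set`.
#' @export
develop_egg <- function(development, step_days, p) {
  development + step_days
}
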