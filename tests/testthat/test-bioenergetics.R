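p <- default_parameters()

test_that("Arrhenius scaling is 1 at the reference temperature and rises", {
  expect_equal(arrhenius(283.15, p), 1)
  expect_equal(arrhenius(293.15, p), 2.011348585, tolerance = 1e-8)
  temps <- seq(275, 295, by = 1)
  expect_true(all(diff(arrhenius(temps, p)) > 0))
})

test_that("ingestion follows the Beddington-DeAngelis response", {
  # half-saturation identity: X = h, no competitors, reference temperature
  expect_equal(ingestion(1, p$h, 0, p$T_ref, p), 0.5 * p$C_max)
  # saturation limit in X
  expect_equal(ingestion(1, 1e12, 0, p$T_ref, p), p$C_max, tolerance = 1e-9)
  # direct evaluation, M = 300 g at X = 2h
  expect_equal(ingestion(300, 2 * p$h, 0, p$T_ref, p), 20.61446183,
               tolerance = 1e-8)
  # monotone: non-increasing in density, non-decreasing in food
  d <- ingestion(100, 2, c(0, 1e9, 2e9, 4e9), p$T_ref, p)
  expect_true(all(diff(d) < 0))
  x <- ingestion(100, c(0.5, 1, 2, 4), 1e9, p$T_ref, p)
  expect_true(all(diff(x) > 0))
})

test_that("metabolic rates match direct equation evaluation", {
  expect_equal(smr(300, 283.15, p), 4.114546325, tolerance = 1e-8)
  expect_equal(smr(600, 283.15, p) / smr(300, 283.15, p), 2^0.75)
  expect_gt(smr(300, 284, p), smr(300, 283, p))
  expect_equal(amr(300, 1.85, 283.15, p), 14.9870064, tolerance = 1e-8)
  expect_equal(amr(300, 2, 283.15, p), 2 * amr(300, 1, 283.15, p))
  expect_equal(amr(300, 0, 283.15, p), 0)  # falls back to SMR upstream
  expect_error(amr(300, -1, 283.15, p), "non-negative")
})

test_that("growth rate is Gompertz before 240 d and von Bertalanffy after", {
  # asymptotes: zero growth at L_1 (first season) and L_inf (later)
  expect_equal(max_growth(p$L_1, 100, p$T_ref, FALSE, p), 0)
  expect_equal(max_growth(p$L_inf, 1000, p$T_ref, FALSE, p), 0)
  expect_equal(max_growth(25, 1000, p$T_ref, FALSE, p), 0.014964,
               tolerance = 1e-9)
  # the adult constant is doubled
  expect_equal(max_growth(30, 1000, p$T_ref, TRUE, p),
               2 * max_growth(30, 1000, p$T_ref, FALSE, p))
})

test_that("simulated growth matches the analytic length-at-age curves", {
  # first season: step the closed-form update and compare to the Gompertz
  # curve; then the adult phase against von Bertalanffy
  L <- gompertz_length(0, p)
  t <- 0
  for (i in 1:48) {  # 240 days in 5-day steps
    L <- scombrus:::growth_update(L, t, p$T_ref, FALSE, 5, p)
    t <- t + 5
  }
  expect_equal(L, gompertz_length(240, p), tolerance = 1e-10)
  L <- vb_length(400, p)
  t <- 400
  for (i in 1:73) {
    L <- scombrus:::growth_update(L, t, p$T_ref, FALSE, 5, p)
    t <- t + 5
  }
  expect_equal(L, vb_length(400 + 365, p), tolerance = 1e-10)
})

test_that("growth is scaled down by available energy", {
  res_full <- grow(25, 25.1, Inf, p)
  expect_equal(res_full$L, 25.1)
  res_none <- grow(25, 25.1, 0, p)
  expect_equal(res_none$L, 25)
  expect_equal(res_none$cost, 0)
  # half the energy: half the mass increment, length by inverse allometry
  res_half <- grow(25, 25.1, res_full$cost / 2, p)
  dM_full <- struct_mass(25.1, p) - struct_mass(25, p)
  expect_equal(res_half$M_struct - struct_mass(25, p), dM_full / 2)
  expect_equal(res_half$L, length_from_struct(struct_mass(25, p) + dM_full / 2, p))
})

test_that("reserve accounting charges synthesis, caps storage, draws deficits", {
  # 53 kJ surplus: stored fraction E_lipid/(E_lipid + E_sl)
  ru <- reserves_update(0, 53, 1000, p)
  expect_equal(ru$stored, 38.57222222, tolerance = 1e-8)
  expect_equal(ru$stored + ru$synth_cost, 53)
  # deficit exactly exhausting reserves
  ru <- reserves_update(20, -20, 1000, p)
  expect_equal(ru$reserve, 0)
  expect_equal(ru$unmet, 0)
  # reserves at cap: surplus discarded, reserve unchanged
  cap <- reserve_cap(100, p)
  ru <- reserves_update(cap, 50, 100, p)
  expect_equal(ru$reserve, cap)
  expect_equal(ru$overflow, 50)
  # unmet demand reported when reserves run dry
  ru <- reserves_update(5, -20, 100, p)
  expect_equal(ru$reserve, 0)
  expect_equal(ru$unmet, 15)
})

test_that("fecundity and batch cost follow the length scaling", {
  expect_equal(potential_fecundity(30, p), 254324.8877, tolerance = 1e-7)
  expect_true(all(diff(potential_fecundity(c(27, 30, 35, 40), p)) > 0))
  fp <- potential_fecundity(30, p)
  expect_equal(batch_cost(fp, p), fp * p$M_0 * (p$E_flesh + p$E_sf) / p$n_b)
})

test_that("prey selection applies the co-location, ratio and size rules", {
  # no cohabitants
  expect_true(is.na(select_prey(30, 1, numeric(0), integer(0), integer(0), p)))
  # candidate only 3x smaller than the focal length: ineligible
  expect_true(is.na(select_prey(0.9, 1, 0.3, 1, 1L, p)))
  # candidate above the absolute cutoff: ineligible
  expect_true(is.na(select_prey(30, 1, 0.5, 1, 1L, p)))
  # different patch: ineligible
  expect_true(is.na(select_prey(30, 1, 0.3, 2, 1L, p)))
  # two eligible candidates: seeded uniform choice is deterministic
  set.seed(99)
  pick1 <- select_prey(30, 1, c(0.3, 0.3), c(1, 1), c(7L, 8L), p)
  set.seed(99)
  pick2 <- select_prey(30, 1, c(0.3, 0.3), c(1, 1), c(7L, 8L), p)
  expect_identical(pick1, pick2)
  expect_true(pick1 %in% c(7L, 8L))
})

test_that("egg development accumulates to the five-day hatch", {
  expect_equal(develop_egg(0, 5, p), 5)
  expect_equal(p$egg_dev_days, 5)
})
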