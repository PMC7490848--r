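p <- default_parameters()

test_that("background mortality by life stage matches the length scaling", {
  pop <- scombrus:::empty_population(5)
  pop$stage <- c(1L, 3L, 4L, 4L, 5L)
  pop$L <- c(0.1, 1, 13.1, p$L_mat, 30)
  m <- background_mortality(pop, p)
  expect_equal(m[1], 0.287)                  # egg
  expect_equal(m[2], 0.287)                  # larva
  expect_equal(m[3], 0.00041 * 26.2 / 13.1)  # juvenile: 0.00082/day
  expect_equal(m[4], p$M_a)                  # continuity at L_mat
  expect_equal(m[5], p$M_a)                  # adult constant
})

test_that("mortality converts rates to survival exactly", {
  pop <- scombrus:::empty_population(2)
  pop$abundance <- c(1e6, 1e6)
  out <- apply_mortality(pop, c(0.00041, 0), c(0, 0), 5)
  expect_equal(out$abundance[1], 1e6 * exp(-0.00205))
  expect_equal(1 - out$abundance[1] / 1e6, 0.002047900185, tolerance = 1e-9)
  expect_equal(out$abundance[2], 1e6)   # zero rates: unchanged
  # SIs falling below one individual are removed
  pop$abundance <- c(0.9, 2)
  out <- apply_mortality(pop, c(0, 0), c(0, 0), 5)
  expect_equal(nrow(out), 1)
})

test_that("abundance decays exactly exponentially under constant M", {
  n0 <- 5e8
  ab <- n0
  for (i in 1:73) ab <- ab * exp(-(0.001 + 0) * 5)
  expect_equal(ab, n0 * exp(-0.001 * 365), tolerance = 1e-12)
  pop <- scombrus:::empty_population(1)
  pop$abundance <- n0
  for (i in 1:73) pop <- apply_mortality(pop, 0.001, 0, 5)
  expect_equal(pop$abundance, n0 * exp(-0.001 * 365), tolerance = 1e-12)
})

test_that("predation removes intake/prey-mass individuals, capped", {
  # 1000 predators each taking 1 g of mackerel prey per day; prey of 1 mg
  out <- predation_mortality(1e7, 0.001, 1000, 1 / p$IR_cannibalism, p)
  expect_equal(1e7 - out, 1e6)
  # no cannibalism share: no predation
  p0 <- load_parameters(list(IR_cannibalism = 0))
  expect_equal(predation_mortality(1e7, 0.001, 1000, 10, p0), 1e7)
  # removal capped at the prey abundance
  expect_equal(predation_mortality(5, 0.001, 1e9, 10, p), 0)
})

test_that("starvation removes SIs at structural mass, sparing naive larvae", {
  pop <- scombrus:::empty_population(4)
  pop$abundance <- 10
  pop$stage <- c(5L, 5L, 3L, 3L)
  pop$starving <- c(TRUE, TRUE, TRUE, TRUE)
  pop$reserve <- c(0, 5, 0, 0)
  pop$M_gon <- 0
  pop$has_fed <- c(TRUE, TRUE, FALSE, TRUE)
  out <- starvation_check(pop)
  # adult with zero reserves and gonads removed; adult with reserves kept;
  # never-fed larva kept; fed larva removed
  expect_equal(out$reserve, c(5, 0))
  expect_equal(out$stage, c(5L, 3L))
  expect_false(out$has_fed[2])
})

test_that("the fishing schedule validates and apportions F by month", {
  f <- stats::setNames(rep(0.24, 16), 0:15)
  frac <- c(rep(0.05, 6), rep(0.1, 2), rep(0.125, 4))
  sched <- make_fishing_schedule(f, frac, years = 3)
  # per-day rate in month m: F * frac / days
  r <- fishing_rate(sched, 1, 3, age_years = c(2L, 10L))
  expect_equal(r, rep(0.24 * 0.05 / 31, 2))
  # the year's total F is recovered by summing day rates over the year
  tot <- sum(vapply(1:12, function(m) {
    fishing_rate(sched, 1, m, 4L) * scombrus:::days_in_month(m)
  }, numeric(1)))
  expect_equal(tot, 0.24)
  expect_error(make_fishing_schedule(f, rep(0.1, 12), 1), "sum to 1")
  expect_error(make_fishing_schedule(f[1:10], frac, 1), "ages")
})

test_that("emergent recruitment divides egg production equally", {
  pos <- cbind(c(3, 4), c(5, 5))
  newp <- recruit_emergent(7e9, 70, pos, c(1, 1), p, next_id = 100L)
  expect_equal(nrow(newp), 70)
  expect_equal(newp$abundance, rep(1e8, 70))
  expect_equal(sum(newp$abundance), 7e9)
  expect_true(all(newp$stage == 1L))
  expect_true(all(newp$x %in% c(3, 4)))
  # zero egg production: suppressed
  expect_equal(nrow(recruit_emergent(0, 70, pos, c(1, 1), p)), 0)
})

test_that("the Ricker curve has the standard shape and closed form", {
  co <- list(alpha = 1, beta = 1e-6, gamma = 0)
  expect_equal(recruit_ricker(1e6, 10, co), 1e6 * exp(-1))
  # linear in SSB when beta = gamma = 0
  co0 <- list(alpha = 2.5, beta = 0, gamma = 0)
  expect_equal(recruit_ricker(c(1, 2, 4) * 1e5, 8, co0),
               2.5 * c(1, 2, 4) * 1e5)
  # maximised at SSB = 1/beta
  ssb <- seq(0.5e6, 1.5e6, by = 1e4)
  r <- recruit_ricker(ssb, 10, co)
  expect_equal(ssb[which.max(r)], 1e6)
  expect_error(recruit_ricker(1e6, 10, list(alpha = 1)), "beta")
})

test_that("F-at-age and month-fraction CSVs round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  fdf <- data.frame(year = 1:2, matrix(0.2, 2, 16))
  names(fdf) <- c("year", paste0("age", 0:15))
  utils::write.csv(fdf, path, row.names = FALSE)
  expect_equal(dim(read_F_at_age(path)), c(2L, 16L))
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(month = 12:1, fraction = 1:12 / 78), p2,
                   row.names = FALSE)
  expect_equal(read_month_fractions(p2), 12:1 / 78)
})
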