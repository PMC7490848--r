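p <- default_parameters()

test_that("minimum swimming velocity scales with length", {
  expect_equal(v_min(26.2, p), 1.847304934, tolerance = 1e-8)
  expect_equal(v_min(42.4, p), 2.489766508, tolerance = 1e-8)
  expect_gt(v_min(30, p), v_min(20, p))
  expect_error(v_min(0, p), "positive")
})

test_that("profitability is the cue with cold-water repulsion", {
  s <- flat_seascape(5, 5, sst = 10, X = p$h)
  s$SST[] <- p$T_ref - 273.15
  s$D[] <- 0
  cue <- profitability(s, p)
  expect_equal(cue[3, 3], 0.5)  # half-saturation identity at A = 1, photo = 1
  s$SST[] <- 5
  expect_true(all(profitability(s, p) == 0))
  # crowding strictly lowers the cue
  s$SST[] <- p$T_ref - 273.15
  s$D[] <- 1e10
  expect_lt(profitability(s, p)[3, 3], 0.5)
})

test_that("migrating SIs descend the distance field and stop on arrival", {
  s <- flat_seascape(3, 21, sst = 12)
  s$feed_dist <- distance_field(s, c(2, 21))
  pop <- one_adult(s, L = 30, x = 2, y = 3)
  pop$migrating <- TRUE
  pop$mig_mode <- 2L
  pop$stop_dist <- 0
  radius <- floor(v_min(30, p) * 24 * 5 / s$cell_km)  # patches per step
  r0 <- s$feed_dist[2, 3]
  set.seed(1)
  pop2 <- migration_step(pop, s, p)
  r1 <- s$feed_dist[scombrus:::patch_of(pop2$x, 3), scombrus:::patch_of(pop2$y, 21)]
  expect_equal(r0 - r1, radius)  # straight corridor: R falls by the radius
  # a larger SI covers at least as much ground per step
  pop_big <- one_adult(s, L = 40, x = 2, y = 3)
  pop_big$migrating <- TRUE; pop_big$mig_mode <- 2L; pop_big$stop_dist <- 0
  pop_big2 <- migration_step(pop_big, s, p)
  expect_gte(pop_big2$y, pop2$y)
  # on the target: flag cleared
  pop$x <- 2; pop$y <- 21
  pop3 <- migration_step(pop, s, p)
  expect_false(pop3$migrating)
})

test_that("larger SIs arrive at the destination no later", {
  s <- flat_seascape(3, 31, sst = 12)
  s$feed_dist <- distance_field(s, c(2, 31))
  arrive_after <- function(L) {
    pop <- one_adult(s, L = L, x = 2, y = 1)
    pop$migrating <- TRUE; pop$mig_mode <- 2L; pop$stop_dist <- 0
    for (i in 1:40) {
      pop <- migration_step(pop, s, p)
      if (!pop$migrating) return(i)
    }
    Inf
  }
  set.seed(4)
  times <- vapply(c(28, 33, 38, 42), arrive_after, numeric(1))
  expect_true(all(diff(times) <= 0))
})

test_that("no SI occupies land after any movement operation", {
  # seascape with a land block in the middle
  depth <- matrix(-300, 15, 15)
  depth[7:9, 7:9] <- 100
  s <- build_grid(list(nx = 15, ny = 15, bathymetry = depth,
                       spawn_dest = c(8, 1), feed_dest = c(8, 15),
                       nursery_lon_max = Inf,
                       ow_rect = list(x = c(1, 15), y = c(13, 15))))
  s$SST <- matrix(12, 15, 15)
  s$X <- matrix(3, 15, 15)
  s$p_photo <- matrix(0.8, 15, 15)
  s$feed_dist <- distance_field(s, c(8, 15))
  set.seed(11)
  pop <- do.call(rbind, lapply(1:20, function(i) {
    one_adult(s, L = 25 + i / 2, x = sample(3:13, 1), y = sample(2:5, 1))
  }))
  pop$id <- 1:20
  pop$migrating <- TRUE; pop$mig_mode <- 2L; pop$stop_dist <- 0
  cue <- profitability(s, p)
  for (step in 1:12) {
    pop <- migration_step(pop, s, p)
    idx <- which(!pop$migrating)
    for (d in 1:5) pop <- gas_daily_step(pop, idx, s, cue, p)
    px <- scombrus:::patch_of(pop$x, 15)
    py <- scombrus:::patch_of(pop$y, 15)
    expect_true(all(s$ocean[cbind(px, py)]))
  }
})

test_that("gradient search climbs a static profitability gradient", {
  s <- flat_seascape(20, 20, sst = 12)
  s$X <- matrix(rep(seq(0.1, 6, length.out = 20), each = 20), 20, 20)
  # X increases with y (column index)
  s$U[] <- 0; s$V[] <- 0
  cue <- profitability(s, p)
  pop <- one_adult(s, L = 35, x = 10, y = 4)
  start_cue <- cue[10, 4]
  for (d in 1:5) {
    pop <- gas_daily_step(pop, 1L, s, cue, p, noise = FALSE, currents = FALSE)
  }
  end_cue <- cue[scombrus:::patch_of(pop$x, 20), scombrus:::patch_of(pop$y, 20)]
  expect_gte(end_cue, start_cue)
})

test_that("currents displace by velocity times 24 h and avoid bad patches", {
  s <- flat_seascape(9, 9, sst = 12)
  s$U[] <- 0.1; s$V[] <- 0
  s$X[] <- 2
  cue <- profitability(s, p)
  pop <- one_adult(s, L = 30, x = 4, y = 5)
  pop$prev_profit <- Inf   # keep heading (zero) on the directed component
  pop$head_x <- 0; pop$head_y <- 0
  pop2 <- gas_daily_step(pop, 1L, s, cue, p, noise = FALSE, currents = TRUE)
  # pure current drift: 0.1 km/h * 24 h = 2.4 km = 0.04 patches at 60 km
  expect_equal(pop2$x - pop$x, 0.1 * 24 / s$cell_km, tolerance = 1e-9)
  expect_equal(pop2$y, pop$y)
})

test_that("the random component never chooses a southward heading", {
  s <- flat_seascape(15, 15, sst = 12)
  s$X[] <- 2
  cue <- profitability(s, p)
  set.seed(5)
  for (i in 1:40) {
    pop <- one_adult(s, L = 30, x = 8, y = 8)
    pop$prev_profit <- Inf  # suppress the directed move (flat cue, heading 0)
    pop$head_x <- 0; pop$head_y <- 0
    pop2 <- gas_daily_step(pop, 1L, s, cue, p, noise = TRUE, currents = FALSE)
    expect_gte(pop2$y, pop$y - 1e-9)
  }
})

test_that("area-constrained random walk stays in the area and is uniform", {
  s <- flat_seascape(9, 9, sst = 12)
  area <- matrix(FALSE, 9, 9)
  area[4:6, 4:6] <- TRUE
  pop <- one_adult(s, L = 42, x = 5, y = 5)
  set.seed(8)
  visits <- integer(81)
  for (i in 1:3000) {
    pop <- random_walk_in_area(pop, 1L, s, area, p)
    px <- scombrus:::patch_of(pop$x, 9); py <- scombrus:::patch_of(pop$y, 9)
    expect_true(area[px, py])
    visits[(py - 1) * 9 + px] <- visits[(py - 1) * 9 + px] + 1
  }
  occ <- visits[visits > 0]
  expect_equal(length(occ), 9)
  expect_gt(stats::chisq.test(occ)$p.value, 0.01)
  # single-patch area: stays put
  area1 <- matrix(FALSE, 9, 9); area1[5, 5] <- TRUE
  pop$x <- 5; pop$y <- 5
  pop2 <- random_walk_in_area(pop, 1L, s, area1, p)
  expect_equal(c(pop2$x, pop2$y), c(5, 5))
})

test_that("spawning movement seeks the nearest northward window patch", {
  s <- flat_seascape(9, 9, sst = 8)
  s$SST[, 7] <- 12   # a band of spawnable water three rows north
  pop <- one_adult(s, L = 30, x = 5, y = 4)
  set.seed(2)
  pop2 <- spawning_move(pop, 1L, s, p)
  expect_equal(c(pop2$x, pop2$y), c(5, 7))
  # no northward window: a random in-window neighbour
  s2 <- flat_seascape(9, 9, sst = 8)
  s2$SST[6, 5] <- 12
  pop$x <- 5; pop$y <- 5
  pop3 <- spawning_move(pop, 1L, s2, p)
  expect_equal(c(pop3$x, pop3$y), c(6, 5))
  # no window anywhere: stays
  s3 <- flat_seascape(9, 9, sst = 8)
  pop4 <- spawning_move(pop, 1L, s3, p)
  expect_equal(c(pop4$x, pop4$y), c(5, 5))
})

test_that("spawner mean latitude is non-decreasing as the window warms north", {
  p <- default_parameters()
  s <- flat_seascape(9, 30, sst = 8)
  set.seed(14)
  pop <- do.call(rbind, lapply(1:12, function(i) {
    one_adult(s, L = 30, x = sample(2:8, 1), y = 2)
  }))
  pop$id <- 1:12
  means <- numeric(0)
  # the 10-14 C band opens progressively further north over five batches
  for (b in 1:5) {
    s$SST[] <- 8
    s$SST[, (3 + 4 * b):min(30, 6 + 4 * b)] <- 12
    pop <- spawning_move(pop, 1:12, s, p)
    means <- c(means, mean(pop$y))
  }
  expect_true(all(diff(means) >= 0))
})
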