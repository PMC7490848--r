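test_that("masks follow the depth definitions", {
  s <- build_grid(list(nx = 40, ny = 40))
  expect_true(any(s$ocean))
  # shelf edge is exactly the -550 < depth < -50 ocean band
  expect_identical(s$shelf_edge,
                   s$ocean & s$depth > -550 & s$depth < -50)
  # nursery patches are at most 200 m deep, west of the configured meridian
  expect_true(all(s$depth[s$NArea] >= -200))
  lon_m <- matrix(s$lon, s$nx, s$ny)
  expect_true(all(lon_m[s$NArea] < s$nursery_lon_max))
  expect_false(any(s$NArea & !s$ocean))
})

test_that("all-land bathymetry and land destinations are rejected", {
  expect_error(build_grid(list(nx = 5, ny = 5,
                               bathymetry = matrix(100, 5, 5))),
               "no ocean")
  expect_error(build_grid(list(nx = 40, ny = 40, spawn_dest = c(40, 1))),
               "land")
})

test_that("distance field equals a hand BFS on an open 5x5 ocean", {
  s <- flat_seascape(5, 5)
  R <- distance_field(s, c(3, 3))
  # 4-neighbour hop count = Manhattan distance on an open grid
  manhattan <- outer(abs(1:5 - 3), abs(1:5 - 3), `+`)
  expect_equal(R, manhattan)
  expect_equal(R[3, 3], 0)
})

test_that("distance field routes around a land wall", {
  depth <- matrix(-300, 7, 7)
  depth[4, 1:6] <- 100  # wall with a gap at the top row
  s <- build_grid(list(nx = 7, ny = 7, bathymetry = depth,
                       spawn_dest = c(2, 4), feed_dest = c(2, 7),
                       nursery_lon_max = Inf,
                       ow_rect = list(x = c(1, 3), y = c(6, 7))))
  R <- distance_field(s, c(2, 4))
  # patch east of the wall: forced up through the gap, much longer than
  # the straight-line hop count
  expect_true(is.na(R[4, 4]))
  expect_gt(R[6, 4], abs(6 - 2) + abs(4 - 4))
  expect_equal(R[6, 4], 10)  # hand BFS: up 3 to row 7, across 4, down 3
})

test_that("neighbouring ocean distance indices differ by at most 1", {
  s <- build_grid(list(nx = 25, ny = 25))
  R <- s$spawn_dist
  for (dd in list(c(1, 0), c(0, 1))) {
    a <- R[1:(25 - dd[1]), 1:(25 - dd[2])]
    b <- R[(1 + dd[1]):25, (1 + dd[2]):25]
    both <- is.finite(a) & is.finite(b)
    expect_true(all(abs(a[both] - b[both]) <= 1))
  }
})

test_that("spawning mask needs shelf edge, sector and the open SST window", {
  s <- flat_seascape(6, 6, sst = 12)
  s$spawn_sector_ymax <- 6
  s <- spawning_mask(s)
  expect_true(all(s$SArea == s$shelf_edge))
  # exact 10 degrees is excluded (strict inequality)
  s$SST[] <- 10
  s <- spawning_mask(s)
  expect_false(any(s$SArea))
  s$SST[] <- 14
  expect_false(any(spawning_mask(s)$SArea))
  # off-shelf patches are excluded even in the window
  s2 <- flat_seascape(6, 6, sst = 12, depth = -2000)
  s2$spawn_sector_ymax <- 6
  expect_false(any(spawning_mask(s2)$SArea))
  # idempotent at fixed SST
  s3 <- spawning_mask(flat_seascape(6, 6, sst = 12))
  expect_identical(spawning_mask(s3)$SArea, s3$SArea)
})

test_that("synthetic forcing is reproducible and seasonally structured", {
  s <- build_grid(list(nx = 20, ny = 20))
  f1 <- generate_synthetic_forcing(s, list(years = 1), seed = 11)
  f2 <- generate_synthetic_forcing(s, list(years = 1), seed = 11)
  expect_identical(f1, f2)
  f3 <- generate_synthetic_forcing(s, list(years = 1), seed = 12)
  expect_false(identical(f1$X, f3$X))
  expect_error(generate_synthetic_forcing(s, list(bloom_amp = 0)),
               "positive")
  # high-latitude July plankton exceeds January at the same patch
  jan <- f1$X[, , 1]
  jul <- f1$X[, , (196 - 1) %/% 10 + 1]
  expect_gt(mean(jul[, 18]), mean(jan[, 18]))
  # all invariants: X >= 0, photoperiod a fraction of 24 h
  expect_true(all(f1$X >= 0))
  expect_true(all(f1$p_photo >= 0 & f1$p_photo <= 1))
})

test_that("a spring 10-14 C spawning band opens and moves north", {
  s <- build_grid(list(nx = 20, ny = 40))
  f <- generate_synthetic_forcing(s, list(years = 1), seed = 1)
  band_centre <- function(doy) {
    sst <- f$SST[, , (doy - 1) %/% 10 + 1]
    rows <- which(sst[1, ] > 10 & sst[1, ] < 14)
    mean(rows)
  }
  expect_gt(length(which(f$SST[1, , 8] > 10 & f$SST[1, , 8] < 14)), 0)
  expect_gt(band_centre(115), band_centre(65))  # late April north of early March
})

test_that("forcing cadences: 10-day composites and month starts", {
  s <- build_grid(list(nx = 15, ny = 15))
  f <- generate_synthetic_forcing(s, list(years = 1), seed = 3)
  s <- update_forcing(s, f, abs_day = 1)
  x_first <- s$X
  # day 6 still inside the first composite: unchanged
  s <- update_forcing(s, f, abs_day = 6)
  expect_identical(s$X, x_first)
  # day 11 enters the second composite
  s <- update_forcing(s, f, abs_day = 11)
  expect_identical(s$X, f$X[, , 2])
  # photoperiod switches to February when the step contains Feb 1 (doy 32)
  s <- update_forcing(s, f, abs_day = 31)
  expect_identical(s$p_photo, f$p_photo[, , 2])
  # mid-month step: no monthly update
  s <- update_forcing(s, f, abs_day = 41)
  expect_identical(s$p_photo, f$p_photo[, , 2])
  expect_error(update_forcing(s, f, abs_day = 5000), "extent")
})

test_that("field CSV round-trips through the reader", {
  m <- matrix(rnorm(12), 3, 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(m, path)
  expect_equal(read_field_csv(path), m)
})
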