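# Shared fixtures, built in code at test time.

# a tiny all-ocean seascape with uniform fields, for movement unit tests
flat_seascape <- function(nx = 5, ny = 5, sst = 12, X = 2, depth = -300) {
  s <- build_grid(list(
    nx = nx, ny = ny,
    bathymetry = matrix(depth, nx, ny),
    spawn_dest = c((nx + 1) %/% 2, 1),
    feed_dest = c((nx + 1) %/% 2, ny),
    ow_rect = list(x = c(1, nx), y = c(max(1, ny - 1), ny)),
    nursery_lon_max = Inf
  ))
  s$SST <- matrix(sst, nx, ny)
  s$X <- matrix(X, nx, ny)
  s$p_photo <- matrix(1, nx, ny)
  s
}

# a single adult SI at a given position
one_adult <- function(s, L = 30, x = 3, y = 3, p = default_parameters()) {
  pop <- scombrus:::empty_population(1)
  pop$id <- 1L
  pop$abundance <- 1000
  pop$stage <- 5L
  pop$gender <- 1L
  pop$age_years <- 5L
  pop$age_days <- 5 * 365
  pop$L <- L
  pop$M_struct <- struct_mass(L, p)
  pop$reserve <- 0.5 * reserve_cap(pop$M_struct, p)
  pop$x <- x
  pop$y <- y
  pop$has_fed <- TRUE
  pop
}

small_config <- function(seed = 1, ...) {
  make_world_small(seed = seed, nx = 30, ny = 30, n_SI = 105,
                   spinup_years = 2, years = 2, ...)
}
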