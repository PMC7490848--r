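# The patch grid: bathymetry, area masks, land-avoiding distance indices and
# per-patch environmental fields. Fields are nx-by-ny matrices indexed
# [x, y]; longitude varies with x, latitude with y.

#' Build a seascape grid
#'
#' Constructs the patch grid with bathymetry, ocean/land, shelf-edge,
#' nursery and overwintering masks, and land-avoiding distance fields to the
#' spawning and feeding destination patches.
#'
#' @param spec A list:
#'   \describe{
#'     \item{nx, ny}{grid dimensions}
#'     \item{cell_km}{cell edge length in km (default 60; the grid is a local
#'       equal-distance approximation, with latitude/longitude attached per
#'       cell centre for photoperiod and reporting)}
#'     \item{lat_range, lon_range}{decimal-degree extents (defaults
#'       47--77 N, -45--20 E)}
#'     \item{bathymetry}{`"synthetic"` (default) or an nx-by-ny depth matrix,
#'       metres, negative below sea level}
#'     \item{nursery_lon_max}{western-bound meridian for the nursery mask;
#'       default: the coast longitude of the synthetic layout}
#'     \item{spawn_sector_ymax}{northern limit (y index) of the spawning
#'       sector on the shelf edge}
#'     \item{ow_rect}{overwintering rectangle, `list(x = c(min,max),
#'       y = c(min,max))`}
#'     \item{spawn_dest, feed_dest}{destination patches `c(x, y)`; defaults
#'       sit at the southern end and northern exit of the shelf corridor}
#'   }
#' @return An object of class `seascape`.
#' @export
build_grid <- function(spec = list()) {
  nx <- spec$nx %||% 40
  ny <- spec$ny %||% 40
  cell_km <- spec$cell_km %||% 60
  lat_range <- spec$lat_range %||% c(47, 77)
  lon_range <- spec$lon_range %||% c(-45, 20)

  if (is.matrix(spec$bathymetry)) {
    depth <- spec$bathymetry
    if (!all(dim(depth) == c(nx, ny))) stop("bathymetry must be nx x ny")
    corridor_x <- spec$corridor_x %||% NULL
  } else {
    b <- synthetic_bathymetry(nx, ny)
    depth <- b$depth
    corridor_x <- b$corridor_x
  }

  lon <- lon_range[1] + (seq_len(nx) - 0.5) / nx * diff(lon_range)
  lat <- lat_range[1] + (seq_len(ny) - 0.5) / ny * diff(lat_range)

  ocean <- depth < 0
  if (!any(ocean)) stop("bathymetry contains no ocean patches")
  shelf_edge <- ocean & depth > -550 & depth < -50

  nursery_lon_max <- spec$nursery_lon_max %||%
    (if (!is.null(corridor_x)) lon[min(nx, max(corridor_x) + 4)] else -4)
  lon_m <- matrix(lon, nx, ny)
  narea <- ocean & depth >= -200 & lon_m < nursery_lon_max

  ow <- spec$ow_rect %||% list(
    x = c(max(1, (corridor_x[1] %||% (nx %/% 2)) - 1), nx),
    y = c(round(0.60 * ny), round(0.80 * ny))
  )
  owarea <- matrix(FALSE, nx, ny)
  owarea[ow$x[1]:min(nx, ow$x[2]), ow$y[1]:min(ny, ow$y[2])] <- TRUE
  owarea <- owarea & ocean

  spawn_sector_ymax <- spec$spawn_sector_ymax %||% round(0.45 * ny)

  pick_dest <- function(given, default) {
    d <- given %||% default
    d
  }
  if (!is.null(corridor_x)) {
    cx <- corridor_x[1]
    spawn_dest <- pick_dest(spec$spawn_dest, c(cx, 2L))
    # feeding entrance: where the corridor opens into the northern seas,
    # south of the overwintering box
    feed_dest <- pick_dest(spec$feed_dest, c(cx, max(2L, round(0.55 * ny))))
  } else {
    oc <- which(ocean, arr.ind = TRUE)
    spawn_dest <- pick_dest(spec$spawn_dest, oc[which.min(oc[, 2]), ])
    feed_dest <- pick_dest(spec$feed_dest, oc[which.max(oc[, 2]), ])
  }
  for (d in list(spawn_dest, feed_dest)) {
    if (!ocean[d[1], d[2]]) stop("destination patch (", d[1], ",", d[2],
                                 ") is on land")
  }

  s <- structure(list(
    nx = nx, ny = ny, cell_km = cell_km,
    lat = lat, lon = lon, depth = depth,
    ocean = ocean, shelf_edge = shelf_edge,
    NArea = narea, OWArea = owarea,
    SArea = matrix(FALSE, nx, ny),
    spawn_sector_ymax = spawn_sector_ymax,
    nursery_lon_max = nursery_lon_max,
    corridor_x = corridor_x,
    spawn_dest = as.integer(spawn_dest), feed_dest = as.integer(feed_dest),
    X = matrix(0, nx, ny), SST = matrix(NA_real_, nx, ny),
    p_photo = matrix(0.5, nx, ny),
    U = matrix(0, nx, ny), V = matrix(0, nx, ny),
    D = matrix(0, nx, ny),
    loaded_comp = 0L, loaded_month = 0L
  ), class = "seascape")

  s$spawn_dist <- distance_field(s, s$spawn_dest)
  s$feed_dist <- distance_field(s, s$feed_dest)
  s
}

# Synthetic bathymetry: a deep basin in the west, a two-cell shelf-edge
# corridor (-300 m) running the full meridional extent, a shallow shelf
# (-120 m) inshore of it, and land along the eastern margin.
#' @keywords internal
synthetic_bathymetry <- function(nx, ny) {
  depth <- matrix(-2500, nx, ny)
  corridor_x <- c(nx - 7L, nx - 6L)
  shelf_x <- (nx - 5L):(nx - 3L)
  land_x <- (nx - 2L):nx
  depth[corridor_x, ] <- -300
  depth[shelf_x, ] <- -120
  depth[land_x, ] <- 200
  list(depth = depth, corridor_x = corridor_x, shelf_x = shelf_x)
}

#' Land-avoiding distance field
#'
#' Breadth-first-search hop count (4-neighbour adjacency) from every ocean
#' patch to a destination patch; land is impassable. Unreachable ocean
#' patches carry `Inf`; land patches carry `NA`.
#'
#' @param seascape A `seascape`.
#' @param destination Integer `c(x, y)`, must be ocean.
#' @param passable Optional logical matrix restricting the traversable set
#'   (intersected with the ocean mask).
#' @return Numeric nx-by-ny matrix of hop counts.
#' @export
distance_field <- function(seascape, destination, passable = NULL) {
  nx <- seascape$nx; ny <- seascape$ny
  ok <- seascape$ocean
  if (!is.null(passable)) ok <- ok & passable
  dx <- destination[1]; dy <- destination[2]
  if (!ok[dx, dy]) stop("destination patch is not traversable")
  dist <- matrix(Inf, nx, ny)
  dist[!seascape$ocean] <- NA_real_
  idx <- function(x, y) (y - 1L) * nx + x
  dist[dx, dy] <- 0
  frontier <- idx(dx, dy)
  d <- 0
  okv <- as.vector(ok)
  distv <- as.vector(dist)
  while (length(frontier)) {
    d <- d + 1
    x <- (frontier - 1L) %% nx + 1L
    y <- (frontier - 1L) %/% nx + 1L
    nbr <- c(
      ifelse(x > 1L, idx(x - 1L, y), NA),
      ifelse(x < nx, idx(x + 1L, y), NA),
      ifelse(y > 1L, idx(x, y - 1L), NA),
      ifelse(y < ny, idx(x, y + 1L), NA)
    )
    nbr <- nbr[!is.na(nbr)]
    nbr <- unique(nbr[okv[nbr] & is.infinite(distv[nbr])])
    distv[nbr] <- d
    frontier <- nbr
  }
  matrix(distv, nx, ny)
}

#' Recompute the spawning-area mask
#'
#' The spawning area comprises shelf-edge patches in the configured spawning
#' sector on which the sea-surface temperature lies strictly between 10 and
#' 14 degrees C. Recomputed whenever SST updates; idempotent at fixed SST.
#'
#' @param seascape A `seascape` with SST loaded.
#' @return The seascape with its `SArea` mask refreshed.
#' @export
spawning_mask <- function(seascape) {
  sst <- seascape$SST
  m <- seascape$shelf_edge
  m[, seq_len(seascape$ny) > seascape$spawn_sector_ymax] <- FALSE
  seascape$SArea <- m & !is.na(sst) & sst > 10 & sst < 14
  seascape
}

#' @export
print.seascape <- function(x, ...) {
  cat("<seascape> ", x$nx, " x ", x$ny, " patches (", x$cell_km, " km edge); ",
      sum(x$ocean), " ocean, ", sum(x$shelf_edge), " shelf-edge\n", sep = "")
  invisible(x)
}

#' Export a mask or field as CSV
#'
#' Long-format `x, y, value` rows, one per patch, for inspection.
#' @param field An nx-by-ny matrix.
#' @param path Output path.
#' @export
write_field_csv <- function(field, path) {
  nx <- nrow(field); ny <- ncol(field)
  df <- data.frame(
    x = rep(seq_len(nx), ny),
    y = rep(seq_len(ny), each = nx),
    value = as.vector(field)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format CSV raster
#'
#' @param path CSV with columns `x`, `y`, `value`.
#' @return An nx-by-ny matrix.
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "value") %in% names(df)))
  nx <- max(df$x); ny <- max(df$y)
  m <- matrix(NA_real_, nx, ny)
  m[cbind(df$x, df$y)] <- df$value
  m
}
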