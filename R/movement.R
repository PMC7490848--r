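# Movement: date-triggered migrations along distance fields, the daily
# gradient-area-search (GAS) foraging model in continuous space, random
# walks constrained to an area type, and northward spawning movement.
# Positions are continuous in patch units; the patch under an SI is the
# nearest cell centre.

#' Minimum swimming velocity
#'
#' `V_min = a_v L^b_v A_r^c_v` km per hour; strictly increasing in length,
#' so larger SIs arrive earliest in destination areas.
#' @param L Body length, cm (positive).
#' @param p A `parameter_set`.
#' @export
#' @examples
#' v_min(26.2, default_parameters())  # ~1.85 km/h
v_min <- function(L, p) {
  if (any(L <= 0)) stop("body length must be positive")
  p$a_v * L^p$b_v * p$A_r^p$c_v
}

#' @keywords internal
clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

#' @keywords internal
patch_of <- function(pos, n) as.integer(clamp(round(pos), 1, n))

# offsets within Euclidean radius r (patch units), cached per radius
.offset_cache <- new.env(parent = emptyenv())
#' @keywords internal
disc_offsets <- function(r) {
  key <- as.character(round(r, 3))
  if (!is.null(.offset_cache[[key]])) return(.offset_cache[[key]])
  ri <- ceiling(r)
  g <- expand.grid(dx = -ri:ri, dy = -ri:ri)
  g <- g[g$dx^2 + g$dy^2 <= r^2 + 1e-9, ]
  .offset_cache[[key]] <- g
  g
}

#' Profitability cue field
#'
#' `c_dd = A(SST) p_photo X / (X + h + c D)`, proportional to potential
#' ingestion rate; forced to zero on patches colder than the avoidance
#' threshold (7 degC) and on land.
#'
#' @param seascape A `seascape` with current fields loaded.
#' @param p A `parameter_set`.
#' @return An nx-by-ny matrix.
#' @export
profitability <- function(seascape, p) {
  sst_k <- seascape$SST + 273.15
  cue <- arrhenius(sst_k, p) * seascape$p_photo * seascape$X /
    (seascape$X + p$h + p$c * seascape$D)
  cue[!seascape$ocean] <- 0
  cue[is.na(seascape$SST) | seascape$SST < p$SST_lim] <- 0
  cue
}

#' One migration step for the migrating SIs
#'
#' Each migrating SI moves to the patch with the lowest distance index R
#' within its search radius (minimum swimming speed times the hours in a
#' step, in patch units), ties broken uniformly at random. Spawning and
#' feeding migrations are constrained to the shelf edge. The feeding
#' migration ends at a randomly drawn stop distance from the target; the
#' overwintering migration ends on entering the overwintering area; the
#' spawning migration ends on the destination patch.
#'
#' @param pop Population data.frame.
#' @param seascape A `seascape` with `spawn_dist`/`feed_dist` computed.
#' @param p A `parameter_set`.
#' @param step_days Step length, days.
#' @return The population with positions and migration flags updated.
#' @export
migration_step <- function(pop, seascape, p, step_days = p$step_days) {
  mig <- which(pop$migrating)
  if (!length(mig)) return(pop)
  nx <- seascape$nx; ny <- seascape$ny
  radius <- v_min(pop$L[mig], p) * 24 * step_days / seascape$cell_km
  for (j in seq_along(mig)) {
    i <- mig[j]
    mode <- pop$mig_mode[i]
    R <- if (mode == MIG_SPAWN) seascape$spawn_dist else seascape$feed_dist
    shelf_only <- mode %in% c(MIG_SPAWN, MIG_FEED)
    px <- patch_of(pop$x[i], nx); py <- patch_of(pop$y[i], ny)
    off <- disc_offsets(radius[j])
    cx <- px + off$dx; cy <- py + off$dy
    keep <- cx >= 1 & cx <= nx & cy >= 1 & cy <= ny
    cx <- cx[keep]; cy <- cy[keep]
    ii <- cbind(cx, cy)
    ok <- seascape$ocean[ii] & is.finite(R[ii])
    if (shelf_only) ok <- ok & seascape$shelf_edge[ii]
    if (!any(ok)) next  # no reachable patch: stay
    rv <- R[ii][ok]
    best <- which(rv == min(rv))
    pickn <- if (length(best) > 1) best[sample.int(length(best), 1)] else best
    sel <- which(ok)[pickn]
    pop$x[i] <- cx[sel]; pop$y[i] <- cy[sel]
    r_here <- rv[pickn]
    arrived <- switch(as.character(mode),
      "1" = r_here == 0,
      "2" = r_here <= pop$stop_dist[i],
      "3" = seascape$OWArea[cx[sel], cy[sel]] || r_here == 0,
      FALSE)
    if (arrived) {
      pop$migrating[i] <- FALSE
      pop$mig_mode[i] <- MIG_NONE
    }
  }
  pop$V_real[mig] <- v_min(pop$L[mig], p)
  pop
}

#' Daily gradient-area-search move for foraging adults
#'
#' Implements one day of the GAS model for the given SIs. Each day has a
#' directed half (gradient ascent on the profitability cue, with one-day
#' heading persistence when the current location improved on the day
#' before), a random half-day in a uniformly drawn non-southward direction
#' (reversed if it points at water colder than the avoidance threshold),
#' and passive displacement by currents over the full 24 h. Displacement
#' onto land or cold water by currents is abandoned in favour of the
#' centroid of the nearest suitable patch.
#'
#' @param pop Population data.frame.
#' @param idx Integer indices of the SIs to move (feeding adults).
#' @param seascape A `seascape`.
#' @param cue Profitability matrix (from [profitability()]).
#' @param p A `parameter_set`.
#' @param noise Include the stochastic components (speed noise and the
#'   random half-day); disabled for convergence diagnostics.
#' @param currents Include current displacement.
#' @return The population with positions, headings and realised speeds
#'   updated.
#' @export
gas_daily_step <- function(pop, idx, seascape, cue, p,
                           noise = TRUE, currents = TRUE) {
  n <- length(idx)
  if (!n) return(pop)
  nx <- seascape$nx; ny <- seascape$ny
  cell <- seascape$cell_km
  x <- pop$x[idx]; y <- pop$y[idx]
  px <- patch_of(x, nx); py <- patch_of(y, ny)
  here <- cbind(px, py)

  cue_at <- function(cx, cy) {
    out <- numeric(length(cx))
    inb <- cx >= 1 & cx <= nx & cy >= 1 & cy <= ny
    out[inb] <- cue[cbind(cx[inb], cy[inb])]
    out
  }
  profit_now <- cue_at(px, py)
  improved <- profit_now > pop$prev_profit[idx]

  gx <- cue_at(px + 1L, py) - cue_at(px - 1L, py)
  gy <- cue_at(px, py + 1L) - cue_at(px, py - 1L)
  gn <- sqrt(gx^2 + gy^2)
  hx <- pop$head_x[idx]; hy <- pop$head_y[idx]
  use_grad <- !improved & gn > 0
  hx[use_grad] <- (gx / gn)[use_grad]
  hy[use_grad] <- (gy / gn)[use_grad]
  hn <- sqrt(hx^2 + hy^2)
  # no heading and a flat cue: no directed displacement this day
  has_dir <- hn > 0
  hx[has_dir] <- hx[has_dir] / hn[has_dir]
  hy[has_dir] <- hy[has_dir] / hn[has_dir]

  eps <- if (noise) stats::runif(n) else 0
  vr <- v_min(pop$L[idx], p) * (1 + eps)
  half <- vr * 12 / cell  # half-day displacement, patch units

  try_move <- function(x, y, dx, dy) {
    tx <- clamp(x + dx, 1, nx); ty <- clamp(y + dy, 1, ny)
    tpx <- patch_of(tx, nx); tpy <- patch_of(ty, ny)
    bad <- !seascape$ocean[cbind(tpx, tpy)] |
      is.na(seascape$SST[cbind(tpx, tpy)]) |
      seascape$SST[cbind(tpx, tpy)] < p$SST_lim
    list(x = ifelse(bad, x, tx), y = ifelse(bad, y, ty), bad = bad)
  }

  # directed half-day
  mv <- try_move(x, y, hx * half, hy * half)
  x <- mv$x; y <- mv$y

  # random half-day, non-southward: uniform on [-90, +90] degrees about north
  if (noise) {
    theta <- stats::runif(n, -pi / 2, pi / 2)
    rx <- sin(theta); ry <- cos(theta)
    tpx <- patch_of(clamp(x + rx * half, 1, nx), nx)
    tpy <- patch_of(clamp(y + ry * half, 1, ny), ny)
    cold <- !is.na(seascape$SST[cbind(tpx, tpy)]) &
      seascape$SST[cbind(tpx, tpy)] < p$SST_lim & seascape$ocean[cbind(tpx, tpy)]
    rx[cold] <- -rx[cold]; ry[cold] <- -ry[cold]
    mv <- try_move(x, y, rx * half, ry * half)
    x <- mv$x; y <- mv$y
  }

  # current displacement over 24 h
  if (currents) {
    u <- seascape$U[here]; v <- seascape$V[here]
    cx2 <- clamp(x + u * 24 / cell, 1, nx)
    cy2 <- clamp(y + v * 24 / cell, 1, ny)
    tpx <- patch_of(cx2, nx); tpy <- patch_of(cy2, ny)
    bad <- !seascape$ocean[cbind(tpx, tpy)] |
      is.na(seascape$SST[cbind(tpx, tpy)]) |
      seascape$SST[cbind(tpx, tpy)] < p$SST_lim
    if (any(bad)) {
      near <- nearest_suitable(seascape, tpx[bad], tpy[bad], p)
      cx2[bad] <- near$x; cy2[bad] <- near$y
    }
    x <- cx2; y <- cy2
  }

  disp_km <- sqrt((x - pop$x[idx])^2 + (y - pop$y[idx])^2) * cell
  pop$x[idx] <- x; pop$y[idx] <- y
  pop$head_x[idx] <- hx; pop$head_y[idx] <- hy
  pop$prev_profit[idx] <- profit_now
  pop$V_real[idx] <- disp_km / 24
  pop
}

# centroid of the nearest ocean patch at or above the temperature threshold
#' @keywords internal
nearest_suitable <- function(seascape, px, py, p) {
  ok <- seascape$ocean & !is.na(seascape$SST) & seascape$SST >= p$SST_lim
  cand <- which(ok, arr.ind = TRUE)
  if (nrow(cand) == 0) return(list(x = px, y = py))
  outx <- px; outy <- py
  for (i in seq_along(px)) {
    d2 <- (cand[, 1] - px[i])^2 + (cand[, 2] - py[i])^2
    j <- which.min(d2)
    outx[i] <- cand[j, 1]; outy[i] <- cand[j, 2]
  }
  list(x = outx, y = outy)
}

#' Random walk constrained to an area type
#'
#' Each SI moves to a uniformly chosen patch of the given area mask within
#' its search radius (minimum swimming speed over the step); position is
#' unchanged if no such patch exists.
#'
#' @param pop Population data.frame.
#' @param idx Indices of the SIs to move.
#' @param seascape A `seascape`.
#' @param area Logical nx-by-ny mask (e.g. `seascape$OWArea`).
#' @param p A `parameter_set`.
#' @param step_days Step length, days.
#' @return The updated population.
#' @export
random_walk_in_area <- function(pop, idx, seascape, area, p,
                                step_days = p$step_days) {
  if (!length(idx)) return(pop)
  nx <- seascape$nx; ny <- seascape$ny
  radius <- v_min(pop$L[idx], p) * 24 * step_days / seascape$cell_km
  for (j in seq_along(idx)) {
    i <- idx[j]
    px <- patch_of(pop$x[i], nx); py <- patch_of(pop$y[i], ny)
    off <- disc_offsets(radius[j])
    cx <- px + off$dx; cy <- py + off$dy
    keep <- cx >= 1 & cx <= nx & cy >= 1 & cy <= ny
    cx <- cx[keep]; cy <- cy[keep]
    ok <- area[cbind(cx, cy)]
    if (!any(ok)) next
    sel <- which(ok)[sample.int(sum(ok), 1)]
    pop$x[i] <- cx[sel]; pop$y[i] <- cy[sel]
  }
  pop$V_real[idx] <- 0
  pop
}

#' Northward spawning movement after a batch is spawned
#'
#' The SI moves to the nearest patch strictly north of its location whose
#' SST lies in the preferred spawning window (10--14 degC); if there is no
#' such patch northwards, to a random neighbouring patch within the window;
#' otherwise it stays put.
#'
#' @param pop Population data.frame.
#' @param idx Indices of SIs that have just spawned a batch.
#' @param seascape A `seascape`.
#' @param p A `parameter_set`.
#' @return The updated population.
#' @export
spawning_move <- function(pop, idx, seascape, p) {
  if (!length(idx)) return(pop)
  nx <- seascape$nx; ny <- seascape$ny
  win <- seascape$ocean & !is.na(seascape$SST) &
    seascape$SST > 10 & seascape$SST < 14
  wpat <- which(win, arr.ind = TRUE)
  for (i in idx) {
    px <- patch_of(pop$x[i], nx); py <- patch_of(pop$y[i], ny)
    north <- wpat[wpat[, 2] > py, , drop = FALSE]
    if (nrow(north)) {
      d2 <- (north[, 1] - px)^2 + (north[, 2] - py)^2
      best <- which(d2 == min(d2))
      j <- if (length(best) > 1) best[sample.int(length(best), 1)] else best
      pop$x[i] <- north[j, 1]; pop$y[i] <- north[j, 2]
    } else {
      nbr <- cbind(px + c(-1L, 1L, 0L, 0L), py + c(0L, 0L, -1L, 1L))
      inb <- nbr[, 1] >= 1 & nbr[, 1] <= nx & nbr[, 2] >= 1 & nbr[, 2] <= ny
      nbr <- nbr[inb, , drop = FALSE]
      ok <- win[nbr]
      if (any(ok)) {
        j <- which(ok)[sample.int(sum(ok), 1)]
        pop$x[i] <- nbr[j, 1]; pop$y[i] <- nbr[j, 2]
      }
    }
  }
  pop
}
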