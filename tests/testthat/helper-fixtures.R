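# Shared fixture builders.  Everything is generated in code; no stored data.

COLONY <- c(167.95, -29.03)

# a planar path object without going through lon/lat (synthetic geometry)
planar <- function(t, x, y, step_km = 0) {
  arsdetect:::planar_path(data.frame(t = t, x = x, y = y), step_km = step_km,
                          trip_id = "fix", colony = COLONY)
}

# straight east-west path at constant speed, already at constant step
straight_path <- function(n = 200, step_km = 0.1, speed_kmh = 40) {
  dt <- step_km / speed_kmh * 3600
  planar(t = (seq_len(n) - 1) * dt, x = (seq_len(n) - 1) * step_km,
         y = rep(0, n), step_km = step_km)
}

# random-walk planar path with roughly constant step and jittered timing
random_walk_path <- function(n = 200, step_km = 0.1, seed = 1) {
  set.seed(seed)
  ang <- cumsum(stats::rnorm(n - 1, 0, 0.6))
  x <- c(0, cumsum(step_km * cos(ang)))
  y <- c(0, cumsum(step_km * sin(ang)))
  t <- cumsum(c(0, stats::runif(n - 1, 5, 15)))
  planar(t, x, y, step_km = step_km)
}

# independent brute-force first-passage search: full distance scan with
# which(), no running-maximum bookkeeping
fpt_brute <- function(path, index, radius_km) {
  pts <- path$points
  n <- nrow(pts)
  d <- sqrt((pts$x - pts$x[index])^2 + (pts$y - pts$y[index])^2)
  fwd <- which(d > radius_km & seq_len(n) > index)
  bwd <- which(d > radius_km & seq_len(n) < index)
  if (length(fwd) == 0 || length(bwd) == 0) return(NA_real_)
  jf <- min(fwd); jb <- max(bwd)
  ff <- (radius_km - d[jf - 1]) / (d[jf] - d[jf - 1])
  tf <- pts$t[jf - 1] + ff * (pts$t[jf] - pts$t[jf - 1])
  fb <- (radius_km - d[jb + 1]) / (d[jb] - d[jb + 1])
  tb <- pts$t[jb + 1] - fb * (pts$t[jb + 1] - pts$t[jb])
  tf - tb
}

# exhaustive minimal-contrast partition by enumerating all breakpoint sets
partition_exhaustive <- function(z, K, Lmin) {
  n <- length(z)
  seg_cost <- function(i, j) { v <- z[i:j]; sum((v - mean(v))^2) }
  if (K == 1) return(list(breaks = integer(0), J = seg_cost(1, n)))
  best <- list(breaks = NULL, J = Inf)
  combos <- utils::combn(n - 1, K - 1)
  for (c_i in seq_len(ncol(combos))) {
    b <- combos[, c_i]
    lens <- diff(c(0, b, n))
    if (any(lens < Lmin)) next
    starts <- c(1, b + 1); ends <- c(b, n)
    J <- sum(vapply(seq_len(K), function(k) seg_cost(starts[k], ends[k]),
                    numeric(1)))
    if (J < best$J - 1e-12) best <- list(breaks = b, J = J)
  }
  best
}

# synthetic behaviour series built directly from a state vector
behaviour_from_states <- function(states, t0 = 0, trip_id = "fix") {
  structure(list(t = t0 + seq_along(states) - 1,
                 states = factor(states, levels = arsdetect:::BEHAVIOUR_STATES),
                 trip_id = trip_id),
            class = "behaviour_series")
}

# a small track drawn on a lon/lat grid around the colony
track_from_km <- function(xy_km, t, trip_id = "fix") {
  ll <- unproject_points(xy_km[, 1], xy_km[, 2], COLONY)
  ars_track(data.frame(t = t, lon = ll$lon, lat = ll$lat), trip_id, COLONY)
}
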