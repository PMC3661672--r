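#' Configuration of the synthetic foraging-trip generator
#'
#' Defines the study conditions the generator emulates: trips of a
#' plunge-diving central-place forager lasting 0.88-14.18 h (mean 6.52,
#' SD 3.79), with 0-4 search patches per trip, fast directed transit,
#' slow tortuous within-patch search, resting bouts on the water, plunge
#' dives concentrated inside patches, 4-min GPS fixes, 1 Hz depth and
#' 16 Hz two-axis acceleration.  A configurable fraction of trips contains
#' a resting-dominated loiter near the colony instead of a true search
#' patch — the mechanism that produces false ARS detections.
#'
#' @param n_trips number of trips in a fleet.
#' @param colony `c(lon, lat)` of the colony.
#' @param dur_mean_h,dur_sd_h,dur_range_h truncated-normal trip duration
#'   distribution (hours).
#' @param cruise_kmh,transit_kappa transit speed and von Mises heading
#'   concentration about the bearing to the next waypoint.
#' @param patch_kmh,patch_kappa within-patch speed and (low) heading
#'   concentration — high turning rates at reduced speed.
#' @param rest_kmh drift speed while sitting on the water.
#' @param n_patch_probs probabilities of 0-4 patches per trip.
#' @param patch_radius_range_km planted patch radius range.
#' @param patch_dwell_range_h dwell time per true patch.
#' @param patch_sit_frac_range within-patch fraction of time sitting on the
#'   water for true patches.
#' @param false_sit_frac_range sitting fraction for false (loiter) patches.
#' @param loiter_dwell_range_h dwell range of a false loiter.
#' @param rest_rate_per_h rate of brief resting pauses during transit.
#' @param rest_dur_range_s duration range of those pauses (seconds).
#'   Extended daytime resting belongs to the patch and loiter states (birds
#'   rest where they have been foraging); transit pauses are kept short so
#'   the planted patch count remains the meaningful zone truth.
#' @param dive_rate_patch_per_h,dive_rate_transit_per_h,dive_rate_loiter_per_h
#'   plunge-dive rates per hour of flight in each context.
#' @param frac_false fraction of trips planted with a false loiter.
#' @param gps_interval_s GPS sampling interval (default 240 s).
#' @param gps_noise_km GPS position noise SD.
#' @param flap_hz,flap_amp_g,noise_g wing-beat frequency, heave amplitude
#'   and sensor noise of the synthesized acceleration.
#' @param seed root seed; trips use independent substreams indexed by trip.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_trips = 50,
                       colony = c(167.95, -29.03),
                       dur_mean_h = 6.52, dur_sd_h = 3.79,
                       dur_range_h = c(0.88, 14.18),
                       cruise_kmh = 40, transit_kappa = 60,
                       patch_kmh = 10, patch_kappa = 1,
                       rest_kmh = 0.5,
                       n_patch_probs = c(0.20, 0.55, 0.20, 0.04, 0.01),
                       patch_radius_range_km = c(0.5, 8),
                       patch_dwell_range_h = c(0.3, 2.0),
                       patch_sit_frac_range = c(0.05, 0.6),
                       false_sit_frac_range = c(0.78, 0.95),
                       loiter_dwell_range_h = c(1, 3),
                       rest_rate_per_h = 0.15,
                       rest_dur_range_s = c(180, 480),
                       dive_rate_patch_per_h = 8,
                       dive_rate_transit_per_h = 0.5,
                       dive_rate_loiter_per_h = 2,
                       frac_false = 0.2,
                       gps_interval_s = 240, gps_noise_km = 0.02,
                       flap_hz = 5, flap_amp_g = 0.4, noise_g = 0.02,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_trips >= 0, cfg$gps_interval_s > 0,
            all(cfg$dur_range_h > 0), cfg$dur_range_h[2] <= 24,
            abs(sum(cfg$n_patch_probs) - 1) < 1e-6,
            all(c(cfg$rest_rate_per_h, cfg$dive_rate_patch_per_h,
                  cfg$dive_rate_transit_per_h, cfg$dive_rate_loiter_per_h) >= 0),
            cfg$frac_false >= 0, cfg$frac_false <= 1)
  structure(cfg, class = "sim_config")
}

# von Mises sampler (Best & Fisher 1979), vectorized rejection.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, 2L * (n - length(out)))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    vals <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    out <- c(out, vals[seq_len(min(length(vals), n - length(out)))])
  }
  out + mu
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:10000) {
    v <- stats::rnorm(1, mean, sd)
    if (v >= lo && v <= hi) return(v)
  }
  stats::runif(1, lo, hi)
}

# movement-state codes used while simulating
.MV_TRANSIT <- 1L; .MV_PATCH <- 2L; .MV_REST <- 3L

#' Simulate one foraging trip
#'
#' State-machine simulation at 1 s resolution: directed correlated-walk
#' transit at cruise speed, tortuous low-speed search inside planted
#' patches, drifting rest bouts, and a return leg to the colony; plunge
#' dives are Poisson events on flight seconds at context-dependent rates;
#' depth and two-axis acceleration are synthesized per behavioural state
#' (flapping as a sinusoidal heave oscillation, gliding and sitting as
#' sensor noise).  Fully reproducible from `(config$seed, trip_index)`.
#'
#' @param config a [sim_config].
#' @param trip_index trip number within the fleet (determines the
#'   substream).
#' @param with_logger synthesize the depth/acceleration record (set
#'   `FALSE` for GPS-only studies; much lighter).
#' @return List with `track` ([ars_track]), `logger` ([logger_record] or
#'   `NULL`), and `truth` (per-second `states`, `phase` codes, planted
#'   `patches`, `dives`, and a one-row `summary`).
#' @export
simulate_trip <- function(config, trip_index, with_logger = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed((config$seed * 1009L + trip_index * 7919L) %% 2147483629L)
  trip_id <- sprintf("sim%03d", trip_index)

  ## ---- plan -------------------------------------------------------------
  T_h <- rtruncnorm1(config$dur_mean_h, config$dur_sd_h,
                     config$dur_range_h[1], config$dur_range_h[2])
  is_false <- stats::runif(1) < config$frac_false
  k <- sample(0:4, 1, prob = config$n_patch_probs)
  k <- min(k, max(if (is_false) 1L else 0L, floor(T_h / 1.2)))
  if (is_false) k <- max(k, 1L)
  dwell <- numeric(0); sitfr <- numeric(0); false_flag <- logical(0)
  if (k > 0) {
    false_flag <- c(is_false, rep(FALSE, k - 1L))
    dwell <- ifelse(false_flag,
                    stats::runif(k, config$loiter_dwell_range_h[1],
                                 config$loiter_dwell_range_h[2]),
                    stats::runif(k, config$patch_dwell_range_h[1],
                                 config$patch_dwell_range_h[2]))
    if (sum(dwell) > 0.55 * T_h) dwell <- dwell * 0.55 * T_h / sum(dwell)
    sitfr <- ifelse(false_flag,
                    stats::runif(k, config$false_sit_frac_range[1],
                                 config$false_sit_frac_range[2]),
                    stats::runif(k, config$patch_sit_frac_range[1],
                                 config$patch_sit_frac_range[2]))
  }
  n_rest <- stats::rpois(1, config$rest_rate_per_h * T_h)
  rest_dur <- stats::runif(n_rest, config$rest_dur_range_s[1],
                           config$rest_dur_range_s[2])
  if (sum(dwell) * 3600 + sum(rest_dur) > 0.7 * T_h * 3600) {
    n_rest <- 0L; rest_dur <- numeric(0)
  }
  travel_h <- T_h - sum(dwell) - sum(rest_dur) / 3600
  Rmax <- max(2, config$cruise_kmh * travel_h / 2 * 0.85)
  radius <- numeric(0)
  if (k > 0) {
    radius <- stats::runif(k, config$patch_radius_range_km[1],
                           config$patch_radius_range_km[2])
    radius <- pmin(radius, pmax(0.3, Rmax / 3))
    radius[false_flag] <- 1.0  # nominal loiter extent; drift sets the size
  }
  # patch centres along a slowly turning outbound bearing, separated enough
  # that zones stay distinct
  cx <- cy <- numeric(k)
  if (k > 0) {
    theta0 <- stats::runif(1, 0, 2 * pi)
    dist_frac <- sort(stats::runif(k, 0.35, 0.95))
    if (k > 1)  # enforce radial separation
      for (j in 2:k) dist_frac[j] <- max(dist_frac[j],
                                         dist_frac[j - 1] +
                                           (3 + radius[j] + radius[j - 1]) / Rmax)
    dd <- pmin(dist_frac, 1) * Rmax
    if (any(false_flag)) dd[false_flag] <- max(3, min(stats::runif(1, 5, 15), 0.9 * Rmax))
    th <- theta0 + cumsum(c(0, stats::runif(max(0, k - 1), -0.3, 0.3)))
    cx <- dd * sin(th); cy <- dd * cos(th)
  }

  ## ---- movement simulation at 1 Hz -------------------------------------
  cap <- 16L * 3600L
  xs <- numeric(cap); ys <- numeric(cap); mv <- integer(cap); ph <- integer(cap)
  pos <- c(0, 0); tick <- 0L
  v_cruise <- config$cruise_kmh / 3600
  v_patch <- config$patch_kmh / 3600
  v_rest <- config$rest_kmh / 3600
  heading <- if (k > 0) atan2(cx[1], cy[1]) else stats::runif(1, 0, 2 * pi)
  emit <- function(n, x, y, code, phase) {
    idx <- tick + seq_len(n)
    xs[idx] <<- x; ys[idx] <<- y; mv[idx] <<- code; ph[idx] <<- phase
    tick <<- tick + n
    pos <<- c(x[n], y[n])
  }
  drift <- function(dur, phase) {
    dur <- min(dur, cap - tick)
    if (dur <= 0) return(invisible())
    h <- heading + cumsum(stats::rnorm(dur, 0, 0.1))
    emit(dur, pos[1] + cumsum(v_rest * sin(h)),
         pos[2] + cumsum(v_rest * cos(h)), .MV_REST, phase)
  }
  transit <- function(target, arrive_km, phase, rest_at = numeric(0),
                      rest_len = numeric(0)) {
    leg0 <- sqrt(sum((pos - target)^2))
    while (tick < cap) {
      d <- sqrt(sum((pos - target)^2))
      if (d <= arrive_km) break
      # scheduled resting bout on this leg?
      if (length(rest_at) > 0 && d / max(leg0, 1e-9) < rest_at[1]) {
        drift(round(rest_len[1]), phase)
        rest_at <- rest_at[-1]; rest_len <- rest_len[-1]
        next
      }
      chunk <- min(30L, cap - tick)
      bearing <- atan2(target[1] - pos[1], target[2] - pos[2])
      h <- bearing + rvonmises(chunk, 0, config$transit_kappa)
      px <- pos[1] + cumsum(v_cruise * sin(h))
      py <- pos[2] + cumsum(v_cruise * cos(h))
      hit <- which(sqrt((px - target[1])^2 + (py - target[2])^2) <= arrive_km)
      nuse <- if (length(hit)) hit[1] else chunk
      heading <<- h[nuse]
      emit(nuse, px[seq_len(nuse)], py[seq_len(nuse)], .MV_TRANSIT, phase)
      if (length(hit)) break
    }
  }
  patch_dwell <- function(centre, r, dur_s, sit_frac, phase) {
    left <- min(dur_s, cap - tick)
    mean_fly <- 240
    mean_sit <- mean_fly * sit_frac / max(1 - sit_frac, 0.02)
    flying <- TRUE
    while (left > 0 && tick < cap) {
      bout <- if (flying) round(min(max(stats::rexp(1, 1 / mean_fly), 30), 900))
              else round(min(max(stats::rexp(1, 1 / mean_sit), 60), 1500))
      bout <- min(bout, left)
      if (flying) {
        done <- 0L
        while (done < bout && tick < cap) {
          chunk <- min(20L, bout - done)
          d <- sqrt(sum((pos - centre)^2))
          base <- if (d > 0.85 * r)
            atan2(centre[1] - pos[1], centre[2] - pos[2]) else heading
          h <- base + cumsum(rvonmises(chunk, 0, config$patch_kappa))
          emit(chunk, pos[1] + cumsum(v_patch * sin(h)),
               pos[2] + cumsum(v_patch * cos(h)), .MV_PATCH, phase)
          heading <<- h[chunk]
          done <- done + chunk
        }
      } else drift(bout, phase)
      left <- left - bout
      flying <- !flying
    }
  }

  # distribute transit rest bouts over the legs (positions as leg fractions)
  legs <- k + 1L
  rest_leg <- if (n_rest > 0) sample.int(legs, n_rest, replace = TRUE) else integer(0)
  patch_span <- matrix(NA_real_, nrow = k, ncol = 2)
  phase_ctr <- 0L
  if (k == 0L) {  # patchless loop: fly to a turn point before heading home
    phase_ctr <- phase_ctr + 1L
    theta0 <- stats::runif(1, 0, 2 * pi)
    transit(c(Rmax * sin(theta0), Rmax * cos(theta0)), arrive_km = 0.3,
            phase = phase_ctr)
  }
  for (j in seq_len(k)) {
    phase_ctr <- phase_ctr + 1L
    sel <- rest_leg == j
    transit(c(cx[j], cy[j]), arrive_km = 0.3, phase = phase_ctr,
            rest_at = sort(stats::runif(sum(sel), 0.2, 0.8), decreasing = TRUE),
            rest_len = rest_dur[sel])
    phase_ctr <- phase_ctr + 1L
    t0p <- tick
    patch_dwell(c(cx[j], cy[j]), radius[j], round(dwell[j] * 3600),
                sitfr[j], phase_ctr)
    patch_span[j, ] <- c(t0p, tick - 1L)
  }
  phase_ctr <- phase_ctr + 1L
  sel <- rest_leg == legs
  # return as a loop: swing via an offset waypoint so the inbound leg does
  # not retrace the outbound corridor
  d_home <- sqrt(sum(pos^2))
  if (d_home > 6) {
    rot <- sample(c(-1, 1), 1) * stats::runif(1, 0.4, 0.7)
    via <- 0.55 * c(cos(rot) * pos[1] + sin(rot) * pos[2],
                    -sin(rot) * pos[1] + cos(rot) * pos[2])
    transit(via, arrive_km = 0.5, phase = phase_ctr)
  }
  transit(c(0, 0), arrive_km = 0.4, phase = phase_ctr,
          rest_at = sort(stats::runif(sum(sel), 0.2, 0.8), decreasing = TRUE),
          rest_len = rest_dur[sel])
  n <- tick
  xs <- xs[seq_len(n)]; ys <- ys[seq_len(n)]
  mv <- mv[seq_len(n)]; ph <- ph[seq_len(n)]
  patch_in <- logical(n)
  for (j in seq_len(k))
    if (!is.na(patch_span[j, 1]))
      patch_in[(patch_span[j, 1] + 1):(patch_span[j, 2] + 1)] <- TRUE

  ## ---- behavioural truth ------------------------------------------------
  states <- character(n)
  states[mv == .MV_REST] <- "WATER"
  states[mv == .MV_PATCH] <- "FLAP"
  # transit flight alternates flapping and short glides, restarting with a
  # flap bout after every interruption
  tr_runs <- rle(mv == .MV_TRANSIT)
  ends <- cumsum(tr_runs$lengths); starts <- ends - tr_runs$lengths + 1L
  for (q in which(tr_runs$values)) {
    len <- tr_runs$lengths[q]
    lab <- character(0)
    flap <- TRUE
    while (length(lab) < len) {
      b <- if (flap) round(min(max(stats::rexp(1, 1 / 20), 8), 60))
           else round(stats::runif(1, 2, 8))
      lab <- c(lab, rep(if (flap) "FLAP" else "GLIDE", b))
      flap <- !flap
    }
    states[starts[q]:ends[q]] <- lab[seq_len(len)]
  }

  ## ---- plunge dives -----------------------------------------------------
  rate <- numeric(n)
  fl <- states == "FLAP"
  rate[fl & patch_in] <- config$dive_rate_patch_per_h
  loiter_in <- logical(n)
  if (k > 0 && any(false_flag))
    for (j in which(false_flag))
      loiter_in[(patch_span[j, 1] + 1):(patch_span[j, 2] + 1)] <- TRUE
  rate[fl & loiter_in] <- config$dive_rate_loiter_per_h
  rate[fl & !patch_in & !loiter_in] <- config$dive_rate_transit_per_h
  cand <- which(stats::runif(n) < rate / 3600)
  cand <- cand[cand > 30 & cand < n - 10]
  starts_d <- integer(0); last <- -100L
  for (s in cand) if (s - last >= 15L) { starts_d <- c(starts_d, s); last <- s }
  dive_dur <- if (length(starts_d)) sample(2:6, length(starts_d), replace = TRUE) else integer(0)
  dive_peak <- stats::runif(length(starts_d), 0.6, 4)
  depth <- pmax(stats::rnorm(n, 0, 0.02), -0.4)
  for (i in seq_along(starts_d)) {
    s <- starts_d[i]; dd <- dive_dur[i]
    prof <- dive_peak[i] * (1 - abs(seq_len(dd) - (dd + 1) / 2) / ((dd + 1) / 2)) * 0.6 + dive_peak[i] * 0.4
    idx <- s:(s + dd - 1L)
    depth[idx] <- prof
    states[idx] <- "DIVE"
  }
  dives <- data.frame(start_t = starts_d - 1,
                      end_t = starts_d - 1 + dive_dur,
                      max_depth_m = dive_peak)[order(starts_d), , drop = FALSE]
  rownames(dives) <- NULL

  # take-off: first 3 s of flight directly after sitting on the water
  fl2 <- states %in% c("FLAP", "GLIDE")
  r2 <- rle(fl2)
  e2 <- cumsum(r2$lengths); s2 <- e2 - r2$lengths + 1L
  for (q in which(r2$values)) {
    if (s2[q] > 1 && states[s2[q] - 1L] == "WATER") {
      w <- s2[q]:min(e2[q], s2[q] + 2L)
      states[w] <- "TAKEOFF"
    }
  }

  ## ---- sensors ----------------------------------------------------------
  tsec <- seq_len(n) - 1
  gps_idx <- unique(c(seq(1L, n, by = config$gps_interval_s), n))
  gx <- xs[gps_idx] + stats::rnorm(length(gps_idx), 0, config$gps_noise_km)
  gy <- ys[gps_idx] + stats::rnorm(length(gps_idx), 0, config$gps_noise_km)
  ll <- unproject_points(gx, gy, config$colony)
  track <- ars_track(data.frame(t = tsec[gps_idx], lon = ll$lon, lat = ll$lat),
                     trip_id = trip_id, colony = config$colony)
  logger <- NULL
  if (with_logger) {
    fs <- 16L
    flapping <- states %in% c("FLAP", "TAKEOFF")
    fl16 <- rep(flapping, each = fs)
    t16 <- (seq_len(n * fs) - 1) / fs
    osc <- sin(2 * pi * config$flap_hz * t16)
    heave <- 1 + stats::rnorm(n * fs, 0, config$noise_g) +
      config$flap_amp_g * osc * fl16
    surge <- stats::rnorm(n * fs, 0, config$noise_g) +
      0.5 * config$flap_amp_g * cos(2 * pi * config$flap_hz * t16) * fl16
    dive16 <- rep(states == "DIVE", each = fs)
    heave[dive16] <- heave[dive16] + stats::rnorm(sum(dive16), 0, 0.05)
    logger <- logger_record(depth, surge, heave, t0 = 0, trip_id = trip_id)
  }
  patches <- if (k > 0)
    data.frame(patch = seq_len(k), centre_x = cx, centre_y = cy,
               radius_km = radius, t_start = patch_span[, 1],
               t_end = patch_span[, 2], is_false = false_flag,
               sit_frac = sitfr)
  else
    data.frame(patch = integer(0), centre_x = numeric(0), centre_y = numeric(0),
               radius_km = numeric(0), t_start = numeric(0),
               t_end = numeric(0), is_false = logical(0), sit_frac = numeric(0))
  truth <- list(states = factor(states, levels = BEHAVIOUR_STATES),
                t = tsec, phase = ph, patches = patches, dives = dives,
                summary = data.frame(trip_id = trip_id,
                                     duration_h = (n - 1) / 3600,
                                     n_patches = k,
                                     patch_radii = paste(round(radius, 2),
                                                         collapse = ";"),
                                     planted_false = is_false,
                                     n_dives = nrow(dives)))
  list(track = track, logger = logger, truth = truth)
}

#' Simulate a fleet of foraging trips
#'
#' @param config a [sim_config].
#' @param dir optional directory; when given, the fleet is written out as
#'   `tracks.csv` (all trips, ISO timestamps), per-trip `logger/<id>_depth.csv`
#'   and `logger/<id>_acc.csv`, and `manifest.csv` of planted truths.
#' @param with_logger synthesize logger records (see [simulate_trip()]).
#' @return List with `trips` (per-trip bundles) and `manifest` (data frame).
#' @export
make_fleet <- function(config, dir = NULL, with_logger = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  trips <- lapply(seq_len(config$n_trips), function(i)
    simulate_trip(config, i, with_logger = with_logger))
  manifest <- if (length(trips) == 0)
    data.frame(trip_id = character(0), duration_h = numeric(0),
               n_patches = integer(0), patch_radii = character(0),
               planted_false = logical(0), n_dives = integer(0))
  else do.call(rbind, c(lapply(trips, function(tr) tr$truth$summary),
                        make.row.names = FALSE))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    origin <- as.POSIXct("2010-02-12 00:00:00", tz = "UTC")
    gps <- do.call(rbind, lapply(trips, function(tr)
      data.frame(trip_id = tr$track$trip_id,
                 timestamp_iso8601 = format(origin + tr$track$fixes$t,
                                            "%Y-%m-%dT%H:%M:%S"),
                 lon = tr$track$fixes$lon, lat = tr$track$fixes$lat)))
    if (!is.null(gps)) data.table::fwrite(gps, file.path(dir, "tracks.csv"))
    data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
    if (with_logger && length(trips) > 0) {
      dir.create(file.path(dir, "logger"), showWarnings = FALSE)
      t_origin <- as.numeric(origin)  # same time base as tracks.csv
      for (tr in trips) {
        lg <- tr$logger
        data.table::fwrite(data.frame(t = t_origin + seq_along(lg$depth_m) - 1,
                                      depth_m = lg$depth_m),
                           file.path(dir, "logger",
                                     paste0(lg$trip_id, "_depth.csv")))
        data.table::fwrite(data.frame(t = t_origin +
                                        (seq_along(lg$surge_g) - 1) / 16,
                                      surge_g = lg$surge_g,
                                      heave_g = lg$heave_g),
                           file.path(dir, "logger",
                                     paste0(lg$trip_id, "_acc.csv")))
      }
    }
  }
  list(trips = trips, manifest = manifest)
}
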