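#' Analysis configuration
#'
#' Bundles every tunable constant of the detection pipeline.  Unknown keys
#' are rejected.
#'
#' @param step_km track rediscretization step (km).
#' @param radii first-passage time radius grid (km).
#' @param Lmin minimum segment length in interpolated steps (10 steps = 1 km
#'   of path at the default step).
#' @param Kmax largest candidate segment count.
#' @param threshold second-difference threshold of the segment-count rule.
#' @param min_drop minimum relative contrast drop before segmenting (see
#'   [choose_k()]).
#' @param min_sep minimum spread of segment means (ln units) for an ARS call.
#' @param flap_rms_g,dive_threshold_m,takeoff_s,flight_context_s ethogram
#'   thresholds, see [classify_behaviour()].
#' @param false_ars_cutoff percentage of zone time sitting on the water above
#'   which a zone is flagged false (strict inequality; default 70).
#' @return An `ars_config` list.
#' @export
ars_config <- function(step_km = 0.1, radii = seq(0.1, 25, by = 0.1),
                       Lmin = 10, Kmax = 20, threshold = 0.75,
                       min_drop = 0.5, min_sep = 0.1,
                       flap_rms_g = 0.1, dive_threshold_m = 0.2,
                       takeoff_s = 3, flight_context_s = 10,
                       false_ars_cutoff = 70) {
  cfg <- as.list(environment())
  stopifnot(cfg$step_km > 0, cfg$Lmin >= 1, cfg$Kmax >= 2,
            cfg$false_ars_cutoff > 0, cfg$false_ars_cutoff < 100)
  structure(cfg, class = "ars_config")
}

#' Detect ARS zones on one foraging trip
#'
#' Chains the track-based stages: colony-centred projection, constant-step
#' rediscretization, first-passage time profile over the radius sweep, ARS
#' scale selection, penalized-contrast segmentation of `ln(FPT)` at that
#' scale, ARS/movement labelling, zone extraction and trip sectioning.
#' A trip whose variance curve has no interior peak, or whose segmentation
#' is homogeneous, is reported with zero zones — a no-ARS trip, not an error.
#'
#' @param track an [ars_track].
#' @param config an [ars_config].
#' @return An `ars_detection`: list with `trip_id`, `metrics`, `path`,
#'   `profile`, `segmentation`, `zones` (data frame) and `sections`
#'   (data frame).
#' @export
detect_ars <- function(track, config = ars_config()) {
  stopifnot(inherits(track, "ars_track"))
  metrics <- trip_metrics(track)
  path <- interpolate_path(project_track(track), config$step_km)
  span <- range(track$fixes$t)
  n <- nrow(path$points)
  profile <- NULL; seg <- NULL
  zones <- empty_zones(track$trip_id)
  if (n >= 2 * config$Lmin) {
    profile <- fpt_profile(path, config$radii)
    if (!is.na(profile$ars_scale_km)) {
      j <- match(profile$ars_scale_km, profile$radii_km)
      seg <- segment_fpt(log(profile$fpt_s[, j]), Lmin = config$Lmin,
                         Kmax = config$Kmax, threshold = config$threshold,
                         min_drop = config$min_drop, min_sep = config$min_sep)
      zones <- extract_ars_zones(path, seg, profile)
    }
  }
  sections <- section_trip(span, zones, trip_id = track$trip_id)
  structure(list(trip_id = track$trip_id, metrics = metrics, path = path,
                 profile = profile, segmentation = seg, zones = zones,
                 sections = sections),
            class = "ars_detection")
}

#' @export
print.ars_detection <- function(x, ...) {
  sc <- if (is.null(x$profile) || is.na(x$profile$ars_scale_km)) "none"
        else sprintf("%.1f km", x$profile$ars_scale_km)
  cat(sprintf("<ars_detection '%s': ARS scale %s, %d zone(s), %d section(s)>\n",
              x$trip_id, sc, nrow(x$zones), nrow(x$sections)))
  invisible(x)
}

empty_zones <- function(trip_id = character(0)) {
  data.frame(trip_id = character(0), start_t = numeric(0), end_t = numeric(0),
             ars_duration_h = numeric(0), scale_km = numeric(0),
             mean_dist_col_km = numeric(0))
}

#' Extract ARS zones from a labelled segmentation
#'
#' Each maximal run of ARS-labelled segments becomes one zone; start and end
#' times come from its member path points, the scale is the trip's ARS scale,
#' and the colony distance is the mean planar distance of member points from
#' the colony (the projection origin).
#'
#' @param path the interpolated `planar_path`.
#' @param segmentation an `ars_segmentation` computed on it.
#' @param profile the trip's `fpt_profile` (provides the scale).
#' @return Data frame of zones: `trip_id,start_t,end_t,ars_duration_h,`
#'   `scale_km,mean_dist_col_km` (zero rows when no segment is ARS).
#' @export
extract_ars_zones <- function(path, segmentation, profile) {
  s <- segmentation
  if (!any(s$labels == "ARS")) return(empty_zones())
  ends <- c(s$breakpoints, length(s$series))
  starts <- c(1L, s$breakpoints + 1L)
  r <- rle(s$labels == "ARS")
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1L
  pts <- path$points
  pi0 <- s$offset - 1L
  rows <- lapply(which(r$values), function(k) {
    i0 <- starts[seg_start[k]] + pi0
    i1 <- ends[seg_end[k]] + pi0
    member <- i0:i1
    data.frame(trip_id = path$trip_id,
               start_t = pts$t[i0], end_t = pts$t[i1],
               ars_duration_h = (pts$t[i1] - pts$t[i0]) / 3600,
               scale_km = profile$ars_scale_km,
               mean_dist_col_km = mean(sqrt(pts$x[member]^2 +
                                            pts$y[member]^2)))
  })
  do.call(rbind, rows)
}

#' Section a trip by ARS presence
#'
#' Tiles the trip span with alternating ARS-absent / ARS-present sections:
#' one interior zone yields three sections, two zones five, no zones a
#' single absent section.  Degenerate zero-length absent sections (a zone
#' touching the trip start or end) are dropped.
#'
#' @param trip_span numeric `c(start, end)` of the trip, seconds.
#' @param zones zone data frame (non-overlapping, within the span).
#' @param trip_id trip identifier for the output rows.
#' @return Data frame: `trip_id,section_index,ars_present,start_t,end_t,`
#'   `duration_h`.
#' @export
section_trip <- function(trip_span, zones, trip_id = NA_character_) {
  stopifnot(length(trip_span) == 2L, trip_span[2] >= trip_span[1])
  z <- zones[order(zones$start_t), , drop = FALSE]
  if (nrow(z) > 1 && any(z$start_t[-1] < z$end_t[-nrow(z)]))
    stop("overlapping ARS zones")
  if (nrow(z) > 0 && (z$start_t[1] < trip_span[1] ||
                      z$end_t[nrow(z)] > trip_span[2]))
    stop("ARS zone outside the trip span")
  bounds <- c(trip_span[1],
              as.vector(rbind(z$start_t, z$end_t)),
              trip_span[2])
  present <- rep(c(FALSE, TRUE), length.out = 2 * nrow(z) + 1)
  out <- data.frame(trip_id = trip_id,
                    section_index = NA_integer_,
                    ars_present = present,
                    start_t = bounds[-length(bounds)],
                    end_t = bounds[-1])
  out$duration_h <- (out$end_t - out$start_t) / 3600
  # sub-second slivers fall below the 1 Hz behaviour resolution
  out <- out[out$duration_h * 3600 > 1, , drop = FALSE]
  out$section_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Time budget of trip sections or ARS zones
#'
#' Adds the proportions of time spent sitting on the water surface and in
#' flight, plus the dive count, to each interval: `pct_sitting` is the share
#' of `WATER` seconds, `pct_flight` the share of `TAKEOFF + FLAP + GLIDE`
#' seconds (both over the at-sea seconds of the interval; `LAND` seconds are
#' excluded), and `n_dives` counts dives whose start falls in the interval.
#' Intervals are half-open `[start_t, end_t)`; the final second of the trip
#' belongs to the last interval.
#'
#' @param sections data frame with `start_t` and `end_t` columns (sections
#'   or zones).
#' @param behaviour a `behaviour_series` covering the intervals.
#' @param dives dive data frame from [detect_dives()].
#' @return `sections` with `pct_sitting`, `pct_flight`, `n_dives` added.
#' @export
time_budget <- function(sections, behaviour, dives) {
  stopifnot(inherits(behaviour, "behaviour_series"))
  st <- behaviour$states
  tt <- behaviour$t
  t_end <- tt[length(tt)]
  out <- sections
  out$pct_sitting <- out$pct_flight <- NA_real_
  out$n_dives <- NA_integer_
  for (i in seq_len(nrow(out))) {
    w <- tt >= out$start_t[i] &
      (tt < out$end_t[i] | (out$end_t[i] >= t_end & tt == t_end))
    s <- st[w]
    s <- s[s != "LAND"]
    if (length(s) == 0) stop("empty section: no at-sea behaviour seconds")
    out$pct_sitting[i] <- 100 * sum(s == "WATER") / length(s)
    out$pct_flight[i] <- 100 * sum(s %in% c("TAKEOFF", "FLAP", "GLIDE")) /
      length(s)
    out$n_dives[i] <- if (nrow(dives) == 0) 0L else
      sum(dives$start_t >= out$start_t[i] & dives$start_t < out$end_t[i])
  }
  out
}

#' Flag false ARS zones by the resting criterion
#'
#' A zone in which the bird sat on the water surface for strictly more than
#' `cutoff` percent of the zone duration is flagged as a false ARS zone:
#' the low travel speed that triggered the detection came from resting, not
#' from active search.
#'
#' @param zones zone data frame with a `pct_sitting` column.
#' @param cutoff percentage cutoff (default 70; strict inequality, so 70.0
#'   itself is not flagged).
#' @return `zones` with logical `is_false` and `criterion` columns added.
#' @export
flag_false_ars <- function(zones, cutoff = 70) {
  stopifnot("pct_sitting" %in% names(zones))
  zones$is_false <- zones$pct_sitting > cutoff
  zones$criterion <- sprintf("resting>%g%%", cutoff)
  zones
}

#' Apply the GPS-only decision rule for false ARS zones
#'
#' Classifies a zone from track-derived features alone, for trips where no
#' logger record exists.  A zone is called false when its spatial scale is
#' below 4.05 km, the trip's total distance below 284.4 km, the zone's mean
#' colony distance below 25.14 km, and either the trip lasted more than
#' 6.0 h or (for shorter trips) the zone lasted less than 0.90 h; every
#' other combination is called true.
#'
#' @param zones data frame with columns `scale_km`, `total_dist_km`,
#'   `mean_dist_col_km`, `trip_duration_h`, `ars_duration_h`.
#' @return Factor with levels `false`, `true`, one per row.
#' @export
apply_printed_rule <- function(zones) {
  need <- c("scale_km", "total_dist_km", "mean_dist_col_km",
            "trip_duration_h", "ars_duration_h")
  miss <- setdiff(need, names(zones))
  if (length(miss)) stop("missing features: ", paste(miss, collapse = ", "))
  if (anyNA(zones[, need])) stop("missing feature values")
  f <- zones$scale_km < 4.05 & zones$total_dist_km < 284.4 &
    zones$mean_dist_col_km < 25.14 &
    (zones$trip_duration_h > 6.0 | zones$ars_duration_h < 0.90)
  factor(ifelse(f, "false", "true"), levels = c("false", "true"))
}

#' Zone feature table for one detection
#'
#' Joins the trip-level movement metrics onto the trip's zones, yielding the
#' feature layout used by the false-ARS classifiers and summaries.
#'
#' @param detection an `ars_detection`.
#' @return Data frame with `trip_id`, `trip_duration_h`, `max_dist_col_km`,
#'   `total_dist_km` and the zone columns.
#' @export
zone_features <- function(detection) {
  z <- detection$zones
  if (nrow(z) == 0) return(cbind(z[0, ], trip_duration_h = numeric(0),
                                 max_dist_col_km = numeric(0),
                                 total_dist_km = numeric(0)))
  z$trip_duration_h <- detection$metrics$duration_h
  z$max_dist_col_km <- detection$metrics$max_distance_km
  z$total_dist_km <- detection$metrics$total_distance_km
  z
}

#' Summarize a zone table
#'
#' Mean and SD of the zone-level foraging parameters, the count of zones
#' without dives, and the trip-level duration summary over distinct trips
#' (a trip with two zones counts once).
#'
#' @param zones zone feature data frame (see [zone_features()]); columns
#'   `ars_duration_h`, `scale_km`, `mean_dist_col_km` are required, the rest
#'   are summarized when present.
#' @return One-row data frame of summary statistics.
#' @export
zone_summary <- function(zones) {
  ms <- function(v) c(mean = mean(v), sd = stats::sd(v))
  out <- data.frame(n_zones = nrow(zones))
  for (col in c("ars_duration_h", "scale_km", "mean_dist_col_km",
                "n_dives", "pct_sitting")) {
    if (col %in% names(zones)) {
      v <- ms(zones[[col]])
      out[[paste0("mean_", col)]] <- unname(v["mean"])
      out[[paste0("sd_", col)]] <- unname(v["sd"])
    }
  }
  if ("n_dives" %in% names(zones))
    out$n_zero_dive <- sum(zones$n_dives == 0)
  if (all(c("trip_id", "trip_duration_h") %in% names(zones))) {
    per_trip <- zones$trip_duration_h[!duplicated(zones$trip_id)]
    out$n_trips <- length(per_trip)
    out$mean_trip_duration_h <- mean(per_trip)
    out$sd_trip_duration_h <- stats::sd(per_trip)
  }
  out
}

#' Example zone records: false ARS zones of masked booby trips
#'
#' Loads the bundled worked-example dataset: 11 ARS zone records from masked
#' booby *Sula dactylatra* foraging trips in which the bird spent more than
#' 70% of the zone duration sitting on the water surface (out of a study
#' cohort of 57 detected zones).  Useful for exercising the false-ARS
#' flagging, summaries and the GPS-only decision rule without raw tracks.
#'
#' @return Zone feature data frame (11 rows).
#' @export
example_false_ars_zones <- function() {
  utils::read.csv(system.file("extdata", "booby_false_ars_zones.csv",
                              package = "arsdetect"),
                  stringsAsFactors = FALSE)
}
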