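#' Foraging-trip track
#'
#' Container for the GPS fixes of one foraging trip of a central-place
#' forager, together with the colony location the trip starts and ends at.
#'
#' @param fixes data frame with columns `t` (seconds, UTC), `lon`, `lat`
#'   (decimal degrees, WGS84).  Timestamps must be strictly increasing and at
#'   least two fixes are required.
#' @param trip_id trip identifier (coerced to character).
#' @param colony numeric `c(lon, lat)` of the colony.
#' @return An object of class `ars_track`.
#' @examples
#' trk <- ars_track(data.frame(t = c(0, 240, 480),
#'                             lon = c(167.95, 167.96, 167.97),
#'                             lat = c(-29.03, -29.02, -29.01)),
#'                  trip_id = "demo", colony = c(167.95, -29.03))
#' trip_metrics(trk)
#' @export
ars_track <- function(fixes, trip_id, colony) {
  stopifnot(is.data.frame(fixes), all(c("t", "lon", "lat") %in% names(fixes)))
  fixes <- fixes[order(fixes$t), c("t", "lon", "lat")]
  rownames(fixes) <- NULL
  if (nrow(fixes) < 2L) stop("a track needs at least 2 fixes")
  if (any(diff(fixes$t) <= 0)) stop("fix timestamps must be strictly increasing")
  if (any(abs(fixes$lat) > 90) || any(abs(fixes$lon) > 180))
    stop("fix coordinates outside valid lon/lat range")
  stopifnot(is.numeric(colony), length(colony) == 2L)
  structure(list(trip_id = as.character(trip_id),
                 fixes = fixes,
                 colony = c(lon = unname(colony[1]), lat = unname(colony[2]))),
            class = "ars_track")
}

#' @export
print.ars_track <- function(x, ...) {
  m <- trip_metrics(x)
  cat(sprintf("<ars_track '%s': %d fixes, %.2f h, %.1f km travelled, max %.1f km from colony>\n",
              x$trip_id, nrow(x$fixes), m$duration_h, m$total_distance_km,
              m$max_distance_km))
  invisible(x)
}

great_circle_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M) / 1000
}

#' Project a track into a colony-centred plane
#'
#' Azimuthal equidistant projection centred on the colony: each fix is mapped
#' to `(d sin b, d cos b)` where `d` is its great-circle distance from the
#' colony (km) and `b` the initial bearing from the colony.  Distances from
#' the colony — the quantity the downstream analysis relies on — are preserved
#' exactly along every radial.
#'
#' @param track an [ars_track].
#' @return A `planar_path`: timestamped `(t, x, y)` points in km with
#'   `step_km = 0` (raw, not yet rediscretized).
#' @export
project_track <- function(track) {
  stopifnot(inherits(track, "ars_track"))
  p <- as.matrix(track$fixes[, c("lon", "lat")])
  col <- matrix(track$colony, nrow = 1)
  d_km <- great_circle_km(col, p)
  if (any(d_km > 2000))
    stop("fix farther than 2000 km from colony; projection distortion too large")
  b <- geosphere::bearing(col, p, a = EARTH_RADIUS_M, f = 0)
  b[is.na(b)] <- 0  # fix exactly at the colony
  br <- b * pi / 180
  planar_path(data.frame(t = track$fixes$t,
                         x = d_km * sin(br),
                         y = d_km * cos(br)),
              step_km = 0, trip_id = track$trip_id, colony = track$colony)
}

planar_path <- function(points, step_km, trip_id = NA_character_,
                        colony = c(NA_real_, NA_real_)) {
  stopifnot(all(c("t", "x", "y") %in% names(points)))
  if (any(diff(points$t) < 0)) stop("path timestamps must be non-decreasing")
  structure(list(points = points[, c("t", "x", "y")], step_km = step_km,
                 trip_id = trip_id, colony = colony),
            class = "planar_path")
}

#' @export
print.planar_path <- function(x, ...) {
  cat(sprintf("<planar_path '%s': %d points, step %s km>\n", x$trip_id,
              nrow(x$points),
              if (x$step_km > 0) format(x$step_km) else "raw"))
  invisible(x)
}

#' Inverse of the colony-centred projection
#'
#' @param x,y planar coordinates in km.
#' @param colony `c(lon, lat)` of the projection centre.
#' @return Data frame with `lon`, `lat`.
#' @export
unproject_points <- function(x, y, colony) {
  d <- sqrt(x^2 + y^2) * 1000
  b <- atan2(x, y) * 180 / pi
  out <- geosphere::destPoint(matrix(colony, nrow = 1), b = b, d = d,
                              a = EARTH_RADIUS_M, f = 0)
  data.frame(lon = out[, 1], lat = out[, 2])
}

#' Rediscretize a path at constant step length
#'
#' Re-samples the polyline so that successive points are exactly `step_km`
#' apart (chord distance), the standard pre-processing for first-passage time
#' analysis.  Timestamps are linearly interpolated within the original
#' segment; the first point is preserved and the final vertex is kept as a
#' (possibly shorter) trailing step, so polyline length is conserved to
#' within one step.
#'
#' @param path a `planar_path` (raw, from [project_track()]).
#' @param step_km step length in km (default 0.1).
#' @return A `planar_path` with `step_km` set.
#' @export
interpolate_path <- function(path, step_km = 0.1) {
  stopifnot(inherits(path, "planar_path"), step_km > 0)
  pts <- path$points
  if (nrow(pts) < 2L) stop("path needs at least 2 points")
  len <- sum(sqrt(diff(pts$x)^2 + diff(pts$y)^2))
  if (len <= 0) stop("zero-length path cannot be rediscretized")
  out <- .redisc_cpp(pts$t, pts$x, pts$y, step_km)
  planar_path(out, step_km = step_km, trip_id = path$trip_id,
              colony = path$colony)
}

#' Per-trip movement metrics
#'
#' Duration, total great-circle distance travelled and maximum great-circle
#' distance from the colony.
#'
#' @param track an [ars_track].
#' @return One-row data frame with `duration_h`, `total_distance_km`,
#'   `max_distance_km`.
#' @export
trip_metrics <- function(track) {
  stopifnot(inherits(track, "ars_track"))
  p <- as.matrix(track$fixes[, c("lon", "lat")])
  n <- nrow(p)
  steps <- great_circle_km(p[-n, , drop = FALSE], p[-1, , drop = FALSE])
  dcol <- great_circle_km(matrix(track$colony, nrow = 1), p)
  data.frame(duration_h = (track$fixes$t[n] - track$fixes$t[1]) / 3600,
             total_distance_km = sum(steps),
             max_distance_km = max(dcol))
}

#' Split an overnight trip into daylight tracks
#'
#' Removes fixes falling inside the supplied night windows (half-open
#' `[start, end)`) and splits the remainder into one track per daylight
#' block.  Nocturnal resting at the sea surface would otherwise inflate the
#' first-passage time variance.
#'
#' @param track an [ars_track].
#' @param night_windows list of numeric `c(start, end)` pairs (seconds),
#'   disjoint and within the track span.
#' @return List of `ars_track` objects (possibly empty; blocks with fewer
#'   than 2 fixes are dropped).  Daylight blocks are suffixed `.1`, `.2`, ...
#' @export
split_overnight <- function(track, night_windows) {
  stopifnot(inherits(track, "ars_track"))
  if (length(night_windows) == 0) return(list(track))
  w <- do.call(rbind, lapply(night_windows, function(v) {
    stopifnot(length(v) == 2L, v[2] > v[1]); v
  }))
  w <- w[order(w[, 1]), , drop = FALSE]
  if (nrow(w) > 1 && any(w[-1, 1] < w[-nrow(w), 2]))
    stop("night windows must be disjoint")
  tt <- track$fixes$t
  in_night <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(w)))
    in_night <- in_night | (tt >= w[i, 1] & tt < w[i, 2])
  keep <- !in_night
  if (!any(keep)) {
    message(sprintf("trip '%s': night windows cover every fix", track$trip_id))
    return(list())
  }
  block <- 1L + vapply(tt, function(ti) sum(w[, 2] <= ti), integer(1))
  out <- list()
  for (b in unique(block[keep])) {
    idx <- keep & block == b
    if (sum(idx) < 2L) next
    out[[length(out) + 1L]] <-
      ars_track(track$fixes[idx, ], sprintf("%s.%d", track$trip_id, b),
                track$colony)
  }
  out
}

#' Read foraging tracks from CSV
#'
#' Expects columns `trip_id,timestamp_iso8601,lon,lat`; one file may hold
#' several trips.
#'
#' @param file path to the CSV file.
#' @param colony numeric `c(lon, lat)`.
#' @return Named list of [ars_track] objects.
#' @export
read_tracks_csv <- function(file, colony) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("trip_id", "timestamp_iso8601", "lon", "lat")
  if (!all(need %in% names(d)))
    stop("track CSV must have columns ", paste(need, collapse = ","))
  ts <- as.POSIXct(d$timestamp_iso8601, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(ts)) stop("unparseable timestamps in ", file)
  out <- lapply(split(seq_len(nrow(d)), d$trip_id), function(idx) {
    ars_track(data.frame(t = as.numeric(ts[idx]), lon = d$lon[idx],
                         lat = d$lat[idx]),
              trip_id = d$trip_id[idx][1], colony = colony)
  })
  out[order(names(out))]
}

#' Export tracks as GeoJSON LineStrings
#'
#' @param tracks list of [ars_track] objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
export_geojson <- function(tracks, file) {
  if (inherits(tracks, "ars_track")) tracks <- list(tracks)
  feats <- lapply(tracks, function(tr) {
    list(type = "Feature",
         properties = list(trip_id = tr$trip_id),
         geometry = list(type = "LineString",
                         coordinates = unname(
                           lapply(seq_len(nrow(tr$fixes)), function(i)
                             c(tr$fixes$lon[i], tr$fixes$lat[i])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
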