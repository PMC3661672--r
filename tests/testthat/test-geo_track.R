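test_that("track construction enforces its invariants", {
  f <- data.frame(t = c(0, 240), lon = c(167.9, 167.91), lat = c(-29, -29))
  expect_s3_class(ars_track(f, "a", COLONY), "ars_track")
  expect_error(ars_track(f[1, ], "a", COLONY), "at least 2")
  expect_error(ars_track(data.frame(t = c(0, 0), lon = 167.9, lat = -29),
                         "a", COLONY), "strictly increasing")
  expect_error(ars_track(data.frame(t = c(0, 240), lon = 167.9,
                                    lat = c(-29, 95)), "a", COLONY),
               "valid lon/lat")
})

test_that("projection is colony-centred, distance-true and invertible", {
  trk <- ars_track(data.frame(t = c(0, 240, 480),
                              lon = c(COLONY[1], COLONY[1], COLONY[1]),
                              lat = c(COLONY[2], COLONY[2] + 1, COLONY[2] + 1)),
                   "p", COLONY)
  pp <- project_track(trk)
  expect_equal(unname(unlist(pp$points[1, c("x", "y")])), c(0, 0))
  # one degree of latitude north: ~111.2 km along +y, against a haversine oracle
  d_oracle <- geosphere::distHaversine(COLONY, c(COLONY[1], COLONY[2] + 1),
                                       r = 6371008.8) / 1000
  expect_equal(pp$points$y[2], d_oracle, tolerance = 1e-9)
  expect_equal(pp$points$y[2], 111.2, tolerance = 0.01)
  expect_lt(abs(pp$points$x[2]), 1e-6)
  # identical fixes project identically
  expect_equal(pp$points[2, c("x", "y")], pp$points[3, c("x", "y")],
               ignore_attr = TRUE)
  # round trip to better than 1 m for fixes out to 500 km
  set.seed(42)
  for (i in 1:25) {
    x <- runif(1, -350, 350); y <- runif(1, -350, 350)
    ll <- unproject_points(x, y, COLONY)
    trk2 <- ars_track(data.frame(t = c(0, 60), lon = c(COLONY[1], ll$lon),
                                 lat = c(COLONY[2], ll$lat)), "r", COLONY)
    p2 <- project_track(trk2)$points
    expect_lt(sqrt((p2$x[2] - x)^2 + (p2$y[2] - y)^2), 1e-3)  # km
  }
  far <- unproject_points(2100, 0, COLONY)
  expect_error(project_track(
    ars_track(data.frame(t = c(0, 60), lon = c(COLONY[1], far$lon),
                         lat = c(COLONY[2], far$lat)), "f", COLONY)),
    "2000 km")
})

test_that("rediscretization yields constant steps and conserves length", {
  # straight 1-km segment at constant speed
  pp <- interpolate_path(planar(c(0, 90), c(0, 1), c(0, 0)), 0.1)
  expect_equal(nrow(pp$points), 11)
  expect_equal(diff(pp$points$x), rep(0.1, 10), tolerance = 1e-9)
  expect_equal(diff(pp$points$t), rep(9, 10), tolerance = 1e-9)
  # L-shaped 2-km path conserves length to within one step
  pl <- interpolate_path(planar(c(0, 60, 120), c(0, 1, 1), c(0, 0, 1)), 0.1)
  chord <- sum(sqrt(diff(pl$points$x)^2 + diff(pl$points$y)^2))
  expect_lt(abs(chord - 2), 0.1)
  # random 50-fix walks: every step exactly 0.1 km, length conserved
  # smooth GPS-like walks: gentle turning between ~0.5 km fixes
  for (seed in 1:5) {
    set.seed(seed)
    ang <- cumsum(rnorm(49, 0, 0.2))
    x <- c(0, cumsum(0.5 * cos(ang))); y <- c(0, cumsum(0.5 * sin(ang)))
    raw <- planar(seq(0, by = 60, length.out = 50), x, y)
    out <- interpolate_path(raw, 0.1)
    steps <- sqrt(diff(out$points$x)^2 + diff(out$points$y)^2)
    expect_true(all(abs(head(steps, -1) - 0.1) < 1e-6))
    expect_true(tail(steps, 1) <= 0.1 + 1e-6)
    # chord stepping never lengthens the polyline, and shortens it by at
    # most one step per original corner (corner cutting)
    raw_len <- sum(sqrt(diff(x)^2 + diff(y)^2))
    expect_lte(sum(steps), raw_len + 1e-6)
    expect_gte(sum(steps), raw_len - 0.1 * 49 - 1e-6)
    # timestamps non-decreasing, first point preserved
    expect_true(all(diff(out$points$t) >= 0))
    expect_equal(unlist(out$points[1, ]), unlist(raw$points[1, ]))
  }
  expect_error(interpolate_path(planar(c(0, 10), c(0, 0), c(0, 0)), 0.1),
               "zero-length")
})

test_that("trip metrics match closed-form trips", {
  # 10x10 km square loop from the colony
  sq <- track_from_km(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0)),
                      t = (0:4) * 900)
  m <- trip_metrics(sq)
  expect_equal(m$total_distance_km, 40, tolerance = 0.01)
  expect_equal(m$duration_h, 1)
  # out-and-back to 50 km
  ob <- track_from_km(rbind(c(0, 0), c(0, 50), c(0, 0)), t = (0:2) * 3600)
  m2 <- trip_metrics(ob)
  expect_equal(m2$total_distance_km, 100, tolerance = 0.01)
  expect_equal(m2$max_distance_km, 50, tolerance = 0.01)
  expect_true(m$max_distance_km <= m$total_distance_km)
  # duplicated positions (distinct timestamps) change nothing
  ob2 <- track_from_km(rbind(c(0, 0), c(0, 50), c(0, 50), c(0, 0)),
                       t = c(0, 3600, 3610, 7200))
  expect_equal(trip_metrics(ob2)$total_distance_km, 100, tolerance = 0.01)
})

test_that("overnight splitting removes night fixes with half-open windows", {
  trk <- track_from_km(cbind(seq(0, 20, length.out = 21), 0), t = (0:20) * 600)
  expect_identical(split_overnight(trk, list()), list(trk))
  # one mid-track night window splits into two daylight tracks
  parts <- split_overnight(trk, list(c(3000, 7000)))
  expect_length(parts, 2)
  got <- sort(unlist(lapply(parts, function(p) p$fixes$t)))
  want <- trk$fixes$t[!(trk$fixes$t >= 3000 & trk$fixes$t < 7000)]
  expect_equal(got, want)
  # boundary convention [start, end): fix at start excluded, at end included
  parts2 <- split_overnight(trk, list(c(3000, 6000)))
  all_t <- unlist(lapply(parts2, function(p) p$fixes$t))
  expect_false(3000 %in% all_t)
  expect_true(6000 %in% all_t)
  # oracle filter equivalence
  expect_setequal(all_t, trk$fixes$t[!(trk$fixes$t >= 3000 &
                                       trk$fixes$t < 6000)])
  expect_message(res <- split_overnight(trk, list(c(-1, 1e9))), "every fix")
  expect_length(res, 0)
})

test_that("tracks round-trip through CSV and export to GeoJSON", {
  tmp <- withr::local_tempdir()
  cfg <- sim_config(seed = 3, n_trips = 2)
  make_fleet(cfg, dir = tmp, with_logger = FALSE)
  tracks <- read_tracks_csv(file.path(tmp, "tracks.csv"), cfg$colony)
  expect_length(tracks, 2)
  expect_s3_class(tracks[[1]], "ars_track")
  gj <- file.path(tmp, "tracks.geojson")
  export_geojson(tracks, gj)
  parsed <- jsonlite::read_json(gj)
  expect_equal(parsed$type, "FeatureCollection")
  expect_length(parsed$features, 2)
  expect_equal(parsed$features[[1]]$geometry$type, "LineString")
})
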