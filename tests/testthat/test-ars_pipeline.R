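test_that("trips are sectioned by ARS presence", {
  zone <- function(s, e) data.frame(trip_id = "t", start_t = s, end_t = e,
                                    ars_duration_h = (e - s) / 3600,
                                    scale_km = 1, mean_dist_col_km = 10)
  # one interior zone: absent / present / absent
  s1 <- section_trip(c(0, 10000), zone(3000, 5000), "t")
  expect_equal(nrow(s1), 3)
  expect_equal(s1$ars_present, c(FALSE, TRUE, FALSE))
  # two interior zones: five sections
  s2 <- section_trip(c(0, 10000), rbind(zone(2000, 3000), zone(6000, 7000)), "t")
  expect_equal(nrow(s2), 5)
  expect_equal(s2$ars_present, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  # no zones: a single absent section
  s0 <- section_trip(c(0, 10000), zone(1, 1)[0, ], "t")
  expect_equal(nrow(s0), 1)
  expect_false(s0$ars_present)
  # a zone touching the trip start drops the degenerate leading section
  s3 <- section_trip(c(0, 10000), zone(0, 4000), "t")
  expect_equal(nrow(s3), 2)
  expect_equal(s3$ars_present, c(TRUE, FALSE))
  # section durations tile the trip span
  for (s in list(s1, s2, s0, s3))
    expect_equal(sum(s$duration_h) * 3600, 10000, tolerance = 1)
  expect_error(section_trip(c(0, 10000),
                            rbind(zone(2000, 5000), zone(4000, 7000)), "t"),
               "overlapping")
})

test_that("time budgets count sitting, flight and dives per section", {
  states <- c(rep("WATER", 100), rep("FLAP", 200), rep("WATER", 100))
  beh <- behaviour_from_states(states)
  sec <- data.frame(trip_id = "t", section_index = 1:2,
                    ars_present = c(FALSE, TRUE),
                    start_t = c(0, 100), end_t = c(100, 399),
                    duration_h = c(100, 299) / 3600)
  dives <- data.frame(start_t = c(150, 250, 380), end_t = c(153, 253, 383),
                      max_depth_m = c(1, 2, 1), type = NA)
  out <- time_budget(sec, beh, dives)
  expect_equal(out$pct_sitting, c(100, 100 / 3), tolerance = 1e-6)
  expect_equal(out$pct_flight, c(0, 200 / 3), tolerance = 1e-6)
  expect_equal(out$n_dives, c(0L, 3L))
  # dive-count conservation over a full tiling
  expect_equal(sum(out$n_dives), nrow(dives))
  # a zone scripted at 50% sitting comes back at 50%
  set.seed(8)
  st <- sample(rep(c("WATER", "FLAP"), each = 500))
  z <- data.frame(start_t = 0, end_t = 1000)
  out2 <- time_budget(z, behaviour_from_states(st), dives[0, ])
  expect_equal(out2$pct_sitting, 50, tolerance = 2)
})

test_that("zones are flagged false only above the strict 70% cutoff", {
  zones <- example_false_ars_zones()
  flagged <- flag_false_ars(zones)
  expect_equal(nrow(flagged), 11)
  expect_true(all(flagged$is_false))           # every record sits above 70%
  edge <- flag_false_ars(data.frame(pct_sitting = c(69.9, 70.0, 70.1)))
  expect_equal(edge$is_false, c(FALSE, FALSE, TRUE))
})

test_that("the printed GPS-only rule reproduces its row-by-row outcomes", {
  zones <- example_false_ars_zones()
  verdict <- apply_printed_rule(zones)
  # row-by-row oracle: evaluate the printed thresholds directly
  oracle <- with(zones, scale_km < 4.05 & total_dist_km < 284.4 &
                   mean_dist_col_km < 25.14 &
                   (trip_duration_h > 6.0 | ars_duration_h < 0.90))
  expect_equal(as.character(verdict), ifelse(oracle, "false", "true"))
  expect_equal(as.character(verdict[1]), "false")      # trip 18.2
  expect_equal(as.character(verdict[11]), "true")      # distant overnight trip
  expect_equal(sum(verdict == "false"), 9)
  expect_error(apply_printed_rule(zones[, -4]), "missing")
})

test_that("maximal runs of ARS segments become single zones", {
  pp <- straight_path(n = 80)
  prof <- structure(list(radii_km = 1, fpt_s = matrix(1, 80, 1),
                         var_log = 1, ars_scale_km = 1.5, trip_id = "fix"),
                    class = "fpt_profile")
  seg <- structure(list(series = rnorm(80), offset = 1L,
                        breakpoints = c(20L, 40L, 60L), K = 4L,
                        labels = c("movement", "ARS", "ARS", "movement"),
                        contrast_by_K = NA),
                   class = "ars_segmentation")
  z <- extract_ars_zones(pp, seg, prof)
  expect_equal(nrow(z), 1)  # the two adjacent ARS segments fuse
  expect_equal(z$start_t, pp$points$t[21])
  expect_equal(z$end_t, pp$points$t[60])
  expect_equal(z$scale_km, 1.5)
  seg$labels <- rep("movement", 4)
  expect_equal(nrow(extract_ars_zones(pp, seg, prof)), 0)
})

test_that("zone summaries aggregate per zone and per distinct trip", {
  zones <- flag_false_ars(example_false_ars_zones())
  s <- zone_summary(zones)
  expect_equal(s$n_zones, 11)
  expect_equal(s$n_trips, 9)          # 70.3 and 287.1 each hold two zones
  expect_equal(s$n_zero_dive, 5)
  expect_equal(s$mean_ars_duration_h, mean(zones$ars_duration_h))
})

test_that("detection end to end finds a planted patch and sections the trip", {
  cfg <- sim_config(seed = 55, n_trips = 1, n_patch_probs = c(0, 1, 0, 0, 0),
                    frac_false = 0, rest_rate_per_h = 0,
                    dur_mean_h = 3, dur_sd_h = 0.5, dur_range_h = c(2, 4),
                    patch_dwell_range_h = c(0.8, 1.2))
  sim <- simulate_trip(cfg, 1, with_logger = FALSE)
  det <- detect_ars(sim$track)
  expect_gte(nrow(det$zones), 1)
  expect_equal(nrow(det$sections), 2 * nrow(det$zones) + 1, tolerance = 1)
  expect_equal(sum(det$sections$duration_h), det$metrics$duration_h,
               tolerance = 1 / 3600)
  # zones lie where the patch was planted
  p <- sim$truth$patches
  expect_lt(abs(det$zones$start_t[1] - p$t_start[1]), 1800)
})
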