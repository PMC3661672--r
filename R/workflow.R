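#' Simulate a fleet to disk
#'
#' Thin workflow wrapper over [make_fleet()] for the command-line front end.
#'
#' @param config a [sim_config].
#' @param out_dir output directory.
#' @param with_logger synthesize logger records.
#' @return The fleet bundle, invisibly.
#' @export
run_simulate <- function(config, out_dir, with_logger = TRUE) {
  fleet <- make_fleet(config, dir = out_dir, with_logger = with_logger)
  message(sprintf("simulate: %d trips -> %s", nrow(fleet$manifest), out_dir))
  invisible(fleet)
}

#' Detect ARS zones across a set of trips
#'
#' Runs [detect_ars()] per trip, logging the ARS scale (or "none") of each,
#' and assembles the combined zone-feature and section tables.  A trip that
#' fails (malformed input) is skipped with a warning rather than aborting
#' the batch.
#'
#' @param tracks list of [ars_track] objects, or a directory containing a
#'   `tracks.csv` written by [run_simulate()].
#' @param config an [ars_config].
#' @param colony `c(lon, lat)`, required when `tracks` is a directory.
#' @return List with `detections` (named list), `zones` (combined
#'   [zone_features()] table) and `sections`.
#' @export
run_detect <- function(tracks, config = ars_config(), colony = NULL) {
  if (is.character(tracks)) {
    stopifnot(!is.null(colony))
    tracks <- read_tracks_csv(file.path(tracks, "tracks.csv"), colony)
  }
  if (inherits(tracks, "ars_track")) tracks <- list(tracks)
  detections <- list()
  for (tr in tracks) {
    det <- tryCatch(detect_ars(tr, config), error = function(e) {
      warning(sprintf("detect: trip '%s' skipped: %s", tr$trip_id,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(det)) next
    sc <- if (is.null(det$profile) || is.na(det$profile$ars_scale_km)) "none"
          else sprintf("%.1f km", det$profile$ars_scale_km)
    message(sprintf("detect: trip=%s fixes=%d scale=%s zones=%d sections=%d",
                    det$trip_id, nrow(tr$fixes), sc, nrow(det$zones),
                    nrow(det$sections)))
    detections[[det$trip_id]] <- det
  }
  zones <- do.call(rbind, c(lapply(detections, zone_features),
                            make.row.names = FALSE))
  sections <- do.call(rbind, c(lapply(detections, `[[`, "sections"),
                               make.row.names = FALSE))
  list(detections = detections, zones = zones, sections = sections)
}

#' Classify detected zones with logger-derived time budgets
#'
#' Computes time budgets for zones and sections from the per-trip behaviour
#' series and dive lists, flags false ARS zones by the resting criterion,
#' fits the false-ARS classification tree, validates it by jack-knife, and
#' fits the binomial model of ARS occurrence over sections.  Trips without
#' a behaviour record are excluded with a message.
#'
#' @param detection_result output of [run_detect()].
#' @param behaviours named list (by trip id) of `behaviour_series`.
#' @param dives named list (by trip id) of dive data frames.
#' @param config an [ars_config].
#' @return List with `zones` (budgeted, flagged), `sections` (budgeted),
#'   `tree`, `jack` (jack-knife counts; `NULL` when the tree cannot be
#'   fitted), and `glmm` (`NULL` when the section table is too small).
#' @export
run_classify <- function(detection_result, behaviours, dives,
                         config = ars_config()) {
  zs <- list(); ss <- list()
  for (det in detection_result$detections) {
    id <- det$trip_id
    if (is.null(behaviours[[id]])) {
      message(sprintf("classify: trip=%s has no behaviour record; excluded", id))
      next
    }
    dv <- dives[[id]]
    if (is.null(dv)) dv <- data.frame(start_t = numeric(0))
    z <- zone_features(det)
    if (nrow(z) > 0)
      z <- flag_false_ars(time_budget(z, behaviours[[id]], dv),
                          cutoff = config$false_ars_cutoff)
    zs[[id]] <- z
    ss[[id]] <- time_budget(det$sections, behaviours[[id]], dv)
  }
  zones <- do.call(rbind, c(zs, make.row.names = FALSE))
  sections <- do.call(rbind, c(ss, make.row.names = FALSE))
  tree_fit <- NULL; jack <- NULL; glmm <- NULL
  feat_cols <- c("ars_duration_h", "scale_km", "mean_dist_col_km",
                 "trip_duration_h", "total_dist_km")
  if (!is.null(zones) && nrow(zones) >= 10 &&
      length(unique(zones$is_false)) == 2) {
    lab <- factor(ifelse(zones$is_false, "false", "true"),
                  levels = c("false", "true"))
    tree_fit <- fit_tree(zones[, feat_cols], lab)
    jack <- jackknife(zones[, feat_cols], lab)
  } else {
    message("classify: zone table too small or single-class; tree skipped")
  }
  if (!is.null(sections) && nrow(sections) >= 20 &&
      length(unique(sections$ars_present)) == 2) {
    sec <- sections
    sec$trip_duration_h <- stats::ave(sec$end_t, sec$trip_id, FUN = max) / 3600
    glmm <- tryCatch(fit_ars_glmm(sec), error = function(e) {
      message("classify: GLMM not fitted: ", conditionMessage(e)); NULL
    })
  }
  message(sprintf("classify: zones=%d (false=%d) sections=%d",
                  if (is.null(zones)) 0L else nrow(zones),
                  if (is.null(zones)) 0L else sum(zones$is_false),
                  if (is.null(sections)) 0L else nrow(sections)))
  list(zones = zones, sections = sections, tree = tree_fit, jack = jack,
       glmm = glmm)
}

#' Run the full pipeline on a synthetic fleet in memory
#'
#' Streams trip by trip — simulate, detect, decode behaviour, budget — so a
#' full fleet with 16 Hz acceleration never has to be held in memory at
#' once, then runs the classification stage on the pooled tables.
#'
#' @param config a [sim_config].
#' @param ars an [ars_config].
#' @param with_logger decode behaviour and budgets (set `FALSE` for a
#'   GPS-only study: detection output only).
#' @return As [run_classify()], plus `detections` and `manifest`.
#' @export
run_synthetic_study <- function(config = sim_config(), ars = ars_config(),
                                with_logger = TRUE) {
  detections <- list(); behaviours <- list(); dives <- list()
  manifest <- list()
  for (i in seq_len(config$n_trips)) {
    sim <- simulate_trip(config, i, with_logger = with_logger)
    id <- sim$track$trip_id
    detections[[id]] <- detect_ars(sim$track, ars)
    if (with_logger) {
      behaviours[[id]] <- classify_behaviour(
        sim$logger, flap_rms_g = ars$flap_rms_g,
        dive_threshold_m = ars$dive_threshold_m, takeoff_s = ars$takeoff_s,
        flight_context_s = ars$flight_context_s)
      dv <- detect_dives(sim$logger$depth_m, ars$dive_threshold_m)
      dives[[id]] <- type_dives(dv, behaviours[[id]])
    }
    manifest[[id]] <- sim$truth$summary
  }
  det_res <- list(
    detections = detections,
    zones = do.call(rbind, c(lapply(detections, zone_features),
                             make.row.names = FALSE)),
    sections = do.call(rbind, c(lapply(detections, `[[`, "sections"),
                                make.row.names = FALSE)))
  out <- if (with_logger) run_classify(det_res, behaviours, dives)
         else list(zones = det_res$zones, sections = det_res$sections,
                   tree = NULL, jack = NULL, glmm = NULL)
  out$detections <- detections
  out$manifest <- do.call(rbind, c(manifest, make.row.names = FALSE))
  out
}

#' Markdown summary report of a classified study
#'
#' Mean (SD) and range of the trip- and zone-level foraging parameters, the
#' false/true zone split, and the validation results, laid out as a small
#' Markdown document.
#'
#' @param result output of [run_classify()] or [run_synthetic_study()].
#' @param file optional path; when given the report is written there.
#' @return Character vector of Markdown lines, invisibly when `file` is
#'   given.
#' @export
run_report <- function(result, file = NULL) {
  msr <- function(v) sprintf("%.2f +/- %.2f (%.2f-%.2f)", mean(v),
                             stats::sd(v), min(v), max(v))
  z <- result$zones
  lines <- c("# ARS study report", "")
  if (!is.null(z) && nrow(z) > 0) {
    per_trip <- z[!duplicated(z$trip_id), ]
    lines <- c(lines, "## Foraging parameters", "",
               "| parameter | value | n |", "|---|---|---|",
               sprintf("| Trip duration (h) | %s | %d |",
                       msr(per_trip$trip_duration_h), nrow(per_trip)),
               sprintf("| Total distance travelled (km) | %s | %d |",
                       msr(per_trip$total_dist_km), nrow(per_trip)),
               sprintf("| Duration of ARS (h) | %s | %d |",
                       msr(z$ars_duration_h), nrow(z)),
               sprintf("| Scale of ARS (km) | %s | %d |",
                       msr(z$scale_km), nrow(z)),
               sprintf("| Distance of ARS from colony (km) | %s | %d |",
                       msr(z$mean_dist_col_km), nrow(z)))
    if ("pct_sitting" %in% names(z))
      lines <- c(lines,
                 sprintf("| %% sitting on water within ARS | %s | %d |",
                         msr(z$pct_sitting), nrow(z)),
                 sprintf("| Dives within ARS | %s | %d |",
                         msr(z$n_dives), nrow(z)))
    if ("is_false" %in% names(z)) {
      lines <- c(lines, "",
                 sprintf("False ARS zones (resting > 70%% of zone duration): %d of %d (%.1f%%).",
                         sum(z$is_false), nrow(z),
                         100 * sum(z$is_false) / nrow(z)))
    }
  } else {
    lines <- c(lines, "No ARS zones detected.")
  }
  if (!is.null(result$jack)) {
    j <- result$jack
    lines <- c(lines, "", "## Jack-knife validation of the decision tree", "",
               sprintf("- %s: %d of %d correct (%.1f%%)",
                       j$class, j$correct, j$n, j$pct_correct))
  }
  if (!is.null(result$glmm)) {
    g <- result$glmm
    lines <- c(lines, "", "## ARS-occurrence model", "",
               sprintf("- %s: b = %.3f (z = %.2f, p = %.3g)",
                       names(g$coefficients), g$coefficients, g$z, g$p))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
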