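BEHAVIOUR_STATES <- c("LAND", "TAKEOFF", "FLAP", "GLIDE", "WATER", "DIVE")

#' Depth/acceleration logger record
#'
#' One trip's worth of logger signals: depth at 1 Hz and two-axis
#' acceleration (surge along the body axis, heave dorso-ventral) at 16 Hz.
#'
#' @param depth_m numeric depth series, 1 Hz, metres (small negative sensor
#'   noise down to -0.5 m tolerated).
#' @param surge_g,heave_g numeric acceleration series, 16 Hz, in g.
#' @param t0 start time in seconds (default 0).
#' @param trip_id trip identifier.
#' @return A `logger_record`.
#' @export
logger_record <- function(depth_m, surge_g, heave_g, t0 = 0,
                          trip_id = NA_character_) {
  stopifnot(is.numeric(depth_m), is.numeric(surge_g), is.numeric(heave_g),
            length(surge_g) == length(heave_g))
  if (any(depth_m < -0.5)) stop("depth below -0.5 m: not sensor noise")
  n_acc <- length(surge_g)
  if (abs(n_acc - 16 * length(depth_m)) > 16)
    stop("acceleration series must cover the depth series at 16 Hz")
  structure(list(depth_m = depth_m, surge_g = surge_g, heave_g = heave_g,
                 t0 = t0, depth_hz = 1, acc_hz = 16,
                 trip_id = as.character(trip_id)),
            class = "logger_record")
}

#' @export
print.logger_record <- function(x, ...) {
  cat(sprintf("<logger_record '%s': %.2f h, depth 1 Hz, acceleration %g Hz>\n",
              x$trip_id, length(x$depth_m) / 3600, x$acc_hz))
  invisible(x)
}

#' Separate static and dynamic acceleration
#'
#' Splits each axis into a static (postural/gravitational) component — the
#' zero-phase low-pass filtered signal — and a dynamic component (raw minus
#' static) carrying the wing-beat oscillations.  A 4th-order Butterworth
#' filter run forward and backward (zero phase lag) is used; wing beats of
#' sulids sit at roughly 4-6 Hz, well above the 1 Hz default cutoff.
#'
#' @param surge_g,heave_g 16 Hz acceleration series in g (at least 4 s).
#' @param fs sampling rate, Hz.
#' @param cutoff_hz low-pass cutoff, Hz; must be below the Nyquist rate.
#' @return List with elements `static` and `dynamic`, each a list with
#'   `surge` and `heave`.
#' @export
separate_acceleration <- function(surge_g, heave_g, fs = 16, cutoff_hz = 1) {
  if (cutoff_hz >= fs / 2) stop("cutoff must be below the Nyquist rate")
  if (length(surge_g) < 4 * fs) stop("need at least 4 s of signal")
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  lp <- function(x) {
    mu <- mean(x)  # filter about the mean to suppress edge transients
    as.numeric(signal::filtfilt(bf, x - mu)) + mu
  }
  st <- list(surge = lp(surge_g), heave = lp(heave_g))
  list(static = st,
       dynamic = list(surge = surge_g - st$surge,
                      heave = heave_g - st$heave))
}

#' Detect dive events from a depth series
#'
#' Maximal runs of depth exceeding the threshold become dive events;
#' adjacent runs separated by less than `merge_gap_s` are merged (brief
#' near-surface moments within one dive).
#'
#' @param depth_m 1 Hz depth series, metres.
#' @param threshold_m dive threshold (default 0.2 m).
#' @param t0 time of the first sample, seconds.
#' @param merge_gap_s merge gap, seconds (default 2).
#' @return Data frame of dive events: `start_t`, `end_t`, `max_depth_m`,
#'   `type` (`NA` until [type_dives()] is applied).
#' @export
detect_dives <- function(depth_m, threshold_m = 0.2, t0 = 0, merge_gap_s = 2) {
  empty <- data.frame(start_t = numeric(0), end_t = numeric(0),
                      max_depth_m = numeric(0), type = character(0))
  wet <- depth_m > threshold_m
  if (!any(wet)) return(empty)
  r <- rle(wet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # merge short dry gaps between wet runs
  for (i in which(!r$values)) {
    if (i > 1 && i < length(r$values) && r$lengths[i] < merge_gap_s)
      r$values[i] <- TRUE
  }
  wet2 <- inverse.rle(r)
  r2 <- rle(wet2)
  ends2 <- cumsum(r2$lengths)
  starts2 <- ends2 - r2$lengths + 1L
  keep <- which(r2$values)
  data.frame(start_t = t0 + starts2[keep] - 1,
             end_t = t0 + starts2[keep] - 1 + r2$lengths[keep],
             max_depth_m = vapply(keep, function(i)
               max(depth_m[starts2[i]:ends2[i]]), numeric(1)),
             type = rep(NA_character_, length(keep)))
}

#' Correct slow depth-sensor drift
#'
#' Subtracts a surface baseline obtained as the block-wise minimum depth over
#' `window_s` windows, linearly interpolated between block centres.  The bird
#' returns to the surface many times per window, so the rolling minimum
#' tracks the sensor zero offset.
#'
#' @param depth_m 1 Hz depth series.
#' @param window_s baseline window, seconds (default 600).
#' @return Corrected depth series.
#' @export
correct_depth_offset <- function(depth_m, window_s = 600) {
  n <- length(depth_m)
  if (n <= window_s) return(depth_m - min(depth_m))
  starts <- seq(1L, n, by = window_s)
  mins <- vapply(starts, function(s) min(depth_m[s:min(n, s + window_s - 1L)]),
                 numeric(1))
  centres <- pmin(starts + window_s / 2, n)
  base <- stats::approx(centres, mins, xout = seq_len(n), rule = 2)$y
  depth_m - base
}

#' Classify per-second behaviour from logger signals
#'
#' Decodes the ethogram of a plunge-diving seabird: `DIVE` wherever depth
#' exceeds the dive threshold; otherwise `FLAP` where the dynamic heave RMS
#' over the second exceeds `flap_rms_g`; `GLIDE` for quiet seconds at the
#' surface within `flight_context_s` of flapping (the absence of wing-beat
#' oscillation inside a flight bout); `WATER` for quiet seconds without
#' flight context (sitting on the sea surface); the first `takeoff_s`
#' seconds of a flapping run that directly follows `WATER` or `LAND` are
#' relabelled `TAKEOFF`; declared on-land intervals override everything
#' with `LAND` (excluded from at-sea analyses downstream).
#'
#' @param record a [logger_record].
#' @param flap_rms_g flapping threshold on the per-second dynamic heave RMS
#'   (default 0.1 g).
#' @param dive_threshold_m dive threshold (default 0.2 m).
#' @param takeoff_s take-off window (default 3 s).
#' @param flight_context_s look-back horizon for flight context (default
#'   10 s).
#' @param land_intervals optional list of `c(start, end)` on-land intervals
#'   (seconds, half-open).
#' @param cutoff_hz low-pass cutoff handed to [separate_acceleration()].
#' @param offset_correct apply [correct_depth_offset()] first (default
#'   `FALSE`).
#' @return A `behaviour_series`: list with `t` (second marks), `states`
#'   (factor over `LAND,TAKEOFF,FLAP,GLIDE,WATER,DIVE`) and `trip_id`.
#' @export
classify_behaviour <- function(record, flap_rms_g = 0.1,
                               dive_threshold_m = 0.2, takeoff_s = 3,
                               flight_context_s = 10, land_intervals = NULL,
                               cutoff_hz = 1, offset_correct = FALSE) {
  stopifnot(inherits(record, "logger_record"))
  depth <- record$depth_m
  if (length(depth) == 0) stop("missing depth series")
  if (offset_correct) depth <- correct_depth_offset(depth)
  n <- length(depth)
  dyn <- separate_acceleration(record$surge_g, record$heave_g,
                               fs = record$acc_hz,
                               cutoff_hz = cutoff_hz)$dynamic$heave
  nn <- min(n, length(dyn) %/% record$acc_hz)
  m <- matrix(dyn[seq_len(nn * record$acc_hz)], nrow = record$acc_hz)
  rms <- sqrt(colMeans(m^2))
  if (nn < n) rms <- c(rms, rep(rms[nn], n - nn))
  flap <- rms > flap_rms_g
  # flight context: any flapping within the preceding flight_context_s seconds
  cs <- cumsum(as.numeric(flap))
  i <- seq_len(n)
  lo <- pmax(i - flight_context_s, 1L)
  prior_flap <- (c(0, cs)[i] - c(0, cs)[lo]) > 0
  states <- ifelse(flap, "FLAP",
                   ifelse(prior_flap & depth <= dive_threshold_m,
                          "GLIDE", "WATER"))
  states[depth > dive_threshold_m] <- "DIVE"
  # take-off: start of a flapping run directly after WATER/LAND
  fl <- states == "FLAP"
  r <- rle(fl)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    s <- starts[k]
    if (s > 1 && states[s - 1L] %in% c("WATER", "LAND")) {
      w <- s:min(ends[k], s + takeoff_s - 1L)
      states[w] <- "TAKEOFF"
    }
  }
  tt <- record$t0 + seq_len(n) - 1
  if (!is.null(land_intervals)) {
    for (iv in land_intervals)
      states[tt >= iv[1] & tt < iv[2]] <- "LAND"
  }
  structure(list(t = tt,
                 states = factor(states, levels = BEHAVIOUR_STATES),
                 trip_id = record$trip_id),
            class = "behaviour_series")
}

#' @export
print.behaviour_series <- function(x, ...) {
  tb <- table(x$states)
  cat(sprintf("<behaviour_series '%s': %d s | %s>\n", x$trip_id, length(x$t),
              paste(sprintf("%s %d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Type dives as plunge or surface dives
#'
#' A dive preceded by flight (`FLAP` or `GLIDE` within the `context_s`
#' seconds before its start) is a plunge dive; a dive entered from sitting
#' on the water is a surface dive.
#'
#' @param dives data frame from [detect_dives()].
#' @param behaviour a `behaviour_series` covering the dives.
#' @param context_s look-back window, seconds (default 10).
#' @return `dives` with the `type` column filled in.
#' @export
type_dives <- function(dives, behaviour, context_s = 10) {
  if (nrow(dives) == 0) return(dives)
  flight <- behaviour$states %in% c("FLAP", "GLIDE")
  dives$type <- vapply(dives$start_t, function(s) {
    w <- behaviour$t >= s - context_s & behaviour$t < s
    if (any(flight[w])) "plunge" else "surface"
  }, character(1))
  dives
}

#' Read a logger record from CSV files
#'
#' @param depth_file CSV with columns `t,depth_m` (1 Hz).
#' @param acc_file CSV with columns `t,surge_g,heave_g` (16 Hz).
#' @param trip_id trip identifier.
#' @return A [logger_record].
#' @export
read_logger_csv <- function(depth_file, acc_file, trip_id = NA_character_) {
  d <- data.table::fread(depth_file, data.table = FALSE)
  a <- data.table::fread(acc_file, data.table = FALSE)
  logger_record(d$depth_m, a$surge_g, a$heave_g, t0 = d$t[1],
                trip_id = trip_id)
}

#' Export an ethogram and dive list as CSV
#'
#' @param behaviour a `behaviour_series`.
#' @param file output CSV (`t,state`).
#' @param dives optional dive data frame written alongside.
#' @param dive_file CSV path for the dives.
#' @return `file`, invisibly.
#' @export
export_ethogram_csv <- function(behaviour, file, dives = NULL,
                                dive_file = NULL) {
  data.table::fwrite(data.frame(t = behaviour$t,
                                state = as.character(behaviour$states)), file)
  if (!is.null(dives) && !is.null(dive_file))
    data.table::fwrite(dives, dive_file)
  invisible(file)
}
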