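#' First-passage time at one path point
#'
#' Time the animal takes to cross a circle of radius `radius_km` centred on
#' path point `index`: the path is walked backward and forward from the point
#' until the distance from it first exceeds the radius; each crossing instant
#' is located by linear interpolation of the distance within the crossing
#' segment, and the first-passage time is their difference.  `NA` when the
#' track ends before crossing on either side — a value, not an error.
#'
#' This scalar function is the definitional reference; [fpt_profile()]
#' computes the whole point-by-radius matrix with a faster scan that is
#' tested equal to it.
#'
#' @param path an interpolated `planar_path` (see [interpolate_path()]).
#' @param index point index (1-based).
#' @param radius_km circle radius in km (> 0).
#' @return Duration in seconds, or `NA`.
#' @export
first_passage_time <- function(path, index, radius_km) {
  stopifnot(inherits(path, "planar_path"), radius_km > 0)
  pts <- path$points
  n <- nrow(pts)
  stopifnot(index >= 1, index <= n)
  x0 <- pts$x[index]; y0 <- pts$y[index]
  d <- sqrt((pts$x - x0)^2 + (pts$y - y0)^2)
  cross <- function(js) {
    dprev <- 0
    for (j in js) {
      if (d[j] > radius_km) {
        f <- (radius_km - dprev) / (d[j] - dprev)
        jprev <- if (j > index) j - 1L else j + 1L
        return(pts$t[jprev] + f * (pts$t[j] - pts$t[jprev]))
      }
      dprev <- d[j]
    }
    NA_real_
  }
  tf <- if (index < n) cross(seq(index + 1L, n)) else NA_real_
  tb <- if (index > 1) cross(seq(index - 1L, 1L)) else NA_real_
  if (is.na(tf) || is.na(tb)) return(NA_real_)
  tf - tb
}

#' First-passage time profile over a radius sweep
#'
#' Computes the full first-passage time matrix (path points by radii), the
#' per-radius variance of `ln(FPT)` over defined entries, and the ARS scale
#' (the radius of the maximum interior peak of that variance curve).  The
#' log transform makes the variance independent of the magnitude of the
#' passage times, so the curve reflects the spatial structure of the track
#' rather than overall speed.
#'
#' @param path an interpolated `planar_path`.
#' @param radii strictly increasing radius grid in km (default 0.1 to 25 km
#'   in 0.1 km increments).
#' @return An `fpt_profile`: list with `radii_km`, `fpt_s` (matrix, `NA`
#'   where undefined), `var_log` (`NA` where fewer than 2 defined entries)
#'   and `ars_scale_km` (`NA` when no interior peak exists).
#' @export
fpt_profile <- function(path, radii = seq(0.1, 25, by = 0.1)) {
  stopifnot(inherits(path, "planar_path"))
  if (path$step_km <= 0)
    stop("fpt_profile() expects an interpolated path; call interpolate_path() first")
  if (length(radii) == 0) stop("empty radius grid")
  if (any(radii <= 0) || any(diff(radii) <= 0))
    stop("radii must be positive and strictly increasing")
  pts <- path$points
  mat <- .fpt_matrix_cpp(pts$t, pts$x, pts$y, radii)
  vl <- apply(mat, 2, function(col) {
    v <- col[!is.na(col)]
    if (length(v) < 2L) NA_real_ else stats::var(log(v))
  })
  prof <- structure(list(radii_km = radii, fpt_s = mat, var_log = vl,
                         ars_scale_km = NA_real_, trip_id = path$trip_id),
                    class = "fpt_profile")
  prof$ars_scale_km <- ars_scale(prof)
  prof
}

#' @export
print.fpt_profile <- function(x, ...) {
  cat(sprintf("<fpt_profile '%s': %d points x %d radii (%.1f-%.1f km), ARS scale %s>\n",
              x$trip_id, nrow(x$fpt_s), length(x$radii_km), min(x$radii_km),
              max(x$radii_km),
              if (is.na(x$ars_scale_km)) "none"
              else sprintf("%.1f km", x$ars_scale_km)))
  invisible(x)
}

#' ARS scale from a first-passage time profile
#'
#' The radius at which the variance of `ln(FPT)` attains its global maximum,
#' provided that maximum is an interior local peak (strictly greater than
#' both grid neighbours; plateau ties resolve to the smaller radius).  A
#' monotone or all-undefined variance curve has no peak: the trip shows no
#' characteristic search scale and `NA` is returned.
#'
#' @param profile an `fpt_profile`.
#' @return Radius in km, or `NA` ("none").
#' @export
ars_scale <- function(profile) {
  stopifnot(inherits(profile, "fpt_profile"))
  ok <- !is.na(profile$var_log)
  v <- profile$var_log[ok]
  r <- profile$radii_km[ok]
  n <- length(v)
  if (n < 3L) return(NA_real_)
  m <- max(v)
  if (m <= min(v)) return(NA_real_)
  at_max <- which(v == m)
  # contiguous plateaus of the global maximum, earliest radius first
  grp <- cumsum(c(1L, diff(at_max) != 1L))
  for (g in unique(grp)) {
    i <- min(at_max[grp == g]); e <- max(at_max[grp == g])
    if (i > 1L && e < n && v[i - 1L] < m && v[e + 1L] < m) return(r[i])
  }
  NA_real_
}

#' Export a first-passage time profile
#'
#' Writes the variance-of-log curve (`radius_km,var_log`) and, if the
#' profile has an ARS scale, the FPT series at that scale
#' (`point_index,t,x,y,fpt_s`).
#'
#' @param profile an `fpt_profile`.
#' @param path the interpolated `planar_path` the profile was computed from.
#' @param file output CSV path for the variance curve.
#' @param series_file optional CSV path for the at-scale FPT series.
#' @return `file`, invisibly.
#' @export
export_fpt_csv <- function(profile, path, file, series_file = NULL) {
  utils::write.csv(data.frame(radius_km = profile$radii_km,
                              var_log = profile$var_log),
                   file, row.names = FALSE)
  if (!is.null(series_file) && !is.na(profile$ars_scale_km)) {
    j <- match(profile$ars_scale_km, profile$radii_km)
    pts <- path$points
    utils::write.csv(data.frame(point_index = seq_len(nrow(pts)),
                                t = pts$t, x = pts$x, y = pts$y,
                                fpt_s = profile$fpt_s[, j]),
                     series_file, row.names = FALSE)
  }
  invisible(file)
}
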